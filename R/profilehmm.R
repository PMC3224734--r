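#' Build a profile HMM from the seed alignment
#'
#' Alignment columns whose non-gap fraction reaches `occupancy_threshold`
#' become match states; anchor columns (F87, ExxR, Cys, RIS flanks) and SCR
#' boundary columns are force-included as match states regardless of
#' occupancy, so every annotated feature is always representable on a query.
#' Emission probabilities use a single-parameter background-weighted
#' pseudocount, `e(a) = (count(a) + alpha * q(a)) / (n_obs + alpha)`;
#' transitions are estimated from the observed state paths of the seed rows
#' with the same scheme (uniform prior over each state's allowed moves).
#' `X` residues occupy a column but contribute no emission count.
#'
#' @param seed A `cyp_seed`.
#' @param ann Its `cyp_seed_annotation`, or `NULL` for an un-annotated
#'   profile (no forced columns, no anchor states).
#' @param occupancy_threshold Match-state occupancy rule, in (0, 1];
#'   default 0.5, the classic profile-HMM convention.
#' @param pseudocount_alpha Total pseudocount mass `alpha >= 0`; default 1.
#' @param background Named length-20 residue frequency vector; default
#'   uniform (1/20).
#' @return A `cyp_profile`: match emissions (L x 20), transition
#'   probability vectors over nodes `0..L` (node 0 is the begin state),
#'   `source_columns`, `anchor_states`, `background`, build parameters.
#' @export
build_profile <- function(seed, ann = NULL, occupancy_threshold = 0.5,
                          pseudocount_alpha = 1, background = NULL) {
  stopifnot(occupancy_threshold > 0, occupancy_threshold <= 1,
            pseudocount_alpha >= 0)
  if (is.null(background)) background <- uniform_background()
  background <- background[AA20]
  stopifnot(abs(sum(background) - 1) < 1e-9)
  alpha <- pseudocount_alpha

  cmat <- do.call(rbind, strsplit(seed$rows, "", fixed = TRUE))
  n_rows <- nrow(cmat); nc <- ncol(cmat)
  occupied <- cmat != "-"
  occupancy <- colMeans(occupied)

  forced <- integer(0)
  if (!is.null(ann)) {
    forced <- sort(unique(c(ann$anchors, ann$ris1, ann$ris2,
                            ann$scrs$start_col, ann$scrs$end_col)))
    zero <- forced[colSums(occupied)[forced] == 0L]
    if (length(zero))
      stop("anchor/boundary column(s) with zero observed residues: ",
           paste(zero, collapse = ", "))
  }
  match_col <- occupancy >= occupancy_threshold
  match_col[forced] <- TRUE
  if (!any(match_col)) stop("no match columns at this occupancy threshold")
  source_columns <- which(match_col)
  L <- length(source_columns)

  # emissions
  E <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- cmat[, source_columns[k]]
    obs <- col[col %in% AA20]            # '-' and 'X' excluded
    cnt <- table(factor(obs, levels = AA20))
    E[k, ] <- (as.numeric(cnt) + alpha * background) / (length(obs) + alpha)
  }

  # transition counts along each row's path through the model
  node_of_col <- cumsum(match_col)       # node emitting/owning each column
  z <- numeric(L + 1)                    # index = node + 1
  cMM <- z; cMI <- z; cMD <- z; cIM <- z; cII <- z; cDM <- z; cDD <- z
  for (r in seq_len(n_rows)) {
    st <- "M"; node <- 0L
    for (c in seq_len(nc)) {
      if (match_col[c]) {
        k <- node_of_col[c]
        nxt <- if (occupied[r, c]) "M" else "D"
        key <- paste0(st, nxt)
        i <- node + 1L
        switch(key,
               MM = cMM[i] <- cMM[i] + 1, MD = cMD[i] <- cMD[i] + 1,
               IM = cIM[i] <- cIM[i] + 1, ID = {
                 # I -> D has no edge in this architecture; route via match
                 # cannot occur: insert runs sit between occupied columns of
                 # the same node, so the preceding state at a match column
                 # after inserts is I only when the row emitted inserts.
                 # Treat as I->M->D is not representable; count as M->D.
                 cMD[i] <- cMD[i] + 1
               },
               DM = cDM[i] <- cDM[i] + 1, DD = cDD[i] <- cDD[i] + 1)
        st <- nxt; node <- k
      } else if (occupied[r, c]) {
        i <- node + 1L
        if (st == "I") cII[i] <- cII[i] + 1
        else if (st == "M") cMI[i] <- cMI[i] + 1
        else {
          # delete -> insert has no edge either; absorb into M -> I
          cMI[i] <- cMI[i] + 1
        }
        st <- "I"
      }
    }
    i <- node + 1L                        # final transition into End
    if (st == "M") cMM[i] <- cMM[i] + 1
    else if (st == "I") cIM[i] <- cIM[i] + 1
    else cDM[i] <- cDM[i] + 1
  }

  est <- function(counts, prior) {
    tot <- sum(counts)
    p <- (counts + alpha * prior) / (tot + alpha)
    p / sum(p)
  }
  mm <- z; mi <- z; md <- z; im <- z; ii <- z; dm <- z; dd <- z
  for (k in 0:L) {
    i <- k + 1L
    if (k < L) {                          # M_k: {M, I, D}
      p <- est(c(cMM[i], cMI[i], cMD[i]), rep(1 / 3, 3))
      mm[i] <- p[1]; mi[i] <- p[2]; md[i] <- p[3]
    } else {                              # M_L: {End, I}
      p <- est(c(cMM[i], cMI[i]), rep(1 / 2, 2))
      mm[i] <- p[1]; mi[i] <- p[2]; md[i] <- 0
    }
    p <- est(c(cIM[i], cII[i]), rep(1 / 2, 2))   # I_k: {M, I}
    im[i] <- p[1]; ii[i] <- p[2]
    if (k >= 1) {
      if (k < L) {                        # D_k: {M, D}
        p <- est(c(cDM[i], cDD[i]), rep(1 / 2, 2))
        dm[i] <- p[1]; dd[i] <- p[2]
      } else { dm[i] <- 1; dd[i] <- 0 }   # D_L: {End}
    }
  }

  anchor_states <- integer(0)
  if (!is.null(ann)) {
    anchor_cols <- c(f87 = unname(ann$anchors["f87"]),
                     glu = unname(ann$anchors["glu"]),
                     arg = unname(ann$anchors["arg"]),
                     cys = unname(ann$anchors["cys"]),
                     ris1_left = unname(ann$ris1["left"]),
                     ris1_right = unname(ann$ris1["right"]),
                     ris2_left = unname(ann$ris2["left"]),
                     ris2_right = unname(ann$ris2["right"]))
    anchor_states <- setNames(match(anchor_cols, source_columns),
                              names(anchor_cols))
  }
  structure(list(
    n_match = L, source_columns = source_columns,
    match_emissions = E,
    transitions = list(mm = mm, mi = mi, md = md, im = im, ii = ii,
                       dm = dm, dd = dd),
    background = background, anchor_states = anchor_states,
    params = list(occupancy_threshold = occupancy_threshold,
                  pseudocount_alpha = alpha),
    n_seed_rows = n_rows, n_seed_columns = nc),
    class = "cyp_profile")
}

#' @export
print.cyp_profile <- function(x, ...) {
  cat(sprintf("<cyp_profile> %d match states (from %d seed rows x %d columns), %d anchors\n",
              x$n_match, x$n_seed_rows, x$n_seed_columns,
              length(x$anchor_states)))
  invisible(x)
}

# log2 transition vectors for the DP core; zeros become -Inf.
#' @noRd
profile_log_trans <- function(profile) {
  lapply(profile$transitions, function(v) {
    out <- suppressWarnings(log2(v))
    out[v <= 0] <- -Inf
    out
  })
}

#' Serialise a profile to versioned JSON
#'
#' Probabilities are written as decimal strings (`%.17g`) so that
#' [read_profile()] round-trips them bit-exactly.
#'
#' @param profile A `cyp_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  s <- function(x) sprintf("%.17g", x)
  obj <- list(
    format = "cypmod-profile", version = 1L,
    alphabet = AA20,
    n_match = profile$n_match,
    source_columns = profile$source_columns,
    background = s(unname(profile$background)),
    match_emissions = apply(profile$match_emissions, 2, s),
    transitions = lapply(profile$transitions, s),
    anchor_states = as.list(profile$anchor_states),
    params = profile$params,
    n_seed_rows = profile$n_seed_rows,
    n_seed_columns = profile$n_seed_columns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Profile JSON file.
#' @return A `cyp_profile`.
#' @export
read_profile <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cypmod-profile"))
    stop("not a cypmod profile: ", path)
  E <- apply(obj$match_emissions, 2, as.numeric)
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  colnames(E) <- AA20
  structure(list(
    n_match = obj$n_match, source_columns = obj$source_columns,
    match_emissions = E,
    transitions = lapply(obj$transitions, as.numeric),
    background = setNames(as.numeric(obj$background), AA20),
    anchor_states = unlist(obj$anchor_states),
    params = obj$params,
    n_seed_rows = obj$n_seed_rows, n_seed_columns = obj$n_seed_columns),
    class = "cyp_profile")
}
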