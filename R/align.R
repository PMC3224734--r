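#' Query-to-profile alignment and scoring
#'
#' Alignment is glocal: the model is traversed begin-to-end while the query
#' may carry unbounded N-/C-terminal flanks that emit at background odds
#' (0 bits), so full-length CYPs with variable termini — including fusion
#' proteins whose reductase domain simply falls into the C-flank — align
#' without penalty outside the modelled fold.  All arithmetic is in log2
#' space; Viterbi ties are broken Match > Delete > Insert (and, at the
#' model exit, toward the smallest number of consumed residues) so outputs
#' are bit-reproducible.
#'
#' @name align
NULL

#' @noRd
as_residue_string <- function(seq) {
  if (inherits(seq, "cyp_seq")) seq$residues else toupper(seq)
}

#' @noRd
query_id_of <- function(seq) if (inherits(seq, "cyp_seq")) seq$id else "query"

# L x N match-emission log2-odds matrix for a query; X scores 0 bits.
#' @noRd
emission_logodds <- function(profile, residues) {
  a <- chars(residues)
  N <- length(a)
  idx <- match(a, AA20)
  em <- matrix(0, profile$n_match, N)
  known <- !is.na(idx)
  if (any(known)) {
    em[, known] <- log2(profile$match_emissions[, idx[known], drop = FALSE])
    em[, known] <- sweep(em[, known, drop = FALSE], 2,
                         log2(profile$background[idx[known]]), `-`)
  }
  em
}

#' @noRd
check_fragment <- function(residues, min_len) {
  if (nchar(residues) < min_len)
    stop("fragment: query has ", nchar(residues), " residues, minimum is ",
         min_len, " (set min_len to override)")
}

#' Align a query sequence to a profile (Viterbi)
#'
#' @param profile A `cyp_profile`.
#' @param seq A [cyp_seq()] or residue string.
#' @param min_len Fragment guard: queries shorter than this are refused
#'   (default 50).
#' @return A `cyp_mapping`: `query_id`, `residues`, `assignments` (per
#'   match state the emitted 1-based query position, `NA` when deleted),
#'   `insertions` (list over nodes `0..L` of inserted query positions),
#'   `n_flank`, `c_flank`, `score_bits`.
#' @export
align_query <- function(profile, seq, min_len = 50) {
  residues <- as_residue_string(seq)
  check_fragment(residues, min_len)
  em <- emission_logodds(profile, residues)
  tr <- profile_log_trans(profile)
  v <- viterbi_glocal_cpp(em, tr$mm, tr$mi, tr$md, tr$im, tr$ii, tr$dm, tr$dd)
  ins <- rep(list(integer(0)), profile$n_match + 1L)
  if (length(v$ins_node)) {
    o <- order(v$ins_pos)
    for (j in o)
      ins[[v$ins_node[j] + 1L]] <- c(ins[[v$ins_node[j] + 1L]], v$ins_pos[j])
  }
  structure(list(query_id = query_id_of(seq), residues = residues,
                 assignments = v$assignments, insertions = ins,
                 n_flank = v$n_flank, c_flank = v$c_flank,
                 score_bits = v$score_bits),
            class = "cyp_mapping")
}

#' @export
print.cyp_mapping <- function(x, ...) {
  cat(sprintf("<cyp_mapping> %s: %d/%d match states emitted, %d inserted, score %.2f bits\n",
              x$query_id, sum(!is.na(x$assignments)), length(x$assignments),
              sum(lengths(x$insertions)), x$score_bits))
  invisible(x)
}

#' Forward (all-paths) log-odds score in bits
#'
#' Always at least the Viterbi `score_bits` of [align_query()]; used by the
#' applicability gate.
#'
#' @inheritParams align_query
#' @return Log2-odds of the sum over all glocal paths, in bits.
#' @export
forward_score <- function(profile, seq, min_len = 50) {
  residues <- as_residue_string(seq)
  check_fragment(residues, min_len)
  em <- emission_logodds(profile, residues)
  tr <- profile_log_trans(profile)
  forward_glocal_cpp(em, tr$mm, tr$mi, tr$md, tr$im, tr$ii, tr$dm, tr$dd)
}

#' Sample a sequence (and its generating path) from a profile
#'
#' `faithful` mode samples states and emissions according to the model
#' probabilities; `mainline` forces the all-match path (one residue per
#' match state, no indels).  No flanks are generated.  The returned mapping
#' is the generating truth, so recovery of known paths can be tested.
#'
#' @param profile A `cyp_profile`.
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param mode `"faithful"` or `"mainline"`.
#' @param id Identifier for the emitted sequence.
#' @return List with `seq` (a [cyp_seq()], or `NULL` for the rare
#'   all-delete path that emits nothing) and `mapping` (a `cyp_mapping`
#'   with `score_bits = NA`).
#' @export
sample_path <- function(profile, rng_seed, mode = c("faithful", "mainline"),
                        id = "sampled") {
  mode <- match.arg(mode)
  L <- profile$n_match
  tr <- profile$transitions
  with_seed(rng_seed, {
    res <- character(0)
    assignments <- rep(NA_integer_, L)
    ins <- rep(list(integer(0)), L + 1L)
    state <- "M"; node <- 0L
    repeat {
      i <- node + 1L
      if (mode == "mainline") nxt <- "M"
      else nxt <- switch(state,
        M = sample(c("M", "I", "D"), 1L,
                   prob = c(tr$mm[i], tr$mi[i], tr$md[i])),
        I = sample(c("M", "I"), 1L, prob = c(tr$im[i], tr$ii[i])),
        D = sample(c("M", "D"), 1L, prob = c(tr$dm[i], tr$dd[i])))
      if (nxt == "I") {
        res <- c(res, sample(AA20, 1L, prob = profile$background))
        ins[[i]] <- c(ins[[i]], length(res))
        state <- "I"
      } else {
        if (node == L) break               # into End
        node <- node + 1L
        if (nxt == "M") {
          res <- c(res, sample(AA20, 1L,
                               prob = profile$match_emissions[node, ]))
          assignments[node] <- length(res)
        }
        state <- nxt
      }
    }
    # an all-delete path emits nothing; seq is NULL then
    seq <- if (length(res)) cyp_seq(id, paste(res, collapse = "")) else NULL
    mapping <- structure(list(query_id = id,
                              residues = if (length(res))
                                seq$residues else "",
                              assignments = assignments, insertions = ins,
                              n_flank = 0L, c_flank = 0L,
                              score_bits = NA_real_),
                         class = "cyp_mapping")
    list(seq = seq, mapping = mapping)
  })
}
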