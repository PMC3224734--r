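#' Parameters for the synthetic seed/query generator
#'
#' The generator emulates an annotated structure-based CYP seed alignment:
#' conserved SCR blocks separated by variable linkers, an ExxR pair and an
#' invariant cysteine at fixed anchor columns, a fully occupied
#' F87-equivalent column drawn from the published composition of that
#' position (F 22%, L 22%, V 12%, I 10%, A 9%, remainder spread over the
#' other residues), and class-conditional variable-length RIS insertions
#' using the published length bands (class I: 3–5 and 3–5; class II: 21–22
#' and 11–17; reductase-independent class II subgroup: RIS2 18–23).
#'
#' @param n_rows Seed rows (default 20).
#' @param n_scrs Number of SCR blocks (default 19; at least 16 so the
#'   anchor-bearing blocks exist).
#' @param scr_len_range SCR block length range (default 6–14 columns;
#'   minimum 4 so the ExxR block fits).
#' @param scr_conservation Probability mass on the consensus residue per
#'   SCR column, in (0, 1]; default 1 (fully conserved core).
#' @param linker_len_range Per-row length range of the variable linkers
#'   (default 2–8 residues).
#' @param anchor_flank Number of conserved, fully occupied columns on each
#'   side of the F87 column inside the BC-loop block (default 5).  These
#'   model the informative match columns that bracket the hotspot in the
#'   real profile; without them the anchor position would be
#'   unidentifiable inside a random loop.
#' @param class_mix Fractions over `classI`, `classII`,
#'   `classII_verylongRIS2`; default mirrors the composition of the
#'   structure set the published seed was built from.
#' @param ris_length_bands Per class, per RIS, inclusive integer range.
#' @param anchor_distribution Residue frequencies at the F87 column.
#' @param rng_seed Integer seed.
#' @return A `cyp_generator_params` list.
#' @export
generator_params <- function(n_rows = 20, n_scrs = 19,
                             scr_len_range = c(6, 14),
                             scr_conservation = 1.0,
                             linker_len_range = c(2, 8),
                             anchor_flank = 5,
                             class_mix = c(classI = 0.5, classII = 0.4,
                                           classII_verylongRIS2 = 0.1),
                             ris_length_bands = NULL,
                             anchor_distribution = NULL,
                             rng_seed = 42) {
  if (is.null(ris_length_bands))
    ris_length_bands <- list(
      classI = list(RIS1 = c(3, 5), RIS2 = c(3, 5)),
      classII = list(RIS1 = c(21, 22), RIS2 = c(11, 17)),
      classII_verylongRIS2 = list(RIS1 = c(21, 22), RIS2 = c(18, 23)))
  if (is.null(anchor_distribution)) {
    anchor_distribution <- setNames(rep(0.25 / 15, 20), AA20)
    anchor_distribution[c("F", "L", "V", "I", "A")] <-
      c(0.22, 0.22, 0.12, 0.10, 0.09)
  }
  stopifnot(n_rows >= 2, n_scrs >= 16,
            scr_len_range[1] >= 4, scr_len_range[1] <= scr_len_range[2],
            scr_conservation > 0, scr_conservation <= 1,
            linker_len_range[1] >= 0, anchor_flank >= 0,
            abs(sum(class_mix) - 1) < 1e-9,
            abs(sum(anchor_distribution) - 1) < 1e-9)
  structure(list(n_rows = n_rows, n_scrs = n_scrs,
                 scr_len_range = scr_len_range,
                 scr_conservation = scr_conservation,
                 linker_len_range = linker_len_range,
                 anchor_flank = anchor_flank,
                 class_mix = class_mix,
                 ris_length_bands = ris_length_bands,
                 anchor_distribution = anchor_distribution,
                 rng_seed = rng_seed),
            class = "cyp_generator_params")
}

# Fixed topology: which SCR block carries what.  Mirrors the CYP fold
# qualitatively (BC-loop after the alphaB-containing block, RIS1 after the
# alphaI/alphaJ block, ExxR ahead of the meander, RIS2 just before the
# Cys-pocket block) without claiming the real column spans.
#' @noRd
syn_topology <- function(n_scrs) {
  list(bc_after = 3L,      # BC-loop (with the F87 column) follows SCR3
       ris1_after = 11L,   # RIS1 between SCR11 and SCR12
       exxr_in = 14L,      # ExxR at the start of SCR14
       ris2_after = 15L,   # RIS2 between SCR15 and SCR16 (Cys-pocket)
       cys_in = 16L)
}

# Build the column blueprint: block list with types scr/linker/bc/ris and
# widths, plus consensus residues for SCR columns.
#' @noRd
syn_blueprint <- function(params) {
  topo <- syn_topology(params$n_scrs)
  max_ris1 <- max(vapply(params$ris_length_bands, function(b) b$RIS1[2], 1))
  max_ris2 <- max(vapply(params$ris_length_bands, function(b) b$RIS2[2], 1))
  scr_lens <- sample(params$scr_len_range[1]:params$scr_len_range[2],
                     params$n_scrs, replace = TRUE)
  # the Cys-pocket block carries the canonical FxxGxxxCxG signature
  scr_lens[topo$cys_in] <- max(scr_lens[topo$cys_in], 10L)
  blocks <- list(list(type = "linker", width = params$linker_len_range[2]))
  for (s in seq_len(params$n_scrs)) {
    cons <- sample(AA20, scr_lens[s], replace = TRUE)
    if (s == topo$exxr_in) { cons[1] <- "E"; cons[4] <- "R" }
    if (s == topo$cys_in) {
      cons[1] <- "F"; cons[4] <- "G"; cons[8] <- "C"; cons[10] <- "G"
    }
    blocks[[length(blocks) + 1L]] <-
      list(type = "scr", scr = s, width = scr_lens[s], consensus = cons)
    after <- if (s == params$n_scrs) "linker"
             else if (s == topo$bc_after) "bc"
             else if (s == topo$ris1_after) "ris1"
             else if (s == topo$ris2_after) "ris2"
             else "linker"
    width <- switch(after,
                    linker = params$linker_len_range[2],
                    bc = 2L * (params$linker_len_range[2] +
                               params$anchor_flank) + 1L,
                    ris1 = max_ris1, ris2 = max_ris2)
    blk <- list(type = after, width = width)
    if (after == "bc") {
      blk$flank_left <- sample(AA20, params$anchor_flank, replace = TRUE)
      blk$flank_right <- sample(AA20, params$anchor_flank, replace = TRUE)
    }
    blocks[[length(blocks) + 1L]] <- blk
  }
  # variable-region draws exclude the consensus residues of the adjacent
  # SCR boundary columns (and, in the BC block, the inner flank residues):
  # a variable residue equal to a boundary consensus would make the
  # alignment-derived interval genuinely ambiguous, defeating ground truth.
  for (i in seq_along(blocks)) {
    if (blocks[[i]]$type == "scr") next
    excl <- character(0)
    if (i > 1L) excl <- c(excl, utils::tail(blocks[[i - 1L]]$consensus, 1))
    if (i < length(blocks))
      excl <- c(excl, blocks[[i + 1L]]$consensus[1])
    if (blocks[[i]]$type == "bc")
      excl <- c(excl, blocks[[i]]$flank_left[1],
                utils::tail(blocks[[i]]$flank_right, 1))
    blocks[[i]]$allowed <- setdiff(AA20, excl)
  }
  list(blocks = blocks, topo = topo)
}

#' Generate a synthetic annotated seed alignment with ground truth
#'
#' Every generated alignment satisfies the seed-annotation schema: all rows
#' carry E/R at the ExxR columns and C at the Cys column, the F87 column is
#' fully occupied, the RIS blocks are left-justified class-conditional
#' insertions padded with gaps, and [load_seed()]-level invariants hold.
#' Output is reproducible per `rng_seed`.
#'
#' @param params A [generator_params()].
#' @return List `seed` (a `cyp_seed`), `annotation`
#'   (a `cyp_seed_annotation`), `truth` (data frame: `id`, `class`,
#'   `anchor_pos`, `anchor_res`, `ris1_len`, `ris2_len`), `scr_truth`
#'   (per-row list of SCR intervals in that row's own degapped
#'   coordinates) and `blueprint` (consumed by [generate_queries()]).
#' @export
generate_seed <- function(params = generator_params()) {
  with_seed(params$rng_seed, {
    bp <- syn_blueprint(params)
    n <- params$n_rows
    ids <- sprintf("syn%02d", seq_len(n))
    classes <- sample(names(params$class_mix), n, replace = TRUE,
                      prob = params$class_mix)
    rows <- character(n)
    truth <- data.frame(id = ids, class = classes,
                        anchor_pos = NA_integer_, anchor_res = NA_character_,
                        ris1_len = NA_integer_, ris2_len = NA_integer_,
                        stringsAsFactors = FALSE)
    scr_truth <- setNames(vector("list", n), ids)
    lr <- params$linker_len_range
    rlen <- function(range) sample(range[1]:range[2], 1L)
    for (r in seq_len(n)) {
      cells <- character(0)
      pos <- 0L                      # degapped position so far
      scrs_r <- list()
      for (b in bp$blocks) {
        if (b$type == "scr") {
          keep <- runif(b$width) <= params$scr_conservation
          res <- ifelse(keep, b$consensus,
                        sample(AA20, b$width, replace = TRUE))
          # invariant anchors never mutate
          if (b$scr == bp$topo$exxr_in) { res[1] <- "E"; res[4] <- "R" }
          if (b$scr == bp$topo$cys_in) res[8] <- "C"
          cells <- c(cells, res)
          scrs_r[[paste0("SCR", b$scr)]] <- c(start = pos + 1L,
                                              end = pos + b$width)
          pos <- pos + b$width
        } else if (b$type == "bc") {
          wa <- rlen(lr); wb <- rlen(lr)
          fl <- length(b$flank_left)
          varw <- (b$width - 1L) %/% 2L - fl
          mut <- function(cons) {
            keep <- runif(length(cons)) <= params$scr_conservation
            ifelse(keep, cons, sample(AA20, length(cons), replace = TRUE))
          }
          anchor_res <- sample(AA20, 1L, prob = params$anchor_distribution)
          seg <- c(sample(b$allowed, wa, replace = TRUE),
                   rep("-", varw - wa),
                   mut(b$flank_left), anchor_res, mut(b$flank_right),
                   sample(b$allowed, wb, replace = TRUE),
                   rep("-", varw - wb))
          cells <- c(cells, seg)
          pos <- pos + wa + fl + 1L
          truth$anchor_pos[r] <- pos
          truth$anchor_res[r] <- anchor_res
          pos <- pos + fl + wb
        } else {
          w <- if (b$type == "linker") rlen(lr)
               else rlen(params$ris_length_bands[[classes[r]]][[
                 if (b$type == "ris1") "RIS1" else "RIS2"]])
          cells <- c(cells, sample(b$allowed, w, replace = TRUE),
                     rep("-", b$width - w))
          pos <- pos + w
          if (b$type == "ris1") truth$ris1_len[r] <- w
          if (b$type == "ris2") truth$ris2_len[r] <- w
        }
      }
      rows[r] <- paste(cells, collapse = "")
      scr_truth[[r]] <- scrs_r
    }
    # column bookkeeping for the annotation
    widths <- as.integer(vapply(bp$blocks, function(b) b$width, 1))
    ends <- cumsum(widths)
    starts <- ends - widths + 1L
    types <- vapply(bp$blocks, `[[`, "", "type")
    scr_idx <- which(types == "scr")
    scrs <- data.frame(
      name = paste0("SCR", seq_along(scr_idx)),
      start_col = starts[scr_idx], end_col = ends[scr_idx],
      content = "", stringsAsFactors = FALSE)
    bc_block <- which(types == "bc")
    f87_col <- starts[bc_block] + (widths[bc_block] - 1L) %/% 2L
    exxr_start <- starts[scr_idx[bp$topo$exxr_in]]
    cys_col <- starts[scr_idx[bp$topo$cys_in]] + 7L
    ann <- structure(list(
      scrs = scrs,
      anchors = c(f87 = f87_col, glu = exxr_start, arg = exxr_start + 3L,
                  cys = cys_col),
      ris1 = c(left = scrs$end_col[bp$topo$ris1_after],
               right = scrs$start_col[bp$topo$ris1_after + 1L]),
      ris2 = c(left = scrs$end_col[bp$topo$ris2_after],
               right = scrs$start_col[bp$topo$ris2_after + 1L]),
      class_labels = setNames(classes, ids)),
      class = "cyp_seed_annotation")
    seed <- new_seed(ids, rows, ids[1], setNames(classes, ids))
    problems <- check_seed_structure(seed, ann)
    if (length(problems))
      stop("internal: generated seed violates schema:\n  ",
           paste(problems, collapse = "\n  "))
    list(seed = seed, annotation = ann, truth = truth,
         scr_truth = scr_truth,
         blueprint = list(blocks = bp$blocks, topo = bp$topo,
                          params = params))
  })
}

#' Generate annotated query sequences with ground truth
#'
#' Queries are plain (ungapped) sequences emitted from the blueprint of a
#' generated seed: SCR residues follow the seed consensus at the seed's
#' conservation level, the F87-equivalent residue is drawn from the anchor
#' distribution, RIS insert lengths are class-conditional, and linkers are
#' background residues of random length.  `indel_rate` adds point
#' insertions/deletions inside the non-RIS linkers only, so the recorded
#' truth stays exact.
#'
#' @param seed_bundle The list returned by [generate_seed()].
#' @param n Number of queries.
#' @param class_mix Fractions over the three generating classes; defaults
#'   to the seed's mix.
#' @param indel_rate Per-linker-residue indel probability in \[0, 0.2\].
#' @param rng_seed Integer seed.
#' @return List `queries` (list of [cyp_seq()]), `truth` (data frame as in
#'   [generate_seed()]) and `scr_truth`.
#' @export
generate_queries <- function(seed_bundle, n, class_mix = NULL,
                             indel_rate = 0, rng_seed = 1) {
  stopifnot(indel_rate >= 0, indel_rate <= 0.2)
  bp <- seed_bundle$blueprint
  params <- bp$params
  if (is.null(class_mix)) class_mix <- params$class_mix
  with_seed(rng_seed, {
    ids <- sprintf("query%04d", seq_len(n))
    classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    queries <- vector("list", n)
    truth <- data.frame(id = ids, class = classes,
                        anchor_pos = NA_integer_, anchor_res = NA_character_,
                        ris1_len = NA_integer_, ris2_len = NA_integer_,
                        stringsAsFactors = FALSE)
    scr_truth <- setNames(vector("list", n), ids)
    lr <- params$linker_len_range
    rlen <- function(range) sample(range[1]:range[2], 1L)
    emit_linker <- function(w, allowed) {
      res <- sample(allowed, w, replace = TRUE)
      if (indel_rate > 0 && w > 0) {
        res <- res[runif(w) >= indel_rate / 2]                 # deletions
        k <- sum(runif(length(res) + 1L) < indel_rate / 2)     # insertions
        if (k) res <- append(res, sample(allowed, k, replace = TRUE),
                             after = sample(0:length(res), 1L))
      }
      res
    }
    for (q in seq_len(n)) {
      res <- character(0)
      scrs_q <- list()
      for (b in bp$blocks) {
        if (b$type == "scr") {
          keep <- runif(b$width) <= params$scr_conservation
          seg <- ifelse(keep, b$consensus,
                        sample(AA20, b$width, replace = TRUE))
          if (b$scr == bp$topo$exxr_in) { seg[1] <- "E"; seg[4] <- "R" }
          if (b$scr == bp$topo$cys_in) seg[8] <- "C"
          scrs_q[[paste0("SCR", b$scr)]] <-
            c(start = length(res) + 1L, end = length(res) + b$width)
          res <- c(res, seg)
        } else if (b$type == "bc") {
          mut <- function(cons) {
            keep <- runif(length(cons)) <= params$scr_conservation
            ifelse(keep, cons, sample(AA20, length(cons), replace = TRUE))
          }
          res <- c(res, emit_linker(rlen(lr), b$allowed),
                   mut(b$flank_left))
          anchor_res <- sample(AA20, 1L, prob = params$anchor_distribution)
          res <- c(res, anchor_res)
          truth$anchor_pos[q] <- length(res)
          truth$anchor_res[q] <- anchor_res
          res <- c(res, mut(b$flank_right),
                   emit_linker(rlen(lr), b$allowed))
        } else if (b$type %in% c("ris1", "ris2")) {
          band <- params$ris_length_bands[[classes[q]]][[
            if (b$type == "ris1") "RIS1" else "RIS2"]]
          w <- rlen(band)
          res <- c(res, sample(b$allowed, w, replace = TRUE))
          if (b$type == "ris1") truth$ris1_len[q] <- w
          else truth$ris2_len[q] <- w
        } else {
          res <- c(res, emit_linker(rlen(lr), b$allowed))
        }
      }
      queries[[q]] <- cyp_seq(ids[q], paste(res, collapse = ""))
      scr_truth[[q]] <- scrs_q
    }
    list(queries = queries, truth = truth, scr_truth = scr_truth)
  })
}
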