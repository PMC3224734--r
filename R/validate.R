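#' Compare a true and a predicted anchor position
#'
#' @param true_pos,predicted_pos 1-based positions, or `NA` for a gap.
#' @return One of `"exact"`, `"deviation_1"`, `"deviation_2"`, `"wrong"`,
#'   `"gap"` (the latter when either side is a gap).
#' @export
compare_positions <- function(true_pos, predicted_pos) {
  if (is.na(true_pos) || is.na(predicted_pos)) return("gap")
  if (true_pos < 1 || predicted_pos < 1) stop("positions must be positive")
  d <- abs(true_pos - predicted_pos)
  if (d == 0) "exact"
  else if (d <= 2) paste0("deviation_", d)
  else "wrong"
}

#' Leave-one-out cross-validation of anchor-position prediction
#'
#' For every non-reference seed row: drop the row from the (fixed)
#' alignment, rebuild the profile from the remaining rows with identical
#' parameters, align the dropped row's degapped sequence and predict the
#' F87-equivalent position; compare it to the row's true position, i.e.
#' the degapped position of its residue at the annotated anchor column
#' (a gap there is a true gap).  The reference row is never held out
#' because column-to-reference bookkeeping depends on it.
#'
#' @param seed A `cyp_seed` with at least 3 rows.
#' @param ann Its `cyp_seed_annotation`.
#' @param occupancy_threshold,pseudocount_alpha,background Profile build
#'   parameters, applied identically in every fold.
#' @param min_len Fragment guard for the per-fold alignment (default 1:
#'   held-out rows are trusted full sequences).
#' @return A `cyp_loo_report`: `outcomes` data frame (`row_id`,
#'   `true_position`, `predicted_position`, `category`), `accuracy_exact`,
#'   `accuracy_within_2`, `n_folds`.
#' @export
leave_one_out <- function(seed, ann, occupancy_threshold = 0.5,
                          pseudocount_alpha = 1, background = NULL,
                          min_len = 1) {
  if (length(seed$ids) < 3L) stop("leave-one-out needs at least 3 seed rows")
  held <- setdiff(seed$ids, seed$reference_id)
  outcomes <- vector("list", length(held))
  for (i in seq_along(held)) {
    id <- held[i]
    row <- seed_row(seed, id)
    rc <- chars(row)
    true_pos <- if (rc[ann$anchors["f87"]] == "-") NA_integer_
                else sum(rc[seq_len(ann$anchors["f87"])] != "-")
    fold_seed <- drop_seed_row(seed, id)
    pred <- tryCatch({
      prof <- build_profile(fold_seed, ann,
                            occupancy_threshold = occupancy_threshold,
                            pseudocount_alpha = pseudocount_alpha,
                            background = background)
      mapping <- align_query(prof, cyp_seq(id, degap(row)),
                             min_len = min_len)
      mapping$assignments[prof$anchor_states[["f87"]]]
    }, error = function(e) NA_integer_)  # e.g. sole observer of an anchor
    outcomes[[i]] <- data.frame(
      row_id = id, true_position = true_pos, predicted_position = pred,
      category = compare_positions(true_pos, pred),
      stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, outcomes)
  structure(list(
    outcomes = outcomes,
    accuracy_exact = mean(outcomes$category == "exact"),
    accuracy_within_2 = mean(outcomes$category %in%
                               c("exact", "deviation_1", "deviation_2")),
    n_folds = nrow(outcomes)),
    class = "cyp_loo_report")
}

#' @export
print.cyp_loo_report <- function(x, ...) {
  cat(sprintf("<cyp_loo_report> %d folds: exact %.1f%%, within 2 residues %.1f%%\n",
              x$n_folds, 100 * x$accuracy_exact, 100 * x$accuracy_within_2))
  invisible(x)
}
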