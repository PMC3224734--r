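#' Default residue grouping for anchor-position composition
#'
#' The published composition summary pools aliphatic residues with
#' phenylalanine, small polar residues and charged residues; the exact
#' memberships are not enumerated there, so this grouping is one documented
#' interpretation and fully configurable.
#'
#' @return Named list of residue character vectors.
#' @export
default_residue_groups <- function() {
  list(`aliphatic+F` = c("G", "A", "V", "L", "I", "P", "M", "F"),
       `small polar` = c("S", "T", "C", "N", "Q", "Y", "W", "H"),
       charged      = c("D", "E", "K", "R"))
}

#' Amino-acid composition at the F87-equivalent position
#'
#' Tabulates the residue called at the anchor across a batch of annotation
#' results; gap calls are counted under `-`.
#'
#' @param results Non-empty list of [annotate_sequence()] results.
#' @param groups Named list of residue groups (each residue in at most
#'   one group); default [default_residue_groups()].
#' @return A `cyp_composition`: `freq` (named fractions over residues
#'   seen plus `-`, summing to 1), `group_freq` (summed fractions per
#'   group), `n`.
#' @export
composition_at_anchor <- function(results, groups = default_residue_groups()) {
  if (!length(results)) stop("no results")
  all_members <- unlist(groups)
  if (anyDuplicated(all_members))
    stop("a residue appears in more than one group")
  res <- vapply(results, function(r) r$f87_call$residue, "")
  tab <- table(res)
  freq <- as.numeric(tab) / length(res)
  names(freq) <- names(tab)
  group_freq <- vapply(groups, function(g) sum(freq[names(freq) %in% g]), 0)
  structure(list(freq = freq, group_freq = group_freq, n = length(res)),
            class = "cyp_composition")
}

#' @export
print.cyp_composition <- function(x, ...) {
  cat("<cyp_composition> n =", x$n, "\n")
  f <- sort(x$freq, decreasing = TRUE)
  cat(" ", paste(sprintf("%s:%.3f", names(f), f), collapse = " "), "\n")
  cat("  groups:",
      paste(sprintf("%s:%.3f", names(x$group_freq), x$group_freq),
            collapse = "  "), "\n")
  invisible(x)
}

#' @noRd
ris_band_of <- function(len, which, t) {
  if (len >= t$unusual_min) return("above35")
  if (which == "RIS1") {
    if (len <= t$ris1_short_max) "short"
    else if (len >= t$ris1_long_min) "long"
    else "ambiguous"
  } else {
    if (len <= t$ris2_short_max) "short"
    else if (len >= t$ris2_verylong_min) "very_long"
    else if (len >= t$ris2_long_lo) "long"
    else "ambiguous"
  }
}

#' RIS length distribution and band fractions over a batch
#'
#' Per-length histogram plus the fraction of entries in each length band
#' (short / ambiguous / long / very long / above 35).  Undefined lengths
#' are excluded from the fractions and reported separately.
#'
#' @param results Non-empty list of [annotate_sequence()] results.
#' @param which `"RIS1"` or `"RIS2"`.
#' @param thresholds A [class_thresholds()].
#' @return A `cyp_ris_distribution`: `histogram` (table over lengths),
#'   `fractions` (named, over defined entries), `n`, `n_undefined`.
#' @export
ris_distribution <- function(results, which = c("RIS1", "RIS2"),
                             thresholds = class_thresholds()) {
  which <- match.arg(which)
  if (!length(results)) stop("no results")
  lens <- vapply(results, function(r)
    as.integer(if (which == "RIS1") r$ris1_len else r$ris2_len), 1L)
  defined <- lens[!is.na(lens)]
  bands <- c("short", "ambiguous", "long", "very_long", "above35")
  if (length(defined)) {
    band <- vapply(defined, ris_band_of, "", which = which, t = thresholds)
    fractions <- vapply(bands, function(b) mean(band == b), 0)
    histogram <- table(defined)
  } else {
    fractions <- setNames(rep(NA_real_, length(bands)), bands)
    histogram <- table(integer(0))
  }
  structure(list(which = which, histogram = histogram,
                 fractions = fractions, n = length(lens),
                 n_undefined = sum(is.na(lens))),
            class = "cyp_ris_distribution")
}

#' @export
print.cyp_ris_distribution <- function(x, ...) {
  cat(sprintf("<cyp_ris_distribution> %s over %d entries (%d undefined)\n",
              x$which, x$n, x$n_undefined))
  cat("  ", paste(sprintf("%s:%.3f", names(x$fractions), x$fractions),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Combined redox-class fractions over a batch
#'
#' @param results Non-empty list of [annotate_sequence()] results.
#' @return Named fractions over the six redox-class labels.
#' @export
class_fractions <- function(results) {
  if (!length(results)) stop("no results")
  cls <- vapply(results, `[[`, "", "redox_class")
  levels <- c("classI", "classII", "classII_verylongRIS2", "ambiguous",
              "discordant", "unusual_flagged")
  vapply(setNames(levels, levels), function(l) mean(cls == l), 0)
}
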