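#' Redox-class length thresholds
#'
#' The published length bands for the two reductase interaction sites:
#' RIS1 (alphaJ/J' region) short below 10 residues, long above 15, with
#' 10–15 unassignable; RIS2 (meander insertion) short below 7, long 11–17,
#' very long from 18, with 7–10 unassignable; either site above 35 residues
#' is formally class II but flagged unusual.
#'
#' @param ris1_short_max,ris1_long_min RIS1 band edges (default 9, 16).
#' @param ris2_short_max,ris2_long_lo,ris2_long_hi,ris2_verylong_min RIS2
#'   band edges (default 6, 11, 17, 18).
#' @param unusual_min Flagging threshold for either site (default 36).
#' @return A `cyp_thresholds` list.
#' @export
class_thresholds <- function(ris1_short_max = 9, ris1_long_min = 16,
                             ris2_short_max = 6, ris2_long_lo = 11,
                             ris2_long_hi = 17, ris2_verylong_min = 18,
                             unusual_min = 36) {
  stopifnot(ris1_short_max < ris1_long_min,
            ris2_short_max < ris2_long_lo,
            ris2_long_lo <= ris2_long_hi,
            ris2_long_hi < ris2_verylong_min)
  structure(list(ris1_short_max = ris1_short_max,
                 ris1_long_min = ris1_long_min,
                 ris2_short_max = ris2_short_max,
                 ris2_long_lo = ris2_long_lo,
                 ris2_long_hi = ris2_long_hi,
                 ris2_verylong_min = ris2_verylong_min,
                 unusual_min = unusual_min),
            class = "cyp_thresholds")
}

#' Transfer SCR intervals onto a query
#'
#' For each SCR, the interval start is the query position of the first
#' non-deleted match state whose source column lies inside the SCR span,
#' and the end the last such; an SCR whose match states are all deleted is
#' reported absent (`NA`).
#'
#' @param mapping A `cyp_mapping` from [align_query()] on `profile`.
#' @param ann The seed annotation the profile was built with.
#' @param profile The `cyp_profile`.
#' @return Named list, one `c(start, end)` (1-based, inclusive, query
#'   coordinates) or `c(NA, NA)` per SCR.
#' @export
transfer_scrs <- function(mapping, ann, profile) {
  out <- vector("list", nrow(ann$scrs))
  names(out) <- ann$scrs$name
  for (i in seq_len(nrow(ann$scrs))) {
    states <- which(profile$source_columns >= ann$scrs$start_col[i] &
                    profile$source_columns <= ann$scrs$end_col[i])
    pos <- mapping$assignments[states]
    pos <- pos[!is.na(pos)]
    out[[i]] <- if (length(pos)) c(start = min(pos), end = max(pos))
                else c(start = NA_integer_, end = NA_integer_)
  }
  out
}

#' Predict the F87-equivalent substrate-specificity position
#'
#' Returns the query position and residue emitted at the F87 anchor state,
#' or a gap call when that state is deleted — a predicted gap indicates
#' that the BC-loop houses no residue close to the heme.
#'
#' @inheritParams transfer_scrs
#' @return List `pos` (1-based query position or `NA`) and `residue`
#'   (single letter, or `"-"` for a gap call).
#' @export
predict_f87 <- function(mapping, profile) {
  k <- profile$anchor_states[["f87"]]
  pos <- mapping$assignments[k]
  if (is.na(pos)) list(pos = NA_integer_, residue = "-")
  else list(pos = pos, residue = substr(mapping$residues, pos, pos))
}

#' Measure a reductase-interaction-site length on a query
#'
#' The RIS length is the number of query residues strictly between the two
#' anchor states (the terminal match states of the flanking SCRs):
#' `pos(right) - pos(left) - 1`, counting both match-emitted residues and
#' insertions.  A deleted anchor state is substituted by the nearest
#' emitting match state inward within its flanking SCR; if a flanking SCR
#' is entirely deleted the length is undefined (`NA`).
#'
#' @inheritParams transfer_scrs
#' @param which `"RIS1"` or `"RIS2"`.
#' @return Non-negative integer length, or `NA` when undefined.
#' @export
measure_ris <- function(mapping, ann, profile, which = c("RIS1", "RIS2")) {
  which <- match.arg(which)
  anchors <- if (which == "RIS1") ann$ris1 else ann$ris2
  pos_of <- function(col, side) {
    k <- match(col, profile$source_columns)
    # flanking SCR: the one whose terminal column is the anchor
    scr <- if (side == "left") ann$scrs[ann$scrs$end_col == col, ]
           else ann$scrs[ann$scrs$start_col == col, ]
    states <- which(profile$source_columns >= scr$start_col[1] &
                    profile$source_columns <= scr$end_col[1])
    if (side == "left") states <- rev(states[states <= k])
    else states <- states[states >= k]
    for (s in states)
      if (!is.na(mapping$assignments[s])) return(mapping$assignments[s])
    NA_integer_
  }
  pl <- pos_of(unname(anchors["left"]), "left")
  pr <- pos_of(unname(anchors["right"]), "right")
  if (is.na(pl) || is.na(pr)) return(NA_integer_)
  as.integer(pr - pl - 1L)
}

#' Assign a redox class from the two RIS lengths
#'
#' A total function over length pairs: both sites short gives class I; a
#' long RIS1 with RIS2 in the long band gives class II, with RIS2 at or
#' above the very-long threshold the reductase-independent class II
#' subgroup; either length in an ambiguity window (RIS1 10–15, RIS2 7–10)
#' is ambiguous; short/long mixtures are discordant; either length at or
#' above the unusual threshold is flagged (formally class II); an
#' undefined length is discordant.
#'
#' @param ris1_len,ris2_len Non-negative integers or `NA` (undefined).
#' @param thresholds A [class_thresholds()].
#' @return One of `"classI"`, `"classII"`, `"classII_verylongRIS2"`,
#'   `"ambiguous"`, `"discordant"`, `"unusual_flagged"`.
#' @export
classify_redox <- function(ris1_len, ris2_len,
                           thresholds = class_thresholds()) {
  t <- thresholds
  if (is.na(ris1_len) || is.na(ris2_len)) return("discordant")
  if (ris1_len < 0 || ris2_len < 0) stop("negative RIS length")
  if (ris1_len >= t$unusual_min || ris2_len >= t$unusual_min)
    return("unusual_flagged")
  r1 <- if (ris1_len <= t$ris1_short_max) "short"
        else if (ris1_len >= t$ris1_long_min) "long" else "ambiguous"
  r2 <- if (ris2_len <= t$ris2_short_max) "short"
        else if (ris2_len >= t$ris2_verylong_min) "verylong"
        else if (ris2_len >= t$ris2_long_lo) "long" else "ambiguous"
  if (r1 == "ambiguous" || r2 == "ambiguous") return("ambiguous")
  if (r1 == "short" && r2 == "short") return("classI")
  if (r1 == "long" && r2 == "long") return("classII")
  if (r1 == "long" && r2 == "verylong") return("classII_verylongRIS2")
  "discordant"
}

#' Applicability gate for non-CYP folds
#'
#' Database-free replacement for a homology-search gate: a query is
#' applicable when its forward score reaches `min_bits` and (optionally)
#' the heme-ligating Cys anchor state maps onto a cysteine.
#'
#' @param profile A `cyp_profile` built with an annotation.
#' @param seq Query sequence.
#' @param min_bits Score threshold in bits (default 100).
#' @param require_cys Also require C at the Cys anchor (default `TRUE`).
#' @param min_len Fragment guard passed to the scorers.
#' @return List `pass` (logical) and `score_bits`.
#' @export
applicability_gate <- function(profile, seq, min_bits = 100,
                               require_cys = TRUE, min_len = 50) {
  score <- forward_score(profile, seq, min_len = min_len)
  pass <- score >= min_bits
  if (pass && require_cys) {
    mapping <- align_query(profile, seq, min_len = min_len)
    k <- profile$anchor_states[["cys"]]
    pos <- mapping$assignments[k]
    pass <- !is.na(pos) && substr(mapping$residues, pos, pos) == "C"
  }
  list(pass = pass, score_bits = score)
}

#' Annotate a query sequence end to end
#'
#' Aligns the query, applies the applicability gate, transfers the SCR
#' intervals, calls the F87-equivalent position, measures both RIS lengths
#' and assigns the redox class.  A query failing the gate still gets all
#' structural fields computed (`gate_pass` records the verdict; the caller
#' decides what to trust).
#'
#' @param profile A `cyp_profile` built with an annotation.
#' @param ann The seed annotation.
#' @param seq Query sequence ([cyp_seq()] or string).
#' @param thresholds A [class_thresholds()].
#' @param min_bits,require_cys Gate parameters (see
#'   [applicability_gate()]); `min_bits = -Inf` disables the score gate.
#' @param min_len Fragment guard (default 50).
#' @return A `cyp_annotation` result: `query_id`, `gate_pass`,
#'   `gate_score_bits`, `scr_intervals`, `f87_call`, `ris1_len`,
#'   `ris2_len`, `redox_class`.
#' @export
annotate_sequence <- function(profile, ann, seq,
                              thresholds = class_thresholds(),
                              min_bits = 100, require_cys = TRUE,
                              min_len = 50) {
  mapping <- align_query(profile, seq, min_len = min_len)
  fwd <- forward_score(profile, seq, min_len = min_len)
  pass <- fwd >= min_bits
  if (pass && require_cys) {
    k <- profile$anchor_states[["cys"]]
    pos <- mapping$assignments[k]
    pass <- !is.na(pos) && substr(mapping$residues, pos, pos) == "C"
  }
  ris1 <- measure_ris(mapping, ann, profile, "RIS1")
  ris2 <- measure_ris(mapping, ann, profile, "RIS2")
  structure(list(query_id = mapping$query_id,
                 gate_pass = pass, gate_score_bits = fwd,
                 scr_intervals = transfer_scrs(mapping, ann, profile),
                 f87_call = predict_f87(mapping, profile),
                 ris1_len = ris1, ris2_len = ris2,
                 redox_class = classify_redox(ris1, ris2, thresholds),
                 mapping = mapping),
            class = "cyp_annotation")
}

#' @export
print.cyp_annotation <- function(x, ...) {
  f87 <- if (is.na(x$f87_call$pos)) "gap"
         else paste0(x$f87_call$residue, x$f87_call$pos)
  cat(sprintf("<cyp_annotation> %s: gate %s (%.1f bits), F87-equivalent %s, RIS1 %s, RIS2 %s, class %s\n",
              x$query_id, if (x$gate_pass) "pass" else "FAIL",
              x$gate_score_bits, f87,
              ifelse(is.na(x$ris1_len), "undef", x$ris1_len),
              ifelse(is.na(x$ris2_len), "undef", x$ris2_len),
              x$redox_class))
  invisible(x)
}
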