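#' The annotated structure-based seed alignment
#'
#' A `cyp_seed` bundles the gapped seed rows with the identity of the
#' reference row (CYP102A1 in the published seed).  A
#' `cyp_seed_annotation` carries the structurally conserved region (SCR)
#' intervals, the anchor columns (F87-equivalent, ExxR glutamate/arginine,
#' heme-ligating cysteine), the reductase-interaction-site (RIS) flanking
#' anchor columns and per-row redox-class labels — everything the profile
#' builder and the annotation transfer need, and nothing derived from 3D
#' coordinates at run time.
#'
#' @name seedmodel
NULL

#' @noRd
new_seed <- function(ids, rows, reference_id, class_labels = NULL) {
  if (is.null(class_labels))
    class_labels <- setNames(rep("unknown", length(ids)), ids)
  structure(list(ids = ids, rows = rows, n_columns = nchar(rows[1]),
                 reference_id = reference_id,
                 class_labels = class_labels),
            class = c("cyp_seed", "cyp_alignment"))
}

#' @export
print.cyp_seed <- function(x, ...) {
  cat(sprintf("<cyp_seed> %d rows x %d columns, reference '%s'\n",
              length(x$ids), x$n_columns, x$reference_id))
  invisible(x)
}

#' @noRd
seed_row <- function(seed, id) {
  i <- match(id, seed$ids)
  if (is.na(i)) stop("no row '", id, "' in seed alignment")
  seed$rows[i]
}

#' Load a seed alignment with its JSON annotation sidecar
#'
#' The sidecar schema (all columns 1-based inclusive):
#' ```
#' {"reference_id": str,
#'  "scrs": [{"name", "start_col", "end_col", "content"}, ...],
#'  "anchors": {"f87_col", "glu_col", "arg_col", "cys_col"},
#'  "ris1": {"left_col", "right_col"},
#'  "ris2": {"left_col", "right_col"},
#'  "class_labels": {id: label}}
#' ```
#' All structural invariants are checked and violations aggregated into a
#' single error report: the reference row must be present and carry a
#' residue at the F87 column, E/R in ExxR spacing (`arg = glu + 3` in its
#' degapped coordinates) and C at the Cys column; SCRs must be in-bounds,
#' sorted and pairwise disjoint; each RIS left anchor must precede its right
#' anchor and both must be terminal columns of the flanking SCRs.
#'
#' @param aln_path Aligned FASTA or Stockholm seed alignment.
#' @param sidecar_path JSON annotation sidecar.
#' @return List with elements `seed` (a `cyp_seed`) and `annotation`
#'   (a `cyp_seed_annotation`).
#' @export
load_seed <- function(aln_path, sidecar_path) {
  aln <- read_alignment(aln_path)
  side <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  scrs <- as.data.frame(side$scrs, stringsAsFactors = FALSE)
  if (is.null(scrs$content)) scrs$content <- ""
  scrs <- scrs[, c("name", "start_col", "end_col", "content")]
  ann <- structure(list(
    scrs = scrs,
    anchors = c(f87 = side$anchors$f87_col, glu = side$anchors$glu_col,
                arg = side$anchors$arg_col, cys = side$anchors$cys_col),
    ris1 = c(left = side$ris1$left_col, right = side$ris1$right_col),
    ris2 = c(left = side$ris2$left_col, right = side$ris2$right_col),
    class_labels = unlist(side$class_labels)),
    class = "cyp_seed_annotation")

  labels <- setNames(rep("unknown", length(aln$ids)), aln$ids)
  known <- intersect(names(ann$class_labels), aln$ids)
  labels[known] <- ann$class_labels[known]
  seed <- new_seed(aln$ids, aln$rows, side$reference_id, labels)

  problems <- check_seed_structure(seed, ann)
  if (length(problems))
    stop("invalid seed annotation:\n  ", paste(problems, collapse = "\n  "))
  list(seed = seed, annotation = ann)
}

# Structural (fatal) checks on seed + annotation; returns character vector
# of problems, empty when clean.
#' @noRd
check_seed_structure <- function(seed, ann) {
  p <- character(0)
  nc <- seed$n_columns
  if (length(seed$ids) < 2L) p <- c(p, "seed needs at least 2 rows")
  if (!ann$anchors["arg"] > ann$anchors["glu"])
    p <- c(p, "glu_col must precede arg_col")
  if (!(seed$reference_id %in% seed$ids)) {
    p <- c(p, paste0("reference row '", seed$reference_id, "' not in alignment"))
    return(p)  # later checks need the reference row
  }
  scrs <- ann$scrs
  oob <- scrs$start_col < 1 | scrs$end_col > nc | scrs$start_col > scrs$end_col
  if (any(oob))
    p <- c(p, paste0("SCR out of bounds: ", paste(scrs$name[oob], collapse = ", ")))
  if (is.unsorted(scrs$start_col, strictly = TRUE))
    p <- c(p, "SCRs not sorted by start_col")
  if (nrow(scrs) > 1) {
    ov <- which(scrs$start_col[-1] <= scrs$end_col[-nrow(scrs)])
    for (i in ov)
      p <- c(p, paste0("SCRs overlap: ", scrs$name[i], " and ", scrs$name[i + 1]))
  }
  bad_anchor <- ann$anchors < 1 | ann$anchors > nc
  if (any(bad_anchor))
    p <- c(p, paste0("anchor column out of bounds: ",
                     paste(names(ann$anchors)[bad_anchor], collapse = ", ")))
  if (length(p)) return(p)

  ref <- chars(seed_row(seed, seed$reference_id))
  if (ref[ann$anchors["f87"]] == "-")
    p <- c(p, "reference row has a gap at f87_col (reference must carry F87)")
  if (ref[ann$anchors["cys"]] != "C")
    p <- c(p, paste0("reference residue at cys_col is '",
                     ref[ann$anchors["cys"]], "', expected C"))
  if (ref[ann$anchors["glu"]] != "E" || ref[ann$anchors["arg"]] != "R")
    p <- c(p, "reference row does not show E/R at the ExxR anchor columns")
  else {
    ref_deg <- cumsum(ref != "-")
    if (ref_deg[ann$anchors["arg"]] - ref_deg[ann$anchors["glu"]] != 3L)
      p <- c(p, "ExxR spacing violated: arg is not glu + 3 in degapped reference coordinates")
  }
  for (which in c("ris1", "ris2")) {
    rr <- ann[[which]]
    if (rr["left"] >= rr["right"])
      p <- c(p, paste0(which, " left anchor column must precede right anchor column"))
    if (!(rr["left"] %in% ann$scrs$end_col))
      p <- c(p, paste0(which, " left anchor is not the terminal column of an SCR"))
    if (!(rr["right"] %in% ann$scrs$start_col))
      p <- c(p, paste0(which, " right anchor is not the first column of an SCR"))
  }
  p
}

#' Write a seed annotation as a JSON sidecar
#'
#' Inverse of the sidecar parsing in [load_seed()].
#'
#' @param ann A `cyp_seed_annotation`.
#' @param reference_id Reference row id to record.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_seed_sidecar <- function(ann, reference_id, path) {
  obj <- list(
    reference_id = reference_id,
    scrs = ann$scrs,
    anchors = list(f87_col = unname(ann$anchors["f87"]),
                   glu_col = unname(ann$anchors["glu"]),
                   arg_col = unname(ann$anchors["arg"]),
                   cys_col = unname(ann$anchors["cys"])),
    ris1 = list(left_col = unname(ann$ris1["left"]),
                right_col = unname(ann$ris1["right"])),
    ris2 = list(left_col = unname(ann$ris2["left"]),
                right_col = unname(ann$ris2["right"])),
    class_labels = as.list(ann$class_labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Check residue-level conservation of the seed anchors
#'
#' Every row is expected to carry E at the glutamate column, R at the
#' arginine column and C at the cysteine column (the three residues that are
#' essentially invariant across the CYP family).  Deviating rows are listed
#' in the returned report; deviations on the reference row are flagged
#' fatal.  An empty report means a clean seed.
#'
#' @param seed A `cyp_seed`.
#' @param ann Its `cyp_seed_annotation`.
#' @return Data frame with columns `row_id`, `column`, `anchor`, `expected`,
#'   `observed`, `fatal` (zero rows when clean).
#' @export
validate_seed <- function(seed, ann) {
  checks <- data.frame(anchor = c("glu", "arg", "cys"),
                       expected = c("E", "R", "C"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_along(seed$ids)) {
    row <- chars(seed$rows[i])
    for (j in seq_len(nrow(checks))) {
      col <- ann$anchors[checks$anchor[j]]
      obs <- row[col]
      if (obs != checks$expected[j])
        out[[length(out) + 1L]] <- data.frame(
          row_id = seed$ids[i], column = unname(col),
          anchor = checks$anchor[j], expected = checks$expected[j],
          observed = obs,
          fatal = seed$ids[i] == seed$reference_id,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(row_id = character(0), column = integer(0),
                      anchor = character(0), expected = character(0),
                      observed = character(0), fatal = logical(0)))
  do.call(rbind, out)
}

#' Map a reference residue position to its alignment column
#'
#' @param seed A `cyp_seed`.
#' @param ref_pos 1-based residue index in the degapped reference row.
#' @return The alignment column whose reference character is the
#'   `ref_pos`-th non-gap character.
#' @seealso [column_to_ref_pos()] for the inverse.
#' @export
ref_pos_to_column <- function(seed, ref_pos) {
  ref <- chars(seed_row(seed, seed$reference_id))
  nongap <- which(ref != "-")
  if (any(ref_pos < 1L | ref_pos > length(nongap)))
    stop("ref_pos out of range 1..", length(nongap))
  nongap[ref_pos]
}

#' Map an alignment column to a reference residue position
#'
#' @param seed A `cyp_seed`.
#' @param col Alignment column index.
#' @return 1-based degapped reference position, or `NA` if the reference
#'   row is gapped at `col`.
#' @export
column_to_ref_pos <- function(seed, col) {
  ref <- chars(seed_row(seed, seed$reference_id))
  if (any(col < 1L | col > length(ref)))
    stop("column out of range 1..", length(ref))
  pos <- cumsum(ref != "-")
  ifelse(ref[col] == "-", NA_integer_, pos[col])
}

#' Drop one row from a seed alignment
#'
#' Columns are kept as-is (the alignment is input data; it is not
#' recomputed per fold).  Used by [leave_one_out()].
#'
#' @param seed A `cyp_seed`.
#' @param id Row to drop; dropping the reference row is an error.
#' @return A `cyp_seed` without that row.
#' @export
drop_seed_row <- function(seed, id) {
  if (id == seed$reference_id) stop("cannot drop the reference row")
  keep <- seed$ids != id
  if (all(keep)) stop("no row '", id, "' in seed alignment")
  new_seed(seed$ids[keep], seed$rows[keep], seed$reference_id,
           seed$class_labels[keep])
}
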