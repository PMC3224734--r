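#' Protein sequence records
#'
#' A `cyp_seq` is a plain list with fields `id`, `description` and `residues`
#' (an uppercase string over the 20 amino-acid letters plus `X`).  Sequence
#' sets are unclassed lists of `cyp_seq` objects, in file order.
#'
#' @param id Identifier (non-empty string).
#' @param residues Residue string; uppercased, `*` stop characters stripped.
#' @param description Free-text description (may be empty).
#' @return A `cyp_seq` object.
#' @export
cyp_seq <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  residues <- gsub("*", "", toupper(residues), fixed = TRUE)
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  bad <- setdiff(unique(chars(residues)), c(AA20, "X"))
  if (length(bad)) {
    if (any(bad %in% AMBIGUOUS_AA))
      stop("sequence '", id, "' contains ambiguous residue code(s) ",
           paste(intersect(bad, AMBIGUOUS_AA), collapse = ", "),
           "; only the 20 standard amino acids plus X are supported")
    stop("sequence '", id, "' contains non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, description = description, residues = residues),
            class = "cyp_seq")
}

#' @export
print.cyp_seq <- function(x, ...) {
  cat(sprintf("<cyp_seq> %s (%d aa) %s\n", x$id, nchar(x$residues),
              x$description))
  invisible(x)
}

# Make ids unique by deterministic suffixing: id, id_2, id_3, ...
#' @noRd
dedup_ids <- function(ids) {
  out <- ids
  for (id in unique(ids[duplicated(ids)])) {
    w <- which(ids == id)
    out[w[-1]] <- paste0(id, "_", seq_along(w)[-1])
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Records are uppercased and `*` stop characters stripped.  Records holding
#' characters outside the 20 amino-acid letters plus `X` are rejected
#' individually with a warning naming them; ambiguity codes (B/Z/J/U/O) are
#' reported explicitly.  Duplicate ids are suffixed deterministically
#' (`id`, `id_2`, ...).
#'
#' @param path FASTA file.
#' @return List of [cyp_seq()] records, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  headers <- names(set)
  ids <- dedup_ids(sub("\\s.*$", "", headers))
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  rejected <- character(0)
  for (i in seq_along(set)) {
    rec <- tryCatch(cyp_seq(ids[i], as.character(set[[i]]), descs[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) rejected <- c(rejected, paste0(ids[i], ": ", rec))
    else out[[i]] <- rec
  }
  out <- Filter(Negate(is.null), out)
  if (length(rejected))
    warning("rejected ", length(rejected), " record(s):\n  ",
            paste(rejected, collapse = "\n  "))
  if (!length(out)) stop("no valid sequence records in ", path)
  out
}

#' Write protein sequences as FASTA
#'
#' Standard FASTA with 60-column line wrapping.
#'
#' @param seqs Non-empty list of [cyp_seq()] records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!length(seqs)) stop("refusing to write an empty sequence set")
  ids <- vapply(seqs, `[[`, "", "id")
  if (any(!nzchar(ids))) stop("sequence with empty id")
  headers <- ifelse(vapply(seqs, function(s) nzchar(s$description), TRUE),
                    paste(ids, vapply(seqs, `[[`, "", "description")), ids)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a multiple alignment (aligned FASTA or Stockholm)
#'
#' Stockholm `#=G*` annotation lines are ignored at this layer; `.` gaps are
#' normalised to `-`; rows are uppercased.  All rows must have equal length.
#' Class labels default to `"unknown"` and are filled from the annotation
#' sidecar by [load_seed()].
#'
#' @param path Alignment file.
#' @param format `"auto"` (sniff the Stockholm header), `"fasta"` or
#'   `"stockholm"`.
#' @return A `cyp_alignment`: list with `ids`, `rows` (gapped strings),
#'   `n_columns`, `class_labels`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && grepl("^# STOCKHOLM", first))
      "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed Stockholm sequence line: ", lines[bad][1])
    ids0 <- vapply(parts, `[[`, "", 1L)
    seqs0 <- vapply(parts, `[[`, "", 2L)
    ids <- unique(ids0)
    rows <- vapply(ids, function(i)
      paste(seqs0[ids0 == i], collapse = ""), "")
  } else {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment input: ", path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
  }
  ids <- dedup_ids(unname(ids))
  rows <- gsub(".", "-", toupper(unname(rows)), fixed = TRUE)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1])[1]
    stop("alignment rows differ in length: row '", ids[off], "' has ",
         lens[off], " columns, row '", ids[1], "' has ", lens[1])
  }
  structure(list(ids = ids, rows = rows, n_columns = lens[1],
                 class_labels = setNames(rep("unknown", length(ids)), ids)),
            class = "cyp_alignment")
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln A `cyp_alignment` (or `cyp_seed`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(setNames(aln$rows, aln$ids))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @export
print.cyp_alignment <- function(x, ...) {
  cat(sprintf("<cyp_alignment> %d rows x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

# Fixed result-table column order shared by the TSV writer/reader.
#' @noRd
results_columns <- function(scr_names) {
  c("id", "gate", "score",
    as.vector(rbind(paste0(tolower(scr_names), "_start"),
                    paste0(tolower(scr_names), "_stop"))),
    "f87_pos", "f87_res", "ris1_len", "ris2_len", "redox_class")
}

#' Write annotation results as TSV
#'
#' One row per query, fixed column order (`id`, `gate`, `score`, per-SCR
#' start/stop, `f87_pos`, `f87_res`, `ris1_len`, `ris2_len`,
#' `redox_class`).  Absent SCRs, gapped F87 positions and undefined RIS
#' lengths are written as `.`; a gapped F87 residue is written as `-`.
#'
#' @param results Non-empty list of [annotate_sequence()] results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  if (!length(results)) stop("no results to write")
  scr_names <- names(results[[1]]$scr_intervals)
  dot <- function(x) if (is.null(x) || is.na(x)) "." else format(x)
  rows <- lapply(results, function(r) {
    scr_cells <- unlist(lapply(r$scr_intervals, function(iv)
      if (anyNA(iv)) c(".", ".") else c(format(iv[1]), format(iv[2]))))
    c(r$query_id,
      if (r$gate_pass) "pass" else "fail",
      sprintf("%.4f", r$gate_score_bits),
      scr_cells,
      if (is.na(r$f87_call$pos)) "." else format(r$f87_call$pos),
      if (is.na(r$f87_call$pos)) "-" else r$f87_call$residue,
      dot(r$ris1_len), dot(r$ris2_len), r$redox_class)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- results_columns(scr_names)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation-results TSV back into a data frame
#'
#' Numeric fields (`score`, positions, lengths) are recovered exactly;
#' missing values (`.`) become `NA`.
#'
#' @param path TSV written by [write_results_tsv()].
#' @return A data frame, one row per query.
#' @export
read_results_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  num_cols <- setdiff(names(df), c("id", "gate", "f87_res", "redox_class"))
  for (cc in num_cols) {
    v <- df[[cc]]
    v[v == "."] <- NA
    df[[cc]] <- as.numeric(v)
  }
  df
}

#' Write transferred SCR intervals as protein-coordinate GFF3
#'
#' One `structural_region` feature per present SCR, `source=cypmod`,
#' coordinates 1-based inclusive in the query protein.
#'
#' @param results List of [annotate_sequence()] results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (r in results) {
    for (nm in names(r$scr_intervals)) {
      iv <- r$scr_intervals[[nm]]
      if (anyNA(iv)) next
      writeLines(sprintf("%s\tcypmod\tstructural_region\t%d\t%d\t.\t.\t.\tName=%s",
                         r$query_id, iv[1], iv[2], nm), con)
    }
  }
  invisible(path)
}
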