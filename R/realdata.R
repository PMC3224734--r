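#' Manifest of the 31 seed crystal structures
#'
#' The published seed alignment was built from 31 PDB structures: 12 class
#' II (CPR-type) CYPs, 16 bacterial class I CYPs and 3 CYPs with unusual
#' redox chemistry (CYP8A prostacyclin synthase, the NO reductase CYP55A2
#' and the peroxide-driven CYP152A1).  The manifest ships with the package
#' as a plain TSV mirroring that table.
#'
#' @return Data frame with columns `cyp`, `pdb_id`, `class_label`
#'   (31 rows).
#' @export
cyp_seed_manifest <- function() {
  path <- system.file("extdata", "table1_manifest.tsv", package = "cypmod",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 31L,
            all(c("cyp", "pdb_id", "class_label") %in% names(df)))
  df
}

#' Fetch the seed sequences (cache-first)
#'
#' For each PDB id the cache directory is consulted for
#' `<pdb_id>.fasta`; on a miss the RCSB FASTA endpoint is tried (first
#' protein chain kept) and the result cached.  Fetches are checksummed so
#' that re-fetches are verifiably identical.  Without network access a
#' warm cache is required; a missing entry raises an error naming the
#' PDB id.
#'
#' @param manifest Data frame from [cyp_seed_manifest()] (or a subset).
#' @param cache_dir Directory holding/receiving `<pdb_id>.fasta` files.
#' @return List of [cyp_seq()] (ids = PDB ids) with attribute
#'   `checksums` (named md5 strings).
#' @export
fetch_seed_sequences <- function(manifest, cache_dir) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", nrow(manifest))
  sums <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$pdb_id[i]
    f <- file.path(cache_dir, paste0(id, ".fasta"))
    if (!file.exists(f)) {
      url <- paste0("https://www.rcsb.org/fasta/entry/", id)
      ok <- tryCatch({
        utils::download.file(url, f, quiet = TRUE, mode = "wb")
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok || !file.exists(f) || file.size(f) == 0) {
        unlink(f)
        stop("cannot obtain sequence for PDB id '", id,
             "': not in cache '", cache_dir, "' and download failed")
      }
    }
    recs <- read_fasta(f)
    seq <- recs[[1]]                      # first (protein) chain
    seq$id <- id
    seq$description <- manifest$cyp[i]
    out[[i]] <- seq
    sums[i] <- unname(tools::md5sum(f))
  }
  names(sums) <- manifest$pdb_id
  attr(out, "checksums") <- sums
  out
}

#' Locate the ExxR and Cys-pocket motifs in a CYP sequence
#'
#' The heme-ligating cysteine sits in the near-invariant
#' `FxxGxxxCxG` Cys-pocket signature; the ExxR pair is pinned as the
#' nearest `E..R` occurrence upstream of the cysteine within a plausible
#' spacing window.
#'
#' @param residues Residue string.
#' @param cys_pattern Regex for the Cys-pocket (default `F..G...C.G`).
#' @param cys_offset 0-based offset of the cysteine within a
#'   `cys_pattern` match (default 7).
#' @param spacing Allowed glutamate-to-cysteine distance (default
#'   `c(10, 200)`).
#' @return List `glu`, `arg`, `cys` (1-based positions), or `NULL` when
#'   either motif is absent.
#' @export
locate_cyp_motifs <- function(residues, cys_pattern = "F..G...C.G",
                              cys_offset = 7L, spacing = c(10L, 200L)) {
  m <- gregexpr(cys_pattern, residues)[[1]]
  if (m[1] == -1L) return(NULL)
  cys <- max(m) + cys_offset                      # last signature match
  e <- gregexpr("E..R", residues)[[1]]
  if (e[1] == -1L) return(NULL)
  d <- cys - e
  e <- e[d >= spacing[1] & d <= spacing[2]]
  if (!length(e)) return(NULL)
  glu <- max(e)                                   # nearest upstream
  list(glu = glu, arg = glu + 3L, cys = cys)
}

# Rebuild a gapped MSA from per-sequence query mappings on one profile.
# N-/C-flank residues are placed in the insert blocks after node 0 / L.
#' @noRd
msa_from_mappings <- function(profile, mappings) {
  L <- profile$n_match
  ins_of <- function(m, k) {
    v <- m$insertions[[k + 1L]]
    if (k == 0L && m$n_flank > 0L) v <- c(seq_len(m$n_flank), v)
    if (k == L && m$c_flank > 0L)
      v <- c(v, nchar(m$residues) - m$c_flank + seq_len(m$c_flank))
    sort(v)
  }
  max_ins <- vapply(0:L, function(k)
    max(vapply(mappings, function(m) length(ins_of(m, k)), 1L)), 1L)
  rows <- vapply(mappings, function(m) {
    a <- chars(m$residues)
    cells <- character(0)
    for (k in 0:L) {
      if (k > 0L)
        cells <- c(cells,
                   if (is.na(m$assignments[k])) "-" else a[m$assignments[k]])
      v <- ins_of(m, k)
      cells <- c(cells, a[v], rep("-", max_ins[k + 1L] - length(v)))
    }
    paste(cells, collapse = "")
  }, "")
  rows
}

#' Reconstruct a seed alignment from sequences by motif pinning
#'
#' Stand-in for an unavailable structural superposition: each sequence is
#' pinned at its detected ExxR and heme-Cys motifs, the three resulting
#' segments are block-justified into an initial alignment (prefix
#' right-justified, the two downstream segments left-justified, so the
#' glutamate, arginine and cysteine each share a column), and the
#' alignment is then refined by rebuilding a profile from it and
#' realigning every sequence (`rounds` iterations).  Because it is
#' sequence-only, annotations derived from it are approximations of the
#' structure-derived original.
#'
#' @param seqs List of [cyp_seq()].
#' @param reference_id Row to use as reference (default the first).
#' @param rounds Refinement iterations (default 2).
#' @param occupancy_threshold,pseudocount_alpha Profile parameters for the
#'   refinement rounds.
#' @param ... Passed to [locate_cyp_motifs()].
#' @return A `cyp_seed`, with attribute `excluded` naming sequences in
#'   which the motifs could not be located (dropped with a warning).
#' @export
bootstrap_seed_alignment <- function(seqs, reference_id = NULL, rounds = 2,
                                     occupancy_threshold = 0.5,
                                     pseudocount_alpha = 1, ...) {
  hits <- lapply(seqs, function(s) locate_cyp_motifs(s$residues, ...))
  ok <- !vapply(hits, is.null, TRUE)
  excluded <- vapply(seqs[!ok], `[[`, "", "id")
  if (length(excluded))
    warning("excluded (no ExxR/Cys-pocket motifs): ",
            paste(excluded, collapse = ", "))
  seqs <- seqs[ok]; hits <- hits[ok]
  if (length(seqs) < 2L) stop("fewer than 2 sequences carry both motifs")
  ids <- vapply(seqs, `[[`, "", "id")
  if (is.null(reference_id)) reference_id <- ids[1]

  seg <- function(s, from, to) if (to < from) "" else substr(s, from, to)
  pre <- mapply(function(s, h) seg(s$residues, 1L, h$glu - 1L), seqs, hits)
  mid <- mapply(function(s, h) seg(s$residues, h$glu, h$cys - 1L), seqs, hits)
  post <- mapply(function(s, h) seg(s$residues, h$cys,
                                    nchar(s$residues)), seqs, hits)
  pad <- function(x, w, side) {
    g <- strrep("-", w - nchar(x))
    if (side == "left") paste0(g, x) else paste0(x, g)
  }
  rows <- paste0(vapply(pre, pad, "", w = max(nchar(pre)), side = "left"),
                 vapply(mid, pad, "", w = max(nchar(mid)), side = "right"),
                 vapply(post, pad, "", w = max(nchar(post)), side = "right"))
  seed <- new_seed(ids, unname(rows), reference_id)
  for (r in seq_len(rounds)) {
    prof <- build_profile(seed, NULL,
                          occupancy_threshold = occupancy_threshold,
                          pseudocount_alpha = pseudocount_alpha)
    mappings <- lapply(seqs, function(s)
      align_query(prof, s, min_len = 1))
    seed <- new_seed(ids, msa_from_mappings(prof, mappings), reference_id)
  }
  attr(seed, "excluded") <- excluded
  seed
}
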