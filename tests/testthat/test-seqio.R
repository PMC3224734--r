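test_that("FASTA reading parses, normalises and deduplicates", {
  p <- write_lines(c(">s1 first protein", "mkvl", ">s2", "ACDEF*",
                     ">s2", "GHIKL"), tmpfile(".fasta"))
  seqs <- read_fasta(p)
  expect_length(seqs, 3)
  expect_equal(vapply(seqs, `[[`, "", "id"), c("s1", "s2", "s2_2"))
  expect_equal(seqs[[1]]$residues, "MKVL")        # uppercased
  expect_equal(seqs[[1]]$description, "first protein")
  expect_equal(seqs[[2]]$residues, "ACDEF")       # '*' stripped
})

test_that("invalid records are rejected individually with a report", {
  p <- write_lines(c(">good", "ACDEF", ">amb", "ACDBF", ">bad", "AC1EF"),
                   tmpfile(".fasta"))
  expect_warning(seqs <- read_fasta(p), "rejected 2 record")
  expect_length(seqs, 1)
  expect_equal(seqs[[1]]$id, "good")
  expect_warning(read_fasta(p), "ambiguous")
  expect_error(suppressWarnings(
    read_fasta(write_lines(character(0), tmpfile(".fasta")))))
})

test_that("FASTA writing wraps at 60 columns and round-trips", {
  s <- cyp_seq("long", paste(rep("A", 61), collapse = ""))
  p <- tmpfile(".fasta")
  write_fasta(list(s), p)
  lines <- readLines(p)
  expect_length(lines, 3)                         # header + 2 wrapped lines
  expect_equal(nchar(lines[2]), 60)

  seqs <- list(cyp_seq("a", "MKVLLE", "desc here"), cyp_seq("b", "ACDEF"))
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_equal(lapply(back, unclass), lapply(seqs, unclass))

  expect_error(write_fasta(list(), p), "empty")
  bad <- cyp_seq("x", "ACDEF"); bad$id <- ""
  expect_error(write_fasta(list(bad), p), "empty id")
})

test_that("alignment reading handles aligned FASTA and Stockholm", {
  p <- write_lines(c(">r1", "AC-DEFGHIK", ">r2", "ACWDE.GHIK",
                     ">r3", "acwdefghik"), tmpfile(".afa"))
  aln <- read_alignment(p)
  expect_s3_class(aln, "cyp_alignment")
  expect_equal(aln$n_columns, 10)
  expect_length(aln$ids, 3)
  expect_equal(aln$rows[2], "ACWDE-GHIK")         # '.' normalised to '-'
  expect_equal(aln$rows[3], "ACWDEFGHIK")         # uppercased
  expect_equal(unname(aln$class_labels), rep("unknown", 3))

  sto <- write_lines(c("# STOCKHOLM 1.0", "#=GF ID toy",
                       "row1  ACDE-", "row2  AC-EF",
                       "#=GC SS_cons  hhhhh", "//"), tmpfile(".sto"))
  a2 <- read_alignment(sto)
  expect_equal(a2$ids, c("row1", "row2"))
  expect_equal(a2$n_columns, 5)

  ragged <- write_lines(c(">r1", "ACDE", ">r2", "ACDEF"), tmpfile(".afa"))
  expect_error(read_alignment(ragged), "differ in length.*r2")
})

test_that("alignment write/read round-trips content", {
  g <- syn_bundle()
  p <- tmpfile(".afa")
  write_alignment(g$seed, p)
  back <- read_alignment(p)
  expect_equal(back$ids, g$seed$ids)
  expect_equal(back$rows, g$seed$rows)
})

test_that("results TSV uses fixed columns, dots for missing, and round-trips", {
  r1 <- fake_result()
  r2 <- fake_result(id = "q2", gate = FALSE, score = -3.25,
                    scrs = list(SCR1 = c(start = NA, end = NA),
                                SCR2 = c(start = 8, end = 19)),
                    f87 = list(pos = NA_integer_, residue = "-"),
                    ris1 = NA_integer_, ris2 = 7L, cls = "discordant")
  p <- tmpfile(".tsv")
  write_results_tsv(list(r1, r2), p)
  lines <- readLines(p)
  expect_length(lines, 3)                         # header + 2 rows
  df <- read_results_tsv(p)
  expect_equal(names(df)[1:3], c("id", "gate", "score"))
  expect_equal(df$scr1_start, c(5, NA))           # absent SCR -> NA
  expect_equal(df$f87_pos, c(15, NA))
  expect_equal(df$f87_res, c("F", "-"))           # gap call residue '-'
  expect_equal(df$ris1_len, c(4, NA))
  expect_equal(df$score, c(123.4567, -3.25))      # numerics exact
  expect_equal(df$redox_class, c("classI", "discordant"))
})

test_that("GFF3 output has one feature per present SCR", {
  p <- tmpfile(".gff3")
  write_gff3(list(fake_result(), fake_result(id = "q2",
    scrs = list(SCR1 = c(start = NA, end = NA),
                SCR2 = c(start = 2, end = 9)))), p)
  lines <- readLines(p)
  expect_equal(lines[1], "##gff-version 3")
  feats <- lines[-1]
  expect_length(feats, 3)                         # 2 + 1 present SCRs
  expect_true(all(grepl("\tcypmod\tstructural_region\t", feats)))
})
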