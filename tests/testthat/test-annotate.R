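test_that("identity transfer reproduces the seed annotation on the reference", {
  g <- syn_bundle()
  res <- syn_ref_annotation()
  expect_true(res$gate_pass)
  for (nm in names(res$scr_intervals))
    expect_equal(unname(res$scr_intervals[[nm]]),
                 unname(g$scr_truth[[1]][[nm]]), info = nm)
  expect_equal(res$f87_call$pos, g$truth$anchor_pos[1])
  expect_equal(res$f87_call$residue, g$truth$anchor_res[1])
  expect_equal(res$ris1_len, g$truth$ris1_len[1])
  expect_equal(res$ris2_len, g$truth$ris2_len[1])
  expect_equal(res$redox_class, g$truth$class[1])
})

test_that("deleted SCR states shift or void the transferred interval", {
  g <- syn_bundle()
  prof <- syn_profile()
  ref <- cyp_seq("ref", gsub("-", "", g$seed$rows[1], fixed = TRUE))
  m <- align_query(prof, ref)
  scr5 <- g$annotation$scrs[5, ]
  states <- which(prof$source_columns >= scr5$start_col &
                  prof$source_columns <= scr5$end_col)
  full <- transfer_scrs(m, g$annotation, prof)

  m1 <- m
  m1$assignments[states[1]] <- NA          # first state deleted
  t1 <- transfer_scrs(m1, g$annotation, prof)
  expect_equal(unname(t1$SCR5["start"]), unname(full$SCR5["start"]) + 1)
  expect_equal(t1$SCR5["end"], full$SCR5["end"])

  m2 <- m
  m2$assignments[states] <- NA             # whole SCR deleted
  t2 <- transfer_scrs(m2, g$annotation, prof)
  expect_true(all(is.na(t2$SCR5)))
  expect_equal(t2$SCR4, full$SCR4)         # others untouched
})

test_that("the F87-equivalent call reports position/residue or a gap", {
  g <- syn_bundle()
  prof <- syn_profile()
  ref <- cyp_seq("ref", gsub("-", "", g$seed$rows[1], fixed = TRUE))
  m <- align_query(prof, ref)
  call <- predict_f87(m, prof)
  expect_equal(call$pos, g$truth$anchor_pos[1])
  m$assignments[prof$anchor_states[["f87"]]] <- NA
  call <- predict_f87(m, prof)
  expect_true(is.na(call$pos))
  expect_equal(call$residue, "-")
})

test_that("RIS measurement counts residues strictly between the anchors", {
  g <- syn_bundle()
  prof <- syn_profile()
  ref_str <- gsub("-", "", g$seed$rows[1], fixed = TRUE)
  m <- align_query(prof, cyp_seq("ref", ref_str))
  expect_equal(measure_ris(m, g$annotation, prof, "RIS1"),
               g$truth$ris1_len[1])
  expect_equal(measure_ris(m, g$annotation, prof, "RIS2"),
               g$truth$ris2_len[1])

  # splice 6 extra residues into the RIS1 span and re-align
  left_state <- prof$anchor_states[["ris1_left"]]
  cut <- m$assignments[left_state]
  spliced <- paste0(substr(ref_str, 1, cut), "WYWYWY",
                    substr(ref_str, cut + 1, nchar(ref_str)))
  m6 <- align_query(prof, cyp_seq("spliced", spliced))
  expect_equal(measure_ris(m6, g$annotation, prof, "RIS1"),
               g$truth$ris1_len[1] + 6L)
  # unrelated intervals keep their lengths
  t0 <- transfer_scrs(m, g$annotation, prof)
  t6 <- transfer_scrs(m6, g$annotation, prof)
  for (nm in names(t0))
    expect_equal(diff(t6[[nm]]), diff(t0[[nm]]), info = nm)

  # deleted anchor state falls back to the nearest emitting state inward
  mdel <- m
  mdel$assignments[left_state] <- NA
  expect_equal(measure_ris(mdel, g$annotation, prof, "RIS1"),
               g$truth$ris1_len[1] + 1L)
})

test_that("adjacent anchors with an empty span measure zero", {
  params <- generator_params(
    ris_length_bands = list(
      classI = list(RIS1 = c(0, 0), RIS2 = c(0, 0)),
      classII = list(RIS1 = c(0, 0), RIS2 = c(0, 0)),
      classII_verylongRIS2 = list(RIS1 = c(0, 0), RIS2 = c(0, 0))),
    rng_seed = 8)
  g0 <- generate_seed(params)
  prof0 <- build_profile(g0$seed, g0$annotation)
  m <- align_query(prof0, cyp_seq("ref", gsub("-", "", g0$seed$rows[1],
                                              fixed = TRUE)))
  expect_equal(measure_ris(m, g0$annotation, prof0, "RIS1"), 0L)
  expect_equal(measure_ris(m, g0$annotation, prof0, "RIS2"), 0L)
})

test_that("redox classification matches the published length bands", {
  expect_equal(classify_redox(4, 4), "classI")
  expect_equal(classify_redox(21, 14), "classII")
  expect_equal(classify_redox(22, 23), "classII_verylongRIS2")
  expect_equal(classify_redox(5, 11), "discordant")
  expect_equal(classify_redox(12, 9), "ambiguous")
  expect_equal(classify_redox(40, 14), "unusual_flagged")
  expect_equal(classify_redox(NA, 5), "discordant")
  expect_equal(classify_redox(4, 18), "discordant")   # short + very long
  expect_equal(classify_redox(18, 7), "ambiguous")    # RIS2 7 is unassigned
  expect_error(classify_redox(-1, 4), "negative")
})

test_that("classification partitions all length pairs totally", {
  labels <- c("classI", "classII", "classII_verylongRIS2", "ambiguous",
              "discordant", "unusual_flagged")
  got <- outer(0:99, 0:99, Vectorize(function(a, b) classify_redox(a, b)))
  expect_true(all(got %in% labels))
  expect_setequal(unique(as.vector(got)), labels)
})

test_that("the applicability gate accepts the seed and rejects noise", {
  g <- syn_bundle()
  prof <- syn_profile()
  ref_str <- gsub("-", "", g$seed$rows[1], fixed = TRUE)
  gate <- applicability_gate(prof, cyp_seq("ref", ref_str))
  expect_true(gate$pass)
  expect_gt(gate$score_bits, 100)

  set.seed(4)
  noise <- random_residues(450)
  gate <- applicability_gate(prof, cyp_seq("noise", noise))
  expect_false(gate$pass)

  mut <- ref_str
  cys_pos <- align_query(prof, ref_str)$assignments[
    prof$anchor_states[["cys"]]]
  substr(mut, cys_pos, cys_pos) <- "A"
  gate <- applicability_gate(prof, cyp_seq("mut", mut), require_cys = TRUE)
  expect_false(gate$pass)
  gate <- applicability_gate(prof, cyp_seq("mut", mut), require_cys = FALSE)
  expect_true(gate$pass)
})

test_that("annotate_sequence composes all fields and propagates the fragment guard", {
  g <- syn_bundle()
  prof <- syn_profile()
  res <- syn_ref_annotation()
  expect_true(res$gate_pass)
  expect_false(any(vapply(res$scr_intervals, anyNA, TRUE)))
  expect_error(annotate_sequence(prof, g$annotation,
                                 cyp_seq("frag", random_residues(30))),
               "fragment")
  # gate failure still yields structural fields
  set.seed(5)
  noisy <- annotate_sequence(prof, g$annotation,
                             cyp_seq("noise", random_residues(400)))
  expect_false(noisy$gate_pass)
  expect_length(noisy$scr_intervals, 19)
})
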