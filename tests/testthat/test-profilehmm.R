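toy_seed <- function(rows, ids = sprintf("r%d", seq_along(rows)),
                     reference = ids[1]) {
  cypmod:::new_seed(ids, rows, reference)
}

test_that("fully occupied columns all become match states", {
  prof <- build_profile(toy_seed(c("ACDE", "ACDF", "ACDE")))
  expect_equal(prof$n_match, 4)
  expect_equal(prof$source_columns, 1:4)
})

test_that("emission pseudocounts follow the background-weighted formula", {
  # column {A, A, V}, alpha = 1, uniform background
  prof <- build_profile(toy_seed(c("A", "A", "V")))
  e <- prof$match_emissions[1, ]
  expect_equal(unname(e["A"]), 0.5125)
  expect_equal(unname(e["V"]), 0.2625)
  expect_equal(unname(e["W"]), 0.0125)
  expect_equal(sum(e), 1)
})

test_that("sparse columns become inserts unless anchored", {
  prof <- build_profile(toy_seed(c("A-C", "A-C", "AWC")),
                        occupancy_threshold = 0.5)
  expect_equal(prof$n_match, 2)
  expect_equal(prof$source_columns, c(1, 3))
})

test_that("anchor and SCR boundary columns are forced match states", {
  g <- syn_bundle()
  prof <- syn_profile()
  anchor_cols <- c(g$annotation$anchors, g$annotation$ris1, g$annotation$ris2)
  expect_true(all(anchor_cols %in% prof$source_columns))
  expect_true(all(!is.na(prof$anchor_states)))
  expect_equal(prof$source_columns[prof$anchor_states[["cys"]]],
               unname(g$annotation$anchors["cys"]))
  boundary <- c(g$annotation$scrs$start_col, g$annotation$scrs$end_col)
  expect_true(all(boundary %in% prof$source_columns))
})

test_that("emissions and transition groups are normalised", {
  for (prof in list(syn_profile(), random_profile(4, rng_seed = 3))) {
    expect_true(all(abs(rowSums(prof$match_emissions) - 1) < 1e-9))
    tr <- prof$transitions
    L <- prof$n_match
    for (k in 0:L) {
      j <- k + 1
      expect_equal(tr$mm[j] + tr$mi[j] + tr$md[j], 1, tolerance = 1e-9)
      expect_equal(tr$im[j] + tr$ii[j], 1, tolerance = 1e-9)
      if (k >= 1) expect_equal(tr$dm[j] + tr$dd[j], 1, tolerance = 1e-9)
    }
  }
})

test_that("the reference of a consensus-dominant gap-free seed maps onto itself", {
  rows <- rep(paste(rep(c("A", "C", "D", "E", "F", "G"), 10), collapse = ""), 4)
  prof <- build_profile(toy_seed(rows))
  m <- align_query(prof, cyp_seq("ref", rows[1]))
  expect_equal(m$assignments, seq_len(prof$n_match))
  expect_equal(sum(lengths(m$insertions)), 0)
  expect_equal(m$n_flank, 0)
  expect_equal(m$c_flank, 0)
})

test_that("Viterbi and forward agree with brute-force path enumeration", {
  set.seed(20)
  for (rep in 1:40) {
    L <- sample(1:6, 1); N <- sample(1:8, 1)
    prof <- random_profile(L)
    s <- random_residues(N)
    oracle <- enumerate_glocal(prof, s)
    v <- align_query(prof, s, min_len = 1)
    f <- forward_score(prof, s, min_len = 1)
    expect_equal(v$score_bits, oracle$best, tolerance = 1e-9)
    expect_equal(f, oracle$total, tolerance = 1e-9)
    expect_gte(f, v$score_bits - 1e-12)
  }
})

test_that("single-state forward score matches the closed form", {
  prof <- random_profile(1, rng_seed = 9)
  tr <- lapply(prof$transitions, log2)
  em <- log2(prof$match_emissions[1, "A"] / prof$background[["A"]])
  # paths: B->M1->End, and B->D1->End with 'A' in either flank (two paths)
  expected <- log2(2^(tr$mm[1] + em + tr$mm[2]) +
                   2 * 2^(tr$md[1] + tr$dm[2]))
  expect_equal(forward_score(prof, "A", min_len = 1), unname(expected),
               tolerance = 1e-12)
})

test_that("a mapping partitions query positions exactly once", {
  g <- syn_bundle()
  prof <- syn_profile()
  q <- generate_queries(g, 5, rng_seed = 31)
  for (s in q$queries) {
    m <- align_query(prof, s)
    used <- c(seq_len(m$n_flank), m$assignments[!is.na(m$assignments)],
              unlist(m$insertions),
              nchar(m$residues) - m$c_flank + seq_len(m$c_flank))
    expect_equal(sort(used), seq_len(nchar(m$residues)))
    emitted <- m$assignments[!is.na(m$assignments)]
    expect_true(all(diff(emitted) > 0))
  }
})

test_that("short queries are refused as fragments", {
  expect_error(align_query(syn_profile(), cyp_seq("frag", "ACDEFGHIKL")),
               "fragment")
  expect_error(forward_score(syn_profile(), "ACDEF"), "fragment")
})

test_that("sampling is deterministic and mainline is indel-free", {
  prof <- syn_profile()
  a <- sample_path(prof, rng_seed = 5, mode = "mainline")
  expect_equal(nchar(a$seq$residues), prof$n_match)
  expect_equal(a$mapping$assignments, seq_len(prof$n_match))
  expect_equal(sum(lengths(a$mapping$insertions)), 0)
  b <- sample_path(prof, rng_seed = 77)
  b2 <- sample_path(prof, rng_seed = 77)
  expect_identical(b$seq$residues, b2$seq$residues)
  expect_identical(b$mapping$assignments, b2$mapping$assignments)
})

test_that("faithful sampling reproduces the emission table", {
  prof <- random_profile(1, rng_seed = 41)
  draws <- vapply(1:10000, function(i) {
    sp <- sample_path(prof, rng_seed = i)
    k <- sp$mapping$assignments[1]
    if (is.na(k)) NA_character_ else substr(sp$seq$residues, k, k)
  }, "")
  draws <- draws[!is.na(draws)]
  freq <- table(factor(draws, levels = cypmod:::AA20)) / length(draws)
  e <- prof$match_emissions[1, ]
  se <- sqrt(e * (1 - e) / length(draws))
  expect_true(all(abs(freq - e) <= 3 * se + 1e-12))
})

test_that("alignment recovers a generating mainline path under sharp emissions", {
  # near-deterministic emissions, heavy mainline transitions
  prof <- random_profile(8, rng_seed = 13)
  for (k in seq_len(8)) {
    e <- rep(0.01 / 19, 20)
    e[k %% 20 + 1] <- 0.99
    prof$match_emissions[k, ] <- e
  }
  for (nm in c("mm")) prof$transitions$mm <- rep(0.9, 9)
  prof$transitions$mi <- rep(0.05, 9); prof$transitions$md <- c(rep(0.05, 8), 0)
  prof$transitions$mm[9] <- 0.95
  sp <- sample_path(prof, rng_seed = 2, mode = "mainline")
  m <- align_query(prof, sp$seq, min_len = 1)
  expect_equal(m$assignments, sp$mapping$assignments)
})

test_that("profile JSON serialisation round-trips bit-exactly", {
  prof <- syn_profile()
  p <- tmpfile(".json")
  write_profile(prof, p)
  back <- read_profile(p)
  expect_identical(back$match_emissions, prof$match_emissions)
  expect_identical(back$transitions, prof$transitions)
  expect_equal(back$source_columns, prof$source_columns)
  expect_equal(back$anchor_states, prof$anchor_states)
  expect_identical(back$background, prof$background)
})

test_that("flank padding does not reassign anchors", {
  g <- syn_bundle()
  prof <- syn_profile()
  set.seed(99)
  q <- generate_queries(g, 10, rng_seed = 17)
  for (s in q$queries[1:5]) {
    m0 <- align_query(prof, s)
    pad_n <- random_residues(15)
    pad_c <- random_residues(15)
    m1 <- align_query(prof, cyp_seq(s$id, paste0(pad_n, s$residues, pad_c)))
    k <- prof$anchor_states[["f87"]]
    expect_equal(m1$assignments[k], m0$assignments[k] + 15L)
    kc <- prof$anchor_states[["cys"]]
    expect_equal(m1$assignments[kc], m0$assignments[kc] + 15L)
  }
})
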