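# Brute-force glocal path enumeration: the independent oracle for the
# Viterbi and forward implementations.  Explores every legal path through
# the model (free N-flank entry points, M/I/D moves, free C-flank exit)
# and returns the max and log-sum of the per-path log2-odds scores.
enumerate_glocal <- function(profile, residues) {
  a <- strsplit(residues, "", fixed = TRUE)[[1]]
  N <- length(a)
  L <- profile$n_match
  q <- profile$background
  idx <- match(a, names(q))
  em <- matrix(0, max(L, 1), max(N, 1))
  for (k in seq_len(L)) for (i in seq_len(N))
    em[k, i] <- log2(profile$match_emissions[k, idx[i]] / q[idx[i]])
  tr <- lapply(profile$transitions, function(v) {
    out <- suppressWarnings(log2(v)); out[v <= 0] <- -Inf; out
  })
  scores <- new.env()
  scores$v <- numeric(0)
  done <- function(sc) if (is.finite(sc)) scores$v <- c(scores$v, sc)
  # state in {"M","I","D"} at node k having consumed i residues
  rec <- function(state, k, i, sc) {
    if (!is.finite(sc)) return(invisible())
    j <- k + 1L
    if (state == "M") {
      if (k == L) {
        done(sc + tr$mm[j])
        if (i < N) rec("I", k, i + 1L, sc + tr$mi[j])
      } else {
        if (i < N) rec("M", k + 1L, i + 1L, sc + tr$mm[j] + em[k + 1L, i + 1L])
        if (i < N) rec("I", k, i + 1L, sc + tr$mi[j])
        rec("D", k + 1L, i, sc + tr$md[j])
      }
    } else if (state == "I") {
      if (k == L) done(sc + tr$im[j])
      else if (i < N) rec("M", k + 1L, i + 1L, sc + tr$im[j] + em[k + 1L, i + 1L])
      if (i < N) rec("I", k, i + 1L, sc + tr$ii[j])
    } else {
      if (k == L) done(sc + tr$dm[j])
      else {
        if (i < N) rec("M", k + 1L, i + 1L, sc + tr$dm[j] + em[k + 1L, i + 1L])
        if (k < L) rec("D", k + 1L, i, sc + tr$dd[j])
      }
    }
  }
  for (i0 in 0:N) rec("M", 0L, i0, 0)
  v <- scores$v
  if (!length(v)) return(list(best = -Inf, total = -Inf, n_paths = 0L))
  m <- max(v)
  list(best = m, total = m + log2(sum(2^(v - m))), n_paths = length(v))
}

# Random valid profile with L match states for property sweeps.
random_profile <- function(L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  aa <- cypmod:::AA20
  rdir <- function(n) { x <- stats::rexp(n); x / sum(x) }
  E <- t(vapply(seq_len(L), function(k) rdir(20), numeric(20)))
  colnames(E) <- aa
  z <- numeric(L + 1)
  mm <- z; mi <- z; md <- z; im <- z; ii <- z; dm <- z; dd <- z
  for (k in 0:L) {
    j <- k + 1
    if (k < L) { p <- rdir(3); mm[j] <- p[1]; mi[j] <- p[2]; md[j] <- p[3] }
    else { p <- rdir(2); mm[j] <- p[1]; mi[j] <- p[2]; md[j] <- 0 }
    p <- rdir(2); im[j] <- p[1]; ii[j] <- p[2]
    if (k >= 1) {
      if (k < L) { p <- rdir(2); dm[j] <- p[1]; dd[j] <- p[2] }
      else { dm[j] <- 1; dd[j] <- 0 }
    }
  }
  structure(list(n_match = L, source_columns = seq_len(L),
                 match_emissions = E,
                 transitions = list(mm = mm, mi = mi, md = md, im = im,
                                    ii = ii, dm = dm, dd = dd),
                 background = setNames(rep(1 / 20, 20), aa),
                 anchor_states = integer(0),
                 params = list(occupancy_threshold = 0.5,
                               pseudocount_alpha = 1),
                 n_seed_rows = 0L, n_seed_columns = L),
            class = "cyp_profile")
}

random_residues <- function(n) paste(sample(cypmod:::AA20, n, replace = TRUE),
                                     collapse = "")
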