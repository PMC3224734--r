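# Shared fixtures built in code.

tmpfile <- function(ext = "") tempfile(fileext = ext)

write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

# Small default-parameter synthetic seed bundle, built once per test run.
syn_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cypmod::generate_seed()
    cache
  }
})

syn_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- syn_bundle()
      cache <<- cypmod::build_profile(g$seed, g$annotation)
    }
    cache
  }
})

# Reference-row identity annotation of the synthetic seed.
syn_ref_annotation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- syn_bundle()
      ref <- cypmod::cyp_seq(g$seed$ids[1],
                             gsub("-", "", g$seed$rows[1], fixed = TRUE))
      cache <<- cypmod::annotate_sequence(syn_profile(), g$annotation, ref)
    }
    cache
  }
})

# A minimal hand-built annotation result for the tabular writers.
fake_result <- function(id = "q1", gate = TRUE, score = 123.4567,
                        scrs = list(SCR1 = c(start = 5, end = 12),
                                    SCR2 = c(start = 20, end = 31)),
                        f87 = list(pos = 15L, residue = "F"),
                        ris1 = 4L, ris2 = 5L, cls = "classI") {
  structure(list(query_id = id, gate_pass = gate, gate_score_bits = score,
                 scr_intervals = scrs, f87_call = f87,
                 ris1_len = ris1, ris2_len = ris2, redox_class = cls),
            class = "cyp_annotation")
}
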