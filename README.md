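# cypmod — structure-anchored annotation transfer for cytochrome P450s

Cytochrome P450 monooxygenases (CYPs) share one conserved fold at sequence
identities that can fall below 20%, which makes the functionally decisive
positions — the substrate-specificity hotspot homologous to **F87** of
CYP102A1 (P450 BM-3) in the hypervariable BC-loop, and the two
**reductase interaction sites** RIS1 (αJ/J′ region) and RIS2 (the
insertion between the meander loop and the Cys-pocket) — nearly impossible
to locate by ordinary sequence alignment.  cypmod solves this by encoding
an annotated, structure-derived seed alignment as a **profile hidden
Markov model** and transferring its annotations onto plain protein
sequences:

* the 19 **structurally conserved regions** (SCRs) of the CYP fold, as
  start/stop positions on the query;
* the **F87-equivalent position** and its residue (or a gap call when the
  BC-loop houses no heme-facing residue);
* the **RIS1/RIS2 lengths**, counted as query residues strictly between
  the terminal match states of the flanking SCRs, and the derived
  **redox class** (class I: both short; class II: both long; a very-long
  RIS2 subgroup of reductase-independent CYPs; ambiguous / discordant /
  unusual otherwise);
* an **applicability gate** (forward score ≥ 100 bits plus a mapped
  heme-ligating cysteine) that rejects non-CYP folds.

The model is a classic match/insert/delete profile HMM with
background-weighted pseudocounts
`e(a) = (n(a) + α·q(a)) / (n + α)`, aligned in *glocal* mode (global in
the model, free query flanks) with log-space Viterbi/forward recursions in
C++ and fixed tie-breaking for bit-reproducible output.  Anchor and SCR
boundary columns are always match states, so every annotated feature is
representable on every query.  A leave-one-out driver validates
anchor-position prediction by rebuilding the profile without each seed row
in turn, and a synthetic generator emits schema-complete seed alignments
and query sets with exact ground truth.  See
`vignettes/cypmod-methods.Rmd` for the full model description and design
rationale.

## Worked example

A schema-complete synthetic seed (20 rows × 395 columns, 19 SCRs, JSON
annotation sidecar) ships under `inst/extdata/`:

```r
library(cypmod)

ld <- load_seed(
  system.file("extdata", "synthetic_seed.afa",  package = "cypmod"),
  system.file("extdata", "synthetic_seed.json", package = "cypmod"))
profile <- build_profile(ld$seed, ld$annotation)
profile
#> <cyp_profile> 326 match states (from 20 seed rows x 395 columns), 8 anchors

g <- generate_seed()                      # the bundle behind the fixture
q <- generate_queries(g, 3, rng_seed = 7) # queries with known truth
res <- annotate_sequence(profile, ld$annotation, q$queries[[1]])
res
#> <cyp_annotation> query0001: gate pass (741.3 bits), F87-equivalent F46,
#>   RIS1 22, RIS2 18, class classII_verylongRIS2
res$scr_intervals$SCR16
#> start   end
#>   252   265

leave_one_out(ld$seed, ld$annotation)
#> <cyp_loo_report> 19 folds: exact 100.0%, within 2 residues 100.0%
```

The annotation says: the query passes the fold gate at 741 bits, its
heme-facing BC-loop residue is a phenylalanine at position 46, its αJ/J′
region spans 22 residues and its meander insertion 18 — a long RIS1 with a
very-long RIS2, i.e. the class II subgroup typical of
reductase-independent CYPs.  Batch helpers (`composition_at_anchor()`,
`ris_distribution()`, `class_fractions()`) aggregate such results, and
`write_results_tsv()` / `write_gff3()` export them.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/cypmod.R simulate --out-dir fix --seed 42
Rscript inst/cli/cypmod.R build    --aln fix/seed.afa --sidecar fix/seed.json --out fix/profile.json
Rscript inst/cli/cypmod.R annotate --profile fix/profile.json --sidecar fix/seed.json \
                                   --queries fix/queries.fasta --out fix/results.tsv
Rscript inst/cli/cypmod.R stats    --results fix/results.tsv --out fix/stats.json
Rscript inst/cli/cypmod.R loo      --aln fix/seed.afa --sidecar fix/seed.json --report fix/loo.tsv
```

For real data, `cyp_seed_manifest()` lists the 31 seed crystal structures,
`fetch_seed_sequences()` obtains their sequences (cache-first; network
only on a cache miss) and `bootstrap_seed_alignment()` reconstructs an
approximate seed alignment by pinning the ExxR and FxxGxxxCxG Cys-pocket
motifs and refining by profile realignment.

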