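---
title: "Structure-anchored annotation transfer for cytochrome P450s: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-anchored annotation transfer for cytochrome P450s: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cytochrome P450 monooxygenases (CYPs) share a single conserved fold even
though pairwise sequence identity across superfamilies can drop below 20%.
Only three residues are essentially invariant: the glutamate and arginine of
the ExxR motif and the heme-ligating cysteine.  The fold decomposes into
structurally conserved regions (SCRs) — in the seed model used here,
19 of them, covering the canonical helices A–L and sheets 1–4 — separated
by variable regions that carry the functional individuality: the BC-loop
with the substrate-specificity hotspot homologous to F87 of CYP102A1
(P450 BM-3), and the two reductase interaction sites, RIS1 (the αJ/J′
region) and RIS2 (the insertion between the meander loop and the
Cys-pocket), whose lengths discriminate the redox-partner classes.

cypmod encodes an annotated, structure-derived seed alignment as a profile
hidden Markov model and uses it to transfer those annotations onto plain
protein sequences.  Structure enters only through the seed alignment and
its JSON sidecar; at run time everything is sequence-based.

## The profile HMM

The model is the classic match/insert/delete column architecture.  A seed
column becomes a match state when its non-gap fraction reaches the
occupancy threshold (default 0.5); anchor columns (F87, ExxR, Cys, the
RIS flanks) and all SCR boundary columns are force-included regardless of
occupancy so that every annotated feature is representable on every query.
Emissions use a single-parameter background-weighted pseudocount,

$$e_k(a) = \frac{n_k(a) + \alpha\, q(a)}{n_k + \alpha},$$

with $\alpha = 1$ by default and a uniform background $q$ (both
overridable).  `X` residues occupy a column but contribute no emission
count and score 0 bits on queries.  Transitions are estimated from the
observed state paths of the seed rows with the same pseudocount scheme
(uniform prior over each state's allowed moves).  The architecture has no
I→D or D→I edges; the rare seed paths that would need them are absorbed
into the match-routed counts.  This is the smallest defensible scheme: the
seed has tens of rows, so elaborate mixture priors or sequence weighting
would be poorly constrained.  No sequence weighting is applied by default.

Alignment is *glocal*: the model is traversed begin-to-end while the query
may carry unbounded N-/C-terminal flanks that emit at background odds
(0 bits).  CYP queries are full-length proteins with highly variable
termini — for fusion enzymes such as CYP102A1 the entire reductase domain
simply falls into the C-flank — while annotation transfer requires
traversing the whole model.  All arithmetic is in log2 space; scores are
reported in bits.  Viterbi ties are broken Match > Delete > Insert, and at
the model exit toward the smallest number of consumed residues, so outputs
are bit-reproducible across platforms.  The Viterbi and forward recursions
are implemented in C++ (Rcpp); both are verified in the test suite against
an independent brute-force enumeration of all legal paths on small models
(up to 6 match states × 8 residues).

Queries shorter than 50 residues are refused as fragments (configurable).
Profiles serialise to versioned JSON with probabilities as decimal strings,
which round-trip bit-exactly.

## Annotation transfer

* **SCR intervals** — for each SCR, the query interval spans the first to
  the last non-deleted match state whose source column lies in the SCR;
  an SCR whose states are all deleted is reported absent.
* **F87-equivalent** — the query position and residue emitted at the F87
  anchor state; a deleted anchor is a *gap call*, meaning the BC-loop
  houses no residue at the heme-facing position.
* **RIS lengths** — the number of query residues strictly between the two
  anchor states (the terminal match states of the flanking SCRs):
  `pos(right) − pos(left) − 1`, counting match emissions and insertions
  alike.  The counting convention between the conserved flanks is not
  uniquely determined by prose descriptions of "residues spanning the
  region", so the anchor columns in the sidecar are the calibration point:
  they are data, not code.  A deleted anchor falls back to the nearest
  emitting match state inward within its flanking SCR; a fully deleted
  flanking SCR makes the length undefined.
* **Redox class** — from the two lengths via fixed bands:
  RIS1 short ≤ 9, long ≥ 16, ambiguous 10–15; RIS2 short ≤ 6, long 11–17,
  very long ≥ 18, ambiguous 7–10; either length ≥ 36 is flagged unusual
  (formally class II).  Both short → class I; long/long → class II;
  long/very-long → the reductase-independent class II subgroup;
  short/long mixtures → discordant; any undefined length → discordant.
  Two edge choices are deliberate: RIS2 = 7 falls in the ambiguity window
  (the published bands leave 7 unassigned between "&lt; 7" and "8–10"),
  and RIS2 = 18 is classified very long (the bands overlap at 18; we close
  the gap at ≥ 18).
* **Applicability gate** — a database-free replacement for a
  homology-search pre-filter: a query is applicable when its forward
  (all-paths) score reaches 100 bits and its Cys anchor maps onto a
  cysteine.  The threshold is generous: on the synthetic seed the
  reference scores ~900 bits while length-matched random sequences score
  far below zero, and the intent is only to reject non-CYP folds, not to
  rank homologs.  Gate failure still returns all structural fields; the
  caller decides what to trust.

## Leave-one-out validation

Each non-reference seed row is dropped in turn, the profile rebuilt from
the remaining rows with identical parameters, and the dropped row's
degapped sequence aligned to predict the F87-equivalent position, compared
against the row's own column placement (exact / deviation by 1 / by 2 /
wrong / gap).  Two design choices: the seed alignment is *not* recomputed
per fold (the alignment is input data here; the structural superposition
that produced it is out of scope), and the reference row is never held out
because column-to-reference bookkeeping depends on it.  A fold whose
removal leaves an anchor column unobservable is reported as a gap, not a
crash.

## The synthetic generator

The generator emulates an annotated seed alignment with known ground
truth: 19 conserved SCR blocks (6–14 columns, consensus residues, per-column
conservation 1.0 by default) separated by variable linkers (2–8 residues
per row), ExxR and the FxxGxxxCxG Cys-pocket signature at fixed columns,
a fully occupied F87 column drawn from the published composition of that
position (F 22%, L 22%, V 12%, I 10%, A 9%), and class-conditional RIS
insertions using the published bands (class I 3–5/3–5; class II 21–22/11–17;
very-long subgroup RIS2 18–23).  The default class mixture (0.5/0.4/0.1)
mirrors the composition of the structure set behind the published seed.
The F87 column sits inside the BC-loop block bracketed by 5 conserved,
fully occupied columns per side, modelling the informative match columns
that bracket the hotspot in the real profile.

Two fidelity caveats.  First, variable-region residues are drawn from the
alphabet *minus* the consensus residues of the adjacent SCR boundary
columns: if a loop residue could equal the boundary consensus, the
residues-between-anchors count would be genuinely ambiguous under optimal
alignment (two co-optimal paths), and no aligner could recover the
generating truth deterministically.  This is a ground-truth
identifiability choice, not a claim about real sequences.  Second, real
CYP variable regions have biased composition, correlated indels and much
lower core conservation than the default 1.0; passing the synthetic
recovery tests therefore demonstrates correctness of the machinery
(coordinate bookkeeping, anchor transfer, length counting,
classification), not expected accuracy on real proteins — that is what
the leave-one-out design on a real seed measures.

Default problem sizes used throughout the tests and the acceptance script
— 20 seed rows, 200 annotated queries, 2,000-sequence cohorts for band
fractions, 5,000 draws for anchor composition — are chosen so that
binomial sampling error is well below the effects being checked.

## The real-data layer

A manifest of the 31 seed crystal structures (12 class II, 16 class I,
3 unusual) ships with the package.  Sequence fetching is cache-first
(per-PDB FASTA files, checksummed); without a warm cache it requires
network access.  Because the original structure-derived seed alignment is
not redistributable, `bootstrap_seed_alignment()` reconstructs an
approximation from sequence alone: each sequence is pinned at its ExxR and
Cys-pocket motifs, block-justified so the three anchors share columns, and
refined by two rounds of profile realignment.  The reconstruction is
deterministic and keeps the anchored cysteine column intact, but it is not
a structural alignment: annotations derived from it are approximations,
and the refinement is not guaranteed to reach a strict fixed point (insert
padding near low-occupancy columns can oscillate between rounds).  All
real-data comparisons are therefore tolerance-framed and reported
side by side rather than asserted exactly.

## Known limitations

* No local–local alignment mode and no E-value calibration; the bit-score
  gate is a fold filter, not a significance test.
* Multi-domain fusion proteins are not parsed; only the P450 domain region
  aligned by the model is annotated.
* Ambiguity codes B/Z/J/U/O are rejected rather than marginalised, keeping
  the emission arithmetic well-defined; `X` is accepted as unknown.
* Crystal-structure versus sequence numbering discrepancies are outside
  the tool's control; all reported coordinates are 1-based positions in
  the provided input sequence.
* Database-scale composition percentages depend on the snapshot of the
  sequence database they were measured on and are reproduced only
  qualitatively, via configured synthetic cohorts.
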