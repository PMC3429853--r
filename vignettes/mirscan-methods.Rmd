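---
title: "mirscan: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirscan: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscan)
```

## The problem

Short hairpin RNAs embedded in the miR30 microRNA backbone are processed
by Drosha and Dicer into a 22-nt guide strand that loads into RISC and
silences its target mRNA. Only a minority of possible guides along a
transcript silence well, and potency is predictable from the guide
sequence itself: position-dependent nucleotide preferences (a 5′-terminal
U is strongly favored for RISC loading; A at position 20 is strongly
avoided) and duplex thermodynamics (efficiency is a bell-shaped function
of total guide–target duplex stability, with an optimum near −33 kcal/mol
— most candidate sites on a typical transcript cluster near −40 kcal/mol
and are therefore over-stable). `mirscan` packages a regression model of
this relationship, the thermodynamic machinery it needs, artifact
filters, a transcript scanner, and the training pipeline to refit the
model on new activity tables.

## The scoring model

The response is the natural logarithm of the silencing score (percent
knockdown in 0–100). The predictor is linear in: a cubic polynomial of
the total duplex free energy (`dG`, `dG2`, `dG3`), the first-dinucleotide
stack energy (`dG1`), and three-of-four one-hot nucleotide indicators per
guide position. The shipped coefficient table (`mirscan_model("table2")`)
carries the published weights for the complete-database model: intercept
−43.85, four thermodynamic terms, 37 nucleotide terms. Natural log is
used throughout; the log base is a convention choice the coefficient
scale depends on, so user-supplied models must match it.

Scoring is a pure dot product (`score()`); every model term must resolve
against a feature column by **name** — the one-hot column order is never
relied upon, which removes any ambiguity about nucleotide encoding order.

## Thermodynamics

All energies are Gibbs free energies at 37 °C in kcal/mol.

**Duplex stability.** `duplex_dG_total()` sums Watson–Crick
nearest-neighbor stack energies along the guide paired with its exact
complement. The bundled stack table is the Xia et al. 1998 set
(`inst/extdata/xia1998_stacks.tsv`, swappable via `nn_params()`).
Corrections (helix initiation +4.09, terminal A·U +0.45 per end) are
**on** by default; since the convention behind a published ΔG axis is
rarely stated, the bare stack sum is available with `corrections =
FALSE`. The per-position profile `duplex_dG_profile()` gives the local
stack stabilities ΔG₁…ΔG₂₁ used by profile-extended models.

**Folding grammar.** `fold_self_dG()` is a Zuker-style MFE dynamic
program over nested structures with: Watson–Crick pairs only (the stack
table covers exactly the 16 WC stacks; G·U wobble is a documented
omission), minimum hairpin loop 3, hairpin/bulge/internal penalties by
total unpaired size, a linear multiloop model (3.4 + 0.4 per branch,
unpaired bases free), loop spans capped at `maxloop = 30`, no coaxial
stacking, no dangles, no terminal-A·U inside folds. The loop tables keep
Turner-family magnitudes but are smoothed to be monotone non-decreasing
in loop size with Jacobson–Stockmayer extrapolation — the loop model of
the original oligo-folding tools is unpublished, so this is an explicit,
versioned stand-in (`inst/extdata/loop_penalties.tsv`). What matters
downstream is a scalar stability used by one filter and one optional
feature, not base-pair-level accuracy; the compact grammar buys an
airtight correctness argument instead: `structure_energy()` scores any
explicit structure under the same model, and the test-suite verifies the
DP against exhaustive enumeration over all structures for a thousand
random sequences (length ≤ 14), plus re-scores every traceback.

**Dimer and target structure.** `dimer_dG()` minimizes over antiparallel
inter-molecular hybridizations (stacks, bulge/internal gaps, initiation,
terminal A·U; never positive). Symmetry in its arguments follows from
the reverse-complement symmetry of the stack table and is property-
tested. `target_local_dG()` folds a clipped window (default flank 100 nt)
around the target site as a proxy for local target accessibility —
a deliberate simplification of partition-function accessibility, which is
out of scope. The fold cost grows steeply with window size; use small
flanks for bulk scans.

## Filters

* **Motifs** (exact substrings on the guide): UGGC, GCCA (cell-viability
  artifacts), GGGG, UUUU, AAAA (low-complexity runs; UUUU additionally
  is an RNA polymerase III termination signal). CCCC is deliberately not
  listed — removing it was found not to improve prediction.
* **Low complexity**: classic DUST triplet score, window = whole guide,
  score `sum(c_t(c_t−1)/2)/(w−3)`; the published account names the
  method but not its cutoff, so the threshold (default 2.0, flag when
  score exceeds it) is an exposed tunable. A 22-nt homopolymer scores
  10; all-distinct triplets score 0.
* **Self-structure**: guide MFE < −2 kcal/mol flags a guide whose
  intramolecular structure competes with target pairing.
* **Seed identity**: guide positions 2–7 (canonical miRNA hexamer seed;
  configurable to 1–8) matched exactly against a seed set extracted from
  a mature-miRNA FASTA, to avoid engineering a guide that mimics a known
  miRNA. Motif matching is applied to the guide strand only.

Filters are independent, order-invariant and idempotent; the survivor
set is the intersection of the per-filter pass sets.

## Training pipeline

`correlate_features()` screens features by Pearson correlation with the
ln response (two-sided t-test p-values; constant columns report R = 0,
p = 1, flagged degenerate). `select_parameters()` adds the stability
criterion: the data are split at random into n = 5 (or 10) equal parts,
the per-part correlation is computed for every feature, and over 1000
such splits the standard deviation of R (S_n) must stay ≤ 0.065 for a
feature to be kept, alongside |R| ≥ 0.014 and p < 0.05. `fit_ols()` is a
QR least-squares fit with classical t-test p-values (matching the
spreadsheet-era regression output the coefficients came from; no
multiple-testing correction, documented). Rank deficiency is a hard
error naming the collinear columns — which is why the full 88-indicator
matrix must first be reduced to 66 columns by `reduce_matrix()` (drop
the least-|R| base per position; ties broken by larger p, then
alphabetically, for determinism). The reduction is computed on the
training split only when used inside cross-validation, matching the
principle that parameter selection sees only training data.

`reduce_model()` implements the published elimination protocol: refit
each round, removing among insignificant terms at most one nucleotide
indicator per position (largest p at that position) and at most one
thermodynamic term, until everything left is significant.
`cross_validate()` uses non-overlapping equal folds, each record
predicted exactly once, and reports R² by the explicit
(ActualVariation − Error)/ActualVariation formula — an identity test
confirms this equals the squared Pearson correlation for in-sample
least-squares predictions and 0 for the mean predictor. `roc_auc()`
labels records efficient at a threshold (default 75% silencing — a
convention, since "efficient" has no canonical numeric definition;
confirm it per analysis) and computes trapezoidal AUC, verified against
Mann–Whitney pair counting.

Activities of 0 are floored at 0.5% before taking logs (`ln_floor`,
configurable): the data scale includes exact zeros and ln(0) must be
guarded somewhere; the floor value is half the smallest nonzero percent
one would report at integer precision.

## The synthetic world

`synth_activity_dataset()` generates random 22-mer guides (i.i.d. bases,
GC 0.5 by default — matching a typical mammalian transcript rather than
any particular one) and simulates
`ln_activity = score(features, generating model) + N(0, sd)` with
`sd = 1.0` by default, roughly the residual scale at which the published
model's training correlation (~0.5) lives relative to the indicator
signal variance. Percent activity is `exp(ln_activity)` clipped to
[0.5, 100], and clipped records are flagged.

One measured property of this world matters for testing: under the
shipped coefficient table, random guides score ≈ −10…0 on the ln scale,
so `exp(score)` is below the 0.5% floor for essentially every record and
the percent column saturates at the clip. The printed coefficients are
internally consistent as a ranking model but their absolute scale does
not map random-guide scores into the observable percent range — a
property of the published values, not of this implementation. The
generator therefore stores the latent `ln_activity` alongside the
clipped percent, and `activity_response()` prefers it when present.
Parameter-recovery tests (n = 5000, noise sd 1.0, 20 seeds: every one of
the 42 generating parameters recovered within 3 standard errors in ≥ 95%
of seeds; cross-validated R within 0.05 of training R) run on that
latent response, which is exactly the stated generating model. What a
green recovery test establishes: the fitting, fold construction and
standard errors are correct. What it does not establish: anything about
real sensor-assay data — the generator has no per-transcript
heterogeneity, no measurement-error structure, no sequence composition
bias, and its guides are not drawn from real transcripts.

## Numerical conventions and degenerate inputs

* Positions are 1-based from the guide 5′ end; transcript coordinates
  are 1-based inclusive on the sense strand.
* DNA input (T, lowercase) is normalized at I/O boundaries only;
  internal alphabet is strictly ACGU. Candidate windows containing other
  IUPAC codes are skipped and counted, never errored.
* Binning (`bin_by_feature()`) uses right-closed intervals — a value on
  an interior edge belongs to the bin on its left; empty bins are
  reported with count 0.
* Scan ranking sorts survivors by descending score with a stable
  position tie-break; ties in ROC are handled by the trapezoid (= 1/2
  credit per tied pair).
* Guide length defaults to 22 everywhere but is overridable in the
  thermodynamic API for library reuse.
* Constant-activity datasets: correlations are reported as 0 with p = 1
  and a degenerate flag; `reduce_matrix()` then falls back to its
  deterministic alphabetical tie-break and says so.

## Known limitations

* No G·U wobble pairs and a simplified loop model in the folder: MFE
  values are comparable within this package, not with Turner-complete
  folders.
* Partition-function target accessibility is not implemented; the
  windowed MFE proxy understates accessibility differences.
* The built-in model is miR30-specific; applying it to synthetic siRNAs
  contradicts its training domain (3′-end preferences differ in sign).
* Published dataset-dependent statistics (training/CV correlations near
  0.4–0.6, AUC, ΔG histogram maxima, hit-rate enrichment) require the
  original external activity table and are intentionally not asserted
  anywhere; the pipeline that would compute them is fully implemented
  and property-tested instead.
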