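---
title: "Hybrid composition features and SVM classification of anticancer peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid composition features and SVM classification of anticancer peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpep)
```

## The problem and the model

Anticancer peptides (ACPs) are short peptides — typically 12–50 residues,
often cationic and amphipathic, folding into membrane-active α-helices or
β-sheets — whose composition differs systematically from that of ordinary
proteins. `acpep` classifies peptides as anticancer / non-anticancer from
primary sequence alone, using a support-vector machine over three
composition-based feature families and a cross-validation harness that
reports the field's standard metrics (Sn, Sp, Qa, MCC).

The package is organized in the classic R modelling idiom: `acp_fit()` is
the front-door fitting function returning an `acp_model` with `print`,
`summary`, `predict` and `plot` methods, while every pipeline stage
(encoders, scaler, grid search, CV, metrics, simulator, CLI) remains an
exported function so each step can be audited or rearranged. `residuals`
and `simulate` methods are deliberately absent: a kernel SVM over peptide
sets has no natural residual, and data simulation is a first-class module
(`simulate_peptides()`) rather than a method of a fitted object.

## Feature encoders

**AAC.** The amino-acid composition is `f_i = n_i/L` over the 20 canonical
residues, in fixed alphabetical order `ACDEFGHIKLMNPQRSTVWY` so column
identity never depends on the data. Rows sum to 1 exactly; the encoder is
permutation-invariant by construction.

**RAAC.** Hydropathy patterns matter more for global fold than residue
identity, so the 20 letters are collapsed to 6 groups — {R,D,E,N,Q,K,H},
{L,I,V,A,M,F}, {S,T,Y,W}, {P}, {G}, {C}; proline, glycine and cysteine keep
singleton groups because their backbone chemistry is sui generis. The 36
ordered group dipeptides are counted over the `L−1` overlapping windows.
The default divides counts by `L` — the literal reading of the defining
formula, under which components sum to `(L−1)/L`, not 1 — because we
preferred reproducing the stated convention over prettier normalization;
`normalization = "L1"` divides by `L−1` and sums to 1. The choice is
recorded in the encoder metadata and affects the SVM only through the
min–max rescaling, i.e. barely.

**acACS.** Backbone chemical shifts correlate with secondary structure, so
a per-residue table of reference average shifts for ¹Hα, ¹H_N, ¹⁵N and ¹³Cα
turns a sequence into four numeric profiles carrying coarse structural
signal. Each atom's 20 reference values are standardized to mean 0, sd 1
across residues (tolerance 1e−9, idempotent, zero-variance atoms are an
error) so atoms contribute on a common dimensionless footing. For each atom
and lag `d = 1..λ` the encoder records the correlation factor

θ(d) = (1/(L−d)) Σ_{p=1}^{L−d} (s_p − s_{p+d})²,

the mean squared lagged difference. The descriptor family this belongs to
admits more than one published functional form; we adopt the
squared-difference form as the default (it is the standard one in
pseudo-composition descriptors), and provide the centered lagged
autocovariance behind `form = "autocov"`. Both vanish on homopolymers,
which the tests assert; the squared-difference form is additionally
reversal-invariant. Defaults are λ = 5 — the lag at which jackknife
accuracy peaks for this descriptor on ACP benchmarks — and all four atoms,
since no single atom combination is canonically superior; both are plain
arguments, and callers can script their own selection loop.

The packaged chemical-shift table
(`inst/extdata/chemical_shift_scale_synthetic.tsv`) is a *synthetic
stand-in*: approximate random-coil-style average shifts compiled from
widely circulated reference ranges, with proline's non-existent amide
proton imputed. It is adequate for exercising the pipeline and for relative
comparisons, but any serious application should supply a measured scale via
`read_shift_scale()`. Every numeric θ assertion in the test suite uses
explicit toy scales, never the packaged table, so the tests do not depend
on its provenance.

Blocks are concatenated in caller order with prefixed, deterministic column
names (`aac:G`, `raac:1-2`, `acacs:N15:d3`). Whether such lagged terms were
ever meant to be blended into a single weighted pseudo-composition vector
rather than plainly concatenated is ambiguous in the descriptor literature;
we implement plain concatenation and note the alternative here rather than
guessing at a weight.

Minimum-length rules are hard errors, never silent padding: `L ≥ 1` for
AAC, `L ≥ 2` for RAAC, `L ≥ λ+1` for acACS; `encode_features()` names the
offending record.

## Classifier

The SVM is a binary C-SVC with RBF kernel `exp(−γ‖x−x′‖²)`, solved by
sequential minimal optimization with maximal-violating-pair working-set
selection (stopping tolerance 1e−3 on the KKT gap; alphas are snapped to
exact bounds so rounding cannot stall the selection). No R SVM library is
assumed: the solver is part of the package and is cross-checked in the test
suite against an independent LibSVM-style implementation on a fixture with
free support vectors, where the decision function is fully determined.

Numerical conventions, all tested:

* **Scaling** — min–max to [0,1], fit on training rows only (re-fit inside
  every CV fold); constant features map to 0; out-of-range values
  extrapolate without clipping.
* **Tie rule** — decision value exactly 0 classifies as positive
  (anticancer). Arbitrary, documented.
* **Grids** — `C ∈ 2^{−5,−3,…,15}`, `γ ∈ 2^{−15,−13,…,3}` by default (the
  conventional RBF-SVM grid); ties break to smallest `C`, then smallest
  `γ`, so selection is deterministic given the fold seed. Singleton grids
  fix the pair without searching.
* **Class weighting** — none; class imbalance is left as-is.

## Evaluation

`run_cv()` supports the jackknife (leave-one-out; `n` models for `n`
records, every record predicted exactly once by a model that never saw it)
and seed-shuffled stratified k-fold. Hyperparameter tuning happens either
once on the full data (`tuning = "global"`, the default — it is the cheaper
protocol and the likelier reading of how such benchmarks are usually run,
but the held-out records leak into selection, and every report says so) or
inside each training split (`per_fold`, the statistically honest mode).
Fold-wise scaler ranges are exposed in the result so leakage-freedom of the
scaling is structurally checkable, and the tests do check it.

Metrics follow the standard definitions; `Qa` equals the
prevalence-weighted mean of Sn and Sp as an exact identity on unrounded
values. MCC with a zero denominator factor is reported as 0 with a warning
flag (the common convention). Reported percentages are rounded **half-up**
to 2 decimals and MCC to 3 — matching how such tables are printed —
while unrounded values stay available; base R's round-half-to-even would
disagree with printed tables on boundary cases.

`recover_confusion()` inverts printed tables: given two-decimal Sn/Sp and
class sizes it reconstructs the integer confusion counts, flags rows whose
printed values cannot round-trip from any integer count, and lets the
package audit published Qa/MCC arithmetic without access to the underlying
data. The acceptance tests use it to verify benchmark-table arithmetic and,
where a printed MCC is internally inconsistent with its own row, assert the
arithmetically implied value instead and document the discrepancy.

## The synthetic-data generator: a stated world

`synthetic_spec()` fixes the generator's world once: class sizes default to
138/206 (the shape of the canonical ACP benchmark), lengths uniform on
12–50 (the typical ACP length band), residues i.i.d. from a uniform
background for negatives, and for positives from the mixture
`(1−δ)·background + δ·uniform({K,L,F,G})` — the enriched set mirrors the
cationic/hydrophobic character of real ACPs. Uniform background was chosen
over natural frequencies because it makes expectations analytic (the
expected enriched-set excess is exactly `δ(1 − 4/20)`), which the tests
verify by brute-force tally; a natural-frequency background is available by
flag. Generation is fully deterministic given the seed and restores the
ambient RNG stream.

What a green test on this generator does and does not establish: the
i.i.d. residue model carries compositional signal only, so it exercises
AAC/RAAC separability, chance-level behaviour at δ = 0, and the
dose–response of accuracy in δ. It has no positional or secondary-structure
signal, so acACS features carry only weak incidental signal on it, and
green pipeline tests say nothing about how well any feature family captures
real structural propensities — that requires real benchmark data, which is
deliberately not bundled.

At the stated world the package's acceptance surfaces measure, for AAC
features with fixed mid-grid hyperparameters: mean jackknife MCC within
±0.1 of 0 over 20 seeds at δ = 0; 5-fold Qa ≥ 90% at δ = 0.30 with 60+60
peptides; and mean 5-fold Qa non-decreasing across δ ∈ {0, 0.1, 0.2, 0.3}
over seeds 1–10 (at most one inversion ≤ 1 point). The reduced grids used
there are configuration, not model changes, chosen to keep the suite inside
a desktop-scale runtime.

## Known limitations

* The packaged chemical-shift scale is synthetic (see above).
* Only the RBF kernel and binary classification are supported; no
  probability calibration, no ROC/AUC.
* Ambiguous residues (B, J, O, U, X, Z) are rejected by default; the
  `drop-record` / `delete-residue` policies are conveniences, not
  statements about how any published benchmark handled them.
* `global` tuning mode reproduces a leaky but common protocol; conclusions
  about generalization should use `per_fold`.
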