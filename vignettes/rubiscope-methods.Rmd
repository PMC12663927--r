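---
title: "Methods: sequence-space coverage, rate harmonization and rate prediction for rubisco kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-space coverage, rate harmonization and rate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubiscope)
```

`rubiscope` packages the computational chain behind large-scale
surveys of rubisco carboxylation kinetics: quantifying how much of the
family's sequence space the kinetically characterized variants cover,
putting heterogeneous rate measurements on one scale, predicting rates
from sequence with identity-aware models, and attributing rate
variation to alignment positions. This vignette records the models,
their assumptions, the tunable parameters, and the design choices made
where the methods literature leaves the details open. Every empirical
statement here is one the package's tests or acceptance script
computes.

## Sequence space

**Containers.** An alignment is an ordinary tibble (`id`, `seq`,
`form`, `characterized`, `complete`) validated by `as_alignment()`;
equal row lengths and unique ids are enforced, and a `column_map`
attribute traces trimmed columns back to the original alignment.

**Identity.** `pairwise_identity()` is Hamming identity on aligned
rows: matching columns divided by compared columns. Columns gapped in
*both* sequences are excluded; a gap against a residue is a compared
mismatch; the ambiguity code `X` matches nothing, including another
`X`. This is the standard alignment-identity convention and keeps
identity(a, a) = 1 for any gapped sequence. One identity definition is
used everywhere — clustering, coverage, model weighting and CV
thresholding — although greedy clustering tools compute their own
internal identities; on a shared alignment the two need not coincide
exactly, which is why the definition is pinned here.

**Trimming.** `trim_gap_columns()` removes columns whose gap fraction
*strictly* exceeds `max_gap_frac` (default 0.95, i.e. a column kept by
at least 5% of sequences survives; 19/20 = 0.95 is kept). Trimming is
idempotent at a fixed threshold.

**Length filter.** Ungapped lengths outside the inclusive
300–700-residue window are rejected (plausible large-subunit range;
fragments and fusions fall outside it), with a per-sequence rejection
report.

**Clustering.** `greedy_cluster()` re-implements greedy centroid
clustering: sequences are scanned in a fixed order (default:
decreasing ungapped length, ties by id — the convention of the usual
tools; `"input"` order is available so tests can fix the scan), each
joining the first centroid at ≥ threshold identity or founding a new
cluster. The output satisfies, and the tests verify by brute force,
both invariants: members ≥ threshold to their centroid, centroids
pairwise < threshold. A threshold of 0 yields one cluster; thresholds
above 1 clamp to 1, so exact duplicates still co-cluster.

**Diversity coverage.** For thresholds X (default grid 0.50–1.00 by
0.05), coverage(X) is the fraction of representative sequences —
typically the centroids of a 90%-identity clustering — whose best
identity to any characterized variant is at least X. Using cluster
representatives de-biases the metric against heavily sequenced groups.
The curve is monotone non-increasing by construction.

## Rate harmonization

Rate tables carry one row per measurement (`variant_id`, `kcat_c` in
s⁻¹, `temp_c`, `assay`, `batch_id`, `source`) plus three flags so each
transform is applied exactly once; re-application is an error.

**Q10.** `q10_correct()` rescales to a target temperature (default
30 °C) with k′ = k·Q10^((T₀−T)/10), Q10 = 2.2 — the standard value for
bringing literature rubisco rates to 30 °C. Correcting to T and back
recovers the input to floating precision.

**Control normalization.** Every pipeline batch includes the same
control rubisco; `normalize_to_control()` multiplies batch b by
`control_reference / g_b`, with g_b the *geometric* mean of the
batch's control measurements — the natural location statistic for
log-normally distributed rates. After normalization each batch's
control geometric mean equals the reference exactly. The reference is
a configuration value (default: the grand geometric mean of the
control's own measurements, which removes batch effects without
rescaling the overall level); it is not hard-coded because no
canonical printed value exists. Batches lacking a control are left
unscaled and reported, not guessed at.

**Assay calibration.** Coupled spectrophotometric assays
systematically read low relative to direct assays. With variants
measured by both, a log–log fit with slope fixed to 1 reduces to the
mean log-ratio b = mean(ln k_direct − ln k_coupled); the correction is
factor = e^b (a geometric-mean ratio, invariant to common rescaling
and to the logarithm base). The confidence interval is a t-interval on
the log-ratios, exp(b ± t_{n−1} s/√n): the minimal defensible choice
given n ≈ 11 pairs, and one whose nominal coverage is testable — the
acceptance suite injects a bias of 2.1 into 200 replicates of 11 noisy
pairs and observes ≈ 95% CI coverage. Published intervals may have
been produced by other means (bootstrap, regression software), so
exact endpoint agreement is not expected.

**Summaries and the rate-ratio landscape.** Summaries report n,
median and 0.25/0.75 quantiles (linear interpolation between order
statistics). `rate_ratio_vs_identity()` computes, for every unordered
pair of measured variants, the identity and the ratio
max(kᵢ,kⱼ)/min(kᵢ,kⱼ) ≥ 1, bins pairs by identity and reports per-bin
medians; variants with several measurements collapse to their
geometric mean first. A flat landscape — similar sequences, similar
rates — appears as high-identity medians near 1; under the default
generator conditions the median ratio above 50% identity stays below
2.

**Order of transforms.** Pipeline data: control normalization, then
assay correction. Literature data: Q10 correction of each published
value, then the per-variant median (`run_full()`); medians are taken
after correction so values measured at different temperatures are
comparable before aggregation.

## Predicting rates from sequence

Rates are modelled in natural-log space (per-form rates are
approximately log-normal, and log targets are standard for rate
prediction). One-hot encoding expands each column into 21 indicators
(20 residues + gap), position-major with a fixed state order; `X`
encodes as an all-zero block — it contributes no similarity — and such
rows are flagged since their row-sum invariant is relaxed.

Four models:

* **Nearest neighbour** — the ln-rate of the most similar training
  sequence; exact ties average.
* **Unweighted mean** of training ln-rates.
* **Weighted mean** — weights w = e^(−λ(1−s)) with s the identity to
  the query. The literature states only "exponential weights", so the
  parameterization is a design choice: this form spans the mean
  (λ = 0, exact identity) to nearest-neighbour behaviour (λ → ∞), and
  the default λ = 14 halves a weight for every 5 identity points
  lost — one interpretable dial, exposed in every signature.
* **SVR** — ε-insensitive support vector regression with RBF kernel
  k(x,x′) = exp(−γ‖x−x′‖²). "Default parameters" are pinned
  numerically so any implementation matches: C = 1, ε = 0.1,
  γ = 1/(n_features · Var(X)) with Var(X) the variance of the
  flattened training matrix; features are not rescaled. When every
  target fits inside one ε-tube the optimum is a constant (the
  underlying solver keeps no support vectors); `fit_svr()` returns
  the midrange constant predictor in that case. All four models are
  deterministic, so fixed inputs give bit-identical results.

**Identity-thresholded leave-one-out CV.** For each held-out variant
and threshold X, training is restricted to the other characterized
variants at identity ≥ X (optionally same-form). Variants with an
empty training set at some X are skipped there and reported via
`n_evaluable` — they are not imputed, so per-threshold errors are
computed over different (nested) target sets, a property to keep in
mind when reading the curves. A one-sequence training set, where the
kernel fit is undefined, predicts that sequence's value. Errors are
ln-space RMSE and the fold change e^RMSE ≥ 1 (1 = perfect, 2 = off by
twofold typically).

**Per-form prediction.** `predict_all()` trains one model per rubisco
form on that form's characterized variants and predicts only same-form
queries, attaching the form's own within-form LOO fold error. Forms
with fewer than `min_train = 3` characterized members (and unknown
forms) are refused rather than extrapolated, and reported.

## Position association

The association procedure follows the resampling design: the
form II/II-III characterized set is split 100 times into 75% training
and 25% held-out rows (`n_iterations`, `train_fraction`); each
iteration fits one depth-≤3 regression tree on the one-hot features —
variance-reduction splits on binary indicators, ties broken by the
lowest feature index for determinism — and evaluates it on the
held-out rows. This realizes the resampled-forest idea as 100
independent shallow trees rather than one bagged forest object, which
keeps every tree, and its attribution, exactly analyzable.

**Exact Shapley attribution.** For a held-out row, the coalitional
value of a feature set S is the tree's expectation with S fixed to the
row's values and all other features marginalized along the tree by
training cover weights. Because a depth-3 tree uses at most 7 distinct
features, the Shapley sum is enumerated exactly over all subsets; the
tests verify both local accuracy (base value + attributions = tree
prediction, to machine precision, for every row) and agreement with an
independent permutation-definition oracle. Per feature the mean
|attribution| over held-out rows is taken; per position the feature
values of its (mutually exclusive) residue states are summed; the
final score is the mean over iterations, in ln-rate units. Positions
that never support a split score 0. Held-out rows are used for
evaluation (the training-row alternative would reward overfit splits);
iteration i draws from seed `seed + i`, so results are bit-identical
under a fixed master seed.

`map_alignment_to_reference()` converts alignment columns to 1-based
ungapped residue numbers of a reference sequence (e.g. the
*R. rubrum* control), and `residue_rate_comparison()` tests rate
differences between residue groups at one position with a
tie-corrected Kruskal–Wallis omnibus test followed by pairwise Dunn
z-tests; the multiplicity adjustment is Bonferroni (no method is
canonical here, and Bonferroni is the conservative default). All-tied
inputs return H = 0 rather than 0/0.

## The synthetic generator

`simulate_dataset()` produces data with the statistical structure the
analysis assumes, with known truth:

* a random binary tree (`simulate_tree()`): standard coalescent by
  default, or a pure-birth ("yule") tree rescaled to the same depth.
  Coalescent terminal branches collapse near the present, so most
  leaves have a near-identical sibling — useful for testing duplicate
  handling, but identity thresholds barely bind. The pure-birth shape
  keeps terminal branches long, resembling a panel of screened cluster
  representatives, and is the shape used for the identity-threshold
  benchmarks;
* sequences evolving site-independently over 20 states (uniform jump
  model, P(change) = (19/20)(1 − e^(−(20/19)μt)) per branch) — no
  indels, since the analysis consumes alignments and alignment
  construction is out of scope;
* a latent ln-rate following Brownian motion (variance σ² per unit
  branch length) on the same tree — the minimal model giving "similar
  sequences, similar rates"; the root value y₀ = ln 7 centres true
  rates on the s⁻¹ scale typical of measured carboxylation rates;
* optional causal positions: residue → effect δ added to the leaf's
  ln-rate when the trigger residue is present. Auto-chosen triggers
  are the second-most-common residue at a polymorphic site (carrier
  frequency 0.2–0.8) whose carrier set differs by ≥ 3 leaves from
  every other site's residue indicator and complement. The last
  condition is an identifiability requirement, not a convenience:
  sequences evolved on a shared tree routinely contain sites whose
  indicators partition the leaves *identically* to the planted signal
  (single-origin linkage), and no attribution method can separate
  perfectly confounded features;
* observations under the measurement model: pipeline records are
  coupled-assay values at 30 °C, biased low by β, scaled by
  log-normal batch effects (σ_batch), with the control variant in
  every batch; literature records are direct-assay values at
  temperatures drawn uniformly from `temp_range`, governed by the true
  Q10; all carry log-normal noise σ_obs. Forms are assigned to clades
  by cutting the ultrametric tree.

**Default conditions** (one choice, stated here): n_leaves = 150,
L = 300 (desk-scale, full pipeline in seconds), μ = 0.15 (pairwise
identities spanning ≈ 0.45–1), σ² = 0.2 (median pairwise rate ratio
below 2 above 50% identity, matching the flat-landscape regime),
y₀ = ln 7, β = 2.1, σ_obs = 0.2, σ_batch = 0.15, batch size 16,
control rate 7 s⁻¹, half the leaves characterized, 30% of those
observed literature-style at 20–40 °C, true Q10 = 2.2.

**Benchmark conditions.** The identity-threshold CV properties are
exercised under strong phylogenetic signal and low noise — pure-birth
tree, n = 50, L = 120, μ = 0.2, σ² = 0.5, σ_obs = 0.05 — where
restricting training to closer relatives demonstrably helps; the
planted-position experiments use a signal-plus-noise configuration
(μ = 1.5, σ² = 0, δ = 1, n = 50, L = 80). Test problem sizes (50
replicates for the CV benchmark, 20 association runs, 200 calibration
replicates) are the package's choices for stable desk-scale
statistics.

**What the generator does not emulate** — and hence what passing
tests do not show about real data: insertions/deletions and alignment
error; realistic residue frequencies or substitution matrices;
selection and structural constraints; epistasis (causal effects are
additive); rate-dependent measurement error; the actual magnitude of
phylogenetic signal in real rubisco data, which is not printed
anywhere and is here only qualitatively matched.

## Numerical choices and degenerate inputs

* Identity with zero compared columns (all-gap vs all-gap) is an
  error, not 0 or 1.
* Clustering thresholds are clamped to [0, 1]; coverage of an empty
  characterized set is 0 for X > 0; an empty representative set is an
  error.
* Quantiles: linear interpolation (R type 7) throughout.
* Degenerate calibration (all pairs equal) returns factor 1 with a
  collapsed CI.
* Tree splits need strictly positive gain (tolerance 1e−12);
  constant-target trees are a single leaf and yield all-zero
  attributions.
* Kruskal–Wallis on fully tied data returns H = 0; Dunn z = 0.
* All stochastic stages derive their seeds from one master seed
  (stage-scoped offsets), and every generator restores the caller's
  RNG state.

## Known limitations

* Position attribution inherits the limits of tree-based importance
  under linkage: positions whose residues co-segregate with the causal
  one share or steal credit, and a perfectly confounded position is
  unidentifiable in principle. Scores are associations, not causal
  effects.
* The weighted-mean model's exponential-weight scale is a
  parameterization choice; other published weighted means need not be
  numerically reproducible.
* Per-threshold CV errors are computed over threshold-dependent
  evaluable subsets; curves should be read together with
  `n_evaluable`.
* The calibration CI is a t-interval on ≈ 11 log-ratios; it assumes
  approximate log-normality and independence of the pairs.
* The pipeline operates on a fixed alignment; alignment uncertainty
  is outside scope.
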