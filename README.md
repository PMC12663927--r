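# rubiscope

Rubisco — ribulose-1,5-bisphosphate carboxylase/oxygenase — fixes nearly
all carbon entering the biosphere, yet its carboxylation turnover
k<sub>cat,C</sub> is famously low. Deciding whether that slowness is a
quirk of the handful of well-studied plant enzymes or a property of the
whole family requires (i) a way to say how much of rubisco sequence
space the kinetically characterized variants actually cover, (ii) a way
to put rate measurements from different assays, temperatures and
batches on one scale, and (iii) models that predict the rate of an
uncharacterized variant from its sequence, with honest error bars.

`rubiscope` implements that analysis chain as a tested, reusable R
package for anyone working with enzyme-kinetics compilations and
aligned protein families:

* **Sequence space** — alignment IO, Hamming identity on aligned rows
  (gap-aware), gap-column trimming, USEARCH-style greedy centroid
  clustering, and a *diversity coverage* curve: the fraction of
  cluster representatives within identity X of any characterized
  variant.
* **Rate harmonization** — Q10 temperature correction
  (k′ = k·Q10^((T₀−T)/10), default Q10 = 2.2 to 30 °C), batch
  normalization against a control variant (geometric-mean scaling),
  and a slope-fixed log–log calibration of coupled against direct
  assays: b = mean(ln k_direct − ln k_coupled), factor = e^b with a
  t-interval CI.
* **Prediction** — nearest-neighbour, unweighted and
  identity-weighted means (w = e^(−λ(1−s))), and RBF-kernel support
  vector regression on one-hot alignment features (C = 1, ε = 0.1,
  γ = 1/(p·Var(X))), benchmarked by identity-thresholded leave-one-out
  cross-validation; errors reported as ln-space RMSE and fold change
  e^RMSE.
* **Position association** — 100× random 75/25 splits, depth-3
  regression trees on one-hot features, exact per-tree Shapley
  attributions aggregated per alignment position, mapped to a
  reference sequence's residue numbering, plus Kruskal–Wallis/Dunn
  comparisons of rates between residue groups at a position.
* **Synthetic data** — a phylogenetic simulator (sequences and a
  Brownian-motion latent ln-rate evolving on one tree, planted causal
  residues, assay bias, batch effects, off-temperature literature
  measurements) so every stage can be tested against known truth.

Everything takes and returns tibbles, chains with the pipe, and has
`autoplot()`/`tidy()`/`glance()` methods where a figure or a flat
summary is the natural view.

## Worked example

Simulate a study-like dataset, harmonize its measurements, and
benchmark the SVR predictor:

```r
library(rubiscope)
library(dplyr)

ds <- simulate_dataset(sim_config(n_leaves = 80, L = 150,
                                  tree_model = "yule", mu = 0.2,
                                  seed = 42))

# literature records: Q10-correct to 30 C; pipeline records: normalize
# each batch to the shared control variant
lit  <- q10_correct(filter(ds$records, source == "literature"))
pipe <- normalize_to_control(filter(ds$records, source == "pipeline"),
                             "control")

# calibrate the coupled assay against direct measurements
pairs <- simulate_rate_pairs(n_pairs = 11, beta = 2.1, seed = 43)
fit <- fit_assay_correction(pairs)
fit
#> Assay correction factor: 1.98 (95% CI 1.61 to 2.44), n = 11 pairs

rates <- bind_rows(
  filter(apply_correction(pipe, fit), variant_id != "control"), lit)
summarize_rates(rates)
#> # A tibble: 1 × 5
#>   group     n median   q25   q75
#>   <chr> <int>  <dbl> <dbl> <dbl>
#> 1 all      40   5.23  3.02  8.56

cv_data <- ds$alignment |> filter(characterized) |>
  inner_join(select(rates, variant_id, kcat_c),
             by = c(id = "variant_id"))
loo_crossval(as_alignment(cv_data), model = "svr",
             thresholds = c(0.5, 0.7, 0.9))
#> # A tibble: 3 × 5
#>   model threshold n_evaluable rmse_ln fold_error
#>   <chr>     <dbl>       <int>   <dbl>      <dbl>
#> 1 svr         0.5          40   0.636       1.89
#> 2 svr         0.7          38   0.549       1.73
#> 3 svr         0.9          18   0.341       1.41
```

The fitted calibration factor of 1.98 (true injected bias: 2.1) rescales
the coupled-assay rates; the harmonized median of 5.2 s⁻¹ sits in the
few-per-second range typical of rubisco; and the leave-one-out fold
error falls from 1.9× toward 1.4× as training is restricted to closer
relatives — the phylogenetic signal the identity-based predictors
exploit. Held-out variants without a training neighbour above the
threshold are skipped and counted out of `n_evaluable`.

`autoplot()` turns the coverage curve, the CV table, the rate-ratio
landscape and the position-association scores into ggplot2 figures,
e.g. `autoplot(diversity_coverage(reps, chars))`.

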