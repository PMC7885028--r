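# paimpact

Counterfactual evaluation of protected-area (PA) effectiveness at
reducing net forest loss, for conservation scientists and impact
evaluators working with gridded land-cover data.

Naive inside/outside comparisons confound protection with where parks
are sited (steep, remote, well-forested land).  `paimpact` implements
the matching-based design that corrects for this, together with the
spatial-autocorrelation (SAC) corrections that make its inference
honest:

* **Propensity-score matching** — logistic model of protection
  P(T = 1 | x) on the siting covariates; greedy 1:1 nearest-neighbor
  matching on the score, without replacement, caliper = 0.25 pooled
  score SDs.  Regional variants: *subsetting*, *exact subsetting*,
  *submatching*.
* **Balance diagnostics** — normalized difference per covariate,
  ND = 100 (x̄_T − x̄_C) / √((s²_T + s²_C)/2); |ND| > 25 flags imbalance.
* **Outcome models** — linear mixed models of loss on protection with
  crossed municipality and matched-pair random intercepts (model 1),
  plus one or two neighborhood mean-loss buffer covariates (models 2–3),
  or a maximum-likelihood spatial error model with row-standardized
  distance-band weights (model 4).
* **Residual diagnostics** — Moran's I correlograms of residuals per
  5-km distance band with a permutation envelope; the first
  non-significant distance ranks the models and drives the iterative
  buffer-radius rule (radius = previous distance − 5 km).
* **Synthetic landscapes** — a generator with spatially autocorrelated
  covariates (exact circulant-embedding Gaussian random fields),
  confounded siting, contiguous park blocks, Voronoi
  region/municipality tessellations, known protection effect, and MCAR
  missingness — the ground truth behind every calibration test.

## Worked example

```r
library(paimpact)

cfg  <- simulation_config(grid_nx = 40, grid_ny = 40, seed = 21)
sim  <- generate_landscape(cfg)
L    <- gap_fill_landscape(inject_missing(sim$landscape, cfg$missing_rate, 22))
loss <- compute_loss(L)

pairs <- match_national(L, loss = loss)
attr(balance_table(L, pairs), "balanced_fraction")
#> after before
#>   1.0    0.4

md <- matched_model_data(L, loss, pairs)
fit_outcome_model(md, model_spec(1))
#> model 1: protection effect -0.00997 (SE 0.00310) p=0.0013**, n=278
fit_outcome_model(md, model_spec(3, c(10, 5)), loss, cbind(L$x, L$y))
#> model 3: protection effect -0.00872 (SE 0.00279) p=0.00181**, n=278

report <- build_report(L, loss, pairs)
#> national row: PA loss 1.57% | matched controls 2.10% |
#>               all unprotected 2.56% | percent reduction 25.1%
```

Reading it: before matching only 40% of covariates were balanced —
protection is heavily confounded — and after matching all are.  The
matched contrast (1.57% vs 2.10%) is much smaller than the naive one
(1.57% vs 2.56%): part of the apparent PA advantage was siting, not
protection.  The mixed-model coefficient (−0.0100, i.e. one percentage
point of forest over the window; true generative effect −0.011) is the
regression version of that contrast; model 3 adds 10-km and 5-km
neighborhood-loss buffers to absorb residual spatial autocorrelation.
Stars: `*` p < 0.05, `**` p < 0.01.

The full pipeline (simulate → gap-fill → loss → match → balance →
select-buffers → fit → correlogram → report, with a hash manifest and
bitwise reproducibility) is one call:

```r
res <- run_pipeline(run_config(master_seed = 1), "pa_run")
```

or from the shell: `inst/scripts/pa-impact run --out pa_run --seed 1`.

## Vignette

`vignettes/methods.Rmd` documents the model, the synthetic world and its
parameters, the numerical conventions (matching order, caliper,
permutation envelopes, buffer pools), and known limitations — including
why park contiguity is the load-bearing geometry for every SAC
phenomenon and where nominal CIs remain optimistic.
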