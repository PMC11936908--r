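# immersr

Analysis of retail service encounters through the neurophysiology of the
*sales associate*. During an encounter, a wrist-worn cardiac (PPG) sensor
streams a 1 Hz "Immersion" index — a commercial composite of attention and
emotional resonance on an arbitrary positive scale. Because physiological
responses synchronize across people sharing an experience, the associate's
signal carries information about the customer's experience; immersr provides
the full chain that turns that signal into tested predictions of customer
behavior:

1. **Session metrics** — for a trace $n(t)$, $t = 0 \dots T$, the session
   threshold $M = \mathrm{median}(n) + 0.5\,\mathrm{SD}(n)$ and

   $$\text{Peak Immersion} \;=\; \frac{1}{I}\sum_{t \,:\, n(t) > M} n(t),
     \qquad I = \sum_t n(t),$$

   the fraction of total session Immersion carried by above-threshold
   samples — dimensionless, scale-invariant, in $[0, 1)$.
2. **Procedural-utility model** — a two-store choice problem
   $\max\, e \ln c_1 + \ln c_2$ s.t. $p c_1 + p c_2 \le M$, whose solution
   spends $M e/(1+e)$ in the experience store; experiential value $e$ is
   proportional to dwell time. Closed form cross-checked by grid search.
3. **Cohort simulator** — calibrated two-store cohorts (sessions, traces,
   purchases) with a retained latent $e$, so every downstream stage is
   testable against known ground truth.
4. **Parametric synthesis** — sequential conditional models (normal-linear /
   logistic) that expand a small cohort to 10,000 synthetic rows per store,
   with Kolmogorov–Smirnov and quantile-MSE fidelity diagnostics.
5. **Stats battery** — pooled-variance Student's t (raw samples *or*
   published (M, SD, N) triplets), 2×2 chi-squared, Pearson r, two-sample KS.
6. **Mediation** — Peak Immersion → dwell → purchase amount: two OLS
   equations, indirect effect $a\cdot b$ with percentile-bootstrap CI and
   Sobel test; exact decomposition total $= c' + ab$.
7. **Ensemble purchase classifier** — random forest + gradient boosting +
   extremely randomized trees, grid-searched and stratified-5-fold
   cross-validated, reporting sensitivity, specificity, accuracy, rank AUC
   and Brier MSE against a logistic baseline.
8. **Pipeline** — `run_pipeline()` chains everything into reproducible
   CSV/JSON artifacts under a single seed; a CLI wrapper lives in
   `inst/scripts/immersr-pipeline.R`.

## Worked example

Session metrics from a 12-second toy trace (two short bursts over a ~4.1
baseline):

```r
library(immersr)
tr <- immersion_trace("s1", 0:11,
  c(4.1, 4.0, 4.2, 4.1, 5.9, 6.2, 4.3, 4.0, 4.1, 5.8, 4.2, 4.1))
compute_session_metrics(tr)
#> # A tibble: 1 × 5
#>   session_id total_immersion avg_immersion threshold peak_immersion
#>   <chr>                <dbl>         <dbl>     <dbl>          <dbl>
#> 1 s1                      55          4.58      4.57          0.325
```

The three burst samples (5.9, 6.2, 5.8) exceed the threshold
median + 0.5 SD = 4.57 and carry 17.9 of the 55 total Immersion units:
Peak Immersion 0.325.

A simulated field study — 31 women's-store (WS) and 25 men's-store (MS)
sessions — analysed with the test battery:

```r
library(dplyr)
cohort <- generate_cohort(default_store_profiles(), rng_seed = 1969)
metrics <- session_metrics_table(cohort$traces)
sessions <- inner_join(cohort$sessions,
                       metrics[, c("session_id", "avg_immersion", "peak_immersion")],
                       by = "session_id") |> discretize_purchase()
cohort_test_battery(sessions)
#> # A tibble: 6 × 7
#>   label              test      mean_a  mean_b statistic    df p_value
#>   <chr>              <chr>      <dbl>   <dbl>     <dbl> <dbl>   <dbl>
#> 1 dwell_min          pooled_t  25.1    12.3     2.54       54  0.0140
#> 2 purchase_usd       pooled_t 179.    146.      0.649      54  0.519
#> 3 avg_immersion      pooled_t   4.41    4.51   -1.99       54  0.0519
#> 4 peak_immersion     pooled_t   0.231   0.246  -1.75       54  0.0865
#> 5 purchase_frequency chi2       0.613   0.6     0.00966     1  0.922
#> 6 return_customers   chi2       0.323   0.48    1.44        1  0.230
```

WS customers dwell about twice as long as MS customers (t = 2.54,
p = 0.014) while spending similar amounts, and Peak Immersion trends higher
in the men's store — the characteristic two-store pattern the simulator is
calibrated to. Mediation in the men's store at this small n:

```r
fit_mediation(sessions[sessions$store == "MS", ],
              mediation_spec(bootstrap_reps = 2000, rng_seed = 1))
#> <mediation_result> n = 25
#>   a  (peak_immersion -> dwell_min): 150.4 (se 35.1, p 0.000281)
#>   b  (dwell_min -> purchase_usd | peak_immersion): 5.495 (se 4.81, p 0.266)
#>   c' (direct): 1220 (se 1.09e+03, p 0.274)
#>   indirect a*b: 826.3  [-842, 2520] (95% percentile bootstrap)
#>   Sobel z: 1.103 (p 0.27); total: 2047
```

Peak Immersion strongly predicts dwell even at n = 25, but the indirect
effect is not resolvable at this sample size — the motivation for the
synthetic expansion (`fit_synthesizer()` / `sample_synthetic()`), after
which the pipeline re-estimates the mediation at n = 10,000 per store.

Full pipeline:

```r
cfg <- pipeline_config(output_dir = "runs/demo", seed = 1969)
run_pipeline(cfg)       # sessions, traces, metrics, synthetic, tests,
                        # mediation and prediction artifacts + manifest
summarize_results("runs/demo")
```

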