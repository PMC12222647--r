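# cnasd — size-dependent copy-number alteration survival analysis

Somatic copy-number alterations (CNAs) are widely used prognostic markers,
but the *size threshold* that turns a segmented copy-number profile into a
binary call ("1p lost: yes/no") is usually fixed by convention — 5% of the
arm in one published model, 50% in another — even though the prognostic
signal of an arm can depend strongly on how much of it is altered. `cnasd`
is an R package for discovering **size-dependent CNAs** from SEG-format
segment tables and time-to-event outcomes, and for building the prognostic
machinery that follows from them.

For each chromosome-arm feature $(a, d)$ (arm $a$, direction
$d \in \{\text{loss}, \text{gain}\}$) the package computes a per-sample
percent-arm-altered fraction $f_{i}$ on a 30 kb grid (segment mean
intensity $< -0.1$ = loss, $> 0.15$ = gain), and sweeps binary markers
$X_i(T) = \mathbf{1}\{100 f_i \ge T\}$ over thresholds $T = 1, \dots, 99\%$.
Each marker is scored by the 5-year cumulative/dynamic time-dependent ROC
AUC of a univariate Cox model (Kaplan–Meier-based estimator). A feature is
*size-dependent* when, for at least one endpoint,

- $\max_T \mathrm{AUC}(T) \ge 0.60$,
- $\mathrm{SD}_T\,\mathrm{AUC}(T) \ge 0.01$, and
- prevalence at the optimal $T$ is $\ge 2.5\%$,

with the SD cutoff calibrated by a permutation/bootstrap null that scrambles
the sample-to-fraction pairing within each arm (`fdr_at_cutoff()`). On top
of the optimized calls the package provides a 200 kb sliding-window scan for
focal prognostic regions (bins whose call AUC exceeds the arm's median bin
AUC by ≥ 0.04), co-occurrence pair/triplet features selected by
cross-validated penalized Cox regression with the 1-SE rule, burden-adjusted
models and log-rank recursive-partitioning burden strata, and a boosted
linear Cox risk score (learning rate 0.009, 2 rounds) with 25th/50th
percentile risk groups. A seeded synthetic-cohort simulator with planted
arm-level, focal, co-occurrence and burden effects makes every stage
testable end to end.

## Worked example

```r
library(cnasd)

# a 300-sample synthetic cohort with a planted size-dependent 1p loss:
# hazard switches on only when >= 25% of the arm is lost (log HR 1.2)
cfg <- sim_config(n = 300, seed = 42,
                  arm_effects = data.frame(feature = "1p_loss", activation = 0.25,
                                           log_hr = 1.2, carrier_prob = 0.25,
                                           sub_prob = 0.2))
cohort <- simulate_cohort(cfg)

fractions <- arm_fractions(cohort$segments, cfg$arms,
                           samples = cohort$clinical$sample)
sw <- sweep_feature(fractions$`1p_loss`, cohort$clinical$time_rec,
                    cohort$clinical$event_rec, feature = "1p_loss")
sw
#> Threshold sweep for 1p_loss: max AUC 0.676 at 23% (SD 0.0528, prevalence 0.290, 99 defined)
```

The sweep recovers an optimal threshold of 23% — two points from the
planted 25% activation fraction — with a maximum AUC of 0.676 and an AUC
standard deviation of 0.053, well above the 0.01 variability floor.
Applying the three criteria across both endpoints flags exactly the
planted feature:

```r
sweeps <- dplyr::bind_rows(
  cna_sweep(fractions, cohort$clinical$time_rec, cohort$clinical$event_rec,
            endpoint = "recurrence"),
  cna_sweep(fractions, cohort$clinical$time_os, cohort$clinical$event_os,
            endpoint = "os"))
flags <- size_dependent_features(sweeps)
dplyr::distinct(dplyr::filter(flags, size_dependent), feature)
#> # A tibble: 1 × 1
#>   feature
#>   <chr>
#> 1 1p_loss

nulls <- null_sd_distribution(fractions, cohort$clinical$time_rec,
                              cohort$clinical$event_rec, reps = 100, seed = 42)
fdr_at_cutoff(nulls, 0.01)
#> [1] 0.2535897
```

The last number is the estimated false-discovery proportion of the
SD ≥ 0.01 criterion alone under this cohort's background alteration noise:
about a quarter of pure-noise features would pass criterion 2 by itself
here, which is why the AUC and prevalence criteria are conjoined with it.

`run_pipeline(config, out_dir)` chains validate → fractions → sweep
(+ SD-FDR) → focal windows → co-occurrence → risk score over one
configuration (a list or YAML file, either input paths or a simulation
block), writing TSV/JSON/bedGraph outputs and a JSON run manifest whose
config hash makes re-runs cache-aware and bit-reproducible.

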