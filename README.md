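# migshuttle

Single-cell quantification of Mig1 nucleocytoplasmic shuttling dynamics
from multi-channel time-lapse microscopy.

## What it is for

In budding yeast, the transcriptional repressor Mig1 mediates carbon
catabolite repression: when cells growing on a poor carbon source are
shifted to a hexose (glucose, fructose or mannose), Mig1-GFP moves into
the nucleus. Time-lapse imaging of single cells in microfluidic devices
shows this response is **biphasic** — an initial nuclear peak within
~30 min that decays over hours, followed by an adapted phase of pulsatile
nucleocytoplasmic **shuttling** — and that the two phases depend
differently on the sugar kinases Hxk1, Hxk2 and Glk1. Quantifying this
requires a full image-analysis chain, and this package implements it for
researchers analysing such experiments:

* **brightfield division** — above-focus / below-focus ratio, cancelling
  uneven illumination and enhancing each cell's diffraction ring;
* **segmentation** of the divided image (threshold → closing → fill →
  watershed → area filter) and **nucleus identification** (Otsu on a
  nuclear-marker channel, with a brightest-fraction GFP fallback);
* the **localization index** per cell and frame,

  ```
  index = median(f_nuc) / median(f_total) − 1
  ```

  (0 = uniform, >0 = nuclear enrichment, ≥ −1);
* **tracking** by optimal bipartite assignment of centroids with gap
  bridging;
* **per-cell metrics**: basal (pre-shift) level, maximum and mean on
  0–60 min, adapted-phase mean on 240–480 min, shuttling pulses on
  60–480 min detected by topographic prominence, mean pulse height,
  reporter expression mean and onset (maturation-lagged), expression-marker
  level;
* **group statistics**: mean / SD / 95% CI per condition, Welch tests
  against wild type, reporter fold changes, dose–response binning with
  Spearman correlation, viability filtering for toxic overexpression
  conditions, and a qualitative strain-by-hexose matrix check.

Because no raw movies ship with experiments like these, the package
includes a first-class **synthetic generator**: seeded ground-truth traces
(biphasic kernel + refractory pulse process + reporter kinetics with
maturation delay + cell-to-cell variability) rendered into 16-bit
multi-channel movies whose nuclear:cytoplasmic split is analytically
invertible. Every pipeline stage is tested against that ground truth; see
`vignettes/mig1-shuttling-quantification.Rmd` for the model and all
design choices.

## Worked example

Simulate a wild-type and an *hxk2Δ* glucose-shift condition (50 cells
each, the default acquisition protocol), compute per-cell metrics and
compare the groups:

```r
library(migshuttle)

sched <- make_schedule()        # -240..0 min every 30, 0..720 min every 5
cfg   <- preset("wt", "glucose", n_cells = 50, seed = 11)
truth <- simulate_traces(cfg, sched)
mt    <- compute_trace_metrics(traces_from_truth(truth))

round(colMeans(mt$metrics[, c("basal", "max_short", "mean_long",
                              "pulse_rate", "mean_pulse_height")],
               na.rm = TRUE), 3)
#>             basal         max_short         mean_long        pulse_rate
#>             0.050             0.910             0.341             1.900
#> mean_pulse_height
#>             0.673

mt2 <- compute_trace_metrics(traces_from_truth(
  simulate_traces(preset("hxk2d", "glucose", n_cells = 50, seed = 12), sched)))
rep <- build_report(list("wt:glucose" = mt$metrics,
                         "hxk2d:glucose" = mt2$metrics))
subset(rep$summary, metric == "mean_long")[, c("condition", "n", "mean",
       "sd", "ci_low", "ci_high", "p_vs_reference", "significant")]
#>       condition  n  mean     sd ci_low ci_high p_vs_reference significant
#>      wt:glucose 50 0.341 0.0728  0.320   0.361             NA       FALSE
#>   hxk2d:glucose 50 0.107 0.0147  0.103   0.111        1.5e-28        TRUE

rep$fold_changes
#>       condition  reference fold group_mean reference_mean
#>      wt:glucose wt:glucose 1.00       3.95           3.95
#>   hxk2d:glucose wt:glucose 7.59      29.94           3.95
```

Reading the output: wild-type cells keep an adapted-phase localization
mean of 0.34 with ~1.9 shuttling pulses per hour, while the *hxk2Δ* cells
fall to 0.11 (essentially basal; the Welch test against wild type is
significant), and their *SUC2*-type reporter is derepressed ~7.6-fold —
loss of Hxk2 abolishes adapted-phase nuclear localization and repression
in glucose while the initial response remains.

The imaging arm runs the same analysis from pixels:

```r
movie <- render_movie(truth, scene_geometry(n_cells = 50))
res   <- analyze_movie(movie, strain = "wt", hexose = "glucose")
mt    <- compute_trace_metrics(res$traces)
```

An end-to-end driver (`run_end_to_end(run_config())`) writes tidy CSVs,
figures and a seed manifest per condition, and a thin CLI wraps it:
`Rscript inst/cli/migshuttle.R run --out demo/` (also `simulate`,
`analyze`, `report` subcommands).

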