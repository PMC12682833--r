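# deeproot

Tools for phenotyping **deep rooting** in field-grown crops from
minirhizotron imaging, and for linking it to **deep water and nitrogen
uptake** with stable-isotope tracers.

Semi-field facilities grow crop rows above inclined transparent tubes
(minirhizotrons) reaching 3 m of soil depth. A camera photographs roots
every 35 mm along each tube; image segmentation yields a root length per
image and hence a depth-resolved root profile per row. Injecting
¹⁵N-labelled nitrate and ²H-labelled water at 1.6–1.8 m depth turns the
same rows into a functional assay: tissue enrichment above natural
abundance measures deep resource uptake, and grain δ¹³C integrates water
stress over grain filling. `deeproot` implements the analysis chain for
this kind of experiment:

- **Geometry** — linear tube-position → soil-depth registration between
  stated anchor depths, pixel → cm calibration, and observation area of
  half-open depth intervals (the pRLD denominator).
- **Root traits** — per-row profiles; planar root length density in
  30-cm bins; *DeepRoot₄₀*, the depth d\* below which 40 cm of
  cumulative root length is observed,
  `d* = max{d : C(d) ≥ 40}` with the cumulative-from-bottom curve C
  interpolated between image depths; the sigmoid-inflection rooting
  depth from a bounded fit of `y(d) = A / (1 + exp(k(d − m)))`; interval
  root lengths and a depth-interval correlation screen.
- **Isotopes** — δ ↔ atom-fraction conversion, excess-¹⁵N mass balance
  `m_dry · %N/100 · (AF(δ) − AF(δ₀))`, per-row-side dose partitioning,
  percent tracer recovery per row (grain and grain+straw), and the
  model transforms ln(δ¹⁵N) and ln(δ²H + 90).
- **Statistics** — replication filters (per-year and all-years),
  genotype marginal means with design covariates and compact-letter
  displays (Tukey/Holm-adjusted pairwise comparisons), and cultivar-mean
  Pearson correlations within and across years.
- **Synthetic trials** — a generator with known ground truth (planted
  genotype depth shifts, per-row tracer uptake fractions) emulating the
  9×10 + 39×4 row design, for end-to-end testing and power analysis.

The methods vignette (`vignettes/deep-root-phenotyping.Rmd`) documents
the model choices, defaults and limitations.

## Worked example

Simulate a trial at the default study conditions (48 genotypes, 246
rows), extract traits, account for the tracer, and correlate deep
rooting with deep N uptake:

```r
library(deeproot)
library(dplyr)

cfg   <- simulation_config()
trial <- simulate_trial(cfg, seed = 2024)

traits <- compute_root_traits(trial$roots, cfg$geometry, fit_sigmoid = FALSE)
head(traits, 4)
#>   row_id     session genotype  year deep_root40_cm L1.6_1.8
#> 1 Y2021_R001 june    G37       2021           96.2    2.21
#> 2 Y2021_R002 june    G29       2021           78.7    0.593
#> 3 Y2021_R003 june    G02       2021           91.6    0.901
#> 4 Y2021_R004 june    G15       2021           62.6    0.387

grain <- filter(trial$tissue, tissue == "grain")
grain$ln15 <- transform_for_model(grain$delta15N, "15N")
xy <- left_join(cultivar_means(traits, deep_root40_cm),
                cultivar_means(grain, ln15),
                by = "genotype", suffix = c("_dr", "_iso"))
cultivar_mean_correlation(xy, mean_dr, mean_iso)
#>       r        p     n note
#> 1 0.913 1.49e-19    48 <NA>
```

`deep_root40_cm` is the DeepRoot₄₀ depth in cm (deeper = more deep
roots; rows with under 40 cm of total root are `NA`), `L1.6_1.8` the
root length observed at the tracer injection depths, and the correlation
shows the planted deep-rooting → deep-N-uptake coupling recovered across
the 48 cultivar means.

Genotype means of the nine core genotypes with compact letters
(genotypes sharing a letter are not significantly different at α =
0.05):

```r
core <- filter(traits, genotype %in% sprintf("G%02d", 1:9)) |>
  left_join(select(trial$truth, row_id, bed, bed_pos), by = "row_id")
tidy(estimate_genotype_means(core, deep_root40_cm))
#>   genotype  mean    se    df letters
#> 1 G01       99.6  1.48    78 cd
#> 2 G02       95.7  1.47    78 d
#> ...
#> 5 G05      119.   1.38    78 a
#> 9 G09       80.5  1.34    78 e
```

Per-row tracer recovery (percent of the 0.0152 g ¹⁵N applied per row):

```r
recovery_percent(trial$tissue, cfg$dose, cfg$consts) |> head(3)
#>   row_id     excess_15N_g_grain excess_15N_g_total recovery_pct_grain recovery_pct_total
#> 1 Y2021_R001          0.000114           0.000134               0.753              0.886
```

`run_pipeline()` drives the same stages from CSV inputs described by a
YAML config and writes tidy outputs plus a text report;
`write_trial()` / `read_observations()` / `read_tissue_samples()` are
the validated serialization layer.

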