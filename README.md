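# shallowplan

Plan shallow shotgun metagenomic sequencing from two-target qPCR.

Human-associated samples mix host and microbial DNA in wildly varying
proportions, so the same sequencing depth can leave one library with
millions of microbial reads and another with almost none. `shallowplan`
predicts, **before sequencing**, what fraction of a shotgun library will be
microbial, using two cheap qPCR measurements per sample: the pan-bacterial
16S rRNA gene and the human β-actin gene (*ACTB*). Because each qPCR cycle
threshold (Ct) drops by one cycle per doubling of template, the difference

    ΔCt = Ct(ACTB) − Ct(16S)

is a log2 measure of the bacterial-to-human DNA ratio. The core calibration
is a logistic-growth curve on the percent of microbial reads *p*:

    p(Δ) = YM·Y0 / ((YM − Y0)·e^(−k·Δ) + Y0)

with baseline Y0 = p(0), plateau YM, and per-cycle rate k. The package
ships a published parameterization (YM = 99.53, Y0 = 0.02733, k = 0.7218;
equivalently p(Δ) = 2.7201549 / (99.50267·e^(−0.7218·Δ) + 0.02733)),
calibrated on 89 oropharyngeal and stool samples over ΔCt ∈ [−8.16, 34.45],
and can refit this curve — or four simpler linear and logit-linear
alternatives using the 16S, *ACTB*, and optionally fungal 18S Cts — on your
own data.

Around the calibration sit the tools a sequencing core actually needs:

* **qPCR I/O** — long-format Ct tables, replicate aggregation with
  discordance flags, censored ("Undetermined") well handling, negative
  control QC (`read_ct_table()`, `aggregate_replicates()`,
  `build_sample_records()`, `validate_run()`).
* **Prediction** — point estimates with a one-tailed 95% lower prediction
  bound, validity flags outside the reliable 4–98% composition range, and
  extrapolation flags outside the training ΔCt range
  (`predict_percent_microbial()`).
* **Depth planning** — the smallest total depth whose microbial yield
  reaches a target (default 10⁶ microbial reads), per sample or in batch,
  with budget feasibility (`required_total_reads()`, `plan_sample()`,
  `batch_plan()`).
* **Rarefaction** — seeded multivariate-hypergeometric subsampling of taxon
  count profiles over a depth grid, with richness, Shannon and
  Berger–Parker indices and group-level median/IQR summaries
  (`rarefaction_grid()`, `group_summary()`).
* **Synthetic data** — generators for calibration cohorts and taxonomic
  communities, plus a deterministic fixture suite
  (`simulate_calibration_records()`, `simulate_community()`,
  `make_fixture_suite()`).
* **CLI** — `predict`, `fit`, `plan`, `rarefy`, `simulate` subcommands via
  `dispatch()` or the wrapper script in `inst/cli/shallowplan.R`.

## Worked example

Generate the synthetic fixture set, build sample records, and plan depth
against the published curve:

```r
library(shallowplan)

dir <- tempfile(); make_fixture_suite(dir, seed = 2021)
meas <- read_ct_table(file.path(dir, "synthetic_ct_table.csv"))
obs  <- read.csv(file.path(dir, "synthetic_observed_percent.csv"))
rec  <- build_sample_records(aggregate_replicates(meas), obs)

m <- published_model()
plan <- batch_plan(head(rec[rec$flags == "", ], 4), m,
                   target_microbial_reads = 1e6)
print(plan[, 1:6], digits = 4, row.names = FALSE)
#>    sample_id percent_microbial lower_bound_95 required_total_reads
#>  syn_orop_01            42.500          35.30              2352950
#>  syn_orop_02            99.524          92.33              1004779
#>  syn_orop_03            99.477          92.28              1005256
#>  syn_stoo_04             8.265           1.07             12099189
#>  feasible_within_budget     warnings
#>                      NA
#>                      NA low_validity
#>                      NA low_validity
#>                      NA
```

Reading the first row: this sample is predicted to be 42.5% microbial (and
at least 35.3% with one-tailed 95% confidence), so about 2.35 million total
reads are needed to bank 10⁶ microbial reads. The two `low_validity` rows
sit above the 98% mark where the sigmoid saturates and the calibration is
less accurate. How well does the shipped curve describe these synthetic
observations?

```r
d <- diagnostics(m, rec[!is.na(rec$observed_percent_microbial) &
                          rec$flags == "", ])
print(d)
#> n = 12  R^2 = 0.9814
#> residuals (%): mean -2.127  median -0.384  sd 5.798  range 20.67
```

The same operations are available from a shell:

```sh
Rscript inst/cli/shallowplan.R plan \
  --ct-table ct.csv --model published-e --target 1000000 --out plan.csv
```

See `vignette("qpcr-depth-planning")` for the model, its assumptions, the
numerical choices behind the nonlinear fit, and known limitations.

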