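---
title: "Planning shotgun sequencing depth from two-target qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning shotgun sequencing depth from two-target qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shallowplan)
```

## The problem

Shotgun metagenomic libraries from human-associated samples are mixtures of
host and microbial DNA, and the mixing ratio spans orders of magnitude: a
stool library may be almost entirely microbial while an oropharyngeal swab
can be dominated by human reads. When sequencing is shallow
(10^5^–10^6^ reads per sample), a host-dominated library may simply not
contain enough microbial reads for taxonomic or diversity analysis. The cost
of discovering this *after* sequencing is a wasted run.

`shallowplan` addresses this with a cheap pre-sequencing assay: quantitative
PCR of a pan-bacterial target (the 16S rRNA gene) and a human target
(β-actin, *ACTB*). Because a qPCR cycle threshold (Ct) falls by one cycle
for every doubling of starting template, the difference

$$\Delta Ct = Ct_{ACTB} - Ct_{16S}$$

is a log~2~-scale measure of the bacterial-to-human DNA ratio: large
positive values mean microbe-rich samples. The package calibrates this
quantity against the observed percentage of microbial reads (reads not
matching a human reference after host filtering), predicts composition for
new samples, and converts predictions into required total sequencing depth.

## The calibration models

Five regression families are supported, all mapping Cts to the percent of
microbial reads $p \in (0, 100)$:

* **A** — linear: $p \sim Ct_{16S} + Ct_{ACTB}$
* **B** — linear, adding the fungal 18S rRNA Ct as a predictor
* **C** — as A but on logit-transformed percentages
* **D** — as B but on logit-transformed percentages
* **E** — logistic growth in the single predictor $\Delta Ct$:

$$p(\Delta) = \frac{Y_M \, Y_0}{(Y_M - Y_0)\, e^{-k\Delta} + Y_0}$$

with baseline $Y_0 = p(0)$, plateau $Y_M = \lim_{\Delta\to\infty} p$, and
per-cycle rate $k$. The sigmoid shape is the natural choice: $p$ is a
bounded proportion and $\Delta Ct$ an unbounded log-ratio, so the relation
must flatten at both ends. Note that $Y_0$ is the curve's value at
$\Delta = 0$, *not* its infimum — for negative $\Delta$ the curve continues
down toward 0.

The package ships a published parameterization of family E
(`published_model()`): $Y_M = 99.53$, $Y_0 = 0.02733$, $k = 0.7218$, trained
on 89 oropharyngeal-swab and stool samples over
$\Delta Ct \in [-8.16, 34.45]$, with a percent-scale residual standard
deviation of 4.35. The constants satisfy the identity
$(Y_M - Y_0 + Y_0)\,Y_0 = 99.53 \times 0.02733 = 2.7201549$, the numerator
of the printed curve.

The 18S target is retained only as an optional linear predictor (families
B/D); it never enters family E, where it adds no predictive value.

### Fitting

Families A–D are ordinary least squares (`stats::lm`), on the percent scale
(A, B) or after a logit transform (C, D). The logit operates on fractions
$p/100$ clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-4}$ by default, so that observed 0% and 100% libraries
remain usable; residual diagnostics are always computed on the percent scale
after back-transformation, which keeps residual ranges comparable across
families.

Family E is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) on the percent scale, with boxes
$Y_0 \in (10^{-6}, 10)$, $Y_M \in [10, 100]$, $k \in (0, 10]$, stopping
tolerances $10^{-10}$ and up to $10^4$ function evaluations. Two numerical
choices matter here:

* **Initialization** is self-starting from the model's own linearization:
  at a plateau guess $Y_{M0}$ slightly above the data maximum (kept strictly
  inside the box), $\ln(p / (Y_{M0} - p)) = k\Delta + \ln(Y_0/(Y_M - Y_0))$
  is a line whose OLS slope and intercept seed $k$ and $Y_0$. A start placed
  *on* a box bound is dangerous with clamped LM steps: the relative-SSR
  stopping rule can be satisfied before the fit has moved, which we observed
  as a false convergence on noiseless data.
* **Boundary restart**: if a converged solution is pinned to a box bound,
  the fit is restarted from mid-box and the lower-SSR solution kept.

With these, refitting 100 noiseless points generated from the shipped
constants returns them to machine precision.

### Prediction, validity, and the one-tailed bound

`predict_percent_microbial()` returns a point estimate plus two flags. The
estimate is considered inside the calibration's validity range when
$4\% \le p \le 98\%$; outside, the sigmoid's asymptotes compress large
composition differences into tiny Ct differences and accuracy degrades.
`extrapolated` marks samples whose predictors fall outside the training
range (for family E, $\Delta Ct \notin [-8.16, 34.45]$ for the published
model; the training min/max for refits). Raw linear predictions leaving
$(0, 100)$ are clamped and noted.

The lower prediction bound is the one-tailed normal-approximation bound

$$L = \hat p - z_{0.95}\, s\, \sqrt{1 + 1/n},$$

with $s$ the percent-scale residual SD and $n$ the training size, clamped at
0. The construction is deliberately simple and is recorded in the result's
`method` attribute; an empirical residual-quantile alternative is available.
A homoscedastic percent-scale band is a compromise — near the asymptotes the
true predictive distribution is skewed — but it errs conservative exactly
where the planner uses it (the low-composition side).

`shift_to_zero_mean_residual()` implements the bias correction useful for
families C and D: it adds the mean percent-scale residual to the model's
shift offset, zeroing the mean residual while leaving its spread unchanged
(idempotent on fixed records).

## The depth planner

`required_total_reads(p, t)` is the exact ceiling
$\lceil t / (p/100) \rceil$: the smallest total depth whose expected
microbial yield reaches the target $t$ (default $10^6$ microbial reads, a
depth adequate for the common alpha-diversity analyses). The ceiling — never
rounding — guarantees the conservation property
$\text{required} \times p/100 \ge t$ with tightness at
$\text{required} - 1$. `plan_sample()`/`batch_plan()` chain prediction into
this requirement and carry the validity flags along as warnings; a
per-sample read budget turns the plan into a feasibility verdict.

## The rarefaction engine

To justify a depth target one needs to know how fast measured diversity
decays with depth for the sample type at hand. `rarefaction_grid()`
subsamples taxonomic count profiles at a grid of depths (default one
million down to one thousand reads, 10 replicate seeds per depth) and
computes three indices per subsample: richness, Shannon ($-\sum q_i \ln
q_i$, natural log), and Berger–Parker dominance ($\max q_i$). Per-sample
replicate means are summarized per group by median and interquartile range
(linear-interpolation quartiles).

Subsampling is multivariate hypergeometric — draws without replacement from
the taxon count bins — implemented as sequential conditional univariate
hypergeometric draws (`stats::rhyper`), which is exact in distribution and
runs in time proportional to the number of taxa. Every subsample is fully
determined by an explicit integer seed, reported in the output, and leaves
the caller's RNG state untouched.

This engine subsamples *taxon-assigned counts*, not raw reads: a pipeline
that subsamples FASTQ files and re-profiles each subsample adds profiler
noise (detection limits near one read, clade reassignments) that count-level
subsampling does not reproduce. The statistical structure of depth loss —
which is what a depth planner needs — is preserved; profiler-specific
artifacts are deliberately out of scope.

MetaPhlAn-2-style relative-abundance tables are accepted by selecting
species-level clades (`s__` without `t__`) and converting percentages to
integer counts at a user-supplied depth with largest-remainder rounding, so
the resulting total is exact.

## The synthetic-data generator

`simulate_calibration_records()` emulates a derivation cohort:
$\Delta_i \sim \text{Uniform}(-8.16, 34.45)$, truth on the logistic-growth
curve at the shipped constants, and observation noise injected on the
*logit* scale, $p_\text{obs} = \text{logit}^{-1}(\text{logit}(p) +
\varepsilon)$ with $\varepsilon \sim N(0, \sigma)$. Logit-scale noise keeps
every observation inside $(0, 100)$ and mimics how compositional error
shrinks near the boundaries. The default $\sigma = 0.59$ was calibrated
once, numerically, so the percent-scale residual SD over the uniform-Δ
design matches the derivation set's 4.35%. The uniform Δ design is a
neutral choice, not a claim about any real cohort's Ct distribution; real
sample types cluster at the extremes (stool high, swabs low and variable).
Absolute 16S Cts are drawn independently of Δ — only Δ matters to family E,
but the absolute values exercise families A–D — and 18S is generated as
uninformative noise around a constant, matching its role.

`simulate_community()` draws taxon abundances from a lognormal
rank-abundance model ($\exp N(0, \sigma)$, normalized) and counts from one
multinomial draw, so totals are exact. `make_fixture_suite()` writes a
deterministic, byte-reproducible set of small files (a Ct table with
duplicates, an undetermined well and a water control; observed percentages;
four communities crossing richness with dominance) that exercise every
reader in the package.

What passing tests on these synthetic data do **not** show: robustness to
assay changes (different primers, reagents, cyclers shift the calibration),
to fungal-rich samples (18S is not in the shipped model), to sample types
whose Ct distribution differs qualitatively from the calibration design, or
to profiler artifacts at very shallow depth. A laboratory adopting the
approach should refit the curve on its own protocol
(`fit_logistic_growth()`) rather than reuse the shipped constants blindly.

## Problem sizes and statistical behavior

The test suite works at the scale of the study conditions: calibration
cohorts of n = 89, noiseless refits of 100 points, rarefaction chi-square
checks on tiny (total ≤ 20) profiles with 10^5^ replicate draws, and a
20-seed ensemble of noisy refits. One behavior deserves a note: at n = 89
and 4.35% residual SD, the sampling SD of the refitted $k$ is about 8% of
its value (refits are verified to sit at the global optimum by multistart),
so a single cohort's $k$ can miss the truth by 15–20% while the ensemble
mean lands within a couple of percent. Tests therefore assert per-cohort
explanatory power ($R^2 \ge 0.95$) but ensemble-level parameter recovery.

## Known limitations

* The shipped constants are protocol-specific; Ct values are not portable
  across primer sets, mixes, or instruments without refitting.
* Predictions below 4% or above 98% are flagged, not refused; the planner
  will happily report the (very large) depth a 0.1% sample needs, with a
  `low_validity` warning.
* The prediction bound assumes homoscedastic percent-scale residuals.
* Count-level rarefaction cannot reproduce profiler detection artifacts.
* Undetermined (censored) Cts propagate as flags and block prediction; no
  imputation is attempted.
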