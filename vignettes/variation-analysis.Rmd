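---
title: "Decomposing plasma-proteome variation from a duplicate-design TMT experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing plasma-proteome variation from a duplicate-design TMT experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtvar)
```

## The design and the model

The package targets a specific, economical design for measuring plasma
protein variation at proteome scale: `n` subjects (42 by default), each
prepared independently twice, multiplexed with TMT 10-plex reagents. Eight
channels per plex carry individual preparations; channels 126 and 131
carry a pooled internal control made from all subjects. Eleven plexes hold
the 84 preparations (the last plex runs partially filled). Relative
quantification against the 126 pool makes proteins comparable across
plexes.

Duplicate preparations of the *same* plasma sample can differ only through
the measurement workflow — digestion, labelling, fractionation, LC-MS/MS,
quantification. Differences between *subjects* additionally contain
inter-individual biology. This is the lever that separates the two
variance components.

For protein $p$ with relative abundances $x$:

* **Analytical CV.** For each subject $t$ with both duplicates present,
  $CV_{pt} = SD_{pt} / \bar{x}_{pt} \times 100$, with the sample SD
  (denominator $n-1$). $CV_a(p)$ is the unweighted mean of $CV_{pt}$ over
  such subjects. Pre-analytical variation is taken as zero: samples are
  processed and frozen immediately, and the duplicates split *after*
  sampling, so nothing in the design can estimate it.
* **Total CV.** $CV_t(p) = SD/\bar{x} \times 100$ over all present
  measurements of the protein — both replicates of every subject, up to
  84 values.
* **Biological CV.** Independent variance components add:
  $CV_b = \sqrt{CV_t^2 - CV_a^2}$.

### Estimator properties, documented rather than corrected

Two biases are inherent to these (field-standard) estimators and are
deliberately left uncorrected, because the procedure this package
implements applies no correction either:

* The SD of a pair underestimates the true SD: $E[SD_{pair}] =
  \sigma\sqrt{2/\pi} \approx 0.798\,\sigma$. A protein with true
  analytical CV 5 % therefore yields a mean duplicate-based estimate near
  4.0 %. Parameter-recovery tests assert against this biased expectation,
  not against the nominal truth.
* $CV_t$ is computed over all 84 measurements, so replicate noise
  contributes to it once at full weight; with the decomposition formula
  this is consistent ($CV_t^2 \approx CV_b^2 + CV_a^2$), but sampling
  noise can push $CV_a$ above $CV_t$ for quiet proteins. The
  decomposition then clamps $CV_b$ to zero and flags the protein
  (`cv_bio_clamped`) instead of returning a complex number.

An ambiguity worth knowing: "the mean of the relative abundances" could be
taken over the 84 measurements or over 42 subject means. The default is
all 84 measurements (the dataset is framed as 84 samples); the
`total_over = "subject_means"` switch provides the alternative, which
down-weights replicate noise.

## Processing chain

`process_reporter_matrix()` composes the canonical order:

1. **Isotope-impurity correction** (`correct_impurities()`): reporter
   labels leak a few percent of signal into neighbouring channels. The
   forward model is a column-stochastic mixing matrix per plex; correction
   solves the linear system. Correction must run on raw signals — it is a
   cross-channel solve and does not commute with per-channel scaling.
   Within a partially filled plex, mixing and correction are restricted to
   the channels actually present (leakage into unused channels is lost
   signal), which keeps the forward/inverse pair an exact round trip on
   complete data. Around *missing* cells the correction is approximate
   (the leakage a missing cell received is unobservable); negative
   solutions are clipped to zero and counted.
2. **Global equal-sum normalization**: every column is scaled so all
   column sums (over present values) are equal; the target is the mean of
   the column sums, which preserves the global scale. Missing cells are
   excluded, not imputed — no imputation is part of the procedure.
3. **Control scaling** (`scale_to_control()`): per protein, each plex is
   scaled so its control value equals the protein's across-plex average
   control value. This protein-wise reading of "scaling on averaged
   controls" is the default; a single channel-wise factor per plex is
   available as `method = "global"`. Proteins missing their control in a
   plex stay unscaled there and are counted.
4. **Relative abundance**: each sample measurement is divided by its
   plex's 126-pool value for the same protein. Channel 131 also carries
   pool, but only 126 serves as the denominator; 131 survives
   normalization and can be kept (`drop_controls = FALSE`) as a
   pool-vs-pool QC ratio. The anchor's self-ratio is identically 1.

The composed chain is invariant to rescaling any input column by a
constant: equal-sum normalization removes per-column factors exactly.
Note the converse: because normalization rescales columns by their
(data-dependent) sums, ratios after the full chain are not numerically
identical to ratios taken on raw signals — the chain assumes equal total
protein load per channel, which is what the pooling protocol aims at.

## What the synthetic generator states, and what it does not

`simulate_dataset()` generates the stated world the tests live in:

* True abundance $A_{pi} = \mu_p L_{pi}$ with $L_{pi}$ log-normal, unit
  mean, CV equal to the protein's biological CV. Every measurement
  observes $A_{pi} E$ with $E$ log-normal, unit mean, CV equal to the
  analytical CV, independent per cell. Log-normal (multiplicative) noise
  is the defensible choice here: abundances are positive and biological
  CVs of acute-phase proteins approach 100 %, where additive Gaussian
  noise would go negative. The parameterization sets
  $\sigma_{\log} = \sqrt{\ln(1 + cv^2)}$ so the *stated* CV is the
  distribution's true CV, not its log-SD.
* Defaults are the design's stated conditions: 42 subjects × 2
  replicates, 265 proteins, biological CV 19.2 % and analytical CV 5.3 %
  (the cohort medians typical of abundant plasma proteins in this kind of
  experiment), no missingness unless requested. True means are drawn
  log-uniform over $10^5$–$10^9$, a realistic reporter-intensity dynamic
  range; CVs are scale-free, so this choice only exercises numerics.
* Pooled controls carry the arithmetic mean of all sample true abundances
  with their own analytical noise per plex — so the control is *noisy*,
  and ratios to it inherit part of that noise. This is visible in
  recovered analytical CVs after full processing (≈ 6.8 % median at 5.3 %
  input in the README example) and is a property of control-normalized
  designs, not a bug. Parameter-recovery assertions against the
  √(2/π)-biased truth are therefore made on the raw simulated channels,
  where replicate pairs differ only by sample-level analytical noise.
* Replicate-to-plex assignment is a seeded random permutation; whether
  real duplicates share a plex is generally not documented, so
  `duplicate_layout` exposes `same_plex` and `cross_plex` variants
  without asserting either as *the* layout.
* Missingness is missing-completely-at-random per cell. Real dropout is
  intensity-dependent; MCAR is the minimal model that exercises the
  ≥ 50 % completeness filter, and an intensity-dependent mechanism is out
  of scope. Consequently, green tests establish correctness of the
  estimators under MCAR — they do not establish robustness to informative
  missingness.
* Optional per-plex batch multipliers (`plex_factor_cv`) inject the
  cross-plex structure that control scaling exists to remove; a test
  verifies the removal.
* The shipped impurity table is a **synthetic** kit-style example
  (`tmt10_impurity_synthetic.tsv`): vendor lot factors are lot-specific
  and not reproduced. Leakage is routed to ±1/±2 neighbours along the
  10-channel sequence, a simplification of true N/C isotopologue routing;
  the mixing-matrix interface accepts any column-stochastic spec if exact
  kit routing is needed.

The generator does not simulate spectra, co-isolation interference,
peptide-to-protein rollup, or fractionation — it starts where a protein ×
channel quantification matrix exists.

## Power analysis

The per-group sample size for detecting an absolute difference $\Delta$
between two groups with common SD $\sigma$ is

$$ n = \left\lceil \frac{2 (z_{\alpha/2} + z_{1-\beta})^2 \sigma^2}{\Delta^2} \right\rceil . $$

The quantiles are *summed*. Published versions of this formula sometimes
print a minus sign between the quantiles; with $z_{1-\beta} = +0.8416$ at
80 % power only the sum reproduces the characteristic $1/\Delta^2$ scaling
of published sample-size tables (e.g. a maximum-variance column falling
2848 → 712 → 114 → 28 across folds 1.1/1.2/1.5/2.0), and a difference
would give absurdly small $n$. The package treats the sum as the intended
formula.

Fold changes are mapped to the ratio scale as $\Delta = (f - 1) \times$
mean. In the default CV formulation the percentile grid is taken over
$CV_{total}$ with mean 1, so each cell is
$n = \lceil 15.698\, (CV/100)^2 / (f-1)^2 \rceil$. An SD formulation
(`scale = "sd"`) takes percentiles over $SD_{total}$ and uses the cohort
median of per-protein means for $\Delta$ — under interpolated quantiles
there is no single "protein at the percentile" whose mean could be used.
Percentiles use linear interpolation (`stats::quantile` type 7);
"maximum" is the sample maximum, not a percentile.

Confidence intervals are nonparametric percentile bootstrap over
proteins — the interval method behind published grids of this kind is
typically not stated, and resampling proteins is the assumption-free
choice. Reps (default 1000), level (0.95) and seed are configurable; point
estimates and bounds are ceiled.

The formula is the known-variance normal approximation. At small $n$ it
is optimistic relative to a t-test: at $\sigma = 0.2$, $\Delta = 0.5$ it
returns $n = 3$, where a two-sample z-test achieves ≈ 0.86 power but a
Welch t-test only ≈ 0.54. `empirical_power()` exposes both tests; the
acceptance checks use the z-test the formula actually models. Study
designers wanting small-sample honesty should cross-check with
`test = "t"`.

## Reference comparison

`compare_to_reference()` inner-joins estimated biological CVs with the
shipped reference table of curated biological-variation values (17
abundant plasma proteins) by UniProt accession, reporting per-protein
differences plus overlap count, median absolute difference and Spearman
rank correlation. Two quirks of the reference are encoded rather than
silently absorbed: the two complement C4 isoforms (P0C0L4/P0C0L5) share
one reference value and both rows are kept; and the IGFBP-3 entry (0.003)
is orders of magnitude below every other value, flagged non-meta-analysis
in the source, and unit-suspect — it stays in the table with
`comparable = FALSE` and is excluded from the summary statistics, not
reinterpreted.

## Numerical choices and degenerate inputs

* Sample SD uses denominator $n-1$ everywhere, including pairs.
* Subjects contributing one replicate count toward $CV_{total}$ but are
  excluded from $CV_{analytical}$; proteins with zero complete pairs get
  `NA` analytical CV and a recorded `n_pairs_used = 0`.
* The completeness filter's denominator is the *designed* count (84), not
  the per-protein observed maximum, and the global count is used rather
  than per-plex availability; the boundary is inclusive (42/84 survives).
* Impurity matrices are rejected when a column's fractions exceed 1 or a
  plex's system is ill-conditioned (condition number > 1e8, reported with
  the plex name).
* Equal-sum normalization refuses all-missing or non-positive columns by
  name; control scaling and relative abundance refuse plexes lacking the
  control channel.
* All randomness (simulation, bootstrap, Monte-Carlo power) is seeded
  through explicit `seed` arguments; identical seeds give bit-identical
  results, and report rendering is deterministic.

## Known limitations

* The duplicate design estimates *inter-individual* biological variation
  only; within-subject (longitudinal) variation needs repeated sampling
  over time, which this design does not have.
* No multiple-testing adjustment in the power analysis — it powers a
  single comparison at the stated α, as grids of this kind conventionally
  do.
* MCAR missingness and the synthetic impurity table limit what the
  simulation can certify (see above).
* Isobaric quantification compresses ratios under co-isolation
  interference; the generator does not model this, so real analytical CVs
  may behave worse than simulated ones at low abundance.
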