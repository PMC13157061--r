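---
title: "Quantifying opioid-induced locomotor responses in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying opioid-induced locomotor responses in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormpharm)
```

## The assay and what this package computes

Transgenic *C. elegans* expressing the mammalian mu-opioid receptor
pan-neuronally (tgMOR) slow their swimming when exposed to opioid agonists
such as fentanyl; the antagonist naloxone blocks or reverses the effect.
The behavioral readout is centroid swimming speed (mm/s) of individual
animals in liquid-filled wells, recorded by a machine-vision tracker:
4 animals per well, 4–5 wells per genotype and treatment per experiment,
and 3–5 independent experiments, with a 10-min pre-treatment baseline
followed by drug application and continued recording.

`wormpharm` implements the full quantification chain for such recordings:

1. **Ingestion / generation** of long-format tracker tables
   (`read_tracker_table()`, `simulate_experiment()`).
2. **Well-level QC** (`qc_filter_wells()`): only wells where all expected
   animals were successfully tracked enter analysis.
3. **Time binning** (`bin_well_means()`) and the three **normalization
   layers** — raw speed, baseline-normalized, vehicle-normalized — plus
   body-size rescaling.
4. **Response metrics** (`response_metrics()`): magnitude (% of maximum
   possible speed reduction over the 1–30 min sensitivity window), time to
   maximum effect, and the 10-min set-time-point speed.
5. **Statistics** (`one_way_anova_bonferroni()`,
   `two_way_anova_timecourse()`, `students_t()`), with wells — never
   animals — as the replicate unit.
6. **Protein conservation** (`global_align()`): global alignment and
   identity/similarity percentages for the Galpha-o orthology comparison.

## The magnitude statistic

For a normalized speed curve $v(t)$ (reference level 1) and sensitivity
window $[t_{lo}, t_{hi}]$ (default $[1, 30]$ min post-treatment):

$$\mathrm{magnitude}(\%) = 100 \cdot
  \frac{A_{\max} - \mathrm{AUC}}{A_{\max}}, \qquad
  A_{\max} = 1 \cdot (t_{hi} - t_{lo}),$$

where AUC is the trapezoidal integral of $v(t)$ over the window and
$A_{\max}$ is the area of the full-reduction rectangle — the "maximum
possible area above the curve". Complete paralysis throughout the window
gives 100%; no deviation from the reference gives 0%; a constant
normalized speed $s$ gives $100(1 - s)$. Magnitudes are deliberately not
clamped below zero: hyperlocomotion above the reference is informative
(several mutants in this assay family have hyperactive baselines) and
shows up as a negative magnitude.

Time to maximum effect is the bin-center time of the minimum smoothed
speed inside the window, after a centered rolling mean of 3 bins
(configurable; partial windows at the series edges; ties broken toward
the earliest time). The source assay did not state a smoothing rule, so
the default is the mildest symmetric filter that suppresses single-bin
noise; `smooth_k = 1` disables it.

## The synthetic generator: what it emulates

No raw tracking data are publicly deposited for this assay family, so the
package ships a generator that emulates the *statistical structure* of
tracker output, making every downstream stage testable:

* per-animal baseline speed $v_0 \sim$ LogNormal (mean
  `baseline_speed_mu`, CV `baseline_speed_cv`);
* a Hill/Emax dose-effect $E(d) = E_{\max} d^h / (d^h + EC_{50}^h)$;
* mono-exponential onset with dose-dependent time constant
  $\tau(d) = \tau_{\min} + (\tau_{\max} - \tau_{\min})
  \cdot EC_{50,\tau} / (EC_{50,\tau} + d)$, so onset accelerates with
  dose;
* a plateau of `t_plateau` minutes followed by exponential recovery
  (`recovery_tau`; `Inf` disables it);
* naloxone as a competitive pre-block (factor $1/(1 + d/K_b)$) or, when
  applied after the agonist, an exponential reversal;
* stationary multiplicative AR(1) noise with unit mean (default CV 15%,
  lag-1 autocorrelation 0.5 at 1-s sampling), and a paralysis floor at
  speed 0.

The observed speed is $v(t) = v_0 \, r(t) \, \varepsilon(t)$ with
$r(t) = 1 - E(d)\,(1 - e^{-(t - t_a)/\tau})\,
e^{-\max(0,\, t - t_a - t_{plateau})/\tau_{rec}}$.

The pharmacodynamic forms are design choices — the simplest structures
that reproduce the qualitative orderings seen in this assay family
(stronger and faster responses at higher dose; antagonist block and
reversal). The generator does **not** model body posture, cuticle
pharmacokinetics, or tracking physics; passing tests demonstrate that the
quantification chain is correct, not that the simulator reproduces any
particular real dataset.

### Genotype presets

`genotype_presets()` encodes the qualitative mutant profiles as
pharmacodynamic parameters: Galpha-o loss (`goa-1`) abolishes the
response (`Emax = 0`) with a hyperactive, small-bodied baseline; RGS6/7
loss (`egl-10`) increases magnitude (higher `Emax`, lower `EC50`); RGS9
complex loss (`eat-16`, `rsbp-1`) accelerates onset and recovery while
reducing magnitude; Galpha-q gain of function (`egl-30gf`) reduces
magnitude and slows onset. All numeric values are fabricated design
values, documented as such — they are not measurements. The tgMOR
defaults (`Emax = 0.9`, `EC50 = 20` uM, `h = 2`) put the 40-uM effect at
exactly 0.72, a convenient round anchor for parameter-recovery tests.

### Acquisition defaults

The tracker's sampling rate is not dictated by the assay description;
the generator defaults to `dt = 1` s, safely finer than the minute scale
on which responses are plotted and binned. Default binning is 60 s with
half-open bins `[left, right)` aligned to the treatment application, so
the set-time-point value at 10 min is the mean of the `[10, 11)`-min bin.

## Normalization choices

*Baseline* normalization divides each well by its mean speed over the
10-min pre-treatment window. The assay description normalizes "a
genotype" over baseline; per-well divisors are the statistically safer
default because they remove per-well animal-batch variance, and
`scope = "genotype"` is provided for fidelity to the original wording.
*Vehicle* normalization divides bin-matched by the across-well mean of
vehicle wells of the same genotype and experiment (vehicle controls were
recorded on the same plate); a single-scalar alternative was considered
and rejected because bin-matched division is what makes a no-effect
genotype end at 1 in every bin. Normalization states never chain: both
modes start from raw binned speeds. Body-size normalization is a simple
speed rescaling to body lengths per second; the original in-acquisition
adjustment is not reproducible from a text description.

## QC operationalization

"Successfully tracked" is made testable as a coverage criterion: an
animal counts as tracked only if its trace spans at least 90% of the
experiment's recording span (configurable). A well is kept only when the
tracked-animal count equals the expected count exactly — a well with an
extra spurious track id is as suspect as one with a missing animal.

## Statistics

Wells are the replicate unit throughout, matching the dot-plot convention
of per-well points. The time-course comparison is a fixed-effects
two-way ANOVA on well-level binned speeds with group and time as
categorical factors and Bonferroni-adjusted pairwise group contrasts
(averaged over time, via emmeans); no repeated-measures covariance is
modeled, which is a fidelity limit of the emulated software behavior, not
a recommendation. Set-point and magnitude comparisons use one-way ANOVA
with all-pairs pooled-variance Bonferroni comparisons, or Student's
two-sided pooled-variance t for single comparisons. Significance is
defined as p < 0.05. Degenerate inputs are handled explicitly: zero
pooled variance with equal means reports t = 0, p = 1; with unequal means
the infinite statistic is flagged rather than hidden.

## Conservation module

`global_align()` produces an optimal Needleman–Wunsch global alignment
with affine gaps (BLOSUM62, gap open 10, gap extension 0.5 per gap
position, end gaps penalized — the EMBOSS-needle-style convention under
which identity/similarity over alignment length is customarily reported).
"Conservation" is read as standard similarity: the fraction of columns
with a positive substitution score, identities included. The bundled
GOA-1/GNAO1 FASTA files are clearly-labelled *synthetic reconstructions*
(see `?goa1_gnao1_sequences`): this build environment has no access to
sequence databases, so the canonical UniProt records (P51875, P09471)
could not be bundled. Alignments of the stand-ins show the expected
high-conservation structure but do not reproduce database-derived
percentages; substitute curated FASTA files for real use. Tie-breaks
among co-optimal alignments follow the alignment engine's deterministic
rule; scores are verified against an independent enumeration oracle in
the test suite.

## Problem sizes used by the tests and acceptance script

The simulated study conditions are 4 animals/well, 5 wells per genotype
and treatment per experiment, and 3 independent experiments, at 1-s
sampling with a 10-min baseline and 35-min post-treatment recording.
Null calibration simulates vehicle-vs-vehicle experiments (two groups of
4 wells, 31-min post window) — 1,000 replicates in the test suite, 300 in
the acceptance script — and checks the one-way ANOVA type-I error against
its nominal 5%. Oracle equivalence checks use 100 random piecewise-linear
traces against a dense midpoint-Riemann integrator, and alignment
optimality is verified exhaustively for all sequence pairs up to length 2
over a 4-letter alphabet plus a seeded sample of longer pairs (pure
enumeration of alignments grows exponentially, so sampling is the
tractable form of the same property).

## Worked example

```{r example}
cfg <- generator_config(
  dt = 5, duration_post = 35, wells_per_group = 3,
  n_experiments = 2, seed = 17
)
groups <- data.frame(
  genotype = c("tgMOR", "tgMOR", "goa-1"),
  compound = c("vehicle", "fentanyl", "fentanyl"),
  dose = c(0, 40, 40)
)
design <- build_plate_design(groups, cfg)
tab <- simulate_experiment(design, cfg)
qc <- qc_filter_wells(tab)
binned <- baseline_normalize(
  bin_well_means(qc$kept, 60, 10, well_metadata(design))
)
metrics <- response_metrics(binned)
dplyr::summarise(
  dplyr::group_by(metrics, genotype, treatment),
  magnitude = mean(magnitude_pct),
  t_max = mean(t_max_effect_min),
  .groups = "drop"
)

one_way_anova_bonferroni(
  split(metrics$magnitude_pct, paste(metrics$genotype, metrics$treatment))
)
```

## Known limitations

* The generator's pharmacodynamics are phenomenological; EC50s, time
  constants, and noise parameters are design values, so quantitative
  agreement with any real experiment is out of scope.
* Binned two-way ANOVA ignores within-well temporal autocorrelation, as
  the emulated analysis did.
* The magnitude statistic depends on the normalization layer used
  upstream; the per-well metric table records which
  (`normalization_state`), and comparisons should only pool wells with
  the same state.
* The conservation workflow ships synthetic stand-in sequences, not
  database records (see above).
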