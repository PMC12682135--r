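---
title: "Methods: ddPCR quantification and longitudinal ctDNA monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ddPCR quantification and longitudinal ctDNA monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnadyn)
```

## The problem

Metastatic uveal melanoma is driven in most patients by a hotspot mutation
in *GNAQ* or *GNA11* (Q209L/Q209P). Because the mutation is clonal and
stable, a single mutation-specific droplet digital PCR (ddPCR) assay can
track a patient's circulating tumor DNA (ctDNA) across an entire treatment
course from small plasma volumes. `ctdnadyn` implements the analysis layer
of such a monitoring program: absolute quantification with per-sample
uncertainty, a confidence-interval-based taxonomy of longitudinal changes,
landmark ctDNA status at a fixed post-treatment window, and survival
comparisons stratified by ctDNA status. A synthetic cohort generator with
known ground truth makes every stage testable without patient data.

## Quantification model

ddPCR partitions a reaction into on the order of 20,000 droplets and reads
each droplet as positive or negative per fluorescence channel. Molecules
distribute over droplets essentially at random, so the count per droplet
is Poisson with mean $\lambda$ (copies per droplet) and

$$\hat\lambda = -\ln\left(\frac{N - k}{N}\right),$$

where $k$ of $N$ accepted droplets are positive. Concentration in
copies/µL of reaction is $\hat\lambda / V$ with $V$ the droplet volume in
µL (default 0.85 nL, the QX200 convention; configurable).

**Confidence interval.** The uncertainty in $\hat\lambda$ comes entirely
from the binomial sampling of the negative fraction $p = (N-k)/N$. We
compute a Wilson score interval for $p$ and push both bounds through the
monotone map $p \mapsto -\ln(p)/V$. The score interval is preferred over
the Wald interval because it never collapses to zero width at boundary
counts: a well with zero positives still gets a positive upper bound, and
wells near saturation keep a finite lower bound. Saturated wells
($k = N$) carry no upper information and are treated as errors at the
operation level; the pipeline excludes such samples and records a warning,
forcing explicit dilution handling upstream rather than silently clipping.

**Replicate wells** of the same sample and assay are summed componentwise
and treated as one meta-well before estimation. Estimating from pooled
counts is the maximum-likelihood combination; averaging per-well estimates
is not the same quantity and is slightly biased for small counts.

**Detection and the limit of blank.** Every run carries no-template
control (NTC) wells. The detection floor is
`max(k_min, 1 + max mutant-positive droplets over NTCs)` with
`k_min = 3` droplets by default; a sample is *detected* when its merged
mutant-positive droplet count reaches this threshold. Three-droplet floors
are common ddPCR practice; both the floor and the NTC pooling (all NTC
wells in the run, regardless of assay) are deliberate simplifications and
configurable.

**MAF.** The mutant allele frequency is
$100 \cdot c_m / (c_m + c_w)$ (%), with $c_m$, $c_w$ the mutant and
wild-type concentrations. Its interval uses the delta method on
$\log(c_m/c_w)$, taking each concentration's CI half-width divided by
$z_{0.975}$ as a standard-error surrogate, and maps back through
$x \mapsto 100x/(1+x)$. There is no single standard CI for a ratio of
Poisson-derived concentrations; this construction is isolated behind
`maf_with_ci()` so it can be swapped without touching anything else.
Undetected samples are reported as MAF 0 — flagged undetected — with a
one-sided upper bound computed from a mutant count of `lob - 1`, the
largest count still compatible with non-detection, so undetected samples
remain comparable on plots.

## Trajectory taxonomy

Consecutive samples of one patient are compared pairwise; there is no
interpolation across gaps, because irregular sampling would otherwise
manufacture events at times nobody measured. With treatment start at day
0:

| previous | current | event |
|---|---|---|
| detected | undetected | CLEARANCE |
| undetected | detected | INCREASE (redetection at any level) |
| undetected | undetected | REMAINS_NEGATIVE |
| detected | detected, CI above previous CI | INCREASE |
| detected | detected, CI below previous CI | DECREASE |
| detected | detected, CIs overlap | STABLE |

"Significant" rises and falls are judged purely by non-overlap of the two
95% confidence intervals, reflecting single-sample assay uncertainty. An
INCREASE is *confirmed* when the next sample is a non-decreasing positive
sample — detected and not a significant decrease; a point-estimate dip
with overlapping CIs still confirms, which keeps the confirmation rule
inside the same CI-significance framework. An increase followed by an
undetected sample, a significant decrease, or nothing (end of follow-up)
is *unconfirmed*.

Summary flags (`any_clearance`, `any_decrease`,
`any_increase_after_treatment_start`) only count transitions whose
destination sample was taken after day 0, so the baseline-to-first
on-treatment transition counts as post-treatment.

**Relation to progression.** An increase anticipates progression when its
day is *strictly* less than the progression day; an increase dated the
progression day itself counts as at-progression. The strict inequality
keeps lead-time claims conservative. Lead time is measured from the
earliest qualifying increase. The five-cell cross-tabulation
(progressed × any increase × before/at-or-after) produced by
`sankey_counts()` is exhaustive and mutually exclusive, so its counts
always sum to the cohort size.

## Landmark analysis and survival

Baseline status is the detection call of the latest sample at or before
day 0; patients without a baseline sample are not evaluable and are
excluded, mirroring standard practice. Landmark status considers samples
in a fixed post-treatment window — days 60 to 122 inclusive by default,
an operationalisation of "2–4 months" that avoids calendar-month
ambiguity — and only samples taken strictly before progression, so
post-progression ctDNA cannot leak into the stratification. At least one
detected evaluable sample makes the patient landmark-positive; evaluable
samples all undetected make them negative; no evaluable sample makes them
not evaluable (dropped from stratified comparisons).

Survival uses treatment start as the origin. OS time runs to death
(event) or last follow-up (censored); PFS to the earlier of progression
and death, else censored — the standard composite, fixed here because the
clinical tables carry both dates. The Kaplan–Meier estimator processes
events before censorings at tied times; the reported median is the
smallest time at which the curve reaches 0.5 or below, and is undefined
when the curve never gets there. Medians are also reported in months
using a 30.44-day month. The two-group comparison is the standard
unweighted log-rank test (1-df chi-square).

The Wilcoxon rank-sum test uses midranks for ties and switches between an
exact branch — exhaustive enumeration of group assignments of the observed
rank multiset, valid under ties — and a tie-corrected,
continuity-corrected normal approximation at a combined sample size of
12. The threshold is configurable; it is set where enumeration is still
instant and because monitoring cohorts of this kind are rarely larger than
a few dozen patients. Pearson correlations use the exact $t$ transform
with $n-2$ degrees of freedom. P-values are reported raw, without
multiplicity adjustment, matching how small biomarker studies report them.

Whether baseline correlations should code undetected samples as MAF 0 or
drop them is a genuine analysis choice; the MAF table keeps the detection
flag alongside the 0 so either convention is a one-line filter.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with every latent quantity recorded as ground truth:

* **Cohort composition.** Default 18 patients; hotspot assays drawn
  9:5:4 (GNA11 Q209L / GNAQ Q209P / GNAQ Q209L). Baseline tumor burden
  (RECIST sum of target lesions) is log-normal around 60 mm.
* **Shedding.** Mutant copies per ml plasma are linear in the RECIST sum
  (default 2.5 genome-equivalents/ml per mm, with a log-normal
  patient-level multiplier). 40% of patients are non-shedders
  (multiplier 0.002), giving realistic baseline negativity. Wild-type
  background cfDNA is log-normal around 2000 genome-equivalents/ml.
  Serum LDH is generated as a noisy power law of burden so
  burden–LDH–ctDNA correlations are recoverable.
* **Response kinetics.** A response class (CR/PR/SD/PD, probabilities
  0.2/0.2/0.4/0.2) drives on-treatment shedding: complete responders
  decay and then stop shedding entirely at a clearance day drawn from
  days 30–60 (so responders are ctDNA-negative in the landmark window);
  partial responders decay to a floor of 15% of baseline; stable disease
  drifts down slowly; progressive disease grows at 0.8%/day. Shedding is
  capped at 20,000 copies/ml (biological saturation; also keeps wells off
  full droplet saturation).
* **Outcomes.** A design-level landmark flag — true copies above the
  detection-equivalent threshold at any scheduled draw in the window —
  multiplies a baseline exponential progression hazard (median 11.1
  months) by a true hazard ratio (default 3). Computing the flag from
  kinetics alone, before progression is drawn, avoids circularity with
  the pre-progression sample filter applied at analysis time. Death
  follows progression after an exponential lag (mean 240 days); follow-up
  is capped at 720 days.
* **Molecular relapse.** 75% of progressors regrow ctDNA, starting
  before progression (lead 25–65 days) with probability 0.625, otherwise
  5–40 days after it. Regrowth restarts shedding at the level of a small
  regrown tumor (4 mm burden-equivalent, scaled by the patient's shedding
  capacity, so non-shedders stay negative at relapse) and grows at
  8%/day. A complete responder's relapse cannot start before their
  clearance.
* **Measurement.** Each scheduled draw (baseline at day −7, then 13
  visits to day 540) converts concentrations to expected copies per
  reaction via 2 ml plasma, a 50% extraction-to-reaction fraction and a
  36 ng input cap, then partitions them into a droplet well: total
  droplets Poisson around 17,000, each channel binomial with occupancy
  probability $1 - e^{-c/N}$, plus a mutant-channel false-positive rate
  of $5\times10^{-6}$ per droplet. Six NTC wells carry false positives
  only.

Two kinds of truth accompany the observables. The generator's *own
accounting* of the cohort it emitted (`truth$sankey`) is produced by
quantifying the emitted wells in memory; a file-based rerun of the
pipeline must reproduce it exactly, which is the round-trip determinism
check. A *noise-free reference* (`truth$maf_ideal`, `truth$landmark`)
runs the same pipeline on expected droplet counts and defines what a
perfect assay would report; agreement with it is necessarily statistical
(borderline detection and CI calls flip under counting noise), so it is
held to a concordance band (>90% of landmark statuses) rather than
equality.

**What the generator does not emulate:** pre-analytical variability
(plasma handling, extraction efficiency drift), assay cross-reactivity
and rain, biological shedding fluctuations beyond the smooth class
kinetics, pseudoprogression, informative censoring, or visit-schedule
irregularities. Passing tests therefore demonstrate that the analysis
recovers what it assumes — not that those assumptions hold in any real
cohort. Parameters not fixed by the emulated study design (shedding
coefficients, false-positive rates, kinetics) are realistic placeholders,
documented here and in `cohort_params()`, and deliberately not calibrated
to reproduce any published cohort's percentages.

## Numerical and testing choices

* Confidence level 95% throughout; $z = \Phi^{-1}(0.975)$.
* Wilson bounds are snapped exactly to 0/1 at boundary proportions to
  avoid float residue leaking into concentration bounds.
* The vectorized cohort quantifier and trajectory classifier are asserted
  against their scalar single-sample counterparts in the test suite, and
  Kaplan–Meier/log-rank against `survival::survfit`/`survdiff`, the
  Wilcoxon exact branch against `stats::wilcox.test` and literal
  enumeration.
* The classifier is checked against an exhaustively enumerated,
  independently written truth table over all status sequences of length
  ≤ 4 with a fixed non-overlapping CI geometry, including all progression
  placements.
* Simulation-based checks use 1000 wells per occupancy for CI coverage,
  500 cohorts of 40 patients for null calibration of the log-rank test,
  and 200 cohorts of 100 patients for hazard-ratio recovery — sizes chosen
  so each property is measured with comfortable Monte-Carlo margin while
  the whole suite stays quick on a laptop.
* All simulation is seeded; a cohort is bit-for-bit reproducible from its
  parameter list, and pipeline stages rerun byte-identically (run
  metadata embeds a configuration hash, never timestamps).

## Known limitations

* The CI constructions (score-through-log for concentration, delta
  method on the log ratio for MAF) are principled replacements for a
  proprietary analyzer's unspecified algorithm, not reconstructions of
  it; absolute CI widths should not be compared against vendor software.
* Detection near the limit of blank is inherently unstable: trajectories
  that linger near threshold can flicker between detected and undetected,
  producing spurious redetection "increases". The taxonomy reports what
  the assay saw; smoothing or evidence accumulation across samples is
  intentionally out of scope.
* The landmark comparison conditions on surviving progression-free into
  the window only through the pre-progression sample filter; it is a
  descriptive stratification, not a guarantee against immortal-time
  subtleties in cohorts with very early progression.
* Exact Wilcoxon enumeration is quadratic-exponential in the combined
  sample size; the default threshold of 12 keeps it trivial, but raising
  it much beyond ~20 is impractical.
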