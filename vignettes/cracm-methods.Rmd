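---
title: "Methods: analysing optogenetic circuit-mapping recordings with cracm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing optogenetic circuit-mapping recordings with cracm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracm)
```

## The scientific problem

Channelrhodopsin-assisted circuit mapping (CRACM) asks whether a long-range
axonal pathway makes functional monosynaptic contact with a recorded neuron.
Thalamocortical fibres from a source nucleus (here the lemniscal VPM or the
paralemniscal POm of the whisker thalamus) are virally transduced with
ChR2-YFP; weeks later, interneurons in barrel-cortex slices (VIP- or
SST-expressing, genetically tagged) are recorded in whole-cell current clamp
while the transduced terminals are driven with 1-ms laser flashes. TTX and
4-AP in the bath abolish action-potential propagation, so any remaining
light-evoked EPSP must be monosynaptic. Because ChR2 expression varies widely
between animals and fibres, the laser intensity is titrated upward in
steps, and synaptic properties are compared at each cell's own *threshold
intensity* — the lowest intensity at which every repetition evokes an event
within a consistent latency window.

`cracm` re-implements this analysis end to end — intrinsic-property
extraction, evoked-response detection and quantification, responsiveness and
threshold calls, SST-subtype classification, incidence modelling, group
statistics and injection QC — and couples it to a seeded synthetic generator
so that every stage can be validated against known ground truth without
laboratory data.

## The synthetic generator

The generator (`make_cell_params()`, `simulate_step_sweep()`,
`simulate_cracm_sweeps()`, `generate_cohort()`) emits sweeps with the
statistical structure the extractors assume, not a biophysical simulation.
All randomness flows from one explicit integer seed per call through a
self-contained RNG stream, so no global state leaks between calls and equal
seeds give bit-identical sweeps.

**Passive response.** Subthreshold steps follow the RC form
$V(t) = V_\mathrm{rest} + I R_\mathrm{in} (1 - e^{-t/\tau_m})$. Sampling is
20 kHz, sweeps are 1.2 s with a 1-s step starting at 100 ms, matching the
recording protocol scale (10 iterations of -10 or -50 pA 1-s steps; we
default to -50 pA).

**Sag.** An Ih-like sag is modelled as a relaxation with time constant
$3\tau_m$ from the peak deflection toward a steady state of
$(1-s)\,D$, where $s$ is the sag fraction and $D$ the asymptotic RC
deflection. The rise is kept a pure exponential until it reaches 99.9% of
$D$ and the relaxation starts there. A smooth product of two exponentials
would never let the measured peak approach the asymptote, so the measured
sag index — (peak minus steady state) over peak — would systematically
underestimate the parameter; with the piecewise form the measured index
equals the parameter to about $10^{-3}$, and the rise phase stays a clean
exponential for the time-constant fit.

**Spikes.** Action potentials are a stereotyped template: a slow 1.5-ms
"foot" from the depolarized plateau to the threshold voltage, a linear
upstroke of duration $w$ (the half-width parameter), a linear downstroke
timed so that the half-amplitude width equals $w$ exactly, a trough at
threshold minus the AHP depth, and an exponential recovery. The foot's slope
is below 10% of the upstroke slope, so the dV/dt threshold criterion
recovers the template threshold at the sample level. Spike count grows by 2
per 10 pA above rheobase (saturating at 30), and inter-spike intervals grow
geometrically with the adaptation strength, which makes the per-tenth spike
counts — and hence the 10:01 adaptation ratio — exactly computable from the
generated spike times.

**Evoked EPSPs.** Light-evoked events are peak-normalised
difference-of-exponentials kernels ($\tau_{rise}$ 2 ms, $\tau_{decay}$
15 ms by default) injected at `latency + jitter` after the flash. Event
probability *and* amplitude scale follow one logistic recruitment curve of
laser intensity; trial-to-trial amplitude variability beyond this scaling is
not modelled (no published figure constrains it, so we expose only the
recruitment parameters and make no fidelity claim). Cells are held at
-70 mV, as in the experiment. Default parameter centres use the reference
medians of the mapped cohorts where such values exist: recruitment midpoints of 0.23 mW (0.44 mW for
SST/POm groups), a 3.7-ms latency centre, Martinotti / non-Martinotti
input-resistance and time-constant centres of 232.0/121.5 MOhm and
30.51/9.94 ms. Baseline noise defaults to 0.1 mV SD, a typical whole-cell
baseline after 3-kHz filtering.

**Cohorts.** `generate_cohort()` reproduces a design table exactly: each
(type, nucleus, solution) group receives `n` cells of which exactly
`n_responsive` carry a recruitable synapse; unresponsive cells are pure
noise at every intensity. Layers are drawn proportionally to laminar
thickness and soma depths uniformly within the home layer.

**What the generator does not emulate.** Electrode drift, seal instability,
synaptic trains and short-term plasticity, IPSPs, correlated (non-white)
noise, multi-component responses and firing-pattern taxonomies beyond the
quantified metrics. Passing the recovery suites therefore shows the
extractors are correct *given the assumed signal structure*, not that they
are robust to every artefact of real recordings.

## Intrinsic-property extraction

All definitions follow standard current-clamp practice:

* **Resting potential**: mean pre-stimulus voltage pooled across the step
  iterations (the full 100-ms baseline by default; configurable).
* **Input resistance**: Ohm's law on the largest-magnitude deflection of the
  average sweep.
* **Membrane time constant**: Levenberg-Marquardt fit of
  $V_0 + \Delta V (1 - e^{-t/\tau})$ (amplitude, tau and offset all free)
  from stimulus onset to the highest deflection; the reported value is the
  time at which the *fitted* curve reaches 63% of the peak change, and the
  fit is flagged invalid when $R^2 \le 0.9$. Reading the value from the fit
  rather than raw samples keeps it stable at 20-kHz sampling.
* **Sag index**: (peak change - steady-state change) / peak change, with
  steady state averaged over the final 20% of the step. The window is
  configurable: what counts as steady state is a judgement call, and 20%
  comfortably clears the sag relaxation for time constants up to ~40 ms.
* **AP detection**: events are seeded by a coarse peak criterion (samples
  above -20 mV, peaks at least 1 ms apart), then each AP's threshold is the
  first sample — searching backward from the peak — at which dV/dt still
  reaches 10% of that AP's maximum rising slope.
* **AP width / AHP**: width between the half-amplitude crossings
  (sub-sample interpolation); AHP as threshold voltage minus the post-AP
  trough.
* **F-I protocol**: rheobase is the lowest level with at least one AP;
  the saturation level is the first whose count does not exceed the previous
  level's or whose AP-amplitude coefficient of variation exceeds 0.2, an
  operational criterion for visibly fluctuating spike amplitudes; the 10:01
  adaptation ratio is 1 - (APs in the last tenth)/(APs in the first tenth)
  at the saturation level. We use last/first orientation so that cells that
  stop firing score 1 (no adaptation scores 0); the literal alternative
  (first/last) is undefined for cells with empty last tenths — precisely the
  bursting cells the ratio has to represent.

## Evoked-response analysis

Detection uses the 3-SD rule: an event begins where the voltage exceeds the
pre-stimulus mean plus three baseline SDs (50-ms baseline window) and ends
where it returns below that level. Three numerical choices matter:

* the search window is 1-50 ms after flash onset — the 50-ms bound is the
  stated amplitude window, the 1-ms lower bound excludes the stimulus
  artefact;
* a crossing must persist for 0.5 ms (10 samples) to count, which bounds the
  false-positive rate on pure noise below 5% per sweep (measured
  empirically in the test suite);
* a baseline SD of exactly zero (possible only for synthetic input) is
  replaced by a configurable noise floor and flagged.

Amplitude is the maximum deviation from baseline within 50 ms of the flash;
the peak is read from a 0.5-ms centered moving average because a pointwise
maximum over 20-kHz wideband noise is biased upward by roughly 2.5 noise
SDs, while EPSP peaks are smooth on the millisecond scale — the smoothing
emulates the acquisition chain's 3-kHz Bessel bandwidth. The integral
(trapezoidal, mV·s) and latency use the raw samples. Rise time runs from the
threshold crossing to the peak.

The threshold intensity scans the ramp in ascending order and takes the
first level at which *all* trials (at least 3) yield an event and the
latency spread is at most 1.5 ms; "reliably" is operationalised as
all-of-three because the protocol guarantees only three repetitions. A cell
is responsive iff some level qualifies. Metrics at threshold are averaged
over trials (means rather than medians: with three trials the median is the
middle order statistic and noisier). Hyperpolarizing deflections are
ignored; at a -70 mV holding potential IPSP driving forces are negligible
by design of the experiment.

## Subtype classification

SST cells are classified Martinotti vs non-Martinotti with a 3-nearest-
neighbour Euclidean classifier on input resistance and membrane time
constant, validated by leave-one-out. Features are z-scored on the training
set by default: raw Euclidean distance would let input resistance (hundreds
of MOhm) dominate the time constant (tens of ms). Whether the original
classifier scaled its features is not stated, so a raw-distance mode is
available behind `standardize = FALSE`. Distance ties at the k-th
neighbour
are broken toward the lowest training index; with two classes and odd k a
vote tie cannot occur. A reference LOO accuracy of 82.6% depends on
the original per-cell recordings, which are not public, so the package
demonstrates the *operating regime* instead: 23 cells (16 MC, 7 nMC) drawn
from log-normal clusters at the reference medians with sdlog 0.5 give LOO
accuracies in the low-to-mid 80s.

## Incidence model

Responsiveness is tabulated per (type, nucleus, layer) stratum with
percentages at one decimal, and modelled by logistic regression with
treatment-coded factors (reference levels VIP / LI / K). Fitting is
maximum-likelihood IRLS; the test suite holds it to a brute-force optimizer
within 1e-6 log-likelihood on small problems. Stepwise selection starts from
the constant model and alternates adding the candidate factor with the
smallest deviance-test p-value (if <= 0.05) and dropping any factor with
p > 0.10, whole factors at a time — common stepwise-GLM defaults; the
original thresholds are not stated. Quasi-separation (small strata with 0%
or 100% response, e.g. an n = 2 layer) is flagged rather than fatal, with
IRLS capped at 100 iterations. McFadden's pseudo-R² is
$1 - LL_{model}/LL_{null}$. Note that with three candidate factors each
tested at 0.05, the familywise chance of a spurious addition under the null
is about 14%, not 5%; the per-test calibration is what the validation
suites check.

## Group statistics

Two-group comparisons are gated on normality: both samples must pass
Shapiro-Wilk at 0.05 (the conservative reading of gating "the parameter's
distribution") for a pooled-variance t-test with means reported; otherwise a
Mann-Whitney rank-sum test with medians. The U statistic of the first sample
and min(U1, U2) are both reported because printed U values do not
disambiguate the convention. P-values use the exact U distribution when
there are no ties and $n_1 n_2 \le 400$, else the normal approximation with
tie correction. The subtype-by-nucleus comparison uses a two-way ANOVA with
Type-II sums of squares, computed by nested model comparison so it reduces
to the classical decomposition when balanced and stays defined for
unbalanced (e.g. 24 vs 26 cells) and degenerate zero-residual designs.

## Injection QC

Vertical fluorescence profiles are column sums between the pia and
white-matter lines, resampled onto 100 normalized-depth bins, smoothed with
a 5-bin moving average and min-max normalized. Peaks with topographic
prominence of at least 10% of the profile range ("noticeable" made
operational) must all fall inside the allowed laminar zones — LIV plus the
LVb/LVI border zone (LVb and the first quarter of LVI) for VPM, LI plus LVa
for POm — and every required zone must contain a peak. The fractional layer
boundaries default to LI 0-0.08, LII/III 0.08-0.35, LIV 0.35-0.50, LVa
0.50-0.60, LVb 0.60-0.75, LVI 0.75-1.0, standard mouse S1 proportions; they
are configurable because the QC verdict depends on them and the original
assessment was partly visual.

## Validation scale and reproduction

The validation suites run at sizes chosen to keep the whole battery
desk-scale while leaving Monte-Carlo error well below the tolerances
checked: 100 synthetic cells for intrinsic recovery (median relative errors
below 5% for $R_\mathrm{in}$ and $\tau$, 0.02 absolute for sag, one sample
period for AP width, grid-exact rheobase), 200 replicate ramp experiments
for the threshold call (within one ramp step of the 0.23-mW midpoint in at
least 90%), 10,000 null replicates for the calibration of the deviance gate
and the gated two-group test (5% ± 1%), and 200+ label shuffles for the
classifier chance level. `scripts/acceptance.R` recomputes all of these
from scratch against the installed package and writes them as JSON.

## Known limitations

* The generator's noise is white; real recordings have 1/f and line
  components, so real-data detection thresholds may need the baseline
  window revisited.
* The AP template has no depolarization block, burst doublets or amplitude
  attenuation, so the amplitude-CV saturation rule is exercised only by its
  count-plateau branch in synthetic data.
* Reference headline statistics that depend on per-cell tables that are
  not public (the VPM incidence model's chi-squared 25.5 and McFadden R²
  0.549, the exact 82.6% LOO accuracy, reported U and F values) are not
  reproduction targets; the package reproduces the reported incidence
  percentages exactly and demonstrates the statistical machinery on
  calibrated synthetic cohorts instead.
* Liquid-junction potentials are deliberately not corrected, matching the
  convention of the analysed recordings; the estimates (+14 mV Cs-based,
  +16 mV K-based) are metadata only.
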