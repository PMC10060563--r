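---
title: "From current-clamp sweeps to pain-resilience composites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From current-clamp sweeps to pain-resilience composites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acex)
```

## The scientific question

Chronic neuropathic pain in rodents (the spared-nerve-injury model, SNI)
produces depression-like behaviour — less grooming after a sucrose spray
(splash test), more immobility in the tail-suspension (TST) and forced-swim
(FST) tests — and hyperexcitability of layer 2/3 pyramidal neurons in the
anterior cingulate cortex (ACC): higher input resistance, lower rheobase.
Extended environmental enrichment (ExEE) can rescue both phenotypes.
`acex` implements the full computational chain that links the two readouts:
per-cell excitability features from current-clamp step recordings, pooled
signed z-score composites for behavioural resilience and neuronal
excitability, their animal-level correlation, and the factorial statistics
used for group comparisons. A cohort simulator with analytic ground truth
makes every stage testable without animal data.

## The model neuron and the step protocol

The simulator uses a leaky integrate-and-fire (LIF) neuron,

$$C_m \frac{dV}{dt} = -\frac{V - E_L}{R_m} + I(t),$$

with spike-and-reset at the threshold voltage $V_{th}$ and a refractory dead
time. The deliberate virtue of the LIF is that every quantity the feature
extractors estimate has a closed form: input resistance is $R_m$, the
membrane time constant is $\tau = R_m C_m$, the rheobase is
$I_{rh} = (V_{th} - E_L)/R_m$, and the inter-spike interval at a
suprathreshold current $I$ is

$$\mathrm{ISI} = t_{dead} + \tau \,
  \ln\!\frac{E_L + I R_m - V_{reset}}{E_L + I R_m - V_{th}}.$$

These closed forms are the oracles the test suite checks the extractors
against.

The default stimulation protocol is ten square current steps from −300 pA to
+600 pA in 100 pA increments, digitized at 10 kHz. Step timing is not part
of the protocol definition we emulate, so the package picks standard
current-clamp values: 200 ms baseline, 500 ms step, 200 ms tail, all
configurable. 500 ms is at least 5 τ for any realistic cortical τ ≤ 30 ms,
which keeps the steady-state voltage used for input resistance within 0.5%
of $I R_m$.

### Numerical integration

Within a sampling interval the injected current is constant, so the membrane
equation is advanced with the *exact exponential update*
$V(t+\Delta t) = V_\infty + (V - V_\infty) e^{-\Delta t/\tau}$, and threshold
crossings are located in continuous time by inverting the exponential.
Forward Euler at 0.1 ms was considered and rejected: its per-interval
overshoot shortens each inter-spike interval by $O(\Delta t)$, which
accumulates to several spurious spikes per 500 ms step at high firing rates
and would defeat the ±1-spike ISI oracle the suite enforces. With the exact
update, simulated inter-spike intervals equal the closed form to machine
precision and only the rendered trace is quantized to the sampling grid.

Spikes are rendered as a stereotyped 2 ms waveform (linear rise from
$V_{th}$ to +30 mV in 0.5 ms, linear decay to $V_{reset}$ over 1.5 ms) so
that waveform-based measures — amplitude, half-width, threshold voltage —
have something to measure on simulated data. Because the waveform occupies
2 ms of trace, the effective post-spike dead time is
$\max(t_{ref}, 2\,\mathrm{ms})$.

Recording noise is additive Gaussian noise on the recorded samples
(measurement noise), not on the dynamics. Ground-truth spike times therefore
do not depend on the noise draw, while the extractors still face realistic
sample-level noise. The default of 0.3 mV is typical for whole-cell traces
after 5 kHz filtering; the noise-robustness checks use 0.5 mV.

## Feature extraction

**Spike detection.** A spike is an upward crossing of −20 mV whose
immediately preceding slope exceeds 20 V/s, with a 2 ms lockout. No
published criterion exists for the recordings we emulate; this one is robust
to 0.5 mV noise (the crossing requires a 160 mV/ms slope on the rendered
waveform, far above noise-induced slopes) and is checked against an
exhaustive per-sample brute-force scan in the tests. Input traces are
assumed already low-pass filtered at acquisition; the detector applies no
further filtering.

**f–I curve and rheobase.** Spikes are counted inside the step window of
each sweep; rates are counts divided by the step duration. Rheobase — the
minimum current eliciting a single action potential — is read off a monotone
shape-preserving cubic spline through (current, spike count) over the
non-negative currents, as the smallest current where the interpolant reaches
a count of one, found on a 1 pA grid. Counts are first passed through
isotonic regression so that noise-induced non-monotonicity cannot break the
monotone interpolant (Hyman-filtered Hermite spline, `splinefun(method =
"hyman")`). The estimate is constrained to the half-open bracket (largest
zero-count current, smallest spiking current]. Cells that never spike get a
flagged, non-numeric rheobase and are excluded from composites; cells that
spike at every tested current get the smallest tested current with a QC
flag. Note the estimate is a *grid-resolution* quantity: with 100 pA
spacing, anything within one grid step of the analytic rheobase is as good
as the input–output curve can support.

**Input resistance.** $R_{in} = \Delta V / I$ at the −300 pA sweep, with
$\Delta V$ the mean over the last 100 ms of the step minus the mean over the
100 ms immediately before it. The trailing window avoids the charging
transient; with mV and pA, $R_{in}(\mathrm{M\Omega}) = 1000\,\Delta V/I$.
Spikes inside that sweep's step window and zero deflections are flagged.

**Passive and waveform measures.** Resting potential is the mean pre-step
baseline across sweeps. The membrane time constant comes from a
single-exponential fit to the first 200 ms of the −300 pA step onset
(`nls`/`SSasymp`, with a log-linear fallback anchored at the steady state,
needed because `nls` declines on noise-free exponentials). AP threshold
voltage, amplitude (peak minus threshold) and half-width (interpolated
duration at half amplitude) are averaged over the first three spikes of the
lowest suprathreshold sweep.

## The composites and the correlation

All three behavioural readouts are z-scored **across all animals, groups
pooled** (sample sd, denominator $n-1$), signed so that higher means more
resilient, and averaged:

$$\mathrm{resilience}_a = \tfrac{1}{3}\left(z^{splash}_a - z^{TST}_a -
z^{FST}_a\right).$$

Input resistance and rheobase are z-scored **across all QC-passing cells**
(pooled), combined per cell as $\tfrac12 (z^{R_{in}} - z^{rheobase})$, and
cell values averaged within each animal to a grand average. The mean (rather
than the sum) of signed z-scores is used; Pearson correlations are identical
either way since the two differ by a positive affine map. Pooling at the
cell level before animal averaging follows the grand-average-per-animal
convention; z-scoring animal means instead is available as
`pool = "animal_means"`. Constant inputs are an error, never a silent zero,
and missing values exclude the animal with a warning.

The association is summarised by the ordinary least-squares line of
resilience on excitability and the Pearson $r$ (Spearman optional) with its
two-sided p-value, over animals matched by id.

## The cohort generator and its calibration

Each animal receives a latent depression-like score
$d_a = \delta_{g(a)} + \mathcal N(0, \sigma_d^2)$ with group means
$\delta = (0, 0, 1, 0.2)$ for sham-SH, sham-ExEE, SNI-SH, SNI-ExEE and
$\sigma_d = 0.3$: the injured standard-housed group carries the full
depression phenotype and enrichment rescues most of it. Behaviour follows
the latent score (grooming $120 - 50\,d_a$ s, immobilities $150/180 +
50\,d_a$ s, residual sd 25 s, clamped to the 300 s / 360 s test durations);
cell parameters follow it through the coupling $\beta$ (default 1):
$R_m = 100\,(1 + 0.30\,\beta d_a)$ MΩ and $V_{th} = -50 - 3\,\beta d_a$ mV,
with animal-level variability (cv 5% on $R_m$, 0.5 mV on $V_{th}$) and
cell-level variability (cv 10%, 1 mV). At $d_a = 1$ this reproduces the
+30% input resistance / −3 mV threshold hyperexcitability of the
injured-standard-housed group, and $\beta = 0$ severs behaviour from
excitability entirely (the null control).

The defaults were calibrated once, analytically, to give a model-implied
animal-level correlation of about −0.8 for a 16-animal, 6-cells-per-animal
cohort. Sketch: with $\mathrm{sd}(d) = \sqrt{0.17 + 0.09} \approx 0.51$
across the stratified cohort, each behavioural test carries signal sd
$50 \times 0.51 \approx 25.5$ s against 25 s noise; averaging three tests
leaves $\rho_R = 25.5/\sqrt{25.5^2 + 25^2/3} \approx 0.87$ between the
resilience composite and $d$. On the excitability side the $R_m$ signal sd
is $30 \times 0.51 \approx 15$ MΩ against 5 MΩ animal-level and
$10/\sqrt{6}$ MΩ averaged cell-level noise, giving $\rho_E \approx 0.93$.
The product, $r \approx -0.81$, is the population correlation the pipeline
is asked to recover; spline-grid and windowing error attenuate the estimate
by a few hundredths.

Von Frey thresholds are generated per paw as six draws around a group- and
day-specific mean: contralateral (and sham ipsilateral) at 4.5 g throughout;
SNI ipsilateral falling after surgery toward 1.8 g (standard housing) or
3.2 g (enriched, the partial rescue) with the injury fraction
$1 - e^{-day/5}$, measurement sd 0.3 g, at days −1, 7, 21, 42, 56.

A root seed spawns three independent sub-streams (animal latents and
behaviour; cell parameters; per-cell recording noise), so changing the
number of recorded cells never reshuffles behavioural draws, and a config
plus seed reproduces every output byte for byte.

### What the generator does and does not emulate

It reproduces the *structure* of the study — the 2 × 2 design, nested cells
within animals, anticorrelated behaviour and excitability, the inclusion
screen's contrast — with known ground truth. It does not emulate real
electrophysiology: no channel noise, sag, adaptation, bridge-balance error
or electrode drift, no morphology, and behavioural scores are Gaussian
rather than scored from video. Passing tests therefore demonstrate that the
*analysis chain* is correct and well-calibrated, not that it would be robust
to every artefact of real recordings.

## Screening and group statistics

The von Frey inclusion rule compares the six ipsilateral against the six
contralateral readings with a two-sided unpaired t-test (Welch by default,
pooled optional): an SNI animal is included when the difference is
significant in the injury direction (ipsilateral lower); a sham animal when
there is no significant difference. The comparison, direction guard and
α = 0.05 are package choices — the emulated protocol states only that an
unpaired t-test was the criterion. Note the sham rule is a true-null test,
so about α of sham animals are excluded by construction.

The battery mirrors the figures' analyses: pooled-variance t-tests (df =
$n_A + n_B - 2$, the reporting convention of the emulated study; Welch
optional), two-way surgery × housing ANOVA with Type-II sums of squares
(the software defaults behind the emulated analyses are unstated; Type-II
reduces to the classical decomposition when balanced and handles the
7–8-per-cell imbalance), a
univariate two-way repeated-measures ANOVA for the paw-withdrawal time
course (no sphericity correction by default, since none is reported in the
emulated analyses), and three post-hoc families over all pairwise cell-mean
comparisons: Tukey–Kramer, step-down Holm–Šídák, and the
Benjamini–Krieger–Yekutieli two-stage FDR. The BKY adjustment is adaptive
and can push an adjusted value below the raw p (a known property); the
post-hoc table takes rejection decisions from the unfloored values and then
floors the reported adjusted p at the raw p, so reported values are always
monotone in the familiar sense. Degenerate designs are guarded explicitly:
zero residual variance reports flagged infinite F for effects with positive
sums of squares and F = 0, p = 1 for null ones.

## Problem sizes and tolerances

The test suite and the acceptance script run everything at the sizes the
analyses are designed for: 16 animals × 6 cells for correlation recovery
(200 and 100 seeds respectively), 100 seeds for the rescue-pattern check,
1000 (suite) / 500 (script) simulated null datasets at 4 observations per
cell for the interaction type-I rate. Feature-recovery tolerances are 2%
(input resistance, noiseless), 3% (0.5 mV noise), 5% (time constant), one
100 pA grid step (rheobase), ±1 spike (ISI oracle), and 1e-12 for the
closed-form statistic oracles.

## Known limitations

- No NWB/HDF5 import: the interchange format is the documented JSON + CSV
  trace pair. The R environment targeted here has no NWB reader, and the
  simulator writes the canonical format directly.
- Cells are aggregated to animal means before correlation; a mixed-effects
  treatment of cells nested in animals is out of scope by design.
- The LIF has no adaptation or sag, so f–I curves saturate only through the
  refractory period and sag-based measures are meaningless on simulated
  data.
- The rheobase spline choice (counts vs rates, knots, crossing level) pins
  down *this package's* convention; other implementations of a
  "spline-derived AP threshold" may differ within the same grid bracket.
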