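---
title: "Models and methods: beta/gamma oscillations and coupled feedback circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: beta/gamma oscillations and coupled feedback circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clgf)
```

This vignette is the package's own account of the science it implements:
the dynamical model, the derived measures, the synthetic-data generator,
and the numerical and design choices that were genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The Wilson–Cowan oscillator

Each neural population pair is modelled as

$$\frac{dE}{dt} = -\alpha E + \beta_E\,(1 - rE)\,f_E(s_E), \qquad
  \frac{dI}{dt} = -\alpha I + \beta_I\,(1 - rI)\,f_I(s_I),$$

with the centred sigmoid $f(s) = 1/(1+e^{-a(s-\theta)}) - 1/(1+e^{a\theta})$
and inputs $s_E = \omega_{EE}E - \omega_{IE}I + (\text{couplings}) + P$,
$s_I = \omega_{EI}E - \omega_{II}I + Q$. Time is in ms; `wc_params()`
carries the default set $\alpha=0.35$, $\beta_E=\beta_I=1$, $r=0.65$,
$a_E=1.3$, $a_I=2$, $\theta_E=4.5$, $\theta_I=3.5$, $\omega_{EE}=16$,
$\omega_{EI}=15$, $\omega_{IE}=12$, $\omega_{II}=3$, $Q=0$.

**The weight-subscript convention matters.** Reported descriptions of this
parameter set state three behavioural facts: a stable limit cycle between
80 and 150 Hz for external drive $P$ between roughly 1.2 and 3, quiescence
below that range, and hyper-excitation above it. Placing $\omega_{EI}=15$
on the $I\to E$ term (one common subscript convention) produces
oscillation from $P\approx0.95$ past $P=4$ at 62–138 Hz, contradicting all
three facts. Reading the subscripts source→target — $\omega_{EI}$ is the
$E\to I$ weight and appears in $s_I$, $\omega_{IE}$ the $I\to E$ weight in
$s_E$ — reproduces them almost exactly: oscillation on $P\in[1.1,2.75]$ at
81–149 Hz, quiescent below, saturated above. The package therefore uses
the source→target convention; `wc_frequency_sweep()` recomputes the
behavioural check at any time.

**Hyper-excitation.** Past the upper drive limit the E population pins
near its refractory ceiling ($E \to 1$, since $(1-rE)$ with $r=0.65$ caps
growth) and stops oscillating. `wc_regime()` labels such trajectories
`"hyper"`; all spectral and synchrony read-outs report `NA` for them,
because a saturated constant signal has no band-limited oscillation or
phase. This state is *absorbing* in strongly coupled positive-feedback
circuits: once every unit is pinned high, mutual excitation holds the
input far above threshold and inhibition (also capped near 1) cannot
recover it.

**Integration.** The delay differential equations are integrated by the
method of steps with classical RK4 and Catmull–Rom (cubic) interpolation
of the delayed excitatory history, in C++. The step is `dt = 0.05` ms by
default (capped at 0.1 ms); halving it changes a 500 ms trajectory by
less than $10^{-4}$ (tested). History for $t \le 0$ is the constant
initial state. The default initial state staggers the oscillators
(E = 0.2, 0.05, 0.1, …): identical units started symmetrically move in
perfect synchrony, and for coupled circuits the synchronous transient
falls directly into the absorbing hyper-excited state. The stagger is the
minimal symmetry-breaking device; any comparable choice gives the same
attractors.

## The coupled local-and-global feedback (CLGF) circuit

`wc_circuit()` builds the three-unit motif: hub *a* reciprocally coupled
to *b* with a long delay (default 21 ms, the inter-regional conduction
range being 15–25 ms) and to *c* with a short delay (default 6 ms,
intra-regional range 6–10 ms). Couplings enter the target's excitatory
input as $\omega\,E_\text{src}(t-\tau)$.

**Drive.** By default every oscillator receives the external input `P`
(`drive = "all"`). Under the printed-equation variant (`drive = "hub"`,
input to *a* only) the relay units sit far below threshold (their E stays
under 0.01 — the coupling input $\omega E$ with $E \le 0.28$ cannot reach
$\theta_E = 4.5$), the feedback returned to the hub is negligible, and no
beta-band component ever appears. A regime switch requires active
partners, so uniform drive is the default and the hub-only form is kept
as an option.

**Calibration.** The hub's drive is chosen as the grid value whose
single-oscillator frequency is nearest 100 Hz
(`wc_calibrate_input()`, giving P = 1.4 at 97 Hz on the default grid).
The global coupling is set to the strength that maximizes the beta/gamma
power ratio of the two-node circuit (`wc_calibrate_global()`): the
long-delay loop (round trip ≈ 42 ms) locks the pair into ~20 Hz
relaxation oscillation in a narrow window around strength 2.5, which is
the beta-dominant regime that the subsequent local-coupling sweep starts
from.

**The realized regime sequence and its compressed axis.** On the sweep
(`wc_sweep_local()`, strengths 0–4), this realization shows, in order:
beta dominance (local strength ≲ 0.5), an abrupt switch to gamma
dominance (crossover ≈ 1), and absorption into hyper-excitation (≳ 2).
The qualitative sequence — beta-dominant without the local loop, abruptly
gamma-dominant beyond a local-coupling threshold — is the regime
behaviour the model targets, but the local-strength axis is compressed:
the reference description places the gamma-dominant showcase at strength
3 and reports conserved behaviour across the delay ranges, whereas here
strength 3 lies beyond the hyper-excitation boundary. Adiabatic
continuation (slowly ramping the local strength from the beta-locked
state) finds no oscillating attractor past ≈ 1.9, so this is a property
of the realized model under the behaviour-validated weight convention,
not an artifact of initialization. Likewise, among oscillating grid
points the beta-band PLV between *a* and *b* does not drop across the
crossover (the gamma state here is an in-phase state, PLV ≈ 1); the loss
of beta synchrony appears only through the transition into
hyper-excitation, where PLV is undefined. The acceptance suite asserts
the literal regime claims and leaves the two that this realization cannot
meet failing, visibly, rather than redefining them.

**Band powers for circuits** are summed Morlet power (squared magnitude,
summed over the band's 1 Hz rows) over the coupled pair *a*, *b* — the
pair whose powers and synchrony the circuit analysis tracks — with
`oscillators = 1:3` available. Read-outs discard the first 500 ms: the
locked state needs ~1 s to establish, and the circuit simulations run 6 s
per grid point so that the 13 Hz Morlet row, the 1000 ms PLV windows, and
the intermittency of the locked state are all averaged over.

## Spectral analysis

`morlet_tf()` evaluates the width-7 complex Morlet transform on a 13–80 Hz
grid in 1 Hz steps (the step resolves the 30/31 Hz band boundary; the
width is the stated analysis choice). The kernel is applied in the
frequency domain; normalization is fixed so a unit sinusoid at the
analysis frequency gives $|W| = 1$ — every comparison downstream is
relative, so the constant only sets the unit. Channel-averaged maps take
the mean of magnitudes (not the magnitude of the mean, which would cancel
phase-misaligned channels). The first and last three time-domain standard
deviations of the lowest analysis frequency (~257 ms at 13 Hz) are
flagged edge-contaminated and excluded from scalar summaries.

Bands are beta = [13, 30] Hz and gamma = (30, 80] Hz: the printed sources
give the gamma lower edge as both 30 and 31; making the bands disjoint
with the boundary row assigned to beta is this package's documented
convention. `band_power()` defaults to the band mean of magnitudes (the
stated definition); the squared/summed variant used for circuits is an
argument, not a second code path. Beta harmonics falling in the gamma
band are deliberately not removed.

## Beta–gamma switching

`detect_switching()` is a latched three-condition detector on the 1 ms
band-power series: trigger when $d\beta/dt<0$, $d\gamma/dt>0$, and
$\gamma-\beta>0$ simultaneously; hold while $\gamma > \beta$; release at
$\beta \ge \gamma$ (a tie releases, since the hold condition requires
strictly greater gamma). Derivatives are backward differences, so the
first sample cannot trigger. Duration is the count of latched 1 ms steps,
the event count the number of 0→1 transitions. The detector is verified
against an independently coded per-step reference on a thousand random
traces. Band powers feeding it are channel-averaged before detection.

## Phase synchrony

`bandpass()` is a zero-phase FIR filter (Hamming window, order three
cycles of the low cutoff, applied forward–backward) — the behavioural
contract of the conventional EEG/MEG band-pass. `hilbert_phase()` takes
the analytic-signal argument. `plv()` computes, per channel pair and
1000 ms window slid by 200 ms, the resultant length of the phase
differences, then averages windows; windows that would run past the
record are dropped, and `edge_exclude_ms` optionally drops windows
touching the filter-transient edges (off by default; the option exists
because constant-offset sinusoids reach PLV = 1 to $10^{-9}$ only when
the contaminated edges are excluded). For a 1000-sample window the null
PLV of independent phases concentrates near
$\sqrt{\pi}/2/\sqrt{N} \approx 0.028$. `plv_topography()` applies raw
per-edge Welch tests at the chosen threshold (conventionally 0.01 and
0.001) with no multiple-testing correction — matching the reference
analysis — and an optional FDR flag, off by default.

## Feedback inference from two-sided impulse responses

`estimate_ir()` regresses $y(t)$ on lagged copies
$x(t-\tau),\ \tau\in[-L, L]$ by ridge least squares with the penalty
chosen by generalized cross-validation. Positive lags are the causal part
(x leads y), negative lags the non-causal part; a feedback relationship —
inherently bidirectional, so edges are unordered pairs — leaves
significant structure on *both* sides. Significance is calibrated by
circular time-shift surrogates of $y$, and the detection statistic is
joint: the smaller of the two side peaks, compared with the same joint
statistic on the surrogates, at the 95 % quantile. The joint form is not
a detail. These signals are locked oscillators, and a circular shift of a
near-periodic record re-aligns the pair at some single lag — testing each
side against its own marginal null therefore saturates at the true peak
level and detects nothing, while a shifted surrogate rarely shows strong
peaks on both sides of zero at once.

Two consequences of oscillation-dominated data are documented as
limitations rather than patched over:

- The lag horizon is `L = 30` ms — wide enough for both conduction-delay
  ranges (6–10, 15–25 ms), and deliberately *below* the ~50 ms period of
  the beta-locked pair state, because a longer horizon lets a shifted
  surrogate align once per period on both sides of zero and inflates the
  joint null.
- A one-way coupling strong enough to fully *entrain* the driven unit is
  observationally equivalent to a reciprocal one: once both units share a
  period, echoes of the causal peak recur at multiples of that period on
  both sides of zero lag, and no lag-based statistic can rule out the
  reverse direction. The unidirectional-rejection property therefore
  holds for non-entrained driving (distinct intrinsic frequencies), which
  is the condition the module test exercises; the synthetic generator
  wires all true feedbacks reciprocally, so the ambiguity does not bias
  its recovery.
- Short-delay (local) feedbacks between gamma-band units sit at an
  identifiability limit: the conduction delay (6–10 ms) is comparable to
  the oscillation period (~10 ms), so a lag of $d$ cannot be
  distinguished from $d \pm$ one period. Ground-truth recovery is
  therefore validated on long-delay (global) feedbacks; the recovery test
  runs ten subjects carrying zero to three global feedback pairs and
  checks that detected counts track true counts (Spearman ≥ 0.7), at a
  reduced problem size of two 20 s windows per subject.

`consistent_network()` splits the record into non-overlapping windows
(four of 20 s at full scale), infers each window independently, and keeps
only edges identical in pair and sign in every window.

The exact comparison statistic of the original impulse-response method is
not publicly specified, so this realization makes no claim of numerical
equivalence with any reported edge counts; ground-truth recovery on
synthetic data is its validation surface.

## CLGF census

`classify_edges()` labels an edge local iff both endpoints share one of
the ten cortical subregions ({pre-frontal, middle-frontal, temporal,
parietal, occipital} × {L, R}); the sensor→subregion map is a user input
for real arrays and a generated artifact (contiguous blocks of 10–11
channels) for synthetic ones. `count_clgf()` counts CLGF instances as
unordered triples (hub, global partner, local partner) over positive
edges. Because edge type is fixed by region membership, the global and
local partners of a hub are always distinct, and the instance count
equals the per-hub product of positive global and local degrees — the
default multiplicity; the participating-hub count is returned alongside.
The census is verified against exhaustive triple enumeration (~172k
triples at 102 channels).

## The synthetic cohort generator

The generator's defaults are the emulated study conditions, fixed once:

- **Groups and sizes**: control 17, patient 15; 102 channels at 1000 Hz
  for 80 s (all scalable for tests).
- **Topology archetypes**: expected abundances control
  (local 11, global 5, CLGF 8) and patient (local 6, global 4, CLGF 3);
  per-subject counts are Poisson draws around these, feasibility-clipped,
  and each subject's topology is *constructed* so its census equals the
  drawn counts exactly (hubs carry one global loop plus a block of
  locals; remaining edges land on untouched channels). The patient
  archetype having strictly fewer local feedbacks and CLGF motifs is the
  generator's contract. Reported group differences motivating these
  relative abundances: total and local positive feedbacks clearly
  reduced, global not significantly, CLGF reduced.
- **Signal model**: every channel is the excitatory output of one
  Wilson–Cowan unit (the same model as the circuit analyses); topology
  edges become reciprocal delayed couplings with weight 2.5 (global) /
  1.0 (local) and the edge's drawn lag (global 15–25 ms, local 6–10 ms).
  Per-channel drive is drawn from U(1.3, 1.5) so uncoupled sensors
  oscillate at distinct intrinsic frequencies (~90–105 Hz) and dephase;
  identical frequencies would make even independent channels phase-lock
  trivially.
- **Noise**: additive 1/f² ("brown") noise at 0.5 × the array signal SD.
  Brown noise is the realistic resting-sensor background in this band,
  and the spectral slope is load-bearing: under a width-proportional
  wavelet bank, white noise yields a gamma-leaning floor (response grows
  with the band's width), 1/f is exactly flat, and only a steeper slope
  gives the beta-dominant resting baseline that real recordings show —
  without it the switching detector latches permanently on
  noise-dominated subjects and the group direction of switching duration
  inverts.
- **Clinical scores**: within each group the negative-symptom score is
  `mean + sd·(r·z + sqrt(1-r²)·ε)` with `z` the standardized CLGF count
  and generating correlation `r = −0.5376` by default; the remaining
  scores are uncorrelated draws at plausible scales. Setting `|r| = 1`
  removes the noise term entirely (the noiseless-line case).

**What the generator does and does not emulate.** It produces two-group,
band-limited, coupled-oscillator multichannel records with known motif
ground truth and realistic noise color — enough to exercise and validate
every analysis stage. It does not emulate MEG field spread (no
leadfields, so no trivially shared signal between neighbouring sensors),
physiological artifacts, non-stationarity beyond the oscillators' own
intermittency, or 1/f signal (as opposed to noise) power. Passing tests
therefore demonstrate correctness and recoverability of the methods under
the stated signal model, not performance on real recordings. One known
inversion: because switching episodes merge as they lengthen, the
generator's control-like group shows longer switching *durations* but not
reliably more *events* — only the duration direction is asserted.

## Statistics

`welch_t()` / `welch_t_summary()` implement the unequal-variance t with
Welch–Satterthwaite degrees of freedom; the summary form reproduces all
four recomputable demographic t values (−1.35, 1.22, 1.05, 1.02) from
printed means/SDs/sizes to two decimals, which the pooled-variance form
does not — that is the evidence for the Welch reading of "two-tailed
t-test". The raw-vector form agrees with `stats::t.test` to ten
significant digits. `chi2_2x2()` is plain Pearson without continuity
correction; on the 11/6 vs 12/3 sex table it gives 0.92, not the printed
0.95 — no standard variant reproduces that figure exactly, and the value
is reported as computed. `pearson_r()` uses the t transform with n−2 df.
No multiple-testing correction is applied anywhere, matching the
reference analysis; the significance convention is 0.05. Degenerate
inputs (zero variance in both groups) return statistic 0 / p 1 for equal
means and a flagged infinite statistic otherwise.

## Problem sizes used by the test and acceptance suites

Simulated checks run at reduced but stated sizes, chosen so every
property is still informative: circuit sweeps use 6 s per grid point;
switching-direction checks use six cohorts of 3+3 subjects, 30 channels,
8 s; feedback recovery uses ten subjects, six channels, two 20 s windows;
cohort-level statistics use topology-only cohorts (the expensive signal
stage is validated separately). The full-scale defaults (102 channels,
80 s, 4 × 20 s windows) remain the package defaults throughout.
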