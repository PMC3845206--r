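---
title: "Modeling attentional gain control in evoked responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling attentional gain control in evoked responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmgain)
```

## The model

### Precision as superficial-pyramidal self-inhibition

In hierarchical predictive coding, superficial pyramidal (sp) populations
report precision-weighted prediction error. A scalar error unit with
expectation signal $\mu$, top-down prediction $f$ and recurrent
self-inhibition $e^{\gamma}$ obeys

$$\dot\xi = \mu - f - e^{\gamma}\,\xi,$$

whose fixed point is $\xi = e^{-\gamma}(\mu - f) = \Pi\,(\mu - f)$ with
precision $\Pi = e^{-\gamma}$. The identity $\gamma = -\ln\Pi$ is the
conceptual core of the package: the log strength of recurrent inhibition on
sp cells *is* a negative log precision, and attention corresponds to lowering
it (raising gain) on the channels expected to carry reliable signal.
`error_unit_trajectory()` realizes this integrator didactically and is
verified against the closed form on a grid of $(\gamma, \mu - f)$ values.

### The canonical microcircuit

Each cortical source is a four-population neural mass: spiny stellate (ss),
superficial pyramidal (sp), inhibitory interneuron (ii) and deep pyramidal
(dp) cells. Every population has second-order (alpha-kernel) convolution
kinetics

$$\dot v = i, \qquad \dot i = \kappa u - 2\kappa i - \kappa^2 v,$$

with rate constants $\kappa = 1/4\ \mathrm{ms^{-1}}$ for the three fast
populations and $1/16\ \mathrm{ms^{-1}}$ for deep pyramidal cells. Firing
rates are logistic in depolarization, $\sigma(v) = 1/(1 + e^{-0.56 v})$,
so the baseline rate is $\sigma_0 = \sigma(0) = 1/2$. All synaptic drives
are expressed in rate *deviations* $\sigma(v) - \sigma_0$; this makes the
all-zero state an exact resting fixed point and lets the modulatory term
vanish when afferents fire at baseline.

The intrinsic wiring follows the canonical-microcircuit family: an
excitatory ss → sp → dp chain, excitatory drive onto the interneurons,
interneuron inhibition of ss, sp and dp, and fixed self-inhibition on ss and
ii. The sp population's self-inhibition is deliberately *not* part of this
fixed table: it is always $e^{\gamma}$, where

$$\gamma = \gamma_0 + [\mathrm{invalid}]\,\Delta\gamma
  - \tfrac{3}{2}\, M \, (\sigma(V_{dp}) - \sigma_0)$$

combines the baseline $\gamma_0$, a condition-specific increment
$\Delta\gamma$ (the valid-cue condition is the baseline), and the
state-dependent top-down modulation by deep-pyramidal firing in higher
sources. The modulation coefficient defaults to $3/2$ and is configurable
(`mod_coef`), as are all other constants.

The baseline $\gamma_0 = 0.4$ is chosen for spectral stability: with the
default coupling strengths the rest-state Jacobian of the coupled network
has all eigenvalues strictly in the left half plane (the package tests
verify this numerically), so perturbations decay and `resting_state()`
converges. At $\gamma_0 = 0$ the rest state is weakly unstable.

### The eight-source hierarchy

`build_posner_network()` assembles bilateral V2 (level 1), V3 and V5
(level 2) and superior parietal PC (level 3) sources. Within each
hemisphere, V2 sends forward (sp → ss) connections to V3 and V5, which send
forward connections to PC; every forward edge is reciprocated by a backward
driving edge (dp → sp, with a 0.5-weighted collateral onto the
interneurons) and a backward modulatory edge (dp → the $\gamma$ of the
target's sp cells). There are no interhemispheric or level-skipping edges,
and no conduction delays — all extrinsic influences act within the
integration step.

The visual target is a Gaussian drive with peak 120 ms after onset and
width 16 ms, delivered to the spiny stellate cells of the V2 source
contralateral to the target hemifield. A configurable fraction
(`contralateral_fraction`, default 0.5) of the input also reaches the mirror
V2 source. This ipsilateral drive is a deliberate design choice: early
visual responses to lateralized stimuli are reliably bilateral (ipsilateral
amplitudes of roughly a third to a half of contralateral are typical), and
without it the unstimulated hemisphere of a delay-free, hemisphere-separated
network would sit exactly at rest, making all of its condition effects
invisible in principle. Keeping the spread as input sharing (rather than
adding interhemispheric edges) preserves the exact mirror symmetry of the
network, which the tests exploit (`mirror_hemispheres()`).

## Observation model

The measured signal is a lead field applied to the weighted sum of
excitatory depolarizations, with weights (ss, sp, dp) = (0.2, 1.0, 0.5) —
only the ordering (sp strictly dominant, interneurons silent) is
theoretically constrained; the values are declared defaults. The synthetic
lead field (`make_lead_field()`) draws smooth random topographies over 64
channels with a between-source correlation of 0.3 to emulate MEG field
spread; it is deterministic given its seed and stands in for a
template-anatomy forward solution, which is out of scope.

For fitting, the data are compressed to the first eight *canonical modes*:
the leading principal components of the condition-concatenated sensor data
after projection onto the lead-field column space. The mode basis is
orthonormal, so white sensor noise stays white in mode space while most of
its energy (the part orthogonal to anything sources can express) is
discarded.

## Preprocessing

The trial pipeline mirrors standard evoked-response practice, in the fixed
order filter → downsample → epoch → average:

* `bandpass()`: 5th-order Butterworth, 2–32 Hz, applied forward–backward
  (zero phase). A 10 Hz sinusoid passes within 5%; 60 Hz is attenuated
  below 0.1.
* `downsample()`: zero-phase low-pass at 80% of the target Nyquist, then
  decimation (600 → 200 Hz is the canonical 3× case). The signal is
  demeaned around the filter so constants are exactly invariant.
* `epoch_baseline()`: closed −50..400 ms window around target onset,
  per-channel baseline (−50..0 ms) mean removal.
* `robust_average()`: per-sample iteratively reweighted averaging with
  bisquare weights (tuning constant 4.685 on MAD-scaled residuals, at most
  20 iterations). The iteration starts from the per-sample *median*: a mean
  start lets a few high-amplitude artifact trials inflate every residual and
  can reject all trials at strongly driven samples. If every trial is
  rejected at a sample (possible only in pathological inputs), the median is
  kept there. Identical trials get unit weights and reproduce the arithmetic
  mean exactly.

## The synthetic scenario

`default_validity_scenario()` encodes the study conditions the analysis is
meant to recover: a left-hemifield target (input to right V2), two cueing
conditions, and invalid-cue effects confined to sp gain and its modulation
with the lateralized sign pattern — left V2 profoundly disinhibited
($\Delta\gamma = -\ln 2$), left V3 slightly less sensitive ($+\ln 1.25$),
right V5 slightly more ($-\ln 1.25$), no parietal gain change, and backward
modulation strengthened on every edge ($\Delta M = +\ln 1.5$) except those
from right PC ($-\ln 1.25$). Effect magnitudes are sign-faithful stand-ins
(the source analysis plots but does not tabulate them) and are configurable.
Defaults: SNR 10 dB of white sensor noise, 128 trials per condition,
per-trial lognormal amplitude jitter (sd 0.1) and Gaussian latency jitter
(sd 10 ms), no artifact trials unless requested.

The baseline connection strengths (forward 2, backward driving 1, backward
modulatory 3, input amplitude 3) were calibrated jointly, once, against
three requirements: responses of a few millivolts at every level of the
hierarchy with realistic latencies (V2 peaks shortly after the 120 ms input,
parietal sources later and weaker); a stable rest state; and — essential to
the phenomenon under study — backward modulation that measurably shapes the
sensor data, so that modulatory condition effects are identifiable at the
scenario's SNR. A regime in which modulation is sensor-invisible would
contradict the premise that model comparison can detect it. Under these
defaults the invalid-condition left-V2 log gain starts 0.69 above its
valid-condition baseline and rises by a further ~1.6 to peak near 145 ms.

What the generator does *not* emulate: structured (correlated) sensor noise,
ongoing oscillatory background, subject-to-subject variability, eye-movement
artifacts, co-registration error, or any right-target conditions. Passing
recovery tests on these data therefore demonstrates the internal consistency
of the pipeline — generator, forward model and inverter agree — not that
real MEG recordings would be as informative.

## Inversion

`variational_laplace()` is a Gaussian fixed-form scheme on the mode-space
evoked responses. All positive structural quantities (extrinsic strengths,
modulatory strengths, rate-constant scalings, stimulus width and amplitude,
lead-field gain) are parameterized as log-scalings of their defaults with
$\mathcal N(0, 1/16)$ priors; the stimulus peak has prior
$\mathcal N(120, 16^2)$ ms; condition effects included by a model get
$\mathcal N(0, 1/4)$, excluded ones are fixed at zero (prior variance 0
removes a parameter from the optimization). Observation noise is white in
mode space with a single log-precision hyperparameter updated by a
closed-form fixed point between parameter steps; temporal correlation is a
declared simplification.

Optimization is Gauss–Newton ascent on the free energy

$$F = -\tfrac{\beta}{2}\,\varepsilon^\top\varepsilon
     + \tfrac{n}{2}\ln\beta - \tfrac{n}{2}\ln 2\pi
     - \tfrac12 (\mu-\mu_0)^\top \Sigma_0^{-1} (\mu-\mu_0)
     + \tfrac12 \ln\lvert\Sigma\,\Sigma_0^{-1}\rvert$$

with Levenberg–Marquardt damping (multiplicative on the curvature
diagonal, adapted by factors of 4–64), Jacobians by central finite
differences (step $10^{-3}$ in parameter space), initialization at the
prior mean, an iteration cap of 64 and convergence declared after three
successive accepted improvements below 0.01 nats. Steps are accepted only
if they improve the best free energy so far, so the accepted-iteration trace
is non-decreasing by construction; a fit is flagged non-converged only if no
improvement on the prior mean is ever found. On a linear forward model the
scheme lands on the conjugate Bayesian solution, and the tests hold it to
the analytic evidence within $10^{-6}$.

## Model comparison

The factorial space crosses three condition-effect subsets — extrastriate
gain ($\Delta\gamma$ on V2/V3/V5), parietal gain ($\Delta\gamma$ on PC) and
backward modulation ($\Delta M$) — into eight models labelled like
`"1 0 1"`. A provisional four-model space asks instead whether backward
*driving* ($\Delta B$) or backward *modulatory* ($\Delta M$) condition
effects (or both, or neither) are needed; intrinsic-gain effects stay free
in all four, since that comparison precedes the gain partition. The
$\Delta B$ parameters exist in the full parameterization precisely so this
space is well defined; they are fixed at zero throughout the factorial
space.

Reduced models are scored by Bayesian model reduction
(`reduce_evidence()`): the reduced evidence is computed analytically from
the full model's Gaussian posterior and the two prior densities, via an
exact Gaussian integral in which parameters with zero reduced variance are
conditioned out in closed form rather than approximated by a large finite
precision. With unchanged priors the reduction returns the full free energy
identically, and on linear-Gaussian models it matches independent refitting
to $10^{-6}$; on the nonlinear network the two routes are only
approximately equal (`bmc_from_fit(..., refit = TRUE)` switches to
refitting for audit). Posterior model probabilities are a softmax of free
energies under a uniform model prior; free-energy ties are broken toward the
model with fewer free effect parameters.

`gain_timecourse()` reconstructs $-\gamma(t)$ (log gain = log precision) per
source from any fitted or constructed network, using the same afferent
deep-pyramidal rates as the integrator, which is how the package reproduces
the redeployment-of-precision pattern: a pre-stimulus lateralized gain
offset installed by the cue, then a post-input rise of the invalid-condition
left-V2 gain peaking before 200 ms.

## Numerical choices

* Integration: fixed-step classical Runge–Kutta at $\Delta t = 1$ ms over
  −50..400 ms, chosen for determinism; halving the step changes the default
  trajectories by well under 1% sup-norm, and the hemispheric mirror test
  holds bit-exactly because the source ordering makes mirrored summations
  associate identically.
* The error-unit integrator is explicit Euler with
  $\Delta t = e^{-\gamma}/10$ and a 40-time-constant horizon, and refuses
  steps beyond its stability bound ($\Delta t\, e^{\gamma} < 2$).
* Degenerate inputs: MAD = 0 in robust averaging (all trials equal at a
  sample) yields unit weights; an all-rejected sample keeps the running
  median; a zero-power signal cannot be noise-scaled (`add_sensor_noise()`
  errors); integration divergence names the first non-finite source.
* Problem sizes in the shipped tests and acceptance script: 64 channels, 8
  modes, 91 samples per condition, 5 generation seeds per scenario arm, 40
  trials per robust-averaging run — sizes at which the whole suite runs in
  a few minutes on a single core while leaving every mechanism exercised.

## Known limitations

* Effect magnitudes in the default scenario are sign-faithful but arbitrary
  in scale; recovery statistics depend on them jointly with the SNR.
* The single white-noise precision in mode space ignores temporal and
  cross-mode correlation; free energies are therefore optimistic relative
  to data with structured noise.
* Bayesian model reduction is exact only in the linear-Gaussian limit; on
  the network model it agrees with refitting to within a few nats, which is
  ample for the decisive comparisons here but matters near ties.
* The four-population microcircuit's intrinsic coupling constants are
  declared defaults of the implementation, not estimates; only their sign
  structure is constrained by the model family.
* Right-hemifield target conditions and interhemispheric connectivity are
  out of scope.
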