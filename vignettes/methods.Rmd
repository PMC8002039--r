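---
title: "Models and methods: bilinear DCM, variational inversion and hierarchical group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bilinear DCM, variational inversion and hierarchical group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Functional electrical stimulation (FES) of the peroneal nerve can restore
voluntary ankle dorsiflexion in a subset of chronic stroke patients even
after the stimulator is removed — the *carryover effect*. `fesdcm`
implements an effective-connectivity analysis of this phenomenon on a
four-region cortical motor network — primary motor cortex (M1), primary
somatosensory cortex (S1), supplementary motor area (SMA) and angular gyrus
(AG) — observed with BOLD fMRI under a 2x2 volitional-by-FES paradigm. The
pipeline has three layers:

1. a **within-subject generative model** (bilinear dynamic causal model plus
   hemodynamics) inverted against each session's four regional time series;
2. a **between-subject hierarchical model** (parametric empirical Bayes,
   PEB) that regresses the subject-level coupling parameters on a group
   mean, a carryover classification (CE = +1, nCE = −1), an acquisition time
   point (PRE = +1, POST = −1) and a normalized clinical capacity score;
3. a **model-structure identification procedure** in six steps that fixes
   the driving-input (C), endogenous (A) and modulatory (B) structures for
   controls and then for patients, using Bayesian model reduction, selection
   and averaging at the second level.

No subject data are distributed; a synthetic-cohort generator reproduces the
statistical structure the analysis assumes, so every stage is testable by
planted-truth recovery.

# The within-subject generative model

Neural dynamics follow the bilinear state equation

$$\dot x = \Big(A + \sum_j u_j B^{(j)}\Big)\, x + C u,$$

with $x$ the (dimensionless) neural activity of the four regions, $u$ the
experimental inputs, $A$ (Hz) the endogenous coupling, $B^{(j)}$ (Hz) the
input-dependent change in coupling, and $C$ (Hz per unit input) the direct
driving influence. Everywhere in the package (including serialization) the
convention is `A[target, source]`.

Three inputs are derived from the block schedule: the volitional drive **V**
(on during the two conditions requiring volitional effort), the stimulation
input **E** (on during the two FES conditions; the *only* input allowed to
modulate connections), and the proprioceptive drive **P** (on during all
four movement conditions; it drives S1). Inputs have unit amplitude —
scaling is absorbed by `C` and `B`.

**Input encoding.** The paradigm is event-related: movements are paced every
3.5 s inside 21 s ON blocks. The generator and pipeline default to event
encoding (1 s unit pulses at the pacing interval, six per ON block); a
boxcar option covers the conservative block reading. Event encoding was
adopted as the default because the pulse train, filtered through the
network, separates the direct drive of a region from its network inputs far
better than a sustained boxcar: under boxcars the decomposition of S1's
inputs (direct P drive versus M1/SMA afferents and their modulations) is
close to unidentifiable, and simulate-then-invert recovery falls short of
the 0.9 correlation level that the test suite asserts — and reaches it —
under event encoding.

Each region's neural activity drives the standard four-state
balloon–windkessel hemodynamic cascade (vasodilatory signal, inflow, blood
volume, deoxyhemoglobin; the latter three log-transformed so the natural
states stay positive), with the canonical constants: signal decay 0.64 1/s,
autoregulation 0.32 1/s, transit time 2 s, vessel stiffness 0.32, resting
oxygen extraction 0.4, echo time 0.05 s, resting venous volume 4%. The
source study relies on the standard DCM hemodynamic model without restating
it, so these canonical values (and the log-normal scale parameters on decay,
transit and the intra/extravascular ratio, prior variance 1/256) are
declared defaults of this package, not facts from that study.

**Integration.** Inputs are piecewise-constant on a microtime grid
(default TR/16 = 0.1875 s) and one classical RK4 step is taken per bin, in
compiled code; a pure-R reference integrator with the same equations serves
as an independent oracle in the tests (agreement to better than 1e-10).
Halving the microtime bin changes trajectories by well under 1e-3 relative
norm.

**Guard rails.** The log-transformed cascade is stiff when inflow collapses
($\mathrm d \log f = s/f$ blows up as $f \to 0$), which an explicit
integrator cannot survive for extreme couplings. The integrator therefore
bounds the log-states to ±3 (natural scale 0.05–20 times baseline) and the
vasodilatory signal to ±10. Ordinary trajectories never approach these
bounds; they only keep extreme Gauss–Newton proposals and extreme synthetic
draws finite so that the step-halving rule, rather than an arithmetic
overflow, rejects them.

# Priors and variational inversion

Free parameters are selected by binary structure masks. Shrinkage priors:
off-diagonal `A` and all `B` entries N(0, 1/16); self-connections
parameterized directly in Hz with prior N(−0.5, 1/256) — a deliberate,
documented deviation from the log-scaling convention some implementations
use; `C` entries N(0, 1); hemodynamic log-scales N(0, 1/256). Observation
noise is white and Gaussian per region with log-precision hyperparameters
$\lambda_r$ under hyperprior N(2, 1) (data are percent signal change, so
precision $e^2 \approx 7$ corresponds to noise sd ≈ 0.37%). Serial
correlations in the BOLD noise are ignored — a stated simplification, and
the synthetic generator produces white noise to match.

`invert()` performs Gauss–Newton ascent on the Laplace free energy

$$F = \mathbb E_q[\log p(y \mid \theta)] - \mathrm{KL}\big(q(\theta)\,\|\,p(\theta)\big),$$

with the Jacobian of the integrator obtained by forward finite differences
(systematic step 1e-4). Each iteration updates the noise log-precisions
jointly with the posterior covariance in a small fixed point (the precision
update is initialized at its analytic no-prior maximizer $\log(N/S)$, which
keeps Newton inside its basin), then proposes a Gauss–Newton step with step
halving. Only steps that do not decrease the recorded free energy are
recorded; because refreshing the Jacobian and the noise precisions re-levels
$F$ by a few nats, improvements *within* the current expansion that do not
beat the recorded best are taken silently, and convergence is declared when
the current expansion cannot be improved (or when the recorded improvement
stays under 0.01 nats for three consecutive iterations; hard cap 128
iterations). The best recorded point is returned. The procedure is fully
deterministic; on linear-Gaussian reductions of the model it reproduces the
analytic Bayesian regression posterior to 1e-6.

Unstable proposals (any eigenvalue of $A$ with nonnegative real part) are
rejected inside the step rule, mirroring how the stability precondition is
enforced for simulation.

# Model comparison: BMR, BMS, BMA

`bayesian_model_reduction()` computes, in closed form, the posterior and
evidence change of a model whose prior pins a parameter subset (reduced
prior variance 1e-8 — not exactly zero, keeping matrices invertible).
`model_posteriors()` converts free energies to posterior model probabilities
under uniform model priors. `bayesian_model_average()` moment-matches the
probability-weighted mixture; searches retain the smallest set of models
with cumulative probability ≥ 0.95 (a configurable Occam window — the
criterion behind "best performing models" is a package decision, the source
study does not state one).

# The hierarchical (PEB) group model

At the second level each subject-session's coupling vector (one field at a
time: A, B or C) is modeled as a design-predicted group value plus Gaussian
between-subject variability. Controls use a single mean regressor; patients
use mean, carryover (±1), time (±1) and capacity score. Capacity scores are
mean-corrected and divided by their maximum absolute deviation, the simplest
map onto [−1, 1] (all-zero when scores are constant).

Implementation: each first-level posterior is converted to its Gaussian
likelihood summary (posterior precision minus prior precision — PSD by
construction; natural means subtracted likewise), which makes the hierarchy
exactly linear-Gaussian given the between-subject precision. That precision
is a single log-scale hyperparameter $\gamma$ scaling a base variance equal
to `expected_variance_fraction` (default 1/16) of the first-level prior
variance; $\gamma$ carries hyperprior N(0, 1/16) and is optimized by 1-D
free-energy ascent, after which the coefficient posterior is available in
closed form. Because the estimated between-subject precision stays finite
under its hyperprior, a residual shrinkage of order 1e-3 toward the
coefficient prior remains even for identical noise-free subjects.

Patients contribute two rows (PRE and POST), treated as independent at the
second level — the design the source analysis implies. The synthetic
generator deliberately violates this by sharing each patient's random effect
across sessions, so the impact of ignored within-subject dependence is
measurable rather than assumed away.

The overall magnitude of a connection for a subgroup and time point is the
signed sum of contributions,
$\theta_{\text{mean}} + \mathrm{CE}\cdot\theta_{\text{CE}} +
t\cdot\theta_t + \mathrm{cs}\cdot\theta_{\text{CS}}$, implemented by
`combine_contributions()`; terms absent from the design contribute zero.

# The six-step structure identification

Every subject is inverted once against the full model (all 16 A entries, all
16 B entries for E, and the union of the candidate C entries); all structure
questions are then asked at the second level by BMR of the PEB posterior,
and resolved structures are propagated to the first-level posteriors by
per-subject BMR before the next step:

* **STEP 1** (controls, C): three candidates — V drives M1, SMA, or both; P
  drives S1 in all of them. Bayesian model selection picks the MAP candidate
  (no averaging over C), which is then fixed.
* **STEP 2** (controls, A): M1↔S1, SMA→M1 and M1→SMA are fixed; the four
  remaining bidirectional pairs (SMA↔S1, AG↔M1, AG↔S1, AG↔SMA) are switched
  jointly (16 candidates; a configuration flag switches the eight directions
  independently). B is full during this step. The winning structure keeps
  pairs with inclusion probability ≥ 0.5; estimates are averaged over the
  Occam window.
* **STEP 3** (controls, B): E modulates any connection of the winning A
  structure, self-connections included; exhaustive on/off search (BMR-scored,
  greedy backward elimination above the 4096-model cap) with BMA.
* **STEP 4** (patients, C): structure inherited from STEP 1, weights
  re-estimated under the four-regressor design.
* **STEP 5** (patients, A): connections of the controls' winner may be
  discarded individually (the previously fixed connections included — the
  source results discard one of them), never added: patients cannot exhibit
  connections absent in controls, and this nestedness is asserted on every
  run.
* **STEP 6** (patients, B): exhaustive search over modulations of the STEP 5
  structure, with BMA.

# The synthetic cohort

Defaults mirror the study layout: 16 controls (one session) and 8 patients
(PRE and POST), balanced CE/nCE labels, capacity scores uniform on the
observed clinical range 8–25 and normalized by the group rule. Ground-truth
coupling follows the winning structures the source study reports, with
magnitudes chosen by this package: endogenous couplings of 0.1–0.25 Hz with
suppressive M1→S1 and SMA→M1 (reciprocal loop gains kept low enough that the
planted modulations leave the system stable), self-connections −0.5 Hz,
drives V→M1 0.125, V→SMA 0.15, P→S1 0.19 Hz (BOLD excursions of a few
percent signal change), FES modulations of ±0.1–0.3 Hz with the SMA→M1
modulation centred at
zero — the connection carrying the planted carryover (−0.25 Hz) and time
(+0.30 Hz) effects, matching the reported sign pattern. A capacity effect of
−0.05 Hz acts on V→SMA. Between-subject variability is Gaussian with sd
0.05 Hz on the free A/B/C entries only (hemodynamics are held at their
canonical values across subjects, isolating what the group stage must
recover). Noise is calibrated per region to SNR 2 (signal sd over noise sd).

Effect magnitudes deserve a note. The reported group coefficients (−0.39 Hz
carryover, +0.51 Hz time on the same connection) would imply sessionwise
modulations of ±0.9 Hz — almost four prior standard deviations outside the
B shrinkage prior — which first-level Laplace inversion attenuates
substantially. That attenuation is a real property of DCM under shrinkage
priors, not an implementation defect; the generator's default effects are
therefore sized so that sessionwise values stay within prior support, which
is what makes planted-effect recovery a sharp test. True effect magnitudes
in the study are unknowable from its figures.

Subject draws are accepted only if every session of the subject yields a
stable A matrix *and* a finite noiseless trajectory (up to 20 resampling
attempts); patients' PRE and POST sessions share the subject-level random
effect.

What the generator does **not** emulate: serially correlated physiological
noise, head motion, scanner drift, lesion anatomy, vascular heterogeneity,
or hemodynamic variability across subjects. Passing recovery tests therefore
demonstrates the correctness and calibration of the estimation machinery
under the model's own assumptions, not robustness to the full complexity of
patient fMRI.

# ROI summarization

For the volume-level stage (exercised on synthetic volumes): isotropic
Gaussian smoothing at 4 mm FWHM (separable convolution, sd = FWHM/2.3548 per
axis converted to voxels; zero padding with renormalization so constants are
preserved at the boundary); per-region activation maxima selected inside
masks under a pairwise Euclidean separation of at least 8 mm — greedy in the
declared region order M1, S1, SMA, AG, falling back to the next-highest
admissible voxel on conflict (the source study only says the separation was
"checked"; the greedy rule is a package decision); and summarization of a
4 mm-radius sphere by its first eigenvariate — the first principal temporal
component of the voxel-by-time matrix (voxelwise demeaned), scaled to the
standard deviation of the mean ROI series, signed to correlate nonnegatively
with it, and recentred on the mean signal level. The scaling and sign
conventions are package decisions; the source study states none.

# Problem sizes and determinism

All simulation studies in the test suite run at the study's own scale — 200
volumes, 4 regions, 16 controls or 8 two-session patients — with 10–20
replicate seeds for the stochastic checks; a full cohort inversion plus the
six-step pipeline takes a few minutes on one core. Every function that
consumes randomness takes an explicit integer seed and restores the RNG
state; repeated calls are bit-identical.

# Known limitations

* White-noise likelihood (no AR model of BOLD autocorrelation).
* One-state-per-region neural model; no stochastic or nonlinear (second
  order) DCM variants.
* Second level treats PRE/POST rows as independent (see above).
* Large modulations (beyond ~2 prior sd) are attenuated by the shrinkage
  priors; comparisons of large reported coefficients with recovered ones
  must account for this.
* The greedy search used above the exhaustive-enumeration cap reports
  pairwise (on/off at the winner) inclusion probabilities, not full
  model-space marginals.
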