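---
title: "Modelling causal motor-network interactions during hand grip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling causal motor-network interactions during hand grip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gripdcm` implements a complete dynamic-causal-modelling (DCM) chain for
event-related hand-grip fMRI: a bilinear neural state equation over a
network of cortical motor regions, a balloon–windkessel haemodynamic
observation stage, variational-Laplace model inversion, fixed- and
random-effects Bayesian model selection with family inference, Bayesian
model averaging (BMA), paired-pulse TMS interhemispheric-inhibition (IHI)
statistics, and a synthetic-cohort generator that stands in for the
original recordings so every downstream stage runs end to end with no
external data. This vignette explains the model, the defaults and why they
were chosen, the numerics, and what the synthetic validation does and does
not demonstrate.

## The generative model

### Neural dynamics

The hidden neural state $x \in \mathbb{R}^n$ of the $n$ regions evolves as

$$\dot x = \Big(A + \sum_{j=1}^{m} u_j(t)\, B_j\Big) x + C\, u(t),$$

where $A$ (1/s) holds the intrinsic coupling among regions during the
task, each $B_j$ the change in coupling induced by input $j$, and $C$ the
direct driving influence of the inputs. Entry $(i, k)$ of $A$ is the
influence of region $k$ on region $i$; positive couplings are facilitatory,
negative inhibitory. Two inputs are used: a *driving* channel marking grip
onsets and a *modulatory* channel carrying grip-force variation, so the
force sensitivity of a connection lives in the modulatory $B$ matrix.

The default network has eight regions — M1, SMA, PMd and PMv in each
hemisphere, the main cortical contributors to the corticospinal tract —
and models right-hand grip: the driving input enters every left-hemisphere
region, and no restriction is placed on $A$ (fully connected).

### Inputs

Grips are coded as one-bin rectangles of height $1/\mathrm{d}t$ (unit
area), the discrete analogue of delta functions at grip onset. The
modulatory channel is impulse-coded the same way with area equal to the
grip's force expressed as a deviation from the mean MVC fraction: forces of
15–55% MVC become areas of $\pm 0.2$ after mean-centring. Centring makes
$B$ express deviation from the average-force condition rather than an
effect present on every grip; `build_inputs(center = FALSE)` switches to
raw MVC fractions, since the original description does not state the
centring convention.

### Haemodynamics

Neural activity $z_i$ drives, per region, the standard four-state
balloon–windkessel cascade (vasodilatory signal $s$, inflow $f$, venous
volume $v$, deoxyhaemoglobin $q$):

$$\dot s = \varepsilon z - \kappa s - \gamma (f - 1), \quad \dot f = s,$$
$$\tau \dot v = f - v^{1/\alpha}, \quad
  \tau \dot q = f\,\frac{E(f, E_0)}{E_0} - v^{1/\alpha}\frac{q}{v},$$

with $E(f, E_0) = 1 - (1 - E_0)^{1/f}$, observed as

$$y = V_0\big(k_1 (1 - q) + k_2 (1 - q/v) + k_3(1 - v)\big).$$

Defaults are the widely used constants $\kappa = 0.64$/s, $\gamma =
0.32$/s, $\tau = 2$ s, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$,
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$, with neural efficacy
$\varepsilon = 1$ (input scaling is carried by $C$, so a separate efficacy
gain would be redundant at the default). They are held fixed during
inversion: estimating them per region is possible in principle but triples
the parameter count for little benefit at desk scale, and the analyses
here concern coupling, not vascular, parameters. Signals are expressed in
percent signal change (`scale = 100`).

## Inversion

`invert_model()` is a variational-Laplace scheme: a Gaussian posterior
$q(\theta) = N(\mu, \Sigma)$ over the free parameters maximises the free
energy $F = \text{accuracy} - \text{complexity}$, the evidence lower
bound, by Gauss–Newton ascent with Levenberg–Marquardt damping.

* **Parameterisation.** Off-diagonal $A$ entries, allowed $B$ entries and
  allowed $C$ entries are free reals; self-connections are
  $-\tfrac12 e^{\theta}$ so any real $\theta$ keeps them negative
  (stability). Masked-out parameters are simply not estimated — they stay
  at the prior mean of zero.
* **Priors.** $A$ off-diagonals $\sim N(0, 1/64)$, self log-scales
  $\sim N(0, 1/256)$, $B$ and $C$ entries $\sim N(0, 1)$: shrinkage keeping
  the prior-mean system stable, on the scale of couplings reported for
  paradigms of this kind. The noise precision carries a Gamma hyperprior
  with shape 1 and rate 1/100 (prior mean precision 100, i.e. noise sd
  0.1%); the rate-100 reading of "Gamma(1, 100)" would cap the attainable
  precision near 4 and make the free energy *decrease* with additional
  noiseless data, contradicting the monotone-data-benefit property the
  estimator should have, so the scale reading is used.
* **Gradients.** Exact forward sensitivities: the neural sensitivity
  system $\dot S_k = (A + \sum u_j B_j) S_k + g_k$ is integrated jointly
  with the states, and each region's tangent is propagated through the
  *linearised* balloon cascade. Because that linearisation is the same
  4×4 operator for every parameter, the whole tangent block is advanced
  with one small matrix product per region per stage (C++/RcppArmadillo).
  No finite differences are used.
* **Noise update.** The precision is updated by EM under its Gamma
  hyperprior between Gauss–Newton steps; each region's series is
  mean-centred internally, so baselines are not modelled.
* **Convergence.** $|\Delta F| < 0.01$ nats on three successive
  near-undamped steps, or 128 iterations (flagged, not an error). Damped
  micro-steps deliberately do not count towards convergence: counting them
  caused premature stops far from the optimum during development.
  Initialisation is the prior mean (deterministic); optional seeded jitter
  and warm starts exist for diagnostics.

## The hypothesis space

Families ask *where* force modulation acts. Crossing the hub M1 (left /
right) with the hemisphere of the secondary areas involved (same /
opposite) and the direction of the modulated connections (from-hub /
to-hub) gives eight families; within a family, one model per non-empty
subset of the three secondary areas times three self-modulation variants
(all areas, hub only, secondary only) gives $7 \times 3 = 21$ members, 168
models in total. The published figure does not pin down whether the four
per-hub variants differ by hemisphere, by direction, or both; the
hemisphere-by-direction reading implemented here is the one consistent
with the winning family being "left M1 to the contralateral secondary
areas" *and* with its label "family 4" (the variant order places
same/from, same/to, opposite/to, opposite/from at positions 1–4 per hub).
The counts 21 and 168 hold under any variant scheme. On the reduced
four-region network (below) the same construction yields
$(2^1 - 1) \times 3 \times 8 = 24$ models.

Group selection is fixed-effects by default — log evidences summed over
subjects (Group Bayes Factors) — on the argument that the physiological
mechanism of grip generation is common across healthy subjects. Family
evidence aggregates members by log-sum-exp minus log family size (a
uniform within-family prior); plain summation is available
(`method = "sum"`) since the original text does not state which was used.
The random-effects family inference treats the generating family as a
random effect with a uniform Dirichlet prior, Gibbs-samples family
frequencies (10^4 sweeps, 10^3 burn-in, seeded), and reports expected and
exceedance probabilities. BMA weights are fixed-effects
($w_k \propto e^{F_k}$) within the selected family, matching the
fixed-effects stance of the selection itself; an RFX-weighted average is
available but off by default.

## The synthetic cohort

`sample_cohort()` emulates the study conditions: by default 27 subjects
with ages uniform on 19–77 years (a truncated-normal mode with mean 41.8,
sd 19.1 exists), sessions of 100 grips (20 each at 15–55% MVC) and 60
nulls at SOA 3.77 s, TR 3.12 s, 196 retained volumes, and ten test plus
ten conditioned MEP trials per TMS condition with test amplitudes around
1.25 mV.

Ground-truth couplings follow per-connection linear age models
$a(\text{age}) = \text{intercept} + \text{slope}\cdot(\text{age} -
\text{48})$ plus Gaussian subject residuals. Defaults:

* Baselines are the group-average connectivity table for this task
  (largest couplings from left M1, 0.11–0.16/s; near-zero or inhibitory
  couplings onto right M1).
* Connections **onto right M1** carry *type 1* patterns — negative at the
  young end, crossing zero, positive at the old end. The left-M1 to
  right-M1 slope is calibrated so the population $r^2$ against age is
  0.64 at the published sample size; other type 1 slopes are calibrated to
  0.30 (the published per-connection values appear only in a figure).
  Calibration uses $\text{slope} = \sqrt{r^2/(1-r^2)}\,\sigma_\epsilon /
  \sigma_{\text{age}}$ with residual sd 0.05/s.
* **Right-hemisphere intrahemispheric** connections between secondary
  areas carry *type 2* patterns — positive throughout and increasing —
  with slopes bounded to keep the mean line positive across the age range
  (residual sd 0.01/s, so only the occasional subject goes negative,
  matching the "all but 1–3 subjects positive" description).
* **Force modulation** lives on the winning-family maximal model: left M1
  to each contralateral secondary area at $B = -0.75$, drifting more
  negative with age. The size follows from the reported one-third decrease
  of these connections under increasing force: with impulse-coded
  modulation of area $\pm 0.2$, the per-event modulated transfer is
  $B \times 0.2 \times \bar x_{\mathrm{M1_L}}$ against an intrinsic
  per-event transfer of roughly $A \times \int x\,\mathrm{d}t \approx
  A \times 2$, so $|B| \approx 0.75$ realises a ~30% effect for
  $A \approx 0.13$. Self-modulation is $-0.02$ (the reported self-effects
  are below 1.5%).
* **Driving weights** are the published group averages (M1 1.26, SMA 0.1,
  PMd 0.04, PMv 0.08, left hemisphere only).
* **TMS linkage.** Expected change-IHI is $1 + \lambda\,a_{\mathrm{LM1
  \to RM1}}$ with $\lambda = 3$ and lognormal trial noise (sdlog 0.25),
  jointly calibrated so change-IHI vs age recovers $r^2 \approx 0.45$ at
  the TMS subset size of 19: the age signal through the coupling has sd
  $\lambda \cdot \text{slope} \cdot \sigma_{\text{age}} \approx 0.20$
  against combined coupling-residual and trial noise of
  $\approx 0.21$. Resting IHI is 0.575, the published group mean.
* BOLD noise is set per subject from the target signal-to-noise ratio
  (default SNR 1, noise sd = sd of the noiseless percent-change signal);
  series are stored at a grand-mean baseline of 100 so the preprocessing
  emulation (grand-mean scaling to 100, 1/128 Hz discrete-cosine
  high-pass) operates on realistic units.

Everything derives from one master seed through fixed sub-seed offsets;
regenerating a cohort with the same configuration is bit-for-bit
identical.

**What the generator does not emulate:** spatial structure (it produces
region summaries directly, so the first-eigenvariate step is exercised on
constructed voxel sets, not simulated volumes), serial noise correlation,
motion and physiological artefacts, slice timing, behavioural
force-tracking error, and any age effect on the haemodynamics (none was
reported for this paradigm). Passing the synthetic validation therefore
shows the chain is *self-consistent* — it recovers what its own forward
model generated under realistic noise — not that the original biological
findings are reproduced.

## Numerical choices

* Fixed-step classical RK4 at $\mathrm{d}t = \mathrm{TR}/16 \approx
  0.195$ s for states, sensitivities and tangents on a common grid;
  inputs are held constant over each bin. The scheme is deterministic and
  its order is verified by step-halving; against a matrix-exponential
  closed form (linear regime, piecewise-constant input) the trajectory
  agrees to better than $10^{-6}$.
* Volumes are read out at bin indices $\mathrm{round}(t_v/\mathrm{d}t)$ —
  no interpolation.
* $f$ and $v$ are clamped at $10^{-8}$ inside the balloon equations;
  divergence (non-finite state) aborts with the offending time bin.
* Posterior curvature is inverted by Cholesky; a singular curvature is
  ridge-regularised with a warning.
* Exceedance probabilities are argmax counts over retained Gibbs sweeps;
  with $10^4$ sweeps their Monte-Carlo error is well under the 0.02
  symmetry tolerance used in the tests.
* Ties in the eigenvariate sign rule resolve towards positive correlation
  with the mean voxel course.

## Desk-scale study sizes

Inversion-heavy validations run on the reduced four-region network
(bilateral M1 + SMA — the hub and the strongest secondary area), chosen so
a family-selection study over all 24 models for cohorts of 8 subjects, a
ten-seed parameter-recovery study on a three-region chain at T = 196 and
SNR 1, and end-to-end pipeline runs of 12 subjects all complete in
minutes. The full eight-region network with 27 subjects is the default of
the cohort generator itself and of the analysis scripts' documented
full-size configuration. The numbered scripts under `analysis/` are thin
drivers over the package functions; the spec-style command-line interface
is intentionally served by these scripts plus the exported functions
rather than a separate shell tool.

## Known limitations

* The free energy is evaluated at a point estimate of the noise precision
  (EM update with its Gamma prior terms); a full variational treatment of
  the precision would add a small constant offset per model and does not
  change rankings in practice.
* Bilinear DCM only: no two-state, stochastic or nonlinear (second-order)
  variants, and no slice-specific haemodynamic delays.
* With delta-coded modulation, $B$ is only weakly identified at SNR 1 in
  single subjects; group-level selection (8+ subjects) is the intended
  operating point, mirroring the original fixed-effects design.
* Sign-flip symmetry of the couplings holds exactly only in the linear
  observation regime; the balloon stage is mildly nonlinear, so the
  corresponding test operates at weak drive.
* No multiple-comparison correction is applied across the per-connection
  age tests, matching the original reporting convention; reports carry the
  number of tests performed so users can correct as they see fit.
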