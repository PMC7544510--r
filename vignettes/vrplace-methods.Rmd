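---
title: "Methods: place coding, theta phase and population decoding in vrplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place coding, theta phase and population decoding in vrplace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vrplace analyzes recordings from mice navigating a virtual corridor by
running on a wheel, in sessions where the *gain* coupling wheel movement to
virtual displacement is manipulated in blocks of trials. The package
quantifies how much a neuron's spatial tuning is anchored to the visual
scene versus to the physical distance run, how firing couples to the 6–9 Hz
hippocampal theta oscillation, how well position can be decoded from CA1 or
V1 populations, and whether the two regions' decoding errors co-fluctuate
beyond what behavior explains. Every stage can be exercised on synthetic
sessions with known ground truth.

## The synthetic world

The generator emulates the task geometry: a 200-cm corridor (two visually
identical 200-cm semicircular corridors forming a 400-cm loop, tracked by a
corridor-identity bit), landmarks centered at 0, 83 and 117 cm, a reward
zone of ±12 cm around the first landmark, and gains {0.8, 1, 1.2} changed in
blocks of 5–10 trials. Block gains are drawn with probabilities
(0.18, 0.64, 0.18) so that ~36% of trials are gain-manipulated, matching the
reported fraction; controlled experiments pass an explicit `trial_gains`
schedule instead.

Wheel speed follows an Ornstein–Uhlenbeck process (mean 22 cm/s, SD 8 cm/s,
time constant 2 s, clipped at zero). These are free parameters — the
underlying publications do not report speed statistics — chosen once to give
realistic occupancy non-uniformity and occasional sub-5 cm/s epochs that
exercise the speed gating. Licks are emitted at 8 Hz inside an approach zone
around the reward location, shifted per gain (−2.4 cm at low, +2.5 cm at
high gain, the reported behavioral shifts), plus a low stray rate; rewards
are delivered on the first in-zone lick of a trial. Pupil covariates are
low-pass OU noise, with pupil size optionally coupled to speed, solely to
exercise the behavioral regression.

Theta is generated by integrating an OU instantaneous frequency clipped to
6–9 Hz; the LFP is the cosine of that phase (peaks at phase 0) plus white
noise, sampled at 600 Hz.

A neuron's spiking intensity is

$$\lambda(t) = \bigl[b + p\,G\bigl(x(t) - A\sin(\theta(t)-\theta_0)\bigr)\bigr]\,
  \bigl(1 + m\cos(\theta(t)-\theta_{pref})\bigr),$$

where $G$ is a wrapped Gaussian bump of width $\sigma$ centered, on a
gain-$g$ trial, at $L_a + D\,(1 + w(g-1))$: landmark $L_a$ plus anchoring
distance $D$, interpolating between visual anchoring ($w=0$) and
wheel-distance anchoring ($w=1$). The visual-coordinate field shift at gain
$g$ is therefore exactly $w(g-1)D$. Positive precession amplitude $A$ moves
the field center forward at $\theta = \theta_0 + 90°$; the measured drift
curve (below) then approximates $A\sin(\theta-\theta_0)$, so recovery tests
are sign-consistent. Spikes are drawn by thinning a homogeneous Poisson
process at the analytic bound $(b+p)(1+m)$, with $\lambda$ defined by linear
interpolation of its values on the 60-Hz behavioral grid. Optional
position-error processes (a common component plus per-region components, OU
with configurable SDs) are added to the position each neuron senses; they
create correlated or independent coding noise for the error-coupling
analyses.

What the generator does **not** emulate: raw broadband voltage, spike
waveforms beyond a scalar width, eye videos, visual rendering of the
corridor textures, multi-animal variability, and non-Poisson spike-history
structure (bursts, refractoriness). A green test therefore establishes that
the estimators recover the stated generative parameters under
Poisson-like variability — not that they are robust to every failure mode
of real extracellular data.

## Behavioral preprocessing

Trials are segmented at crossings of position 0 on the unwrapped trajectory;
because crossings are detected on the unwrapped coordinate, backward jitter
across the boundary cannot double-count a lap. Licks chain into bouts when
consecutive licks of the same trial are closer than 20 cm (circular
distance); a bout is correct when it overlaps the reward zone and triggered
reward. Trials are `correct` when rewarded with at most 5 incorrect licks
(the published rules leave exactly 5 unspecified; rewarded 5-lick trials are
classified correct and the case is logged), `early` when more than 5
incorrect licks follow a correct trial, and `late` otherwise. Putative
interneurons have trough-to-peak waveform widths strictly below 600 µs;
V1 layers are assigned from recording depth in half-open bins
[250, 500) µm (L2–4), [500, 700) µm (L5), [700, 950) µm (L6). All rate and
decoding analyses use only samples with speed strictly above 5 cm/s;
lick-position analyses ignore the mask.

## Spatial profiles and permutation tests

Response profiles are ratios of circularly smoothed (8-cm s.d. Gaussian)
spike-count and occupancy maps over 2-cm bins; smoothing count and
occupancy separately before dividing keeps empty-bin artifacts local, and
bins with zero smoothed occupancy are flagged rather than NaN-propagated.

Spatial significance uses circular time shifts of the whole spike train by
random periods greater than 5 s. The statistic is the profile's maximal
amplitude, implemented as `max − mean` of the profile — invariant to DC
rate, which is what the shuffle is meant to test. Gain-shift significance
permutes the per-trial gain labels (permuting whole trials, not per-spike
labels, so within-trial structure is respected). The corridor-identity test
compares firing at matching positions 200 cm apart: the statistic is the
rate difference between corridors at the pooled-profile peak, with a
per-trial corridor-label shuffle.

Two conventions matter for calibration and were set deliberately:

* **Threshold order statistic.** "Observed above the $(1-\alpha)$
  percentile of $n$ shuffles" is implemented as the null order statistic of
  rank $\lceil (1-\alpha)(n+1) \rceil$, which makes the level exactly
  $\alpha$ for continuous exchangeable statistics; the naive
  $\lceil (1-\alpha)n \rceil$ rank inflates the level to
  $(\alpha n + 1)/(n+1)$, which is visible at 200 shuffles.
* **Continuous shift statistic.** The reported gain shift is the
  correlation argmax over the 2-cm offset grid (ties broken toward smaller,
  then negative shifts). Inside the permutation test, however, the argmax
  (observed and null alike) is refined to sub-bin resolution by a parabolic
  fit through the correlation peak; a gridded statistic has heavy ties that
  make the test conservative (empirical level near 1–2% at nominal 5%).

The variance decomposition fits the scaled reference profile
$R_g \approx \alpha R_m$ by least squares and reports
$1 - \sum_x (R_g - \alpha R_m)^2 / \sum_x (R_g - \langle R_g\rangle)^2$,
both for the static reference and after applying the estimated shift. The
printed ratio itself is also exposed, since the residual/total ratio and
"percentage of variance explained" differ by exactly this complement.

Note that permutation calibration is session-length dependent: on very
short sessions (a few minutes) circular shifts near multiples of the lap
duration partially realign spikes with position, correlating null draws and
inflating the level of the profile test by a factor ~2. The calibration
suite therefore runs on a ~15-minute session, the order of a real recording.

## Theta analyses

Theta phase is extracted by band-passing the LFP to 6–9 Hz (FFT mask —
adequate for the synthetic narrowband signal), detecting local maxima with
a minimum prominence of 0.5 SD (the source methods specify none), discarding
peaks arriving within 60 ms of the previously retained one, and
interpolating phase linearly between retained peaks (peaks = 0°/360°). When
CA1 spikes are supplied, one global offset per session centers the CA1
population rate peak at 180°. Spikes are resampled to the *nearest* 60-Hz
sample; flooring to the containing sample would lag every spike phase by
~24° at 8 Hz, a bias the recovery tests caught.

The theta modulation index is $(F_{max}-F_{min})/F_{mean}$ over 20° bins
smoothed with a 40° s.d. circular Gaussian. For a sinusoidal modulation of
depth $m$ the *unsmoothed* index converges to $2m$; the 40° smoothing
attenuates it by $\exp(-\sigma^2/2) \approx 0.78$ ($\sigma$ in radians), so
analytic-limit tests run the estimator unsmoothed and a separate property
pins the smoothed index to the attenuated value. Pairwise phase consistency
is computed in O(N) through the resultant identity and is tested to equal
the exhaustive pairwise mean cosine to 1e-10; for sinusoidal modulation it
converges to $(m/2)^2$.

Phase-by-position profiles (20° × 2-cm bins, 40° × 8-cm smoothing) yield a
drift curve: for each phase bin, the spatial offset maximizing the
cross-correlation between that phase's profile and the phase-averaged
profile. The argmax is refined to sub-bin resolution by a parabolic fit —
with 2-cm bins the raw grid quantization dominates small (V1-like, 2–3 cm)
amplitudes. The drift curve is summarized by a closed-form least-squares
sinusoid $A\sin(\theta - \varphi) + c$ (two quadrature regressors plus
intercept; no nonlinear optimization); the reported offset $\varphi$ is the
ascending zero-crossing, so a noiseless curve $4\sin(\theta-180°)$ returns
amplitude 4 and offset 180°. Under this convention positive drift means the
profile is shifted ahead of the phase-averaged profile. Precession
significance permutes spike phases and recomputes the drift amplitude
*without phase smoothing* (position smoothing kept), so smoothing across
phases cannot manufacture a drift.

Layer comparisons (fractions and preferred-phase medians) use permutation
nulls that shuffle recording depths within animals; the equal-circular-
medians statistic is the count-based construction (observations per group on
each side of the pooled circular median), whose exact normalization is
non-critical because p-values come from the same within-animal permutation.
The linear-circular correlation is provided for comparison with the drift
method; in-field spikes are selected by the contiguous region above 50% of
the profile peak (the field-extent definition is a documented choice — the
source methods do not state one).

## Bayesian decoding

The decoder assumes independent Poisson spike counts:

$$P(x \mid R) = \frac{1}{Z} P(x) \Bigl(\prod_{i=1}^{M} f_i(x)^{r_i}\Bigr)
  \exp\Bigl(-t \sum_{i=1}^{M} f_i(x)\Bigr),$$

computed in the log domain with rates floored at 0.01 Hz (configurable) to
avoid log(0), and normalized per window. The prior is the training
occupancy by default (a uniform option exists); the source does not state
which prior was used. Decoding uses 250-ms windows (50 ms for phase-resolved
analyses); a window is usable when more than half its samples pass the speed
mask. Encoding models are trained on reference-gain (gain 1) correct
trials; reference windows are decoded with 20-fold held-out models over
*contiguous* trial blocks (random folds would leak temporally adjacent
samples), and manipulated-gain windows with the full reference model —
whether the original analysis cross-validated those too is not explicit, and
the full-model choice matches training profiles being defined on
medium-gain trials. Argmax ties break toward the lowest-index bin.

Per-position error summaries give the error distribution (2-cm bins on the
circular error axis, 2-cm smoothing), its weighted circular mean (mean
decoding error) and its mode (decoding bias); manipulated gains are
reported after subtracting the reference value per position, and standard
errors come from leave-one-fold-out jackknife. Direction: with
distance-anchored fields ($w>0$) the fields shift to *earlier* visual
positions at low gain, so a reference-trained decoder reads out positions
*ahead* of the animal — corrected bias is positive at gain 0.8 and negative
at 1.2, shrinking near landmarks where anchoring distances reset. (Deriving
the bias sign from the field-shift formula gives the opposite sign; the
physical argument and the original results fix the convention used here.)

## V1–CA1 error coupling

Joint error maps are histograms of simultaneous signed errors in 4-cm bins,
smoothed with a 4 × 4-cm Gaussian and normalized to sum to 1. The null
permutes error pairings only among windows sharing a conditioning cell
(2-cm position bin × session-wise speed quintile), preserving both marginals
per cell; singleton cells stay fixed and are counted. The number of shuffle
repetitions averaged into the shuffled map is not stated in the source and
defaults to 100. Coupling is summarized by the integrated difference map
within 10 cm of the diagonal. The split-thirds control trains the V1 model
on the first third of usable trials, the CA1 model on the second, and
evaluates coupling on the last. Cycle-by-cycle coupling fits a sinusoid to
each region's errors within every theta cycle (≥ 3 windows), correlates the
absolute amplitudes across cycles, and compares against the same
within-(position, speed) shuffle applied at the cycle level.

## Behavioral ridge regression

Spike counts in 250-ms windows, mean-centered on reference-gain windows,
are fitted in two steps that keep the behavioral component orthogonal to
the positional one: first ridge on 100 position indicators (2-cm bins),
then ridge of the cross-validated positional residual on the behavioral
design — speed, acceleration, pupil size/azimuth/elevation and lick counts
in 10 quantile bins each (edges from reference windows, global rather than
per-gain — a logged choice) plus a binary reward regressor, each replicated
at 9 lags from −1 to +1 s, i.e. 549 columns. Acceleration is the first
difference of boxcar-smoothed speed (not defined in the source). Ridge is
solved in closed form $(X^\top X + \lambda I)^{-1} X^\top y$; the penalty
default is modest ($\lambda = 1$) and exposed — the source never states
one. Degenerate covariates collapse to fewer quantile bins with a warning
while the design keeps its full column layout.

Predicted response profiles are built from the model prediction binned
against the *true* (undelayed) position, exactly as spike profiles are
built, and predicted gain shifts use the same correlation argmax. The delay
scan refits the model with the position design read at $t - d$ for
$d = 0, 0.1, \dots, 1$ s and scores each delay by the correlation between
model-predicted and *measured* profiles at the manipulated gains. The
published phrasing ("correlation between response profiles predicted at low
or high gain and at medium gain") cannot identify the latency as literally
read — a delayed-position model predicts identical profiles across gains at
$d = 0$ by construction, so that correlation is always maximized at zero.
Only the manipulated gains are informative: at the true latency the
predicted shift $(g-1)\bar v d$ matches the measured one. This reading
recovers an injected 300-ms latency exactly on the 100-ms grid.

## Degenerate inputs and numerical conventions

Constant profiles make correlations undefined: shift estimation returns a
flagged degenerate result. Zero-spike neurons yield all-zero profiles, a
zero rate-difference statistic (never significant), and warnings rather
than errors in the theta tests. All permutation consumers take explicit
seeds; the pipeline derives per-stage, per-neuron seeds deterministically
from one master seed, so identical configurations produce byte-identical
outputs. Session containers are plain TSV tables plus a JSON header;
numeric columns are written with 17 significant digits so round trips are
exact.

## Known limitations

Permutation levels are exact only for session lengths where circular time
shifts decorrelate from the lap structure (see above). The FFT band-pass is
not appropriate for broadband real LFP (no analytic-signal phase, no edge
handling beyond circularity); real data should arrive with precomputed
phase or a dedicated filter. The decoder models counts as Poisson and
independent across neurons; the look-up-table variant mentioned in the
source is out of scope. The GLM is linear-Gaussian on counts, not a
point-process likelihood.
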