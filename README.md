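# vrplace

Analysis of spatial coding in virtual-corridor navigation: gain-manipulation
shifts, theta-phase statistics, Bayesian population decoding, V1–CA1 error
coupling, and a behavioral ridge regression — together with a synthetic
session generator that provides ground truth for every stage.

## The problem

Head-fixed mice run on a wheel through a circular 200-cm virtual corridor
with landmarks and a reward zone, while CA1 and V1 populations are recorded.
On blocks of trials the *gain* coupling wheel movement to virtual
displacement is changed (0.8 / 1 / 1.2), dissociating the physical distance
run from the visual position: at gain 0.8 the animal runs 250 cm per lap, at
1.2 only ~166 cm. Three questions drive the analyses this package
implements for users working with such recordings (or wanting a tested
reference implementation):

1. **Distance coding.** Does a neuron's spatial response profile shift with
   the distance run? The profile at gain $g$ is compared with the
   medium-gain profile by the circular offset maximizing their Pearson
   correlation; for a field anchored a distance $D$ past a landmark with
   anchoring weight $w \in [0, 1]$, the shift is $w(g-1)D$. Significance
   comes from permuting per-trial gain labels.
2. **Theta coupling.** Firing-rate modulation across the 6–9 Hz theta cycle
   is measured by the index $(F_{max}-F_{min})/F_{mean}$ and by pairwise
   phase consistency $\frac{2}{N(N-1)}\sum_{i<j}\cos(\theta_i-\theta_j)$;
   spatial drift across the cycle (phase precession) is the per-phase
   argmax of the spatial cross-correlogram against the phase-averaged
   profile, summarized by a fitted sinusoid $A\sin(\theta-\varphi)$.
3. **Population codes.** Position is decoded with an independent-Poisson
   Bayesian decoder,
   $P(x|R) \propto P(x)\prod_i f_i(x)^{r_i} e^{-t\sum_i f_i(x)}$,
   cross-validated on medium-gain trials; decoding error and bias per
   position quantify the population-level pull of distance coding, and
   joint V1×CA1 error maps against position/speed-conditioned shuffles test
   whether the two regions' errors co-fluctuate.

All permutation tests (spatial, gain shift, rate change, corridor identity,
theta modulation, precession, phase-resolved decoding, layer contrasts) use
explicit seeds and circular-shift or label-permutation nulls as
appropriate.

## Worked example

```r
library(vrplace)

cfg <- generator_config(n_trials = 45, n_ca1 = 30, n_v1 = 0, seed = 42)
session <- simulate_session(cfg, trial_gains = rep(c(0.8, 1, 1.2), 15))
session
#> vr_session: 23304 samples (388.4 s), 45 trials, 30 neurons, 18809 spikes

trials <- segment_trials(session$timeline)
mask <- speed_mask(session$timeline$speed_cm_s)

# strongest distance-anchored cell and its expected low-gain shift w*(g-1)*D
nid <- with(session$neurons, neuron_id[which.max(distance_weight * anchor_D_cm)])
truth <- session$neurons[session$neurons$neuron_id == nid, ]
truth$distance_weight * (0.8 - 1) * truth$anchor_D_cm
#> -11.7

st <- attr(trials, "sample_trial")
sub <- function(g) which(st %in% trials$trial_id[trials$gain == g])
sp <- spike_times(session$spikes, nid)
estimate_gain_shift(
  spatial_profile(sp, session$timeline, mask, sample_subset = sub(0.8)),
  spatial_profile(sp, session$timeline, mask, sample_subset = sub(1)))[c("shift_cm", "correlation")]
#> $shift_cm    [1] -10
#> $correlation [1] 0.99

res <- decode_session(session$spikes, session$timeline, trials,
                      session$neurons$neuron_id, mask = mask)
median(abs(res$error_cm))
#> 4.7
mean(error_summaries(res)[["0.8"]]$bias_cm, na.rm = TRUE)
#> 2.9
```

Reading the numbers: the cell's field is anchored 62 cm past its landmark
with weight 0.95, so at gain 0.8 it should fire ~12 cm earlier on the
virtual track; the estimator reports −10 cm on the 2-cm offset grid. The
30-cell population decodes position with a median error under 5 cm, and at
low gain the decoder — trained at medium gain — reads out positions ahead
of the animal (positive corrected bias), the population signature of
distance-anchored fields.

The full pipeline (simulate → preprocess → profiles → theta → decode →
couple → glm → report) runs from one seeded configuration:

```r
run_pipeline(pipeline_config("out", seed = 1,
                             generator = list(n_trials = 30, n_ca1 = 20, n_v1 = 20)))
```

writing per-stage TSV tables and a JSON report; a thin command-line wrapper
is in `inst/scripts/run_pipeline.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
it simulates a default session and executes every pipeline stage
(profiles and permutation tests, theta statistics, CA1 and V1 decoding,
error coupling, ridge regression) under the given seed — and writes the
target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The quantitative acceptance checks (permutation-test calibration, ground
truth parameter recovery, analytic limits, decoder consistency and error
coupling recovery) live in `tests/testthat/test-acceptance.R` and run with
the test suite.
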