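# pfif

Acoustic 3D tracking of bats at lit forest edges, and distance–response
models of their flight paths.

## The problem

Streetlights change where bats fly. At a forest edge, light-tolerant bats
drift toward the lit open space while light-averse species retreat into the
vegetation, so the *probability of flying inside the forest* (**PFIF**)
changes with how close a bat is to the light and with the light's spectrum
(unlit control, red, white). Two derived quantities summarize the
behavioural response:

- **FPSD** (flight-path switch distance): the distance to the light at
  which bats on average fly as much inside the forest as outside —
  predicted PFIF = 0.5;
- **onset distance**: the distance at which the predicted PFIF first rises
  above a small threshold (default 0.05) coming in from the far field —
  where the perturbation begins.

`pfif` implements the full measurement-to-inference chain for this kind of
study, plus a synthetic-campaign generator so that every stage can be
validated against known ground truth:

1. **simulate** — bat flight trajectories (3D correlated random walks)
   whose inside-forest occupancy follows a known logistic model, and
   echolocation-call arrival times at a 4-microphone array with Gaussian
   timing noise;
2. **localize** — time-difference-of-arrival (TDOA) multilateration
   (grid-search start, damped Gauss–Newton, GLS weighting with the exact
   TDOA noise correlation), with per-axis standard deviations `dx, dy, dz`
   propagated from the timing noise and the cumulated imprecision
   `I = sqrt(dx² + dy² + dz²)`;
3. **track** — greedy nearest-neighbour linking of positions into
   individual flight passes (speed and time-gap gates);
4. **label** — quality filter (discard `I` > 1 m and positions not in any
   trajectory), distance to the light `D = sqrt((x−4)² + (y−4)² + (z−4)²)`
   for a 4-m lamppost on the edge, PFIF label from the forest-edge plane,
   and spatial zones (under/above, front/back of the light);
5. **assign** — species groups (*Eptesicus/Nyctalus*, *Myotis/Plecotus*,
   *Pipistrellus*) from call peak frequency within 5-second files;
6. **fit** — a precision-weighted binomial mixed model, per species group:

   ```
   PFIF ~ D * spectrum + (1 | trajectory) + (1 | night),   weights = 1/I²
   ```

   a Bernoulli-logit GLMM (Laplace approximation via glmmTMB) in which each
   observation's log-likelihood is multiplied by its precision weight,
   with Wald tests, AIC against the null model, and latent-scale
   marginal/conditional R²;
7. **fpsd** — per-spectrum switch and onset distances in closed form from
   the fitted fixed effects, with delta-method prediction curves.

## Worked example

A full default campaign — 12 nights alternating dark/red/white, about
10,000 localized calls — in one call:

```r
library(pfif)
res <- run_pipeline(pipeline_config(), seed = 1, out_dir = "runs/demo")
res$fits[["Pipistrellus/all"]]
```

```
Precision-weighted binomial mixed model of PFIF
  subset: all, Pipistrellus | n = 8602 | reference spectrum: dark
                estimate      se       z        p
(Intercept)      -2.3697  0.3577   -6.63 3.46e-11 ***
D                -0.0439  0.0395   -1.11    0.267
spectrumred       5.7595  0.5287   10.89  < 2e-16 ***
spectrumwhite    7.9477  0.5285   15.04  < 2e-16 ***
D:spectrumred    -0.7617  0.0662  -11.50  < 2e-16 ***
D:spectrumwhite  -0.9031  0.0632  -14.28  < 2e-16 ***
  random-intercept SDs: trajectory 1.393, date 0.076 (logit)
  logLik -2649.80 | AIC 5315.6 (null 6193.1) | R2 marginal 0.439, conditional 0.647
```

On dark nights PFIF is low (intercept −2.37 logit ≈ 9%) and essentially
flat in distance; red and white light raise PFIF near the light (large
positive spectrum contrasts) and make it fall off steeply with distance
(negative interactions): bats dive into the forest close to a lit lamppost
and come back out beyond a few metres.

```r
res$fpsd[["Pipistrellus/all"]]
```

```
Flight-Path Switch Distances (predicted PFIF = 0.5) and onset distances (PFIF = 0.05):
  dark   fpsd = not estimable, onset = 13.10 m (insufficient PFIF (negative root))
  red    fpsd = 4.21 m, onset = 7.86 m
  white  fpsd = 5.89 m, onset = 9.00 m
```

The generating campaign placed the true switch distances at 6 m (white)
and 4 m (red); the pipeline recovers 5.89 m and 4.21 m after localization
noise, trajectory linking, quality filtering and species assignment. On
dark nights the predicted PFIF never reaches 0.5, so no switch distance
exists — the expected behaviour for an unlit edge.

Every stage writes a schema-versioned CSV plus a manifest and log into the
run directory; `relevel_contrasts()` re-expresses a fitted model against
another reference spectrum (e.g. white) exactly, and
`simulated_residual_check()` gives a randomized-quantile goodness-of-fit
diagnostic. A command-line wrapper lives at
`inst/scripts/pfif-pipeline.R`.

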