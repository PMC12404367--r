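# narhmm

Behavioural-state analysis of duty-cycled marine-mammal satellite telemetry.

Deep-diving Arctic whales overwintering in offshore pack ice are observable
only through satellite tags whose winter data are sparse by design:
error-prone Argos fixes arrive every 3–4 days under a battery-saving duty
cycle (with occasional >7-day dropouts), and diving is reported as 6-hour
time-at-depth (TAD) and dive-maximum-depth (DMD) histograms whose depth-bin
tables differ between deployment years. `narhmm` is for movement ecologists
who want behavioural-state inference from this kind of material rather than
from the high-resolution tracks most movement models assume.

## What it does

1. **Track preparation** — duplicate/speed-filter cleaning, automated winter
   delineation (change-point on z-scored southward coordinate and surface
   time, manual override supported), segmentation at >7-day gaps, and a
   continuous-time correlated random walk (integrated Ornstein–Uhlenbeck)
   Kalman filter/smoother with per-fix error-ellipse observation
   covariance, predicting positions on a 2-h grid phased to the tags' 03:00
   GMT dive windows.
2. **Data streams** — per 6-h step: mean speed `Ms`, tortuosity
   `Tr = L/D − 1`, surface time `Sf` (< 6 m), mean depth `Md`, relative
   dive depth `Rd = Md/bath`, and zero-inflated deep time `Dp` (> 400 m),
   plus covariates (20-km buffer bathymetry and slope, shore distance,
   local-hour cosinor, winter day).
3. **3-state HMM** — gamma emissions for `Ms`, `Tr`, `Sf`, `Dp` (with a
   zero-mass component on `Dp`) and Weibull for `Md`, `Rd`; covariate
   effects on both natural parameters through log links (bathymetry on dive
   streams in the diving states, winter day on surface time, tag-programming
   intercepts); multinomial-logit transition probabilities; maximum
   likelihood via a C++ forward recursion with analytic emission gradients;
   Viterbi decoding; stationary state probabilities
   `δΓ(c) = δ` along covariate grids.
4. **Spatial summaries** — gridded state counts, the disproportionate-state
   statistic `S′_i = argmax_S (N_i(S)/N_i)/(N(S)/N)`, dive-to-bottom
   proportion maps, and the overall state time budget.
5. **Synthetic data** — a generator with ground truth emulating the full
   observation process (duty cycle, dropouts, elliptical Argos error,
   dialect-specific depth binning), used for end-to-end recovery testing.

## Worked example

```r
library(narhmm)

rec <- simulateRecovery(n_steps = 9000, seed = 7, n_starts = 10)
print(rec$fit)
```

```
3-state HMM fit: 9000 steps; 45 parameters; logLik = 19293.66 ; AIC = -38497.32
State means at reference covariates:
              state1   state2  state3
Ms          1901.510 1447.622 187.398
Tr             0.216    0.509   1.009
Sf            32.069   26.718  23.887
Md            97.884  219.512 332.766
Rd             0.071    0.160   0.239
Dp             6.700   17.058  34.956
zeromass_Dp    0.303    0.088   0.009
Decoded time budget (%): 1: 22.4, 2: 38.4, 3: 39.2
```

The generator drew 9,000 six-hour steps from a 3-state chain whose
stationary distribution is 22/37/40% with per-state stream distributions set
to the published winter estimates (state 1 = surface travel: fast, straight,
shallow; state 2 = pelagic diving; state 3 = deep diving: slow, tortuous,
deep). Refitting from scratch recovers every emission mean within a few
percent (e.g. mean depths 98/220/333 m against generating 98/220/331) and
the zero-mass probabilities (fraction of windows with no time below 400 m)
at 0.30/0.09/0.01; the Viterbi-decoded time budget lands within ~1.5
percentage points of the generating 22/37/40 split.

For the full pipeline on degraded observations (Argos error, duty cycling,
dive-histogram reconstruction):

```r
res <- runPipeline(simConfig(n_animals = 3, n_steps_per_animal = 250,
                             seed = 5), out_dir = "out")
res$budget                       # decoded state time budget
res$sprime$sprime                # disproportionate-state grid (50 km cells)
```

which writes `decoded_steps.csv`, `hmm_params.json` and `sprime.asc` (ESRI
ASCII grid) under `out/`.

## Layout

* `R/` — synthetic generator (`synthgen.R`, `recovery.R`), track prep
  (`trackprep.R`, `ctcrw.R`), streams (`streams.R`, `divebins.R`), HMM
  (`hmm-spec.R`, `hmm-fit.R`, `transitions.R`), spatial summaries
  (`spatial.R`), I/O (`io.R`), pipeline driver (`pipeline.R`).
* `src/` — scaled forward/backward and Viterbi recursions (Rcpp).
* `vignettes/winter-behaviour.Rmd` — the methods account: model
  assumptions, parameter choices, generator design, numerical details,
  limitations.
* `tests/testthat/` — unit, property and oracle tests (exhaustive path
  enumeration, dense-Gaussian smoothing oracle, hand-binning oracles).
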