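---
title: "Behavioural states from duty-cycled whale telemetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural states from duty-cycled whale telemetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narhmm)
```

## The problem

Deep-diving Arctic cetaceans such as narwhal overwinter in remote offshore
pack ice where the only practical observation platform is a satellite tag.
Winter tag data are doubly degraded: Argos locations carry kilometre-scale
elliptical error and arrive only on duty-cycled transmission days (every 3-4
days), with occasional dropouts longer than a week; diving is reported not as
a depth trace but as 6-hour histograms — time-at-depth (TAD, percent of the
window per depth bin) and dive-maximum-depth (DMD, dives per bin) — under
tag-programming dialects that changed between deployment years. `narhmm`
implements a pipeline that turns this material into behavioural-state
inference: which 6-hour windows were dominated by surface travel, pelagic
diving, or deep (near-benthic) diving, and how those behaviours organize
along environmental gradients and in space.

## Track regularization (CTCRW)

Raw fixes are first cleaned: duplicate timestamps collapse to the fix with
the tighter error ellipse, a 10 m/s course speed filter removes error spikes
(a fix is removed only when the speeds implied to *both* temporal neighbours
exceed the threshold, so genuine fast transit survives; the filter is applied
to convergence, which makes cleaning idempotent), and fixes on land
(bathymetry 0) are dropped. All planar computation happens in kilometres on
an azimuthal equidistant projection centred on the study area; longitudes and
latitudes exist only at I/O boundaries, which keeps distance computations
honest at high latitude.

Winter residency is delineated by automating the usual visual rule: the
z-scored southward coordinate and z-scored surface time are smoothed with a
rolling mean (window 5 observations) and a single least-squares change-point
is fit to the stacked series. Confidence is judged on the *unsmoothed*
series — smoothing manufactures apparent change-points in pure noise — and if
the relative RSS reduction is below 0.2 the whole range is returned with a
low-confidence flag. A manual override always wins, since the underlying
field practice is expert judgement.

Tracks are segmented wherever more than 7 days pass without a location or
dive record; interpolating across such holes would fabricate straight-line
movement. Within segments, positions are modelled as a continuous-time
correlated random walk: velocity is a 2-D Ornstein–Uhlenbeck process
(autocorrelation `beta`, 1/hr; diffusion `sigma`) and position its integral.
The exact Gaussian state-space form is evaluated by a Kalman filter whose
per-fix observation covariance comes from the error ellipse (SD along an
axis = semi-axis / sqrt(2), rotated by the ellipse orientation); fixes
without ellipse information receive a configurable isotropic SD (default
1.7 km, consistent with 95% of errors within ~4.2 km). Parameters are
maximum likelihood, shared across an animal's segments as independent
likelihood blocks — segments are too short to support per-segment dynamics,
and an animal's movement style is plausibly stable within a winter. The
smoother then predicts positions on a 2-hour grid phased to 03:00 GMT so
every 6-hour dive window boundary is a grid point.

Numerical choices: the initial state uses the first fix with a diffuse
position variance (1e4 km^2) and the stationary velocity variance
`sigma^2 / (2 beta)`; for `beta * dt < 1e-7` the exact transition and
process-noise matrices switch to their integrated-random-walk series limits;
covariances are symmetrized after every update; the smoother uses a
pseudo-inverse for the one-step prediction covariance so exactly-observed
(zero-noise) toys do not break the recursion.

## Data streams and covariates

Six streams summarize each 6-hour window:

* `Ms` mean speed (m/hr): path length over the 2-h positions in the window.
* `Tr` tortuosity: three-step path length over straight-line displacement,
  minus 1, so straight travel scores 0. The last three steps of a segment
  are missing by construction; a closed loop (zero displacement) is missing
  with a log message.
* `Sf` surface time (%): TAD mass shallower than 6 m (the tags' "not
  diving" boundary).
* `Md` mean depth (m): TAD-weighted mean of sub-surface bin midpoints. The
  estimator excludes the surface bin; bins straddling a boundary are
  apportioned linearly by depth-range overlap (unbiased if time is uniform
  within a bin); the open-ended deepest bin uses floor + half the adjacent
  bin's width as its midpoint.
* `Rd` relative dive depth: `Md / bath`, capped at 1 — a proportion of the
  available water column, which is the scale on which benthic affinity is
  interpretable and which suits a Weibull emission on (0, 1].
* `Dp` time at depth (%): TAD mass deeper than 400 m, zero-inflated because
  many windows contain no deep time at all.

The exact depth-bin tables of the original tag programmings are not
reproduced here; the two dialects in `diveBinEdges()` are synthetic
stand-ins with the documented properties (2009 coarser and shallower, 2010+
to 1800 m, edges at the 6 m and 400 m analysis boundaries). `Md` is
reconstructed from TAD rather than taken from a tag-reported mean; that is a
dialect of this pipeline, and the DMD histogram is kept in I/O for the
maximum-depth maps.

Covariates per step: `bath`, the *maximum* bathymetry within a 20-km buffer
(an animal can travel far within 6 h, and what matters behaviourally is the
deepest water available); `slope`, the mean seafloor slope in the same
buffer; `shore`, distance to the nearest 0-m cell; `hour`, local clock time
(UTC-4) entering the model only through the cosinor pair
cos(2*pi*h/24), sin(2*pi*h/24); and `wday`, days since September 1 of the
season's start year. Covariates may not be missing; streams may.

## The 3-state hidden Markov model

Emissions are gamma (mean `mu`, SD `sigma`) for `Ms`, `Tr`, `Sf` and for the
positive part of `Dp`, and Weibull (shape `kappa`, scale `lambda`) for `Md`
and `Rd`. `Dp` carries a state-specific zero-mass probability `z`: a zero
contributes `log z`, a positive value `log(1 - z)` plus the gamma density.
Missing streams contribute zero log-density, i.e. are marginalized rather
than dropped — essential for duty-cycled data where windows routinely lack
one side of the data.

Covariates act on both natural parameters of a stream through a shared
formula: bathymetry on the dive streams (`Md`, `Rd`, `Sf`, `Dp`) for the two
diving states only (available depth constrains what a dive can look like,
but surface travel is indifferent to it); winter day on surface time in all
states (migration-to-residency transition expresses as declining surface
time); and a tag-programming intercept on `Md`, `Rd` and `Dp` (the dialect
changes the apparent depth distribution, with 2010+ as reference level).
The linear predictors live on a log scale — the natural parameters must stay
positive, and a log link is the standard choice — with z-scored covariates
inside the design matrices so that intercepts are interpretable at the data
centre and optimizer scaling is sane; `z` uses a logit link. Transition
probabilities are multinomial logit with the staying-put diagonal as
reference, over intercept, `wday`, `bath`, `slope`, `shore` and the cosinor
pair jointly. Each segment is an independent likelihood block whose initial
distribution is the stationary distribution of the transition matrix at its
first step's covariates — this spends no extra parameters and is exact if
the chain is locally in equilibrium.

Fitting is direct maximization of the forward log-likelihood (scaled
recursion in C++) over all coefficients on the working scale with BFGS. The
gradient is analytic for the emission block via the Fisher identity
(posterior-weighted complete-data scores from a forward-backward pass, with
closed-form gamma/Weibull parameter derivatives) and finite-difference for
the much smaller transition block, where the emission densities can be held
fixed so each probe costs only a forward pass. Initialization seeds states
by `Md` tertiles and converts per-state moments to working intercepts; the
default 10 restarts perturb the working vector (SD 0.25). Identifiability
across restarts is restored post hoc by relabeling states so the
reference-covariate `Md` mean increases with state index: 1 = surface,
2 = pelagic, 3 = deep.

Decoding uses the Viterbi max-product recursion per segment with ties broken
toward the lower state index. Stationary state probabilities solve
`delta Gamma(c) = delta`, `sum(delta) = 1` by the standard linear system,
falling back to the unit-eigenvalue left eigenvector with a warning if the
matrix is reducible.

Spatial summaries count decoded steps on a configurable grid (default 50 km
cells, the scale at which state maps are legible with this data density; the
finer rasterization sometimes quoted for such analyses is available through
`cell_km`). The disproportionate-state statistic
`S'_i = argmax_S (N_i(S)/N_i) / (N(S)/N)` flags where a behaviour
concentrates relative to its global frequency; cells with fewer than 4 steps
are masked and fewer than 16 flagged low-certainty. Dive-to-bottom maps take
the deepest non-empty DMD bin midpoint over the buffer bathymetry, capped at
1.

## The synthetic-data generator

No telemetry accompanies the analysis this package implements, so the
generator is a first-class module that emulates the data structure the
pipeline assumes, with ground truth retained for recovery testing. Its
defaults are the study conditions: 22 animals, ~400 six-hour steps each; a
homogeneous 3-state kernel whose stationary distribution equals the
published 22/37/40% behavioural time budget, with self-transition weight
`rho = 0.6` (the kernel `rho I + (1 - rho) 1 delta'` leaves `delta`
stationary for any `rho`; 0.6 reflects the persistence expected of 6-hour
behavioural bouts); per-state stream distributions set to the published
state estimates at the reference covariates (2010+ programming, 1379 m
bathymetry, winter day 100); 3-day duty cycling (4 for the 2009 dialect);
Bernoulli dropout (p = 0.08 per transmission day) with geometric gap
lengths of mean 10 days, which produces a realistic share of >7-day holes;
and elliptical Argos error with a 2:1 axis ratio, uniform orientation, and a
scale placing ~95% of errors within 4.2 km. Relative-depth parameters,
which the source estimates do not tabulate, are set to the mean-depth values
divided by the reference bathymetry with proportional spread.

Because no generative movement model is published, the fine-scale track is
simulator plumbing: a state-dependent correlated random walk whose 2-h step
lengths equal the drawn `Ms` and whose heading diffusion grows with the
drawn `Tr`, bouncing off land and the domain boundary. Likewise the within-
window depth series (5-min samples organized into surface/dive bouts
consistent with the drawn `Sf`, `Md`, `Dp`) exists so that the tag-style
TAD/DMD binning code has something real to bin. The generator reproduces
duty-cycled irregularity, elliptical error, dialect-specific binning and
zero-inflation; it does not reproduce real bathymetry, sea-ice forcing,
inter-animal heterogeneity, or emission-parameter covariate dependence
(streams are drawn at the reference covariates unless covariate-dependent
parameters are planted explicitly). Passing recovery tests therefore show
the estimator is consistent for the model it claims to fit — not that real
narwhal data satisfy that model.

## Problem sizes and tolerances in the test-suite

Recovery tests refit 9,000-12,000 simulated steps with 10 optimizer
restarts — enough for Monte-Carlo error on emission means to sit well inside
a +/-5% band (+/-10% for the small-mean tortuosity stream) and for decoded
occupancy to sit inside +/-2 percentage points of the generating stationary
distribution. Exhaustive-enumeration oracles (all 3^T paths) check the
forward likelihood and Viterbi decoder on instances up to 8 steps;
filter/smoother output is checked against dense joint-Gaussian conditioning
on small segments; conversions round-trip to 1e-9 or better. The end-to-end
pipeline smoke test uses 3 animals x 250 steps, where duty-cycling leaves a
few hundred usable windows.

## Known limitations

* The winter delineation is a single change-point on two series; slow,
  drifting arrivals (no crisp residency onset) are flagged low-confidence
  rather than resolved.
* CTCRW parameters are shared within an animal; behaviour-dependent
  movement variance (state-switching diffusion) is not modelled at the
  track level.
* Confidence intervals on emission curves and stationary-probability curves
  (delta-method ribbons) are not implemented; point curves only.
* `Md` from binned TAD is biased toward bin midpoints; the 2009 dialect's
  coarse deep bins make its `Md` systematically coarser, which is exactly
  why the programming intercept exists.
* The S' statistic is a ratio of small counts in sparse cells; the masking
  thresholds are blunt instruments, not inference.
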