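---
title: "Information dynamics of paired homing flights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of paired homing flights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Homing pigeons released repeatedly from the same site converge on stable,
individually distinct routes. When a bird that knows such a route flies
together with a naive partner, route knowledge passes between them — but
who is leading whom, moment to moment? And when the pair departs from the
established route to search for a better one, which bird initiates the
departure? `infoflow` implements a symbolic information-theoretic analysis
of these questions for pairs of GPS-tracked birds, together with a
ground-truth simulator that makes every stage of the analysis testable.

## From tracks to symbols

Tracks are 5 Hz planar positions. Geographic fixes are projected to metres
with an azimuthal-equidistant projection about the home loft, computed from
WGS84 geodesic distances and azimuths (`project_to_plane()`); at homing
scale (< 50 km) any locally distance-preserving projection would do, and
this one makes distances from the loft exact.

Each trajectory is reduced to a binary series of turning directions: the
sign of the planar cross product between consecutive motion vectors, 1 for
counterclockwise, 0 for clockwise (`rotation_series()`). Two choices are
deliberately explicit because the source procedure leaves them open:

* **Zero cross products** (exactly collinear motion) carry the previous
  symbol forward rather than introducing a third symbol; runs of ties are
  flagged in `tie_mask` so their prevalence can be audited. On real
  GPS-noise-dominated tracks exact zeros are rare; on idealised test
  geometries they are the norm, which the flag makes visible.
* **Subsampling precedes encoding.** The series at sampling period $T$ is
  built from every $(T/0.2)$-th position, so larger periods measure coarser
  turning, not smoothed copies of the 5 Hz symbols.

## The estimator

For source series $S$ and target $T$ with history length $k$, the package
computes the plug-in transfer entropy

$$\mathrm{TE}_{S \to T} = H(T_{i+1} \mid T_i^{(k)}) - H(T_{i+1} \mid T_i^{(k)}, S_i),$$

with all probabilities estimated as empirical frequencies of one flight
(`transfer_entropy()`). The per-transition log-ratio whose mean is TE — the
local transfer entropy — is exposed by `local_transfer_entropy()`; the
identity $\overline{\mathrm{lte}} = \mathrm{TE}$ holds exactly because both
use the same counts, and the test suite asserts it to $10^{-9}$.

Transitions that touch a masked sample (logger gap, tie at the series
boundary) are dropped from the counts, never imputed: entropy estimates are
sensitive to invented data, and the cost of dropping a few transitions is
far lower than the cost of fabricating rotations.

**Predictive power** expresses TE as the percentage of the target's
*remaining* uncertainty it removes, $100 \cdot \mathrm{TE} / H(T_{i+1} \mid
T_i^{(k)})$. The conditional denominator is the default because TE is by
definition a reduction of exactly that quantity; the marginal denominator
$H(T_{i+1})$ is available via `pp_denominator = "marginal"` for
sensitivity analysis.

**No bias correction** is applied by default. Plug-in estimates on a binary
alphabet with $2^{k+1}$ contexts are biased upward at flight-length sample
sizes, and the bias grows with $k$ and with subsampling (fewer symbols).
The analysis neutralises the bias by comparison — real pairs against
surrogate pairs estimated with identical settings — rather than by
correcting the point estimates, which is also why per-flight TE values
should never be read as absolute information rates.

**Parameter selection.** `parameter_scan()` evaluates the mean total
within-pair transfer, $\mathrm{TE}_{E \to N} + \mathrm{TE}_{N \to E}$, over
a grid of periods and history lengths and reports the argmax. On simulated
colonies with one-step coupling the total is maximal at the native 0.2 s
period and decays towards zero by 4 s, matching the transitory-interaction
signature the method is designed to detect. The default analysis
configuration is period 0.2 s, $k = 10$.

## Position and information

The signed projected distance $d_{EN}$ (`projected_distance()`) projects
the vector from naive to experienced bird onto the pair's current direction
of motion, taken as the normalised sum of the two unit velocities (the
bisector). Positive $d_{EN}$ means the experienced bird is in front. The
alternative reading of "current direction of the pair" — the heading of the
mean trajectory — differs only at large heading disagreements, where the
bisector construction is the one that stays aligned with what both birds
are doing.

`local_te_by_distance()` bins local TE values of both directions by
$d_{EN}$ at each transition (default 5 m bins over ±50 m) and reports
per-bin means with flight-level bootstrap confidence intervals plus a
front-bird dominance statistic (front-to-back minus back-to-front mean
local TE). Fixed-width binning replaces smoothed conditional means
deliberately: it is deterministic and directly testable, at the cost of
some visual smoothness.

## The surrogate null

Estimation bias, shared release environment and home-directedness all
inflate TE between birds that never interacted. The null that controls for
all of them at once pairs each experienced-role track with naive-role
tracks of *other* pairs that share no subject (`build_surrogate_pairs()`),
aligned on elapsed time since release and truncated to the shorter flight
— release-time alignment is the natural correspondence for birds released
at the same site, and no more specific alignment is defensible. Real and
surrogate per-flight totals are compared with a two-sided
Mann-Whitney-Wilcoxon test. On simulated colonies with no coupling the
resulting p-values are uniform across replicates (the test is calibrated);
with coupling at realistic strengths 20 flights per arm separate decisively.

## Leadership segments

Runs of constant sign of $d_{EN}$ tile each flight into leadership segments
(`leadership_segments()`). Exact zeros and masked samples extend the
incumbent run — a leader change requires an observed sign flip — because
the front/back GPS error (median ~1.7 m) makes the sign noisy near zero. An
optional hysteresis band (`hysteresis = 1.69`) additionally retains the
incumbent within the error band; it is off by default so that the default
output is a pure function of the data. Durations are samples × period.
`duration_distribution_fit()` fits log-normal and exponential models by
maximum likelihood (via `fitdistrplus`) and compares them by AIC and KS
distance; AIC+KS stands in for a fuller model-selection procedure and is
labelled as such in reports.

## Exploration and exploitation

A sample of a focal route explores when its distance to the closest vertex
of a baseline route exceeds 300 m, and exploits otherwise; equality counts
as exploitation, since a bird exactly at the threshold has still "remained
within" its route. Distances are exact nearest-vertex (no segment
interpolation): at 5 Hz and ~20 m/s, vertex spacing is ~4 m, two orders of
magnitude below the threshold.

Two baseline models are implemented (`select_baseline()`): the
previous-release model (release $r$ vs $r-1$, with the first release of a
generation compared against the last of the previous generation) and the
last-of-previous-generation model (all releases of a generation vs that
single route). The chain's very first flight has no baseline and is
excluded from proportions.

**Transition initiation** is attributed to the bird at the front (sign of
$d_{EN}$) at the first sample of the new phase, falling back to the nearest
preceding valid sample when the sign is masked or zero. "Initiate" has no
operational definition in the source procedure; front-bird-at-onset is this
package's choice, justified by the front bird's dominant local information
transfer, and a majority-over-first-second variant would be the natural
robustness check.

## The simulator

`simulate_pair_flight()` is a correlated random walk for two birds at
constant speed: each step, the latent leader blends its previous heading
with the bearing to its goal (home, an inherited route corridor, or an
exploration waypoint), the follower blends its previous heading with the
leader's heading $\tau$ steps earlier and, beyond a cohesion radius, the
bearing to the leader; all blends are normalised weighted sums of unit
vectors (angle averaging would wrap), and wrapped-Gaussian noise perturbs
every heading. Leadership alternates by a per-step switch probability
(geometric runs), or by log-normal run lengths in the alternative mode used
to test the duration fits. One integer seed drives every draw of a flight.

Exploration bouts are a reach-then-dwell excursion: the leader steers (with
a stronger weight, since a half-hearted departure never leaves the
corridor) to a waypoint drawn on a 300–1000 m band lateral to the
release-home beeline, re-drawn if it falls within the band minimum of the
inherited corridor — the labelling baseline is the previous *route*, so a
waypoint near a previous excursion would not be a departure at all — dwells
there for a geometric number of steps, and resumes. Bouts start only in the
first 85% of beeline progress; near the loft all routes converge and a
departure is neither realistic nor completable.

`simulate_transmission_chain()` reproduces the experimental design:
generation 1 is 12 solo releases of the founding bird; each later
generation pairs the previous naive bird (now experienced, inheriting its
last route as its preferred corridor) with a new naive bird whose
bout-start probability is elevated by a factor $1 + 8e^{-(r-1)/2}$ over the
releases $r$ of its first generation.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: wind and terrain, landmark-guided route memory
(corridor-following is a geometric stand-in), GPS noise, altitude, speed
variation, and any flock larger than two. Ground speed is fixed at a
conventional 20 m/s and flights last 2600 steps (8.7 min at 5 Hz),
matching the scale of a typical homing release; both are configurable.

## Validation problem sizes

The test suite validates the estimator on analytic binary channels
($n = 10^5$, closed-form TE $1 - H_b(p)$), coupling-direction recovery on
20-seed ensembles of 20000-step flights, front-bird dominance on a
20-flight colony of 6000-step flights, surrogate calibration on 50
replicate 6-pair colonies of 3000-step flights, and bout recovery on three
2-generation chains of 12 releases at 2600 steps. Bout recovery is scored
at the event level (matched bouts over the union of true bouts and labelled
phases): any threshold labelling spends the outbound leg of a bout below
threshold, so sample-level overlap understates detection by construction.

## Known limitations

* Plug-in TE values are bias-inflated at flight lengths; only comparisons
  (between directions, against surrogates, across bins) are meaningful.
* Nearest-vertex baseline distance slightly overestimates distance to the
  baseline *path* between vertices; negligible at 4 m vertex spacing.
* The initiator attribution is a single-sample rule; transition timing
  error of a few samples can flip attribution of individual transitions
  (not of aggregate proportions, which the tests target).
* The simulator's leadership switching is exogenous; it does not model the
  positional negotiation that produces switching in real pairs.
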