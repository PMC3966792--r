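---
title: "Methods: from raw tracks to eddy association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw tracks to eddy association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eddyforage)
```

`eddyforage` implements an analysis chain for central-place foraging
seabirds carrying GPS and leg-mounted saltwater-immersion loggers, in a
study system where birds commute from a colony either to nearby shelf
waters (100--200 m deep) or far into a deep oceanic basin (> 200 m)
where mesoscale eddies concentrate prey. This vignette explains each
stage's model and assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## Trip processing

A *trip* is a maximal run of GPS fixes farther than `radius_km`
(default 1 km) from the colony lasting at least `min_duration_min`
(default 15 min); the at-colony fixes bracketing the run set the trip's
start and end. These two thresholds are not part of the published
method (which reports trips but no departure rule); the defaults were
chosen to be small relative to the shortest habitat scale in the system
(shelf trips average ~27 km and hours in duration), so that trip
metrics are insensitive to them -- halving or doubling either value
changes no trip boundary in the synthetic checks. A trip missing a
bracket (track starts or ends at sea) is flagged `incomplete`; a trip
with an internal fix gap of 30 min or more is flagged `gappy`.

Tracks are resampled by inserting points every 10 m along the
great-circle segment between consecutive fixes, but only where the pair
is separated by less than 30 min; longer gaps are left unfilled. The
10-m rule is read as *spatial* resampling along each segment, with
timestamps interpolated linearly in the fraction of the segment
traversed. Because inserted points lie on the great-circle chord
between existing fixes, interpolation can never move a trip's furthest
point, so `process_trips()` leaves it off by default and metrics are
identical either way.

Distances use the haversine formula on a sphere of radius 6371.0088 km
(the WGS84 mean radius). At the study scale (< 500 km) the deviation
from ellipsoidal distances is orders of magnitude below the 0.1-km
precision at which trip distances are reported.

Habitat is assigned from the *furthest* fix of each trip alone:
bilinear water depth at that point, with depth of 200 m or less
classed `shelf` and anything deeper `basin`. The boundary case (exactly
200 m) goes to shelf because the basin is defined strictly as deeper
than 200 m; the narrow shelf-break band is merged into basin, matching
how the source analysis folded its few shelf-break trips. Per-bird
habitat preference is simply the fraction of classified trips to each
habitat (a bird with 1 basin and 2 shelf trips scores 0.33/0.67);
two-decimal rounding is applied only for reporting, with full precision
retained.

## Logger fusion and foraging classification

GPS fixes are subsampled to one per 10 min and matched to immersion
samples in an asymmetric window from 8 min before to 2 min after the
fix -- the asymmetry maximizes matched points given how the loggers
buffer their records. The wet fraction is a count of wet *samples* over
all samples in the window, never a count of seconds, which makes 1-s
and 3-s loggers directly comparable. Windows holding fewer than half
the expected sample count are dropped rather than rescaled: a wet
fraction estimated from a sparse window is unstable, and dropping is
conservative.

A window is classified `resting` when its wet fraction is at least 0.9
*and* an adjacent window of the same bird is also at or above 0.9 --
the rationale being that a bird sitting on the water (bathing,
preening, drifting) stays wet continuously across windows, whereas
surface-feeding produces broken wet/dry alternation. "Similarly high"
adjacent wetness is operationalized as the same 0.9 threshold, since no
separate quantity is published for it. Any other window with positive
wet fraction is `foraging`; dry windows are `not_wet`. The rule is
symmetric in time (reversing a window sequence reverses its labels),
and the test suite checks it against an independent brute-force
implementation on 10,000 random windows.

Light classes use geometric solar elevation from the NOAA low-precision
solar position algorithm: above 0 degrees is daylight, 0 to -6 degrees
is civil twilight, below -6 degrees is dark. Civil twilight is used
because no explicit twilight definition is published for the analysis;
local clock hours apply a fixed UTC-11 offset appropriate to the
study longitude (~170 degrees W), with no daylight-saving logic.

## Space use

Core feeding areas are kernel density estimates computed in an
azimuthal-equidistant plane (km) so that the bandwidth is a true
distance. The bandwidth is selected by least-squares cross-validation
for a bivariate Gaussian kernel, minimized over a configurable interval
(default 1--100 km) with `stats::optimize()`. On tightly clustered
multi-modal foraging data LSCV is known to favour small bandwidths and
can run to the lower end of the interval; the published bandwidth for
the real data (h = 14.05 km) can always be supplied directly to
`kde_surface()` as an override. Contours are *mass-calibrated*: the 50%
core area is the smallest region enclosing half the probability mass
(the home-range convention), not a density quantile. Overlap between
two core areas is area(a intersect b)/area(a), which is deliberately
asymmetric. The surface is renormalized so cell masses sum to exactly
one; the grid is the bounding box of the data padded by three
bandwidths at 1-km cells by default.

## Eddy kinetic energy

Under geostrophy the surface velocity anomaly is the sea-surface-height
anomaly slope rotated a quarter turn:

$$U'_g = -\frac{g}{f}\frac{\partial \eta'}{\partial y}, \qquad
  V'_g = \frac{g}{f}\frac{\partial \eta'}{\partial x}, \qquad
  \mathrm{EKE} = \tfrac12\left\langle U_g'^2 + V_g'^2 \right\rangle$$

with $g = 9.81$ m s^-2^, $f = 2\Omega\sin(\mathrm{lat})$,
$\Omega = 7.2921\times10^{-5}$ s^-1^, and spherical spacings
$\Delta x = R\cos(\mathrm{lat})\Delta\lambda$, $\Delta y = R\Delta\phi$.
With $\eta'$ in cm the velocities come out in cm s^-1^ and EKE in
cm^2^ s^-2^ directly. Derivatives are central differences (second-order,
matching the 1/3-degree product's resolution) with one-sided stencils at
grid edges; grids touching $|\mathrm{lat}| \le 5^\circ$ are rejected
because $f$ degenerates. The July mean is the time average of
$\tfrac12(U'^2+V'^2)$ over July snapshots, then a cos(lat)-weighted
spatial mean over grid nodes inside the minimum convex polygon of
at-sea locations.

## Eddy association

Each foraging location is matched to the weekly eddy table at the week
minimizing the absolute time offset, required to be at most 7 days --
the published "plus or minus 3--7 days" describes the weekly cadence of
the product, not a tunable window. Eddies are treated as circles from
their center and radius (the trajectory product supplies a speed-based
radius; a circle is the only closed perimeter reconstructable from it),
and the signed distance is distance-to-center minus radius, negative
inside. "Closest eddy" is taken as the one with the smallest *absolute*
perimeter distance, which follows the published phrasing "distance to
the perimeter of the closest eddy"; the alternative (most-negative
signed distance) differs only when a location sits inside one eddy yet
within a few km of another's perimeter, which does not occur for
non-overlapping eddies at these scales. Categories: `inside`
(signed < 0), `near` (0 to < 20 km), `outside` (20--200 km); beyond
200 km a location is uncategorized.

The null model draws an equal number of points from the bivariate
normal with the observed locations' mean and covariance, rejection
sampled into the convex hull of the observed locations. The published
description constrains the null to be "normally distributed" and to lie
"within the perimeter of the foraging locations" without giving
parameters; taking the moments from the observed sample and the
perimeter as the convex hull honours both constraints jointly. The
association test is a Pearson chi-square (df = 2) on the 2 x 3 table of
sample by category; below an expected count of 1 a Fisher exact
p-value is attached and flagged. Type-I calibration of the full
match-and-test chain (null vs null, 1,000 replicates) is exercised in
the test suite.

## Diet, productivity and stress summaries

Frequency of occurrence is the percentage of *non-empty* samples in
which a prey category occurs. The EKE--diet correlation table uses
one-tailed Pearson correlations for oceanic prey (the prior hypothesis
is directional: eddy activity can only make oceanic prey more
available) and two-tailed for fledging success, after excluding
colony-years where myctophids made up less than 4% of prey -- such
years indicate negligible basin use, so no EKE signal could register in
diets. Fledging success is the mean of per-plot ratios, not a pooled
nest count, to reduce the leverage of large plots. Baseline CORT is
summarized as mean log10 concentration, with the non-return risk flag
(> 0.90 ng/mL) applied on the raw scale. The printed 2 x 2 comparison
of colony by trip habitat reproduces at 8.521 only with the
*uncorrected* Pearson statistic, although the source methods state
Yates correction; both forms are exposed
(`chi_square_2x2(..., yates =)`) and the package's checks pin the
uncorrected value to the printed one rather than hiding the
discrepancy.

## The synthetic-data generator

`simulate_tracks()` and its companions generate the full input bundle
with planted truth. The defaults are the study conditions: 46% of trips
target the basin; shelf trip distances are normal with mean 27.2 km
(truncated 6--60 km), basin distances mean 180 km (truncated 120--465
km, spanning the reported 1.3--464.7 km range); commuting flight is 40
km/h; GPS fixes every 180 s; immersion sampled at 3 s. Immersion bout
archetypes are chosen to make the 0.9-wet rule discriminative by
construction: foraging alternates 5--30 s wet with 10--120 s dry
(window wet fractions well below 0.9), resting is continuously wet for
30--60 min (wet fraction 1 across adjacent windows), flight is dry.
Basin trips depart in the local evening and stay out overnight while
shelf trips are daytime -- mirroring the reported day/night contrast in
the two habitats, not fitted to it. Planted eddies are isotropic
Gaussian bumps in the SSHA field (anticyclonic positive, cyclonic
negative, amplitudes at the reported 9.7--21 cm scale) whose weekly
trajectory table is emitted alongside; bathymetry is a radial shelf
plateau (150 m) with a linear break at 80 km to a 3,000-m basin; diets
are drawn conditionally on the habitat of a bird's furthest trip; and a
10% per-trip chance of a 45-min transit recording gap exercises the
gap flags.

The generator is deterministic under its seed and every record carries
a truth label. What it does *not* emulate: behaviorally realistic
movement (no correlated random walks or hidden-state switching -- trips
are piecewise-linear commutes with local jitter), GPS measurement
error, tidal or advective drift of resting birds, eddy shapes beyond
circles, or any coupling between EKE and simulated diets beyond the
habitat link. Passing the synthetic recovery checks therefore
demonstrates that the pipeline's rules are implemented exactly, not
that they are robust to every pathology of field data.

## Problem sizes and numerical choices

The packaged checks run the end-to-end recovery at 40 birds (about
70--90 trips, roughly a million immersion samples), the classifier
oracle at 10,000 windows, the association-test calibration at 1,000
null-vs-null replicates of 120 locations, and KDE calibration at 2,000
points -- sizes chosen so the whole suite completes in about a minute
and a half while keeping every binomial/chi-square check comfortably
powered. Ties in trip segmentation are resolved by strict inequality
(distance > radius counts as away); KDE contour thresholds are chosen
from the sorted cumulative cell masses, so enclosed mass is calibrated
to within one cell's mass; interpolation guards the
exact-multiple-of-10-m case with a 1e-6 m tolerance; and the matched
window [t - 8 min, t + 2 min] is closed on both ends, with a
half-second shift protecting the lower endpoint from double rounding at
POSIXct magnitudes.
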