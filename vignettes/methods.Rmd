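---
title: "Process formulation and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process formulation and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`olivesim` simulates the daily water and carbon economy of an olive
orchard: a two-zone multilayer soil water balance, a soil-plant-atmosphere
(SPAC) hydraulic network coupled to sunlit/shaded leaf gas exchange,
phenology, a carbon budget with fruit-priority allocation and alternate
bearing, soil carbon turnover, and the management operations (tillage,
irrigation, harvest, pruning) that shape commercial orchards. This
vignette documents the model structure, the defaults and why they were
chosen, the numerical schemes, and the limits of what the test suite can
demonstrate.

## Forcing and sub-daily disaggregation

Inputs are daily: maximum and minimum temperature, mean vapor pressure,
global solar radiation, mean wind speed and precipitation. Root water
uptake, photosynthesis, maintenance respiration and chilling are
sub-daily processes, so each day is split into `n_steps` equal intervals
(default 24). Temperature follows a sine from sunrise (anchored at the
daily minimum) to a 14:00 solar-time peak (anchored at the maximum), with
an exponential night decay; only the two printed extremes constrain the
curve, so any smooth interpolant with those anchors would serve equally.
Radiation is distributed across steps in proportion to the sine of solar
elevation and renormalised so the daily integral is reproduced exactly;
vapor pressure and wind are held at their daily values because only daily
means are available. PAR is taken as 0.45 of global shortwave, split into
beam and diffuse with a daily clearness-index correlation; both the
fraction and the split are configurable because different sites justify
different partitions.

The synthetic weather generator emulates a semi-arid Mediterranean
climate: seasonal temperature and radiation sinusoids with AR(1) daily
anomalies, and rainfall from a seasonal occurrence probability with
gamma-distributed amounts whose expected annual total is 600 mm,
concentrated outside the summer. Those normals describe the kind of site
on which the evaluation experiments were conducted. The generator does
not produce multi-day synoptic rain spells, heat waves with realistic
persistence, or hail/extreme events; tests that pass on this forcing
demonstrate internal consistency and plausible behavior, not predictive
skill on any specific real site.

## Soil water balance

The surface is divided into a dry and a (drip-)wetted zone that share no
lateral flow; irrigation water enters only the wetted zone, directly as
surface infiltration (drip emitters apply water below the canopy at low
rates, so interception and runoff are bypassed). Effective precipitation
(after canopy interception) reaches both zones as an equal depth; the
alternative of weighting the depth by ground cover is exposed through the
`precip_partition` config entry but not implemented as the default, since
the equal-depth reading conserves area-weighted volume without extra
assumptions.

Rainfall interception treats the canopy as a capacitor with capacity
`c_int x LAI` (default 0.4 mm per unit LAI); stored water evaporates at
the Penman-Monteith rate with zero canopy resistance and a log-profile
aerodynamic resistance, and while any stored water remains, transpiration
is suppressed. Runoff uses the SCS curve-number method with the base CN
tabulated by soil hydrological condition (editable defaults 86/80/74 for
poor/fair/good), reduced by 10 x ground cover, and adjusted for
antecedent moisture through the standard AMC I/III conversions using the
wetness of the top two layers in three classes. Drainage is a CERES-type
tipping bucket: each layer holds up to saturation, passes the excess
downward immediately, and drains `SWCON x (theta - theta_UL)` per day
(SWCON default 0.4 d^-1); a small diffusive exchange moves water between
adjacent layers below field capacity. Soil evaporation follows the
two-stage scheme: stage 1 evaporates at the potential rate times the
radiation fraction transmitted through the canopy (and a microadvection
factor >= 1.0, default 1.3, for the small wetted patch surrounded by dry
soil) until a cumulative limit `U` (default 9 mm); stage 2 follows
`alpha (sqrt(t) - sqrt(t-1))` with `alpha` = 3.5 mm d^-1/2. Evaporation
and uptake never draw a layer below the air-dry limit (half of wilting
point). Every daily step closes the zone and orchard water balances to
numerical precision; the run aborts if a residual exceeds 1e-6 mm, so a
closure bug cannot pass silently.

## Crown geometry and radiation interception

Crowns are spheroids of constant leaf area density (LAD) with a fixed
vertical-to-horizontal radius ratio. Leaf area follows from leaf biomass
times SLA; crown volume from leaf area over LAD; the horizontal radius is
capped at half the smaller spacing, with LAD recomputed if the cap binds
so leaf area is never lost. Beam interception is computed by deterministic
quadrature: a 12 x 12 grid of ground points in one planting cell, with
chord lengths through every crown of the surrounding lattice (neighbor
shading is therefore exact for the regular grid, up to grid resolution)
and extinction `exp(-G x LAD x path)` with a spherical leaf angle
distribution (G = 0.5). A Monte-Carlo ray-casting oracle validates the
quadrature to well under 5%. Diffuse interception integrates the beam
model over three elevation bands and four azimuths of a uniform-overcast
sky. Sunlit leaf area is `f_beam sin(beta) / G` (capped at LAI); shaded
leaves receive the per-leaf diffuse flux plus a single scattering
correction (10% of intercepted beam). A full 3-D scene, within-crown LAD
gradients and the thermal balance are out of scope.

## SPAC network and gas exchange

Water flow follows the electrical analogy: each rooted layer in each zone
is a branch with a soil resistance (single-root Gardner/Cowan form with
Campbell retention and unsaturated conductivity) in series with a root
resistance (inverse of permeability times root surface area, the
permeability reduced below a soil-water threshold and at low temperature),
all joining at the collar; a Hagen-Poiseuille xylem resistance computed
from vessel diameter and density, sapwood area and path length (height
plus crown radius) links the collar to the leaves. Gravity enters as a
0.01 MPa m^-1 offset on each branch. The collar potential has a closed
form from Kirchhoff's law, verified in the tests against a dense linear
solve of the node equations. Reverse flow (hydraulic redistribution) is
allowed by default (`allow_efflux`); the electrical analogue permits it
and clamping is available where undesired.

Leaf biochemistry is a C3 model (Rubisco- and RuBP-regeneration-limited
rates with Arrhenius temperature scaling; Vcmax25 = 90, Jmax25 = 162
umol m^-2 s^-1, values in the range reported for olive) coupled to a
stomatal conductance proportional to net assimilation, reduced by VPD
(Leuning form, D0 = 1.5 kPa) and by a logistic leaf-water-potential
factor falling from ~0.95 at -1.5 MPa to ~0.05 at -4.5 MPa - olive keeps
stomata partially open at water potentials that would close most crops,
and these two anchors are the tunable expression of that behavior. Leaf
temperature is taken equal to air temperature, consistent with the
imposed-evaporation (well-coupled canopy) assumption used for
transpiration, `E = 1.6 gs VPD / P`.

Numerically, all sub-daily steps of a day are solved simultaneously: an
outer damped fixed point over leaf water potential (shared by the two
leaf classes) and an inner one over intercellular CO2 per class, both
with per-element sign-flip adaptive damping (initial 0.5, halved when the
update oscillates). The stomatal downregulation is steep enough near
closure that a fixed damping two-cycles; the adaptive scheme converges in
a few tens of iterations, and non-convergence raises an error rather than
returning silently. Tolerances: 0.1 umol mol^-1 on Ci, 0.005 MPa on leaf
water potential. Halving the step length (N = 24 vs N = 96) changes
summer daily transpiration and assimilation by well under 1%.

## Phenology

Vegetative dormancy is induced on day 305 and released by chilling: a
triangular effectiveness function (zero at 0 and 14 degC, optimum at
7 degC) integrated sub-daily, with a requirement of 45 chill-day
equivalents. Flowering follows the two-phase chilling/forcing pattern:
after release, forcing degree-days above 9.1 degC accumulate to a
450 degCd requirement - values in the range published for Mediterranean
olive cultivars; all are per-cultivar config entries. Budbreak (start of
vegetative growth) requires a 7-day trailing mean temperature above
10 degC; the window length is a design choice where only "average
temperature above a threshold" is specified. Fruit growth starts
150 degCd (base 10) after flowering and ceases at maturity (2400 degCd)
or harvest, whichever comes first.

## Carbon economy

Gross assimilation (converted at 30 g CH2O per mol CO2) plus fruit
photosynthesis (a linear coefficient on fruit biomass during active fruit
growth) feeds a daily assimilate pool from which maintenance respiration
(organ-specific coefficients with Q10 = 2, integrated sub-daily) is paid
first; deficits draw on a reserve pool, and when reserves are exhausted
the unpaid demand is recorded as starvation (growth stops; the model does
not yet kill biomass). Growth allocation gives fruits priority: their
demand is the fruit number times a potential growth rate per degree-day,
capped at a source-limited share (default 0.6) of the pool; the remainder
is split by fixed vegetative coefficients including an explicit reserve
share, and during vegetative rest everything goes to reserves.
Remobilization from reserves (up to 5% per day) supplements days when
fruit demand exceeds supply. Production values (g DM per g substrate)
express growth respiration; the bookkeeping keeps substrate conservation
exact, and the run-level audit closes the whole-system carbon balance
(biomass + reserves + soil pools + exports) to numerical precision daily.

Fruit number is set at flowering from the previous season's records,
`FN = max(0, a x nodes_prev - b x FN_prev)`, then trimmed for each
flowering-window day hotter than 38 degC. The linear form is the minimal
relation consistent with a dependence on both quantities; `a` = 1.5
fruits per node and `b` = 0.9 were calibrated so that (i) simulated oil
yields of a well-watered mature orchard fall in the 100-360 g m^-2 range
reported for comparable orchards, and (ii) the recurrence operates around
the source/sink-limitation boundary, which is what sustains the biennial
ON/OFF alternation instead of damping to a fixed point: ON crops are
source-limited (capping yield and squeezing shoot/node production), OFF
crops are sink-limited (freeing assimilates for shoots, hence a large
next-year fruit number). Senescence is first-order turnover of leaves and
fine roots; shoots age through three annual cohorts into branches; frost
defoliates linearly between -7 and -14 degC. Fine-root growth is
distributed over layers by volume times plant-available wetness, and root
length density follows from a constant specific root length.

Soil carbon uses two pools (fresh residues and humus) with first-order
decay modified by Q10 temperature and a moisture factor reduced towards
both dryness and saturation (`4 w (1 - w)` on relative saturation); 20%
of fresh-pool decay humifies. Ecosystem respiration and NEE follow by
identity, with NEE positive as a source.

## Management

Irrigation is either an explicit event list or an automatic rule that, at
a fixed interval inside the irrigation season, replaces a fraction of the
maximum-ET deficit accumulated since the last application. The
maximum-ET accumulator uses a Penman-Monteith reference ET0 from the same
daily weather times a ground-cover-dependent crop coefficient
(0.30 + 0.55 x GC); running a parallel well-watered simulation to define
maximum ET would double the cost of every run for a bookkeeping input,
and the ET0 proxy keeps the rule monotone in demand, which is all the
scheduling requires. Harvest (default day 349, mid-December) removes the
fruit biomass and reports dry and oil yield (oil:dry ratio 0.42). Pruning
removes a fraction of leaves, shoots and branches at a configurable
interval, with residues incorporated into the soil fresh pool or
exported. Tillage sets or offsets the curve number.

## Initialization

Simulations start on January 1. The crown radius is inverted from the
initial ground cover, leaf biomass from crown volume x LAD / SLA, woody
organs from allometric ratios to leaves, and fine roots from the initial
root length density profile (so the Lv -> biomass -> Lv round trip is
exact). The first season's fruit-number recurrence is seeded from the
prior-year dry yield divided by a mean fruit mass (0.8 g), with the node
record chosen so the recurrence starts at its neutral point. Phenology is
pre-run on the 90+ days of temperatures preceding the start.

## Evaluation statistics

The evaluation module implements the goodness-of-fit set used in crop
model testing: MAE (mean absolute error), signed mean error (reported
separately because published tables sometimes print the signed form under
the MAE label), RMSE, coefficient of residual mass `1 - sum(S)/sum(M)`,
Nash-Sutcliffe modelling efficiency, and OLS of simulated on measured
with r^2. Biennial aggregation averages overlapping consecutive-year
pairs per treatment - the definition under which 24 annual records from
eight 3-year treatments give 16 biennia. The packaged fixture carries the
observed and simulated seasonal ET and oil yields of two 3-year
irrigation trials (ET unobserved in the first year of one experiment),
and the test suite reproduces the published summary statistics from it to
within printed-rounding tolerances.

## Problem sizes used in the tests

The acceptance-level tests run a 12-year automatically irrigated
simulation (closure audits, bearing autocorrelation, radiation-use
efficiency), a matched 3-year full/deficit irrigation pair, and one-year
runs at N = 24 and N = 96 for refinement consistency, all on seeded
synthetic weather; unit tests use single days, single zones and random
small networks. These sizes keep the full suite to a few minutes while
exercising every coupling in the model; longer runs change none of the
audited identities, which hold day by day.

## Known limitations

Within-tree water storage and stomatal kinetics are not simulated, so
diurnal transpiration has no lag relative to its drivers. Oil
accumulation dynamics inside the fruit, nutrient limitation, pests and
diseases are absent. Starvation does not yet kill biomass. The alternate
bearing recurrence is an empirical stand-in for poorly understood
physiology; its coefficients are cultivar- and site-specific in reality.
The evaluation fixture tests the statistics module against published
numbers; it does not constitute a field validation of this
implementation, which would require the original (unpublished) weather,
soil moisture and sap-flow records.
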