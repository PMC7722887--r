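---
title: "Particle tracking and closed-area connectivity on a synthetic cap ocean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle tracking and closed-area connectivity on a synthetic cap ocean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Networks of deep-sea fisheries closures are only effective if the protected
populations can replenish each other. For sessile animals such as sponges,
sea pens and gorgonian corals the only mobile stage is the larva, which in
the absence of behavioural data is best modelled as a passive particle
advected by the ocean. `capdrift` implements that model end to end: a 3-D
Lagrangian particle tracker driven by gridded climatological currents, and
the statistics used to turn trajectory clouds into management-relevant
quantities — connectivity matrices with retention, transit-time
distributions, source-density maps, vertical-displacement percentiles, and
a bottom water-mass characterization of each closure.

## The kinematic model

Particles obey

$$\mathbf{x}_t = \int_{t_0}^{t_1} \mathbf{v}(\mathbf{x}, t)\,dt + \mathbf{x}_0$$

integrated with the classical fourth-order Runge–Kutta scheme on a
20-minute step (`dt = 1200` s). Velocities are interpolated trilinearly in
(lon, lat, depth) and linearly in time between adjacent climatological
months, with December wrapping to January; the interpolation order is a
design choice (the standard one for structured-grid trackers) since it is
not dictated by the data. Masked (land or sub-seabed) neighbours are
excluded with weight renormalization rather than zero-filled, which avoids
spuriously damping the flow against the seabed.

Unresolved mesoscale stirring enters as a horizontal random walk with
independent Gaussian increments of standard deviation
$\sqrt{2 K_h \Delta t}$ metres per axis, with $K_h = 100\ \mathrm{m^2\,s^{-1}}$
by default; there is no vertical diffusion. Ensembles then satisfy the
Fickian law $\langle r^2 \rangle = 4 K_h t$, which the test suite checks to
within 5% at $N = 10^4$. Backward (source-finding) runs negate the velocity
and run the climatological clock backwards; the random walk keeps its
forward form, a standard heuristic rather than an exact adjoint.

Boundary rules: a particle whose new position leaves the configured domain
box (31.4–73.9°W, 40.8–70.5°N by default) or the forcing grid is removed
and frozen (`removed_boundary`); depth is clamped to `[0, seafloor]`, so
particles ride the seabed rather than being killed there (surface releases
persisting at < 3 m depth motivate the no-removal-at-surface rule); only a
position over land grounds a particle. One RNG stream per run, seeded from
the configuration, makes every run bit-reproducible.

A note on the seabed clamp: a particle that diffuses horizontally into
shoaling topography is lifted to the local seafloor. On a small, steep cap
this produces substantial up-slope excursions for deep releases — visually
striking but consistent with the large release-to-minimum-depth ranges
deep-release experiments report, and the percentile statistics (below) are
robust to it.

## The synthetic cap ocean

Real forcing fields (an eddy-resolving regional model; an objectively
analysed T/S climatology) are external downloads, so the package ships a
generator that reproduces the *structure* the analysis relies on, on a
desk-scale grid (0.1°, 14 levels, ~7° × 4.4° domain):

* **Relief**: a Gaussian seamount,
  $h(r) = h_{abyss} - (h_{abyss} - h_{summit})\,e^{-r^2/R^2}$, with a 140 m
  summit, 4000 m abyss and $R = 80$ km. The real feature it emulates is
  roughly 2.5× larger; everything below scales accordingly.
* **Horizontal flow**: azimuthal about the cap — equivalently derived from a
  streamfunction that is a function of seafloor depth — hence exactly
  tangent to isobaths and horizontally non-divergent. Speed peaks at
  0.1 m/s where the seafloor crosses the 1000 m isobath (the slope-jet
  core), with a clockwise (anticyclonic) sense. The 0.1 m/s choice gives
  adjacent closures transit times of ~3–6 days at the scaled geometry,
  matching the few-day peaks reported for neighbouring areas. The flow is
  depth-independent above the seabed; this barotropic simplification keeps
  trajectory behaviour analysable (isobath conservation is a test).
* **Vertical velocity**: prescribed independently of continuity (a
  kinematic test ocean, not a dynamically consistent one): a downwelling
  band $w < 0$ over slope seafloor centred on the 1500 m isobath with a
  1500 m width in seafloor-depth space, upwelling over the abyssal flank
  near 3500 m, and zero in the top 50 m (ramping to full strength by
  200 m). The band is wide enough that releases at 450, 1000 *and* 2250 m
  all sit under net downward velocity — the qualitative pattern the
  analysis is designed to detect. Peak magnitudes (−3 and +1.5 × 10⁻⁴ m/s)
  match the order of magnitude of published vertical-velocity maps for
  such slopes.
* **Seasonality**: every monthly slice is scaled by
  $1 + A\cos(2\pi(m - m_{peak})/12)$ with $A = 0.3$ and an August peak, so
  summer/autumn currents and vertical velocities are the strongest —
  seasons use the DJF/MAM/JJA/SON convention (the month boundaries are not
  fixed by the source analyses, so the northern-hemisphere standard is
  used).
* **Hydrography**: exponential profiles giving ~12 °C fresh surface water
  over 2.5 °C, 34.92-salinity deep water, a surface-intensified seasonal
  cycle, and optional interannual noise as a spatially uniform Gaussian
  offset per year-month. Bottom water at closure depths is below 4 °C and
  above salinity 34.8, and 12-month averaging damps the interannual noise —
  the stability property the multi-year analysis checks.
* **Closures**: 14 annular-sector polygons whose seafloor-depth ranges
  bracket the release-depth presets, with group labels (sponges 1–6; sea
  pens 2, 7–12, 14; gorgonians 2, 4, 5, 13), a large downstream closure
  (area 2) reaching shallower water, and two areas (7, 14) whose ~700 m
  maximum depths exclude deep releases. These are geometric stand-ins, not
  real closure coordinates; real polygons can be supplied as GeoJSON.

What a green test on this ocean establishes: that the tracker, the seeding
and every statistic behave correctly on fields with the right structure
(slope jet, up/downwelling bands, seasonality, stratification). What it
does not establish: realism of any particular connectivity percentage —
eddies, baroclinicity and real closure geometry are absent by design.

## Statistics definitions and numerical choices

* **Visits**: horizontal point-in-polygon per step ("passing over" ignores
  depth, matching the 2-D lineage of the metric; a depth-aware variant is
  the obvious extension). First arrivals include the release position at
  time zero. With `track_particles(..., areas = )` containment is checked
  at every *integration* step so thin polygons cannot be jumped between
  coarse output records.
* **Connectivity matrix**: entry (s, r) is 100 × (particles from s that
  passed over or terminated in r) / released(s). The diagonal is retention:
  particles whose *terminal* position lies in their release area, so a
  particle that exits and re-enters still retains.
* **Transit-time distribution**: histogram of first-arrival days per
  receiving area, retention excluded, normalized to unit mass per area.
* **Source-density map**: initial positions of particles that later enter
  any closure, floor-binned on a 0.1° grid; proportions are relative to all
  released particles.
* **Vertical statistics**: per-particle extreme depths; "depth reached by
  the first p% of particles" is read as the p-th percentile (median-style
  linear interpolation) of the per-particle extreme-depth distribution,
  counting from the least extreme — the reading under which the reported
  p50 values sit between the release depth and the absolute extreme, as
  published tables show. The upward side mirrors the downward side.
* **Seasonal comparison**: Pearson's r over flattened count matrices;
  self-correlation returns exactly 1, zero-variance inputs are flagged NA.
* **Along-path T/S**: population (N-denominator) standard deviation — the
  convention is stated because the source is silent on it.
* **Bottom values**: the deepest unmasked level of the nearest column, no
  vertical extrapolation. Per-area averages weight columns equally.
* **Regridding**: strict bilinear by default (any masked corner masks the
  target). The hydrography workflow regrids onto a 0.03° grid with
  *renormalized* weights instead, because near steep topography strict
  masking systematically discards the deepest usable level and biases
  "bottom" values warm and shallow.

## Seeding

Release positions form a regular lattice at the configured spacing (0.01°
in the full-scale setup, 0.005° for fine backward releases), anchored at
the polygon bounding box minimum plus half a spacing — cell centres,
half-open on the upper side. This anchoring satisfies simultaneously the
expected lattice density (a 1° × 1° rectangle at 0.01° yields exactly
10 000 seeds), strict interiority (no boundary-touching seeds), and the ×4
count under halved spacing. Positions where the seafloor is shallower than
the release depth are dropped, so seed counts fall with release depth
exactly as area geometry dictates; `release_depth = "bottom"` puts
particles on the seabed (the default for sponge releases is the fixed
preset depths; on-bottom is available since the source description is
ambiguous between the two).

## Experiments and reproducibility

`run_experiment()` drives the three experiment types (vertical movement,
source populations, functional connectivity) plus the hydrographic
characterization from a YAML manifest holding every parameter and the RNG
seed; each scenario derives its own sub-seed deterministically, outputs are
plain CSV, and the completed manifest is copied beside them, so rerunning a
manifest reproduces byte-identical files. The "average" season is the
unweighted mean of the 12 monthly slices; named seasons are 3-month means
run as steady fields.

## Known limitations

* The test ocean is kinematic: `w` is prescribed, not derived from
  continuity, and the horizontal flow is depth-independent.
* No larval behaviour (swimming, buoyancy, mortality, settlement windows) —
  particles are strictly passive, which is the deliberate baseline.
* Backward diffusion is sign-symmetric forward diffusion, not the adjoint.
* The plain-text field format trades file size for a zero-dependency,
  bit-exact round trip; it is not a community interchange format. NetCDF
  support would slot in behind `read_field()`/`write_field()` when a
  NetCDF library is available.
* Curvilinear grids, dateline crossing and unstructured meshes are out of
  scope.
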