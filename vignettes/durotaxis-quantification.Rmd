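---
title: "Quantifying stiffness gradients and durotaxis with durotaxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stiffness gradients and durotaxis with durotaxr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durotaxr)
```

Durotaxis — cell migration up gradients of matrix stiffness — is
quantified from two data streams: AFM nanoindentation maps of tissue,
and cell positions or trajectories on engineered stiffness-patterned
hydrogels. This vignette documents the models `durotaxr` implements,
the parameters that matter, the numerical conventions, and what the
synthetic generators do and do not capture.

## The Hertz contact model

A rigid sphere of radius $R$ indenting an elastic half-space to depth
$\delta$ experiences

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

so the Young's modulus follows from a force–indentation pair as
$E = \tfrac{3}{4}(1-\nu^2)F/(\sqrt{R}\,\delta^{3/2})$. The model
assumes small strains, a homogeneous isotropic sample, and indentation
depths small relative to both sample thickness and tip radius —
assumptions that are conventional for soft-tissue nanoindentation but
are violated near tissue boundaries and for strongly viscoelastic
samples (no viscoelastic correction is attempted here).

Defaults follow standard tissue protocols: a 5&nbsp;µm diameter
spherical probe ($R = 2.5$&nbsp;µm), $\nu = 0.4$ for tissue, a
~60&nbsp;pN&nbsp;nm⁻¹ cantilever (metadata only; deflection-to-force
conversion is upstream), and a 16&nbsp;nN force cap delimiting the
fitted range. All are overridable per curve or per fit.

**Fitting.** Because $F$ is linear in the reduced modulus once
parameterized as $F = \beta\,\delta^{3/2}$, the fit is the closed-form
no-intercept least-squares regression of $F$ on $\delta^{3/2}$, with
$E = \tfrac34 \beta (1-\nu^2)/\sqrt{R}$. This avoids iterative-optimizer
fragility entirely; on noiseless synthetic curves it recovers $E$ to
machine precision, and under 2&nbsp;% multiplicative force noise the
mean of 200 fitted curves sits within 5&nbsp;% of truth (tested).
Curves with fewer than 8 usable samples yield `valid = FALSE` rather
than an error, and become missing cells in assembled maps.

**Contact point.** Raw approach traces are aligned by estimating the
baseline mean $\mu$ and noise $\sigma$ from the leading 20&nbsp;% of
samples, finding the first sustained crossing of $\mu + c\sigma$
(default $c = 3$; the value is a configuration knob recorded in
provenance, since acquisition software conventions differ), then
refining with a piecewise grid search that models the trace as a flat
baseline followed by a Hertzian $(z - z_0)^{3/2}$ rise. The refinement
matters: the raw threshold crossing is systematically late because the
Hertzian force grows only as $\delta^{3/2}$ near contact, and the
piecewise fit brings the estimate within about one sample of truth at
1&nbsp;% noise.

## Elastographs and the average-slope statistic

Stiffness maps store moduli on lattice *nodes* at
$\mathrm{origin} + i \cdot \mathrm{pitch}$ (0-based), so an
$n \times n$ map spans $(n-1)\cdot\mathrm{pitch}$ per side: a
17 × 17 grid at 5&nbsp;µm pitch covers exactly the 80 × 80&nbsp;µm
field of the standard mapping protocol. This node convention (rather
than pixel centres at $(i+\tfrac12)\cdot\mathrm{pitch}$) was chosen so
that the standard grid size and extent are mutually consistent; queries
between nodes use bilinear interpolation and missing nodes propagate
as gaps.

The per-sample gradient statistic is the mean magnitude of many
transect slopes. The slope count (50 per sample) is conventional; the
sampling scheme had to be chosen here, and three decisions define it:

1. **Anchor and orientation.** Each transect is anchored at a seeded
   uniform random in-extent point and oriented along the local
   steepest-ascent direction of the interpolated field (central finite
   differences at half-pitch), extended to the map boundary both ways.
   Randomly *oriented* transects would be systematically biased: on a
   linear field a transect at angle $\theta$ to the gradient measures
   $|\nabla E|\cos\theta$, so random orientations would recover only
   $2/\pi$ of the true gradient magnitude. Steepest-ascent orientation
   makes the statistic estimate the gradient magnitude itself, and on
   rasterized linear-gradient substrates it reproduces the nominal
   gradient within 2&nbsp;% (tested).
2. **Per-run slopes.** Each profile is split into maximal monotone
   runs (flat stretches break runs; ties resolve toward the earlier
   point; runs shorter than 3 points are discarded; transects crossing
   missing cells are split at the gap), and one least-squares slope
   magnitude is taken per run. On a trapezoidal stripe profile this
   isolates the transition ramps from the plateaus.
3. **Determinism.** Anchors are drawn from a local RNG seeded by the
   `seed` argument, slopes accumulate until the requested count (or a
   transect budget of 20× runs out), and the summary records seed,
   count and transect usage, so identical inputs are bit-identical.

A uniform map has no steepest-ascent direction anywhere, yields zero
slopes, and reports an average of 0. Peak/valley detection flags nodes
strictly more extreme than their 8 neighbours with
$|E - \mathrm{median}|$ above a prominence floor, optionally after a
moving-average smooth.

## Patterned substrates

`substrate_pattern()` models the engineered hydrogels as continuous
fields in µm coordinates, origin lower-left, gradient axis +x:

* *step stripes* — alternating soft/stiff plateaus (defaults: 100 µm
  stiff, 200 µm soft, matching the photomask geometry) joined by linear
  ramps over a 40 µm transition. With 4 and 40 kPa plateaus the nominal
  gradient $(E_\mathrm{stiff}-E_\mathrm{soft})/\Delta x$ is
  900 Pa µm⁻¹. The ramp shape inside the transition is not measurable
  from end moduli alone; the linear profile is a documented modelling
  choice.
* *linear gradient* — one ramp over `transition_width` (1,000 µm for
  the microfluidic design: 36 Pa µm⁻¹), clamped to plateaus outside.
* *island* — a circular soft island blended over the transition width
  into a surrounding striped field (tumour–stroma mimic). Both reported
  island parameterizations (1–10 kPa and 1–25 kPa) are expressible via
  `E_soft`/`E_stiff`; the examples use 1/25 kPa.
* *uniform* and *field* (a measured map interpolated bilinearly).

Stiffness is always bounded by the plateau moduli, striped kinds are
exactly periodic, and the analytic local gradient is zero on plateaus
and equal in magnitude to the nominal gradient inside transitions —
all property-tested over random points.

## Durotaxis assay

The durotactic index is the stiff/soft cell-count ratio. By
convention the plating-time distribution (about 4 h after seeding) is
equal on both stripe types and anchors the index at 1; later
observations are normalized by that baseline. Decisions made where
protocols are silent:

* cells over a transition band are excluded from both counts by
  default (reported as `n_excluded`); a midpoint-split rule is
  selectable;
* the index is a raw count ratio by default, faithful to the "ratio of
  cells" convention even though default stripe widths are unequal;
  area-density normalization is an explicit option (and exactly
  cancels unequal stripe areas — property-tested);
* a zero soft count reports a saturation flag, never infinity;
* multiple fields are pooled by summed counts, not by averaging
  per-field indices.

Classification uses the conventional thresholds — strong above 6,
moderate above 2, above 4 for confluent (collectively migrating)
monolayers — and is non-decreasing in the index.

## Track metrics

All metrics derive from the tidy table (`track_id`, `t`, `x`, `y`).
Directionality (straightness) is net displacement over path length,
in $[0,1]$; the forward migration index is the signed net-displacement
component along the gradient axis divided by path length, so
$|\mathrm{FMI}_\parallel| \le$ directionality and
$\mathrm{FMI}_\parallel^2 + \mathrm{FMI}_\perp^2 \le$
directionality² always. The angular statistic is the end-to-end angle
per track (matching rose diagrams that bin one event per trajectory);
a per-step variant pooling every frame-to-frame displacement angle is
available via `rose_histogram(..., mode = "step")`.
Speeds use actual timestamps — no constant-frame-interval assumption.
Rose histograms use 18 half-open 20° bins partitioning (−180°, 180°].

Coverage filtering keeps tracks observed for strictly more than 10 %
of the recording; a track seen in $k$ frames of an $N$-frame recording
covers $k/N$, implemented as $(\mathrm{span} + \Delta t)$ over the
recording duration so the rule is exact for frame-sampled data.
Drift correction subtracts the accumulated per-frame median
displacement of the ensemble: a rigid common translation is removed
exactly, at the cost of also removing any true median motion — which
is the standard trade-off of registration-free drift correction and
the reason it should be applied to fields with many asynchronously
moving cells. The invasion index (fraction of tracks starting on the
non-invaded side of a boundary polyline and ending on the invaded
side) is a declared operationalization: no standard formula exists for
it, so it should be read as this package's definition.

## Tumour metrics

The metastatic index divides the summed photon flux of the selected
metastatic sites (default liver + lung; configurable to e.g.
liver + GI) by the primary-tumour flux, per animal; it is invariant to
per-animal exposure rescaling. Fibre curvature ratio is chord over arc
length (1 = straight), orientation is the axial angle of the
end-to-end chord in $[0°, 180°)$ (a length-weighted per-segment tangent
mode is available), and the alignment score is the mean resultant
length of doubled axial angles (1 = parallel, ~0 = uniformly
dispersed). The chord convention is declared rather than derived: fibre
analysis tools differ, and the chord is the robust choice for noisy
centerlines.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its seed (a root seed can be
fanned out with `derive_seed()`, so adding generators never perturbs
existing fixtures) and returns its ground truth alongside the data.

* `sim_force_curves()` — Hertzian curves to the 16 nN setpoint with
  multiplicative Gaussian force noise (default 2 %, a modelling choice;
  instrument noise spectra are not modelled).
* `sim_stiffness_field()` — healthy: 2 kPa baseline with a smooth
  ±0.3 kPa undulation (average slopes well under 100 Pa µm⁻¹);
  fibrotic: baseline plus Gaussian foci rising towards 40 kPa and
  valleys towards 0.5 kPa — the reported extremes of fibrotic
  stiffness heterogeneity — with centres separated by ≥ 3σ
  (σ = 6 µm) so each focus is a resolvable extremum. Real fibrotic
  elastographs have anisotropic, non-Gaussian structure; recovering
  planted Gaussian foci shows the detector works, not that it
  segments real fibrotic niches.
* `sim_tracks()` — a persistent random walk (heading noise variance
  $2\,\Delta t/\tau$, default persistence $\tau = 30$ min, speed
  0.5 µm min⁻¹ with 10 % CV, 5-min frames) plus a deterministic
  heading torque $w \sin(\varphi_\nabla - \theta)$ with
  $w = \frac{b}{1+b} \cdot \frac{|\nabla E|}{g_{1/2} + |\nabla E|}$,
  both factors saturating below 1 so the relaxation never overshoots
  the gradient direction and mean FMI is monotone in the bias gain
  $b$ (tested over 5 gain levels). This coupling is an explicit
  phenomenological stand-in for mechanosensing — no molecular-clutch
  or focal-adhesion fidelity is claimed, and the walk is 2-D with
  reflecting boundaries.
* `sim_flux_table()` — log-normal primaries, gamma-distributed
  metastatic fractions split across sites; indices are exact by
  construction.
* `sim_fibers()` — random-walk polylines: near-straight with a shared
  axis (±5° jitter) and larger widths for the aligned phenotype,
  strongly wiggling with uniform initial orientation for the curly
  phenotype. Fibre *extraction* from images is out of scope; the
  package consumes centerlines.

Consequently, passing tests demonstrate correctness of the estimators
and statistics under known generative models at desk scale — they do
not validate biological conclusions about any particular tissue, and
tissue-derived numbers (e.g. average slopes of specific fibrotic
organs) are not reproduction targets here.

## Numerical conventions and problem sizes

SI units (m, N, Pa) internally for AFM, µm/s/Pa/degrees at all file
interfaces; 0-based grid indices; half-open angular bins; CSV with
header, '.' decimal; maps as TSV + JSON sidecar (kept text-based and
diffable). Ties in run detection break toward the earlier point;
profile sampling defaults to half-pitch; finite differences use
half-pitch (maps) or 0.05 µm (parametric fields, matching the 1 %
consistency requirement between local and nominal gradients).

Test and demo problem sizes are chosen as the smallest that make the
statistics stable: 200 curves per Hertz recovery condition, 20 seeded
fibrotic fields for foci recall, 500 walkers per bias level (1,000 for
the unbiased null), 10,000 positions for assay-index convergence. The
demo pipeline (`run_pipeline()`) runs a 17 × 17-node elastography flow
and a 60-walker migration flow in a few seconds on one CPU.

## Known limitations

* Hertz only: no viscoelastic or finite-thickness (bottom-effect)
  corrections.
* Approach-curve semantics: fitting assumes the supplied indentation
  axis is from the approach segment; retract-curve adhesion is not
  modelled.
* Drift correction removes the ensemble-median motion; coordinated
  collective migration would be partially subtracted.
* The invasion index and the 50-slope sampling scheme are declared
  operationalizations where no standard definition exists.
* 2-D only; z-trajectories and 3-D substrate geometry are out of
  scope.
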