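---
title: "Dose gradient curves: model, estimators, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose gradient curves: model, estimators, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Stereotactic radiosurgery (SRS) and stereotactic ablative radiotherapy
(SABR) deliver ablative doses to small targets and depend on the dose
falling off steeply outside the target to spare adjacent organs at risk.
The standard evaluation tool, the cumulative dose-volume histogram (DVH),
is spatially blind: two plans with nearly identical DVHs near the
prescription can have very different fall-off behaviour. Conventional
single-number indices -- the Paddick conformity index (CI), the gradient
index (GI, the ratio of the half-prescription isodose volume to the
prescription isodose volume), and R50 -- each probe the distribution at
one or two dose levels, and the volume-ratio metrics among them are
strongly target-size-dependent.

The dose gradient curve (DGC) characterises fall-off as a *distance*.
For a family of nested isodose surfaces, the differential dose gradient
index of the shell between levels $d$ and $d + \Delta d$ is

$$\mathrm{dDGI}_d \;=\; \frac{V(d) - V(d+\Delta d)}
        {\tfrac12\,\bigl[S(d) + S(d+\Delta d)\bigr]},$$

where $V(d)$ and $S(d)$ are the volume and surface area enclosed by the
isodose surface at $d$. Dividing shell volume by mean shell surface area
gives the average physical distance, in mm, between the two surfaces.
Because the raw value scales with the step, $\mathrm{dDGI_N} =
\mathrm{dDGI}/\Delta d$ (mm/Gy) is reported alongside. The cumulative
index sums shells from a level $i$ up to the reference dose $D_0$
(the prescription by default),

$$\mathrm{cDGI}_i \;=\; \sum_{j=i}^{D_0-\Delta d} \mathrm{dDGI}_j,
  \qquad \mathrm{cDGI}_{D_0} = 0,$$

i.e. the total physical fall-off distance from the prescription isodose
surface down to level $i$. Dose levels are generated symmetrically
around the prescription so that $D_0$ is always an explicit calculation
point; both Gy and percent steps are supported.

The dDGI at the prescription is graded on a four-tier scale: Ideal
(< 3 mm, typical of small-volume SRS; the 3 mm anchor is the classic
optimum-gradient criterion of a fall-off from the prescription to the
half-prescription isodose within 3 mm), Good (3 to < 5 mm, typical
SBRT), Acceptable (5 to < 7 mm, larger targets or low-density tissue),
Poor (>= 7 mm, re-optimisation may be warranted). The published band
labels do not assign the endpoints; this package makes the bands
lower-inclusive, so exactly 3 mm grades Good.

## Estimators and numerical choices

**Volumes.** $V(d)$ is the count of voxels with dose at or above $d$
(inclusive threshold, matching "at or above") times the voxel volume.
Structure volumes are computed independently from the contours by the
shoelace formula per plane times the inter-slice thickness, with
even-odd parity so nested contours subtract as holes.

**Surface areas.** The default estimator extracts a triangulated
isosurface and sums exact triangle areas. Extraction is by marching
tetrahedra: each grid cell is split into six tetrahedra sharing the main
diagonal, crossing vertices are placed by linear interpolation along
tetrahedron edges, and each tetrahedron contributes one or two
triangles. This member of the marching-cubes family has no ambiguous
configurations, so the surface is always closed and consistent. The
field is virtually padded by one zero layer so regions touching the grid
edge close.

A consequential choice is *what* to extract from. Extracting at the 0.5
level of the *binary* isodose mask constrains every vertex to an edge
midpoint; on curved surfaces this produces a resolution-independent
lattice bias of several percent (about +8--9 % for spheres with cubic
marching, worse with tetrahedral decomposition). Extracting from the
*continuous dose field* at the isodose value itself uses sub-voxel
interpolation and is accurate to a fraction of a percent at clinical
grid spacings. The DGC pipeline therefore extracts $S(d)$ from the dose
field at level $d$; binary-mask extraction remains available through the
same function, with the bias documented. The alternative voxel-based
estimator counts exposed faces under 6-connectivity; its raw area
overestimates smooth surfaces by the Manhattan-surface factor
(1.5 for a sphere), and an optional multiplicative correction factor is
exposed (default 1.0, i.e. uncorrected) so users can emulate corrected
variants. Since surface area sits in the dDGI denominator, estimator
bias propagates inversely into dDGI -- a reason the surface method is
recorded in every output.

**DVHs.** Structure masks test voxel centres against the contour
polygons of the matching plane (nearest dose slice within half the
slice spacing) with even-odd parity; points on a contour edge count as
inside, so a contour drawn through voxel centres includes them. Doses
inside the mask are binned at 1 cGy; Dx metrics interpolate the
cumulative curve linearly (clamping at the curve ends with a flag), Vx
metrics interpolate on the dose axis, the mean is the trapezoidal
integral of the normalised cumulative curve, and max/min are the D2/D98
surrogates. No sub-voxel supersampling is performed; for structures
spanning only a few voxels this is a known small-structure bias.

**Prescription.** Precedence is user override > RT Plan
(`DoseReferenceSequence` target prescription, fractions from
`FractionGroupSequence`) > estimation as $\tfrac56 D_{max}$,
approximately the 83 % isodose prescription convention of SRS/SABR.
A plan file lacking a target prescription falls back to estimation with
a warning.

**Degenerate inputs.** Shells whose mean surface is zero yield NaN,
are flagged, and are excluded from the minimum-dDGI summary. Levels
above the prescription whose mask is empty terminate the table upward;
if the shell anchored at the prescription is unavailable the shell
below it is used, flagged `rx_shell = "below"`. Slice offsets must be
uniform within 0.01 mm, far below any clinical grid. Contours with
fewer than three vertices are rejected with a warning; ROIs entirely
outside the dose grid are flagged, never silently dropped.

## The synthetic phantom as oracle

Validation needs ground truth that DICOM test data cannot provide, so
the package generates spherical phantoms whose isodose geometry is
closed-form. A target of radius $r_0$ carries the prescription $d_0$ at
its surface and the dose falls off linearly at $g$ Gy/mm, so every
isodose radius is

$$r(d) = r_0 + \frac{d_0 - d}{g}, \qquad
  V(d) = \tfrac43 \pi r(d)^3, \qquad S(d) = 4\pi r(d)^2,$$

each shell's dDGI is $\Delta d / g$, the cumulative index at level $d$
is $(d_0 - d)/g$, and the gradient index obeys the cube law
$(1 + d_f/r_0)^3$ with $d_f = 0.5\,d_0/g$ the prescription-to-half-
prescription fall-off distance. A linear profile was chosen over
inverse-square or Gaussian fall-off precisely because it makes every
DGC quantity closed-form.

Two profile variants exist. The default continues the linear rise
inward through the target surface, plateauing only in a small core
(peak $d_0 + g\,r_0/2$), the shape of a clinical SRS plan prescribed to
a sub-maximum isodose; this keeps the closed forms valid above the
prescription too, so the shell anchored *at* the prescription always
exists. A `"plateau"` variant holds the dose at exactly $d_0$ inside
the target, exercising the fallback to the shell below the
prescription. Defaults emulate the clinical SRS setting: $d_0 = 13$ Gy,
$g = d_0/6$ (placing the 50 % isodose 3 mm outside the target), 1 mm
isotropic grids (0.5 mm in the tighter oracle runs).

Two practical points about lattice effects, both visible in the test
design. First, a sphere centred exactly on the voxel lattice is the
measure-zero worst case for voxelization error; oracle phantoms offset
the centre by a fixed sub-voxel amount, which is also what any real
patient geometry looks like. Second, the voxel-counted volume
difference across a shell much thinner than a voxel is
quantization-limited, so per-shell oracle checks use steps spanning
about two voxels of radial distance ($\Delta d = 2\,g\,\times$spacing),
while the cumulative index -- whose shell errors telescope -- is
checked at the default-style 5 % step. With these conditions the
implementation reproduces the closed forms to well under the test
tolerances (shells within 5 % of $\Delta d/g$, surfaces within 2 %,
volumes within 1 %, cumulative index within 5 %).

Multi-target phantoms (the voxelwise maximum of disjoint component
fields) keep additive closed forms while the analyzed isodose surfaces
stay disjoint, which is enforced as a precondition. What the generator
does *not* emulate: non-convex or concave target shapes, tissue
heterogeneity, dose calculation noise, and realistic OAR geometry. A
passing oracle suite therefore demonstrates correctness of the
geometric estimators and index algebra, not clinical realism of any
particular plan.

The DICOM writer emits the phantom as a standards-conformant RT Dose /
RT Structure Set / RT Plan triplet (16-bit dose quantized below 0.01 %
of the prescription), and the loader round-trips it within one scaling
quantum, so the same files exercise the full ingestion path. Output is
byte-deterministic given the spec and seed.

## Cohort statistics

Batch analysis assembles one record per case (target volume, dDGI at
Rx, minimum dDGI, cDGI at 50 % Rx, CI, GI, R50, grid spacing, step).
Correlations report Pearson r (t-transform p-values) and Spearman rho
(exact null distribution for n <= 30, large-sample approximation
above); no multiple-testing correction is applied, matching the
exploratory character of such analyses. Paired reproducibility uses the
symmetric mean absolute percentage difference
$\mathrm{mean}_i\,|x_i^{A}-x_i^{B}|/\bar x_i \times 100\%$. Volume
subgroup bands are lower-inclusive on the upper side (1.0 cc belongs to
the 1--3 cc band), mirroring the ">= 3 cc" labelling convention.

On sphere cohorts these utilities reproduce the central qualitative
findings exactly as designed: with a fixed fall-off slope, dDGI at the
prescription is nearly constant across target sizes while GI falls with
the cube law -- the geometric reason volume-ratio protocols need
size-stratified tolerance tables, and a physical-distance metric does
not; and with fixed geometry but varying slope, the conformity index is
constant while dDGI tracks $1/g$, showing gradient steepness and
conformity are independent axes of plan quality.

## Problem sizes and runtime

The test and validation phantoms use grids from about $40^3$ to $230^3$
voxels (0.5--1 mm spacing, target radii 6--50 mm), sizes at which the
complete oracle suite runs in well under a minute on one CPU; a full
single-plan analysis at clinical SRS scale (1 mm grid, 1 % steps)
completes in a few seconds, dominated by one isosurface extraction per
dose level.

## Known limitations

* Binary-mask isosurface areas carry the lattice bias described above;
  quantitative gradient reporting should use the dose-field extraction
  (the default).
* dDGI from shells much thinner than a voxel is quantization-noisy;
  report $\Delta d$ and grid spacing with every value (the outputs do)
  and compare plans only at matched settings.
* Structure masks are centre-sampled without supersampling, biasing
  metrics for structures a few voxels across.
* The DICOM layer reads Explicit VR Little Endian only, the transfer
  syntax it writes; compressed or implicit-VR objects are out of scope.
* No biologically effective dose conversion, no image registration, no
  multi-plan comparative scoring.
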