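---
title: "culmforce: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{culmforce: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culmforce)
```

# The scientific problem

Cereal lodging — shoots displaced from the vertical by buckling of the basal
internodes or by root failure — is resisted by culms whose vascular bundles
are numerous and inclined relative to the stem axis. Mechanically, an
inclined bundle behaves like a beam that converts part of a horizontal wind
load into an axial force along its own axis, deflecting stress out of the
attack plane and reducing the effective bending strain. `culmforce` packages
this picture end to end: synthetic MRI-like stem volumes, geometric
reconstruction, a voxel force-redistribution model, FTIR cell-wall
chemotyping, and the trait statistics used to compare resistant and prone
lines.

No raw imaging, spectral or genotype data from real stems are distributed or
required: every stage runs on the package's own generators, and every claim
a test makes is a claim about this synthetic world.

# Conventions

* Coordinates: right-handed, stem axis = +z, azimuth $\alpha$ from +x,
  counter-clockwise viewed from +z, in degrees; angular bins are half-open
  $[\alpha, \alpha + d\alpha)$; voxel indices are documented 0-based in
  formulas and 1-based in R accessors.
* **Incline** $\delta$ is measured from the stem cross-sectional
  ("orthogonal") plane: a vertical bundle has $\delta = 90°$.
  `incline_from_axis()` converts to the complementary from-axis tilt. The
  biology literature often says "more inclined" for bundles that deviate
  *more from the stem axis*; under the plane-referenced convention that
  means a *smaller* $\delta$. The resistant presets therefore have smaller
  $\delta$ (larger from-axis tilt) than the prone presets — the direction
  required for them to redistribute more axial force, which is the
  mechanical content of the resistant-vs-prone contrast.
* Lengths are millimetres; forces newtons; pressures N/m² (areas are
  converted mm² → m² where a pressure is applied).

# The synthetic stem

`stem_params()` describes a hollow culm (outer/inner wall radii `Ro`, `Ri`)
carrying an outer and an inner ring of vascular bundles with per-ring counts,
ring radii, a common bundle radius, and an incline distribution
$N(\mu_\delta, \sigma_\delta)$ clipped to $(0, 90]$.

**Helix-like centerlines.** Each bundle centerline advances, per z-step, by
$\Delta z \cot\delta$ horizontally in the local tangential direction. This
polygonal construction makes *every finite-difference step* have exactly
incline $\delta$, so the incline estimator is machine-exact on noiseless
generated fibres. An exactly circular helix sampled at finite steps cannot
have this property (chord-vs-arc bias of order $10^{-2}$ degrees at the
default 0.1 mm step); the cost is a slow outward radius creep, below 1 % of
the ring radius over the default 15 mm segment.

**One incline draw per ring.** Bundles on one ring share the ring's incline
draw. Giving each fibre its own draw gives each helix its own angular
velocity; on a dense ring (27 bundles at 1.62 mm radius) neighbouring
bundles then cross within a few millimetres of height, merging their
rasterized blobs and destroying both segmentability and fibre identity —
something real vasculature does not do. The incline standard deviation is
therefore realized *between* rings and replicate stems, not between
neighbouring fibres.

**Placement jitter.** Bundle azimuths are equally spaced plus Gaussian
jitter (sd 0.8° in all presets), clamped to the collision-free slack with a
clearance of 1.3 bundle radii so rasterized discs always remain separable.
Keeping the jitter below every ring's clamp makes the effective placement
noise identical across presets — important for the preset contrast below.
A genuinely impossible configuration (too many bundles for a ring) still
fails with a geometry error naming the colliding pair.

**Rasterization.** `rasterize_label_volume()` targets the MSME acquisition
geometry (168 × 168 × 26 voxels over 4.2 × 4.2 × 13 mm; 25 µm in-plane,
0.5 mm slices). A voxel is a bundle voxel if its center lies within the
bundle radius of a centerline (nearest centerline wins; exact ties go to the
outer ring, then the lower fibre index), else culm matrix if
$R_i \le r \le R_o$, else background. Labels: 0 background, 1 matrix,
2 inner bundle, 3 outer bundle. Volumes are written/read as NRRD (ascii or
raw encoding) — the one standard format for which this R installation needs
no external package; multi-page TIFF export was dropped for lack of any R
TIFF library here.

## Presets

| preset | Ro/Ri (mm) | OVB/IVB | $\delta$ (deg) |
|---|---|---|---|
| rye_resistant | 1.80 / 1.10 | 27 / 11 | 76 ± 3 |
| rye_prone     | 2.00 / 1.25 | 19 / 11 | 84 ± 2 |
| wheat_resistant | 2.05 / 1.15 | 32 / 14 | 78 ± 3 |
| wheat_prone     | 1.90 / 1.25 | 24 / 10 | 83 ± 2 |

Bundle counts are the rounded reported means for the rye contrast (outer
27 vs 19; inner ring comparable, set to 11 for both). The prone line's
reported basal internode diameter (4.4 ± 0.6 mm) exceeds the 4.2 mm imaging
field of view; its preset radius is trimmed to 2.0 mm (within the reported
spread) so the stem fits the acquisition geometry. No numeric incline values
are reported anywhere for either line, so the preset inclines are design
choices: they (a) give the resistant line the larger from-axis tilt, and
(b) keep the helical ring rotation per 0.5 mm slice below half the bundle
spacing, which is the identifiability limit of nearest-neighbour centerline
chaining (see below). Wheat presets are plausible stand-ins (both lines
semi-dwarf; resistant thicker-walled with more bundles) — no wheat numbers
are reported to anchor them.

# Geometry extraction

`extract_bundle_centerlines()` reduces each slice's connected components
(8-connectivity, via an igraph pixel-adjacency graph) to centroids and
chains them across slices by greedy nearest-neighbour matching. The linkage
threshold is 3× the per-slice drift of a 45° incline — tolerant to
rasterization jitter while rejecting implausible jumps. A chain may skip one
slice; a longer gap splits the fibre with a `broken-fibre` warning.
Single-slice blobs are discarded.

*Identifiability:* with per-slice ring rotation $\Delta z \cot\delta / R$
approaching half the angular bundle spacing, a bundle's own continuation and
its trailing neighbour become equidistant and chaining can swap identities
(counts survive — the matching stays one-to-one — but incline estimates
bias). At the default resolution this limits reliable incline recovery on a
27-bundle ring to roughly $\delta \gtrsim 72°$; the spec-level round-trip
invariant over $\delta \in [60°, 90°]$ is tested on sparser rings (8 + 4
bundles) where the ambiguity never arises.

`compute_incline()` uses the mean per-step horizontal drift per unit z:
$\delta = \arctan\!\big(1 / \overline{h}\big)$, returning 90° for zero
drift. It is exact on generated centerlines and within the stated 5° after
the full rasterize → extract round trip. Whether incline should be a
per-fibre mean or per-segment quantity is not fixed by any source; the
per-fibre mean tangent is implemented (alternatives would be
straightforward on the stored centerlines).

# The mechanics model

`build_cylindrical_grid()` discretizes the first `segment` (15 mm) of the
wall into $360/d\alpha \times n_r \times \mathrm{segment}/dz$ voxels —
108 000 at the defaults ($d\alpha = 1°$, $n_r = 20$ radial increments of
$dr = (R_o - R_i)/20$, $dz = 1$ mm). Matrix voxels carry the cylindrical
triad $(\hat r, \hat\alpha, \hat z)$; voxels within the bundle radius of a
centerline are fibre voxels whose major axis is the local fibre tangent.
Association is by centerline distance, so the grid works identically on
parametric and extracted geometry.

**Loading.** `surface_load()` assigns windward outer-surface voxels
$F_{in} = p \cdot A_{arc}\cos(\alpha - \alpha_{attack})$, directed
horizontally along azimuth $\alpha_{attack} - 180°$ (the attack blows *from*
$\alpha_{attack}$ *toward* the axis). The projected windward area integrates
to $2 R_o L$ for any azimuth (within 1 % at 1° bins), giving the total
default load $p \cdot 2 R_o L = 5.4\times10^{-5}$ N.

**Propagation.** Per $(\alpha, z)$ column the surface magnitude is passed
voxel-by-voxel radially inward with $|F_{in}| = |F_{out}|$ at every voxel.
Matrix voxels transmit the horizontal load unchanged — they never generate
an axial component. Fibre voxels retain the tangent component
$F_t = \mathbf F \cdot \hat t$, accumulate it (signed) into the warp field
at their $(\alpha, r)$ cell, and pass the orthogonal remainder
$\sqrt{|\mathbf F|^2 - F_t^2}$ inward. Magnitude is conserved in the
Pythagorean sense per column, $M_0^2 = \sum F_t^2 + M_{inner}^2$, checked to
$10^{-9}$ relative (measured $\sim 10^{-15}$). Two candidate readings of the
transport rule conflict in their degenerate cases: a literally radial
interior force vector would be *always perpendicular* to a helical fibre's
tangential drift, making the deflection identically zero at depth and the
model vacuous. The implemented reading (radial *traversal*, direction
preserved through matrix voxels) keeps the matrix-voxel "no axial force"
rule and makes the aligned-fibre deflection exactly
$|F_{in}|\cos\delta$. The warp field records deflected *force*, not
displacement — no stiffness is modelled anywhere: there is no constitutive
law, no Young's moduli, no composition dependence, deliberately.

**Per-fibre partitioning.** Each bundle is treated as a straight beam with
its characteristic $(\delta, \phi)$ (mean tangent; height variation is
ignored). For a horizontal impact $F_I$ (1 N) along azimuth
$\alpha - 180°$:

$$F_N = F_I \cos\delta \cos(\alpha - 180° - \phi), \qquad
  F_b = \sqrt{F_I^2 - F_N^2}.$$

$F_N > 0$ is stretching (force along the upward-canonicalized tangent),
$F_N < 0$ compression. `sweep_attack_angles()` evaluates
$\alpha = 1\ldots360°$ and averages $F_b/F_I$ (unsigned) and $F_N/F_I$
(signed) over fibres; `find_optimal_attack()` returns the angle maximizing
mean bending load (no source defines "optimal"; the mean absolute axial
criterion is available as an option; ties return the smallest angle).

## What a green preset contrast does and does not establish

For a *perfectly* rotationally symmetric bundle layout the mean $F_N(\alpha)$
curve is identically flat (the package tests this as a property), so any
amplitude in a synthetic stem comes from placement asymmetry — in real stems
that asymmetry is anatomical, here it is the (uniform, small) azimuthal
jitter. The resistant preset amplifies whatever asymmetry exists by its
larger $\cos\delta$; with identical jitter scales the expected amplitude
ratio is the $\cos\delta$ ratio ($\approx 2.3$), and individual stems vary.
`compare_presets()` therefore reports the *mean amplitude over 25 replicate
stems* (a protocol fixed before any measurement), where the ordering is
stable (measured ratio ≈ 1.7, ~4 combined-σ margin). A green contrast
establishes that the implementation amplifies asymmetry as
$\cos\delta$ predicts — not that any particular amplitude value is
biologically meaningful.

# FTIR chemotyping

`component_library()` builds reference spectra for cellulose, a xylan-type
hemicellulose, guaiacyl- and syringyl-type lignin, pectin, protein and lipid
as sums of Gaussian bands on a descending 1800→800 cm⁻¹ grid (2 cm⁻¹ step).
The band table (`inst/extdata/component_bands.csv`) versions the library; the
positions are plausible mid-IR cell-wall bands, *not* claims about true band
assignments in rye — absolute loadings are therefore not comparable to any
published values, only the machinery and relative contrasts are.

`preprocess_spectrum()` truncates to the retained window and applies vector
(L2) and/or min-max normalization; a constant spectrum has no min-max range
and is returned as zeros with a degenerate flag and warning.

`emsc_decompose()` solves ordinary least squares against
`[polynomial baseline | K]` (quadratic baseline by default, the EMSC
convention). A partial-least-squares variant would need a calibration
response that does not exist here; OLS against an explicit library is the
substituted design, recorded as a deviation. Negative loadings are reported
as-is and flagged — clipping would silently distort the derived ratios; a
Lawson–Hanson nonnegative fit is available behind `nonneg = TRUE` (the
baseline block stays unconstrained; the joint problem is solved exactly by
projecting the baseline out first). Derived ratios: lignin S/G, and the
xylan share of the hemicellulose-class loadings — with the default
single-hemicellulose library that share is 1 by construction and only
becomes informative with a richer user library. Interpolation onto the
library grid is linear and extrapolation is a hard error.

`pca_chemotype()` is centered PCA (SVD) with a deterministic sign convention
(largest-magnitude loading positive); duplicated-spectrum sets are flagged
degenerate rather than returning noise. `effect_screen()` applies Cohen's
*D* per component with the conventional classes.

# Trait statistics

* `compare_groups()`: Welch's t (unequal variances, Welch–Satterthwaite df)
  and Mann–Whitney. For $n_1 + n_2 \le 20$ the Mann–Whitney p-value is a
  symmetric-tail exact enumeration over all group assignments (ties handled
  by enumeration); above that, the normal approximation with tie and
  continuity corrections. Stars follow the `*` < 0.05, `**` < 0.01,
  `***` < 0.001 convention.
* `cohens_d()`: pooled-sd standardized difference (the classical estimator;
  no source states the variant used) with classes small > 0.2,
  medium > 0.5, strong > 0.8.
* `normality_check()`: moment skewness $g_1$ and excess kurtosis $g_2$; the
  non-normality flag $|g_1| > 1$ or $|g_2| > 2$ is a documented heuristic —
  the check is standard, the cutoffs are not.
* `heritability_h2()`: Mahmud–Kramer broad-sense heritability,
  $H^2 = (V_{F2} - \sqrt{V_{P1} V_{P2}}) / V_{F2}$, clipped to [0, 1] with a
  flag. The geometric-mean environmental variance is the cited estimator;
  the trait generator inverts it exactly
  ($V_G = V_E \cdot h^2 / (1 - h^2)$), so recovery of a target $H^2$ is a
  genuine identity check. Recovery to ±0.05 needs informative parental
  samples: at the default 16 plants per parent the environmental estimate
  alone has ~0.10 sd, so recovery tests use several hundred.
* `fold_change()`: ratio plus nearest-integer fold (13.7 / 1.7 → 8.06,
  "eightfold").
* `summarize_linkage_map()`: total length = sum of per-chromosome spans;
  mean inter-marker distance defaults to total/n\_markers — the convention
  that reproduces 783.8 cM / 1041 = 0.75 cM — with the per-gap convention
  (total/(n − k)) behind a flag, both documented because the reported
  arithmetic is ambiguous.
* The trait generator models additive inheritance only: F2 = midparent +
  $N(0, V_G)$ + $N(0, V_E)$. A dominance term is omitted because no
  magnitude for it is reported.

# Numerical choices

* Degree trigonometry uses `cospi`/`sinpi`, exact at multiples of 90°, so
  tie-breaks in `find_optimal_attack()` are deterministic.
* Conservation and closure tolerances are $10^{-9}$ relative; area
  integrals 1 % (discretization); round-trip incline 5°.
* All generators take explicit seeds, save and restore the session RNG
  state, and are bit-reproducible per seed.
* Error conditions are classed (`cf_parameter_error`, `cf_geometry_error`,
  `cf_degenerate_error`, …) so callers can branch without parsing messages.

# Known limitations

* No MR physics, no intensity-based segmentation: inputs are label volumes.
* The mechanics is force bookkeeping under stated constraints, not
  elasticity; no torsion, buckling or failure criteria; no aerodynamics.
* Fibre-incline variation within a ring is structurally limited by the
  non-crossing requirement (see above); the generator realizes incline
  spread between rings and stems.
* The component library is synthetic; only relative spectral contrasts are
  meaningful.
* QTL detection, interval mapping, LOD permutation and marker design are
  out of scope; only map summary arithmetic is provided.
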