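---
title: "Spatial mechanomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial mechanomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanomics)
```

# The problem

During bone fracture healing, the mechanical environment of the callus
regulates how cells form and resorb tissue. A spatial *mechanomics*
analysis links three layers measured at a single fracture site:

1. **Time-lapsed micro-CT morphometry** — registered weekly density
   volumes reveal, voxel by voxel, where bone was formed, maintained or
   resorbed, and yield the standard morphometric indices (BV/TV, bone
   formation and resorption rates, defect size).
2. **Voxel micro-finite-element (micro-FE) analysis** — each 10.5 µm
   voxel becomes one linear hexahedral element; simulated uniaxial
   compression maps the tissue-scale effective strain throughout the
   callus, and an adaptive rule individualizes the applied load.
3. **Spatial transcriptomics** — a 2D section carrying a grid of 55 µm
   capture spots is embedded into the 3D strain field; each spot
   inherits its local mean effective strain and a strain-region label,
   and expression statistics are stratified by strain.

This package implements the full pipeline, together with synthetic
generators that supply every stage with inputs whose ground truth is
known exactly. The in vivo datasets this kind of pipeline consumes are
small animal cohorts that are rarely publicly deposited, so the
package's tests are property-based: closed forms, independent oracles
and simulations with planted effects.

# Image processing and morphometry

Density volumes (mg HA/cm³) are smoothed with a truncated Gaussian
(default σ = 1.2 voxels, half-width 1 voxel). The kernel is normalized
to sum to one and, at image borders, renormalized over the voxels
actually present. This "no padding" convention preserves constant
images everywhere, which in turn makes thresholding of filtered
phantoms exact. Mineralized tissue is segmented at 395 mg HA/cm³; the
comparison is *inclusive* (a voxel exactly at the threshold is bone) —
the convention is stated explicitly because protocol descriptions in
the field usually leave strictness ambiguous.

Four non-overlapping volumes of interest partition the analysis region:
defect center (DC), defect periphery (DP), fracture cortex plus
medullary cavity (FC) and cortex periphery (FP). Their geometric
construction is study-specific and is treated as an *input* (a label
volume) that the package validates; only the synthetic phantom builds
VOIs itself.

Between two registered scans, each voxel is classified as formation
(bone at the later scan only), quiescence (both) or resorption (earlier
only). The morphometric indices follow the field's normalization
convention: bone volumes are divided by the *central* VOI volumes that
represent the intact-bone total volume, i.e. DC/DC, DP/DC, FC/FC,
FP/FC, and reported in percent. Formation and resorption rates divide
the formation/resorption voxel counts by the same normalizers and by
the scan interval in days; resorption rates are reported ≤ 0. The same
normalizers are used for BFR/BRR as for BV/TV — the literature does not
spell out the BFR/BRR denominator, and adopting the BV/TV normalizer is
the natural reading. Rates are attributed to the later scan of each
interval. Defect size is h = 2·DC/(CSA_P + CSA_D) with DC the baseline
defect volume and CSA the adjacent proximal/distal cortical
cross-sections.

# The micro-FE model

Every voxel is converted to an 8-node trilinear hexahedral element.
Bone voxels receive a Young's modulus from a linear density-to-modulus
calibration E = k·ρ; the slope is a user input (default 1/60 GPa per
mg HA/cm³, which maps 1200 mg HA/cm³ cortical tissue to 20 GPa) because
the appropriate calibration depends on the scanner and reconstruction.
Soft tissue is assigned 0.003 GPa — small but strictly positive, so the
stiffness matrix stays positive definite. Soft-tissue voxels on the
top and bottom slices are replaced by 20 GPa plate material to suppress
edge artifacts of the marrow cavity under the prescribed displacement.
Poisson's ratio is a single global value, default 0.3 and configurable;
the analytic test cases use ν = 0 where the closed form requires it.

Boundary conditions follow the uniaxial protocol literally: all
bottom-slice nodes are fixed in three directions; top-slice nodes are
prescribed an axial displacement of 1% of model height (compression)
with free in-plane motion. Because all elements are congruent cubes,
one unit stiffness matrix (2×2×2 Gauss quadrature) is scaled per
element by E·h. The assembled sparse system is solved by supernodal
sparse Cholesky factorization — a direct method, exact to factorization
accuracy, which at the problem sizes this package targets (up to a few
hundred thousand degrees of freedom) is faster and simpler than an
iterative solver; the `tol` argument is retained in the interface but
the direct solve does not iterate.

Per element, the strain tensor is evaluated once at the centroid from
the trilinear shape-function gradients, and converted to the *effective
strain* EFF = √(2U/E) with U the strain-energy density — a scalar that
combines volumetric and deviatoric contributions. For a uniform bar
with ν = 0 under 1% compression this gives exactly 10,000 µε, the
closed form used in the test suite. Strains are reported in µε.

The resultant force is the sum of axial nodal reactions over the top
surface. Linearity makes rescaling exact:
ε_actual = (F_applied / F_resultant) · ε_simulation, element-wise, and
re-scaling replaces (never compounds) a previous scaling.

**Load optimization.** The applied force is chosen so that the median
effective strain over *bone* elements reaches a target, clamped to the
protocol bounds (default 8–16 N). A safety rule then derates the load:
while more than 100 bone voxels exceed 10,000 µε at the current force,
the force is reduced by 1 N (as long as the clamp permits). Two
documented choices: overstrain counting is restricted to bone-mask
elements (the protocol's wording, "voxels", does not qualify), and the
1 N reduction is iterated to a fixed point — protocol descriptions
read as a single reduction, but iterating is the safe generalization
and a `singleStep = TRUE` mode restores the literal behavior.

# Spot embedding and strain regions

The histological section's pose inside the volume is a user-supplied
rigid transform (4×4 matrix, µm) with a section thickness (default
5 µm); automated 2D-to-3D registration is deliberately out of scope —
in practice the alignment is performed visually. Each spot's footprint
is a disk of radius diameter/2 (55 µm spots → 27.5 µm) around its
center in the section plane, extruded through the thickness. The
per-spot strain is the arithmetic mean of ε_actual over bone elements
whose *centers* fall inside the footprint: with 10.5 µm elements and
55 µm spots, center-in-footprint membership errs by at most a thin
boundary shell, and partial-volume weighting would complicate the
enumeration oracle used to test it. Spots without any bone element in
their footprint are *unassigned* rather than given zero strain — the
analysis concerns bone spots.

Strain regions follow the 500/1000 µε convention: low < 500 µε,
high > 1000 µε, reference in between. The conventional inequalities
are strict on both sides, which leaves the boundary values unclassified;
this package folds exact boundary values into the reference region so
that the three labels partition every assigned spot.

Spot quality control retains spots with ≥ 500 UMIs and ≥ 250 detected
genes (inclusive thresholds). Per-region medians of UMI and gene counts
use the standard even-count convention.

# Expression statistics

The expression computations are authored in this package rather than
delegated, so that each step has an explicit, testable definition;
standard implementations (DESeq2) serve as independent cross-checks in
the test suite, never as the implementation.

**Normalization.** Median-of-ratios size factors against a
geometric-mean pseudo-reference over genes expressed in every spot,
rescaled to geometric mean one. A pool-and-deconvolve variant
(sliding pools over spots ordered by library size, two window widths to
keep the design full-rank, least-squares deconvolution) is available
for sparser data; it is approximate and held to a looser tolerance in
the tests.

**Differential expression.** Per eligible gene, a negative-binomial GLM
with log link and size-factor offsets: full model intercept + group,
null model intercept. Gene-wise dispersions are estimated by profile
maximum likelihood and shrunk on the log scale toward a lowess trend of
log-dispersion versus log-mean, with prior weight d0/(d0 + df) and
d0 = 8 prior degrees of freedom — enough to stabilize small samples
while leaving well-estimated dispersions nearly untouched. The p value
is χ²(1) on twice the log-likelihood difference; BH adjustment runs
across eligible genes; a DEG requires FDR < 0.05 *and*
|log2FC| > 0.5. Fold changes are raw fitted-mean ratios — no shrinkage
— the convention in strain-stratified analyses. The eligibility filter
(total count ≥ 10 and detection in ≥ 5% of spots, both inclusive) is a
mild default standing in for an unstated data-driven filter; both
thresholds are exposed.

**CV ranking.** Within one region's spots, genes detected in at least
half the spots are ranked *ascending* by CV = sd/mean of normalized
expression: a low CV marks consistently expressed, functionally
significant genes, which matches the canonical high-abundance markers
such rankings surface. Ties break by higher mean, then gene id, for
determinism. The direction is configurable in spirit (the ranking table
carries mean, sd and CV, so a descending view is a `rev()` away).

**Gene-set scoring.** Per gene, the log2 ratio of group mean normalized
expression with a pseudo-count (default 0.5) guarding zero means; per
set, a two-sample t statistic of member versus non-member ratios with
two-sided p and BH adjustment across sets — the "mean expression
one-on-one comparison" style of GAGE. Sets with fewer than two present
genes are skipped.

# Synthetic generators

The phantom is an idealized cortical tube with a mid-shaft defect gap
that fills with callus on a per-frame schedule (and can clear a core,
modelling resorption). It is *not* an anatomically realistic femur:
its purpose is exact, cheap ground truth — the generator records the
precise voxel sets of formation and resorption between frames, the VOI
labels, and densities that sit safely on either side of the
segmentation threshold. Striped strain fields put known region labels
on axial bands. The count simulator draws NB counts with
variance = mean + φ·mean² (the same parameterization the DE fitter
uses), log-normal baselines and size factors, and a planted-effect
table that shifts chosen genes in one region's spots; a single seed
makes every draw bit-for-bit reproducible.

What the generators do **not** emulate: partial-volume and
beam-hardening artifacts, registration error between frames,
anatomically realistic trabecular architecture, spatial correlation of
expression between neighboring spots, zero-inflation beyond NB, or
section deformation. Passing tests therefore demonstrate correctness
of the computations under the stated statistical model, not robustness
to those real-data effects.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for interactive runs: the
analytic FE check uses an 8×8×8 cuboid; dense-oracle comparisons use
random heterogeneous meshes up to 6³ elements (where a dense direct
solve is exact and fast); DE calibration uses 2,000 genes across
40 + 40 spots; and the end-to-end chain runs a 20×20×24 phantom
(~31,000 degrees of freedom) with a dense 25 µm spot grid so that all
three strain regions are populated on a small section. These sizes are
the package's own choices for a fast, deterministic suite; the
implementation itself handles the 300×300×186 crops used in practice
given memory proportional to the mesh.

Other numerical conventions: voxel centers sit at
origin + (index − 0.5)·spacing (1-based indexing, third axis axial);
internal FE units are mm/MPa/N (inputs in µm and GPa); degenerate
inputs (zero resultant force, zero-volume normalizing VOI, empty
regions, sets with < 2 genes) raise errors rather than returning
silent NaNs; and rank ties and FDR computations are deterministic under
permutation of gene order.

# Known limitations

* The density-to-modulus calibration and the VOI geometry are inputs;
  the package validates but cannot invent them.
* The solver is direct; meshes far beyond ~10⁶ elements would need an
  iterative or out-of-core solver.
* The NB LRT assumes two groups; multi-factor designs are out of scope.
* Strain-region boundary handling (boundaries → reference) and the CV
  ranking direction are documented conventions where common practice
  is ambiguous; both are isolated behind single functions so a
  different convention is a one-line change.
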