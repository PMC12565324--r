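---
title: "Discovering nasal-cavity morphotypes with sliding semi-landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering nasal-cavity morphotypes with sliding semi-landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphocavity)
```

## The problem

The segment of the nasal cavity between the nasal valve and the anterior
olfactory region is the bottleneck that intranasally delivered drug
particles must cross to reach the olfactory mucosa. Its 3D shape varies
substantially between individuals, and that variation plausibly
modulates how accessible the olfactory region is. morphocavity
implements a landmark-based geometric-morphometrics pipeline that turns
a cohort of unilateral cavity surface meshes into (i) a small number of
recurring shape classes ("morphotypes") and (ii) statistical maps of
where and along which axis those classes differ.

Throughout, the coordinate convention is: X medio-lateral (the sagittal
plane is x = 0, so mirroring a left cavity to the right-side convention
negates X), Y antero-posterior, Z infero-superior, origin at the
anterior-inferior corner of the region of interest. Units are mm.

## Semi-landmark correspondence

Ten fixed anatomical landmarks (anterior origin, vestibule front, valve
top and bottom, front/back of the olfactory roof, choana top, lowest
septal point, posterior point of the inferior cutting plane, anterior
inferior-meatus point) are assumed digitized on every specimen. The 200
semi-landmarks — two 10 x 10 patches covering the anterior and
posterior bands of the region — exist only on the template and are
transferred to each specimen:

1. a 3D thin-plate spline interpolating the 10 fixed-landmark pairs
   warps the template semi-landmarks near the specimen surface;
2. each warped point is projected to its exact closest surface point
   (point-triangle projection over all triangles, implemented in C++);
3. the projected points then *slide* tangentially to minimize the
   bending energy of the template-to-specimen TPS, re-projecting after
   every step.

### TPS and bending energy

For control points $p_i$ the 3D TPS is
$f(x) = A^\top[1, x] + \sum_i W_i\,U(\lVert x - p_i\rVert)$ with kernel
$U(r) = r$, solving the bordered system $KW + PA = Y$, $P^\top W = 0$
($K_{ij} = \lVert p_i - p_j \rVert$, $P = [1 \mid p]$). The bending
energy of target $Y$ is the quadratic form $\mathrm{tr}(Y^\top B Y)$.

A numerical subtlety: in 3D the kernel $r$ is conditionally *negative*
definite (unlike the 2D kernel $r^2\log r$), so the upper-left block of
the inverse bordered matrix is negative semidefinite. `morphocavity`
defines $B$ as the *negated* block, the standard 3D convention, giving a
positive semidefinite form whose null space is exactly the affine maps
($B\,[1\mid p] = 0$, rank $\le k-4$) and which scales as $1/s$ when the
source is scaled by $s$. The warp coefficients themselves are
unaffected.

### Sliding

Sliding minimizes $\mathrm{vec}(Y)^\top (I_3 \otimes B)\,\mathrm{vec}(Y)$
over tangential displacements of the 200 semi-landmarks (two orthonormal
tangent directions per point, from area-weighted vertex/edge normals;
fixed landmarks contribute no degrees of freedom and never move). $B$ is
built once from the full 210-point template configuration, so the fixed
anatomy constrains the deformation. Each iteration solves the reduced
normal equations (a 400 x 400 system, assembled with the Khatri-Rao-type
identity $T^\top(I_3\otimes B)T = B[\mathrm{ii},\mathrm{ii}] \circ DD^\top$,
ridge $10^{-10}\,\mathrm{tr}$ for safety), displaces, re-projects onto the
mesh, and accepts only energy-decreasing steps, halving the step up to 5
times otherwise. Defaults: relative-decrease tolerance $10^{-6}$, at most
10 iterations. The sliding literature offers no canonical termination
rule; only the energy-decrease contract is promised, and the recorded
trace is non-increasing by construction. The sliding reference is the
template (an optional second pass against the GPA mean exists,
`slide.reference = "mean"`, off by default, matching the
template-to-patient transfer design).

## Alignment and testing

GPA centers every configuration, scales it to unit centroid size and
iteratively rotates to the running mean (reflections disallowed because
all specimens are pre-mirrored to the right-side convention). The
bilateral-dimorphism test is a permutation Procrustes ANOVA: Goodall's
$F$ from sums of squared distances to side means versus the grand mean,
with $p = (\#\{F^{perm} \ge F\} + 1)/(n_{perm}+1)$ over label
permutations (999 by default, seeded). The pipeline pools sides only
when this test is non-significant; otherwise it warns and attaches
per-side analyses (the underlying study design expects symmetry, so this
branch is an extension). A sensitivity re-run excludes specimens whose
patient lacks the matching side.

PCA runs directly on the aligned coordinates, not on tangent-space
projections: shape variation here is small relative to the curvature of
shape space, so the difference is negligible (a config flag is reserved
but off). Components are retained by the geometric elbow rule: the scree
point with maximum perpendicular distance to the chord joining the first
and last points, ties to the smaller index, flat spectra defaulting to
1. Resampling stability (subsets of increasing size, 100 replicates
each, without replacement) reports the mean and sd of the cumulative
variance of the first 5 PCs, the diagnostic used to argue the cohort is
large enough for stable PCA.

## Clustering and characterization

Ward (D2) clustering on the retained scores; the cluster count maximizes
the inertia-gain ratio $\Delta W(k)/\Delta W(k+1)$ over a scan range
(default 2..10), with a `low_confidence` flag when the best ratio is
below 1.5 — for unimodal data every split gains about equally, and no
partition deserves confidence. A reduced three-index battery
(Calinski-Harabasz, mean silhouette, inertia gain) provides a
verification vote; the full 30-index battery of the NbClust tradition is
deliberately out of scope. Optional k-means consolidation after the tree
cut exists but is off by default.

Morphotypes are characterized per landmark: one-way MANOVA on (x, y, z)
with Pillai's trace (robust to covariance heterogeneity; Wilks is a
summary option of the underlying fit), per-axis one-way ANOVA, and
Tukey-Kramer HSD per cluster pair with the studentized-range
distribution. The reported sign of a significant pair difference is the
sign of mean(A) − mean(B) on that axis — positive meaning cluster A lies
further from the origin. No multiple-testing correction is applied by
default across the 200 landmarks (raw significance is the convention
this analysis reports); Benjamini-Hochberg is available via
`stats.p_adjust = "BH"`. Digitization agreement uses Lin's CCC with 1/n
moments, pooled across specimens, landmarks and axes per session pair
(the pooling convention is not standardized; a per-landmark CCC table is
emitted alongside). Cohort demographics use Pearson chi-square without
continuity correction (side, sex) and Kruskal-Wallis with tie correction
(age); patients with missing demographics are dropped only from the
affected statistic.

## The synthetic generator: what it emulates, what it does not

No patient data ship with the package, so every stage is exercised on a
parametric stand-in. The surface is a smooth half-shell
$S(u,v)$ over $[0,1]^2$:

$$x = s\,[w_i(1-v) + (w_a(1-u) + w_p u)v]\sin(\pi v),\quad
  y = s\,[d\,u - c(1-u)^2\sin(\pi v)],\quad z = s\,H\,v,\ H = 40$$

with anterior width $w_a$, posterior-superior width $w_p$, inferior
width $w_i$, depth $d$, frontal-edge curvature $c$ and global size $s$.
Defaults (10, 12, 8, 50, 6, 1 mm) give a cavity of realistic adult
proportions (≈50 mm deep, ≈40 mm high, 8–14 mm half-width). Landmark
anchors sit at parametric coordinates that are multiples of 0.05, so
with the default resolution (20 grid cells per side, a multiple of 20)
they coincide with mesh vertices and are exactly on-surface; refining
the mesh does not move them.

The default population (45 patients x 2 sides = 90 cavities) encodes
three latent morphotypes in proportions 0.25/0.55/0.20, mirroring the
published cluster sizes: cluster 1 widest posterior-superior
($w_p$ = 14 vs 11.5) and anterior ($w_a$ = 12 > 10 > 8), shallowest
($d$ = 46 < 50 < 54) with the flattest frontal edge ($c$ = 4.5);
cluster 3 narrowest, deepest, most curved ($c$ = 7.5); cluster 2
intermediate with the widest inferior band ($w_i$ = 10). Within-cluster
parameter sd (0.5 mm widths/curvature, 1 mm depth) keeps between-cluster
gaps at ≥ 3 within-sd. Digitization noise is iid Gaussian, sd 0.3 mm, on
landmark coordinates only — the mesh stays exact so projection
contracts stay testable; because a real operator clicks on the rendered
surface, the noisy fixed landmarks are re-projected onto the mesh
(`digitized_fixed`) before entering the transfer. Each side inherits the
patient's latent morphotype with probability 0.75 (`rho_pair`),
reproducing the mixed left-right pairs seen in real cohorts; sex and age
are drawn independently of cluster.

What a green test does *not* establish: the generator is smooth,
single-sheeted and turbinate-free, its deformations live in a
6-parameter family, and noise is isotropic — real segmented cavities
have branching meatus geometry, segmentation artifacts, anisotropic
digitization error and template bias. Recovery of the synthetic
morphotypes (ARI ≥ 0.9) validates the pipeline's mechanics, not the
clinical claim that three morphotypes exist.

## Numerical choices and edge cases

* Vertex deduplication at $10^{-9}$ mm (STL repeats facet corners);
  zero-area triangles dropped at load.
* Closest-point ties across triangles resolve to the lowest triangle
  index; vertex/edge feet use area-weighted incident-face normals.
* TPS preconditions: k ≥ 4, no coincident points within $10^{-9}$ mm
  (reported by index pair), not all coplanar; rcond below $10^{-12}$
  warns.
* GPA converges on mean change $< 10^{-10}$ (cap 100 iterations);
  degenerate zero-size configurations abort with the specimen id.
* The elbow rule on the stepped spectrum (0.5, 0.3, 0.05, ...) selects 3
  — the chord-distance maximum — and 1 on flat spectra.
* Permutation p-values are never 0: $(b+1)/(n_{perm}+1)$.
* Percentages in cohort tables round to 1 decimal, half away from zero
  (11/73 → 15.1), matching how published tables print.
* Reports are byte-deterministic for a fixed config and seed; paths are
  excluded from the serialized config.

## Known limitations

* Tangent-plane (2-dof) sliding only; curve (1-dof) semi-landmarks and
  landmark-free correspondence are out of scope.
* Bit-compatibility with proprietary digitization software is not
  promised — only the bending-energy-decrease contract.
* The side-significant branch (per-side analysis) is an extension with
  no published reference behavior.
* Mesh repair beyond degenerate-triangle removal, CT segmentation and
  CFD are out of scope.
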