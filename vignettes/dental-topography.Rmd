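---
title: "Quantifying molar crown shape and inferring diet with dentopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying molar crown shape and inferring diet with dentopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentopo)
```

## The problem

The shape of a mammal's molar crown reflects what it eats: insectivores carry
tall, sharp cusps; folivores shearing crests; frugivores and hard-object
feeders low, blunt crowns. Dental topographic metrics (DTMs) quantify this
without requiring homologous landmarks, so crowns of distantly related
mammals — say marsupials and primates — can be compared on one scale, and the
diet of extinct species can be inferred from classifiers trained on living
ones. `dentopo` implements the full chain on triangulated surface meshes of
single lower molars: mesh conditioning, seven 3D/size metrics plus a 2D
trigonid-talonid height index, and equal-prior quadratic discriminant
classification with leave-one-out and clade-based cross-validation.

## The metrics

Let the crown be an oriented triangle mesh with +z occlusal, +x mesial, +y
buccal.

**Relief index (RFI).** $\mathrm{RFI} = \ln\big(\sqrt{A_{3D}} /
\sqrt{A_{2D}}\big)$, where $A_{3D}$ is the 3D crown area and $A_{2D}$ the
area of the occlusal (z = 0) outline. A flat patch has RFI 0, a hemisphere
$\ln\sqrt2 \approx 0.3466$; taller, steeper crowns score higher. The outline
is an alpha-shape polygon of the projected vertices; in `alpha = "auto"` mode
the smallest alpha on a 64-point log grid between 0.01x and 10x the median
projected edge length whose complex is a single simple hole-free polygon
carrying every projected vertex is chosen, with the convex hull as a logged
fallback. The natural log of the outline area (lnOA) doubles as the size
proxy; under uniform scaling by $s$ it shifts by exactly $2\ln s$ while all
shape metrics are scale-free.

**Dirichlet normal energy (DNE).** The integral of the squared variation of
the unit-normal field, $\int (k_1^2 + k_2^2)\,dA$ for a smooth surface. Per
face, the energy density is $e(p) = \mathrm{tr}(G^{-1}H)$ computed from the
first fundamental form of the embedding and the corresponding form of the
angle-weighted vertex-normal field; DNE $= \sum e(p)a(p)$. Faces on an open
boundary are excluded by default (cropped crowns have arbitrary cut edges),
as is the top 0.1% of faces by energy-times-area (spike outliers). A closed
sphere gives $8\pi$ at any radius; this is the package's primary geometry
oracle. *Convex DNE* restricts the sum to faces whose discrete
mean-curvature sign (divergence of neighbour normals along the surface;
ties count as convex) marks them as outward-curving — the cutting surfaces.

**ariaDNE and its CV.** A bandwidth-controlled variant robust to meshing
artefacts: the mesh is rescaled to unit surface area, and at each vertex a
weighted least-squares quadric is fitted over all vertices within the
Gaussian kernel $w_{ij} = \exp(-\lVert v_i - v_j\rVert^2/\varepsilon^2)$;
the per-vertex density is the sum of squared principal curvatures of that
quadric, and the scalar is the barycentric-area-weighted sum. The default
bandwidth $\varepsilon = 0.08$ (as a fraction of the square root of crown
area) sits near the upper end of the recommended 0.04–0.1 range, so large
structures dominate and fine texture is ignored; values outside the range
are computed with a warning. The coefficient of variation of the density
field (area-weighted SD / mean) is a separate metric. On smooth crowns DNE
and ariaDNE agree closely (within a few percent in our tests); on crowns
with creases or noise they deliberately diverge, ariaDNE being the
band-limited reading.

**OPCR.** Faces are binned by normal azimuth into eight 45° sectors
(near-vertical normals — horizontal component below 1e-4 — are "flat" and
excluded); edge-connected same-sector runs of at least 3 faces count as
patches; the patch count is averaged over eight rotations of the binning
frame in 5.625° steps. A single radially symmetric cusp scores exactly 8,
one patch per sector.

**TriTaHI.** On the lingual silhouette (projection onto the x–z plane), a
straight baseline joins the mesial and distal cervical endpoints;
$\mathrm{TriTaHI} = (H_{tri} - H_{tal})/L_{max}$ with heights measured
perpendicular to the (infinite) baseline line and the maximal molar length
parallel to it. Positive values mean a taller trigonid. Endpoints are
auto-detected as the lowest-z projected points within the mesial-most and
distal-most 15% of the x extent (lowest-x tie-break, with a warning), but
manually supplied endpoints always take precedence, since on real specimens
the cervical junction is an operator's judgement. The trigonid/talonid
division defaults to the midpoint of the maximal length (fraction 0.5
measured from the distal end) — the published workflow places this division
by hand in an image tool and does not state a rule, so the default is a
deterministic stand-in with a per-specimen override. Because region height
maxima are attained on the outline, heights are computed over all projected
vertices, which is equivalent and robust to outline discretisation.

## Mesh conditioning

Real crowns arrive as cropped, manually oriented meshes of wildly varying
resolution. The conditioning chain mirrors standard practice:

1. `cleanAndCenter()` — drop duplicate faces and all but the largest
   connected component, prune unused vertices, translate the centroid to the
   origin.
2. `simplifyMesh()` — quadric edge-collapse decimation to a fixed budget of
   10,000 triangles (within two), with Garland–Heckbert boundary-constraint
   planes so open cervical margins do not drift; meshes already at or below
   the budget are returned unchanged with a warning, the treatment
   low-resolution museum scans receive. Area is preserved to well under 2%
   and the bounding box to under 1% at this budget.
3. `smoothHCL()` — HC Laplacian smoothing: uniform-weight Laplacian
   averaging followed by the HC back-projection correction (factors
   $\alpha = 0$, $\beta = 0.5$), which suppresses the volume shrinkage of
   plain Laplacian smoothing (enclosed volume changes by far less than 1%
   per pass on closed meshes). One pass is the default, matching a protocol
   that invokes the operation once; the count is configurable because the
   upstream protocol does not state it. Open-boundary vertices are anchored
   so the cervical rim stays put; flat interior regions are exact fixed
   points.

Orientation is accepted as given (`oriented` flag); `orientOcclusally()`
offers a principal-axes heuristic but is explicitly marked as such and does
not resolve the mesial direction.

## The classifier

Diet classification uses quadratic discriminant analysis on species means
(pooling m2 and m3 of a specimen as separate observations — note this
double-weights two-tooth specimens). Per class: the sample mean, the
unbiased covariance, and a prior; priors are **equal** by default, because
comparative samples are unbalanced by collection history, not by ecology.
Prediction maximises
$\delta_k(x) = -\tfrac12\ln\lvert\Sigma_k\rvert - \tfrac12 (x-\mu_k)^\top
\Sigma_k^{-1}(x-\mu_k) + \ln\pi_k$, with ties broken by lexicographic label
order; posteriors are the softmax of $\delta$. No covariance regularisation
is applied by default: a class with $n_k \le p$ raises a loud singularity
error naming the class, and the analysis-level remedy is to exclude the
category (an optional ridge exists but defaults off). Validation modes:

* `looAccuracy()` — leave-one-out: each row predicted from a model fitted
  on the others (exactly *n* fits, deterministic).
* `crossCladeValidate()` — fit on one clade, predict the other, and score
  **shared categories only**: test rows whose true category exists in the
  training set. The full confusion table, including non-shared true
  categories, is returned for inspection.

In tests the classifier is checked two independent ways: against a
brute-force per-class Gaussian density oracle (direct `solve`/`det`, no
discriminant shortcut), exactly, and against `MASS::qda` with matching
priors, both plain and under leave-one-out.

## Gated univariate comparisons

The univariate procedures reproduce a normality-gated testing protocol: a
Shapiro–Wilk gate at $\alpha = 0.05$ (per group for paired and two-sample
comparisons, on ANOVA residuals for multi-group ones) selects paired t vs
Wilcoxon signed-rank, Welch t vs Wilcoxon rank-sum, and one-way ANOVA vs
Kruskal–Wallis; a significant omnibus test triggers the matching post-hoc
(Tukey HSD after ANOVA, Dunn's rank test after Kruskal–Wallis). Dunn
p-values are reported both unadjusted and Bonferroni-adjusted, since the
adjustment convention varies across toolchains; the display default is
unadjusted. Wilcoxon procedures use exact null distributions up to n = 25
and the continuity-corrected normal approximation above. Groups of n = 1
are excluded with a warning (the treatment a single-pair category receives).
`varianceHomogeneity()` is the mean-centred Levene preflight that motivates
QDA over LDA, and `pcaScores()` is correlation-matrix (unit-variance) PCA
for visualisation. Every result records which branch fired. Seeded
calibration suites verify type-I rates of 5% ± 2% at $\alpha = 0.05$.

## Synthetic data: what it emulates and what it does not

Two generators make the whole pipeline testable without museum downloads.

`generateTooth()` builds Gaussian-bump height fields
$z(x,y) = \sum_i h_i \exp(-((x-x_i)^2 + (y-y_i)^2)/2\sigma_i^2)$ on a
triangulated rectangular footprint with vertical side walls down to the
cervical plane. Height fields with walls have open boundaries like cropped
real molars — deliberately, so DNE's boundary exclusion is exercised — and
their generator parameters drive the metrics monotonically (sharpness →
DNE/ariaDNE, height → RFI, cusp count → OPCR), which grounds the
property-based tests. Named presets (`insectivore-sharp-v1`,
`folivore-blunt-v1`, `dasyurid-v1`) pin the qualitative crown types used in
tests to versioned parameter sets: the sharp preset lands above the
RFI > 0.56 high-relief band and the dasyurid-like preset above the
TriTaHI > 0.26 tall-trigonid band. These crowns are not anatomically
tribosphenic — no cristids, no wear facets, no enamel texture — so passing
geometry tests demonstrates correctness of the operators, not realism of the
shapes.

`generateFeatureTable()` draws per-diet multivariate normal feature vectors
over {RFI, ariaDNE, lnOA, TriTaHI}. The preset class means encode the
qualitative ordering seen across diets in comparative samples — faunivores
and folivores large (high lnOA), faunivores high RFI and TriTaHI, folivores
low TriTaHI, insectivores and frugivore-insectivores small with high
curvature — with per-feature SDs (0.06 RFI, 0.008 ariaDNE, 0.45 lnOA,
0.07 TriTaHI) chosen to resemble the within-diet spread of real tables. The
`primate-v1` preset shifts TriTaHI down by a constant 0.12 within matched
diets (reversed for folivores), the clade-offset phenomenon; `separation`
rescales class-mean deviations (0 collapses all classes to one
distribution), and `tritahi_shift` injects an explicit offset for controlled
experiments. Real specimen tables have non-Gaussian, correlated features
and phylogenetic structure; the generator's diagonal-covariance normals test
the classifier's machinery and the direction of the clade-offset effect,
not field accuracy levels.

With these conditions the package reproduces the headline qualitative
finding directionally: adding a between-clade TriTaHI offset to otherwise
matched diet distributions lowers cross-clade shared-category accuracy while
leaving within-clade leave-one-out accuracy exactly unchanged (a constant
shift cannot move within-clade decision boundaries).

## Numerical choices and degenerate inputs

* Faces are 1-based integer triples internally (the R convention); PLY/OFF's
  0-based and OBJ's 1-based conventions are translated at the file boundary.
  I/O is lossless: no welding or de-duplication at read time.
* Vertex normals are angle-weighted face-normal averages — the standard
  choice for curvature estimation on irregular meshes.
* Convexity ties ($|\kappa| <$ 1e-12) count as convex; degenerate metric
  tensors (near-zero first-fundamental determinant) contribute zero energy.
* The ariaDNE kernel support is truncated at $4\varepsilon$ (weight
  $< 10^{-7}$); a vertex with fewer than 6 support points raises a
  bandwidth error naming the vertex rather than fitting an underdetermined
  quadric.
* Alpha-shape qualification is exact: one edge-connected component, Euler
  characteristic of a disc, boundary a simple cycle, every projected vertex
  carried. Collinear projections raise a degenerate-input error.
* Decimation refuses nothing but targets below 4 faces; collapses that
  would flip a surviving face normal or violate the edge link condition are
  skipped.
* All-zero paired differences report p = 1 with a warning; a constant
  sample is treated as failing the normality gate (Shapiro–Wilk is
  undefined there).
* Problem sizes in the test-suite and acceptance script — 10k-face spheres,
  ~12k-face hemispheres, crowns of 5–20k faces, 100–200 seeded classifier
  replicates — were chosen so each oracle's discretisation error sits an
  order of magnitude inside its asserted tolerance while the whole suite
  runs in a few minutes on one CPU.

## Known limitations

* The mesial (+x) direction and occlusal orientation must be supplied for
  real specimens; the built-in orientation helper is a heuristic.
* The trigonid/talonid split is positional (default 0.5 of molar length),
  not homology-aware; specimens with strongly mesial or distal cusp
  placement may need a per-specimen split or manual baseline.
* No wear or damage modelling: the upstream protocol excludes such
  specimens rather than repairing them, and so does this package.
* OPCR and ariaDNE CV are known to be sensitive to specimen material
  (original vs cast surfaces); no computational correction exists or is
  attempted — treat cross-material comparisons of those metrics with
  caution.
* Equal numerical agreement with any particular external implementation is
  not promised; correctness is anchored to closed-form oracles and
  independent in-package cross-checks.
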