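---
title: "Methods: outline morphometrics and species classification of arvicoline m1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics and species classification of arvicoline m1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(voletooth)
```

## The problem

Arvicoline rodents (voles and lemmings) are identified — in palaeontology
almost exclusively — from the occlusal surface of the first lower molar (m1):
an elongate tooth with alternating buccal and lingual enamel triangles
(T1–T7) separated by deep re-entrant folds (BRA/LRA), a rounded posterior
lobe and an anterior cap. Species are morphologically similar and the
literature is full of drawings and photographs of this one tooth, so an
automated pipeline that turns such images into comparable shape data and
classifies them against a labelled reference collection removes a large
amount of expert time and subjectivity.

`voletooth` implements that pipeline end to end:

1. **Image ingest** — load a cleaned photograph or line drawing, calibrate it
   (mm per pixel), and bring it into canonical pose (anterior left, buccal
   side down).
2. **Outline geometry** — extract the closed outline, detect the anatomical
   feature points, isolate the *anterior semiperimeter* (the arc between the
   deep points of the third buccal and fourth lingual re-entrants, through
   the anterior apex: triangles T4–T7 plus the anterior cap), and resample it
   to 200 equally spaced landmarks in mm.
3. **Classification** — four affinity measures against a reference database:
   modified Hausdorff distance to every specimen (HDV) or to per-species
   centroid shapes (HDC), Procrustes nearest neighbour, a Fisher canonical
   discriminant with Mahalanobis assignment, and one-vs-one linear SVMs under
   an error-correcting output-code scheme.
4. **Linear indices** — the Van der Meulen measurements (L, W, a, b, c, e)
   and the La/Li asymmetry, measured automatically from the full outline,
   with per-segment manual override and dependent recomputation.
5. **Evaluation** — leave-one-out accuracy tables and a UPGMA similarity
   cluster of per-species exemplars.

The posterior part of the molar is deliberately excluded from the landmark
representation: it carries little taxonomic signal and is the part most often
damaged in fossils. It *is* used for the linear indices, which need the whole
outline.

## The synthetic-molar generator

No reference image collection ships with the package, so every stage is
developed and tested against a parametric generator (`make_template()`,
`generate_specimen()`, `render_molar()`) that emulates the m1 topology with
exact, labelled ground truth:

* a closed outline built from an explicit vertex plan — posterior lobe,
  alternating fold slots along the tooth axis, anterior cap — with quadratic
  Bezier corner rounding; every feature point (T apices, fold deep points,
  cap apex, posterior tip) is a labelled vertex lying exactly on the curve;
* folds of the two sides are assigned jointly to alternating slots, so they
  interdigitate (deep points may cross the midline) without intersecting;
  fold throats keep a minimum absolute width (0.028 mm) so they stay
  resolvable when rasterized;
* five presets named after the taxa whose topology they imitate
  (`microtus-like` 5+6 folds, `arvalis-like` 5+6, `agrestis-like` 6+7,
  `oeconomus-like` 4+6 with T6 suppressed, `allophaiomys-like` 3+4 with a
  confluent anteroconid). The presets are *schematic*: they reproduce fold
  counts, interdigitation and proportion ranges, not measured outlines of the
  real species, and their centred 200-landmark semiperimeters are mutually at
  least 0.1 mm apart in modified Hausdorff distance, which the test suite
  asserts;
* specimen noise is a smooth random 2-D deformation field — a low-order
  spatial Fourier series over the tooth's bounding box (default maximum
  frequency order 2), with Gaussian coefficients normalized so each
  displacement component has pointwise standard deviation `noise_sigma_mm`.
  Smoothness in *space* matters: a field defined along the perimeter (e.g. a
  radial perturbation) moves the two walls of a fold independently — their
  outward normals point into the fold gap, so wall-wise noise pinches
  ~0.06 mm throats shut already at sigma = 0.02 mm — whereas a spatial field
  displaces the spatially adjacent walls together and deforms the fold as a
  unit. If a perturbed outline nevertheless self-intersects, the field is
  deterministically damped by factors of 0.8 until it is simple (the count is
  recorded in the specimen); at the study level of 0.02 mm damping never
  engages, while at extreme levels (0.3 mm on a 1.4 mm tooth) it routinely
  does, which bounds the effective noise there;
* renders come in the two dialects the pipeline accepts — `filled` (solid
  dark tooth on white, the cleaned-photograph case) and `stroke_cement`
  (a 3 px outline stroke with cement blobs drawn inside the folds, the
  literature-drawing case) — with the truth polyline and labels attached in
  both pixel and mm coordinates.

What the generator does **not** emulate: uneven illumination, partial
breakage, wear of the enamel band, anti-aliased or greyscale photographs,
touching neighbouring teeth, and the within-species covariance structure of
real populations (noise is isotropic along the outline). Perfect scores on
synthetic data therefore demonstrate the correctness of the geometry and the
classifiers, not field-ready accuracy on museum material.

```{r template, fig.height = 3.2}
autoplot(make_template("microtus-like"))
```

## Outline extraction

**Photographs** are binarized with Otsu's threshold (drawings with a fixed
50% threshold, since line art is near-binary), holes are filled, and the
boundary of the single foreground component is traced. Boundary pixel
centres sit half a pixel inside the continuous edge, so the chain is shifted
half a pixel along its outward normals.

**Drawings** need the *midline* of the drawn stroke. Rather than thinning the
stroke to a skeleton and hunting for its largest cycle — brittle when the
stroke sprouts spurs — the extractor locates the enclosed interior
background region (the hole bounded by the stroke's inner edge), dilates it
by the estimated stroke half-width, and traces that boundary. Cement blobs
are drawn inside the re-entrant folds, i.e. *outside* the enamel line, so
they never touch the interior hole and cannot perturb the midline; no
separate cement-removal pass is needed. The stroke width is estimated from
the distance map at the interior-adjacent stroke pixels, and a residual
subpixel bias (the integer dilation radius versus the true half-width) is
measured from the across-stroke distance map and removed along the normals.

Two numerical details matter for landmark quality. First, an integer pixel
chain is up to ~5% longer than the smooth curve it approximates (staircase
inflation); one pass of Chaikin corner cutting (which moves points by at most
0.25 px) plus setting the point count from the arc length of a smoothed copy
brings the traced perimeter to within a fraction of a percent of the true
one. Second, when 200 landmarks are placed by equal arc length, the residual
short-wavelength noise of the chain perturbs the *parameterization* even
where the geometry is accurate; `resample_landmarks()` therefore measures
arc length on a lightly smoothed copy (window 7 samples at unit spacing)
while emitting points that stay on the raw chain, with the two endpoints
preserved exactly.

## Feature detection

In canonical pose the trace is smoothed with a 7-sample circular moving
average and the *convexity-defect depth* of every point is computed: the
distance to the convex-hull chord bracketing it along the chain. Re-entrant
folds are maximal runs of depth above a threshold, and each fold's deep point
is the centre of the near-maximum plateau of its depth profile (stable on
rounded fold tips, where a raw argmax wanders). Folds are numbered from the
posterior end separately on the buccal (lower) and lingual (upper) chains;
salients (triangle apices) are the vertical extrema between consecutive
same-side folds; the segment-'a' anchors are the deep points of BRA3 and
LRA4. Fewer than 3 buccal or 4 lingual folds is an error — the anchors
cannot be placed — and the caller may supply endpoints manually with
`manual_a_endpoints()`.

The depth threshold defaults to 2% of the outline length. A fraction of
*outline length* is a natural scale-free choice, but it interacts with the
anatomy: a deeply folded outline's perimeter grows with its folds, so for a
5+6-fold tooth the anatomical fold depth converges to only ~3% of the
outline length regardless of proportions. A 3% cut-off would sit exactly on
the folds it is supposed to accept; 2% sits comfortably below every fold of
every preset (measured margins 1.2–2.4x) while still rejecting noise dents
an order of magnitude shallower. The parameter is exposed
(`min_depth_frac`), as is the smoothing window.

## Landmarks, database, centroids

The anterior semiperimeter is the branch of the closed trace from the buccal
anchor through the apex to the lingual anchor, oriented buccal-first, and is
resampled to exactly 200 points (endpoints exact), converted to mm in a y-up
frame. A reference database (`ref_db()`) stores labelled landmark tables,
sorted by (species, specimen id) so that every tie-break in the package is
reproducible, and per-species centroid shapes: the pointwise arithmetic mean
of the raw calibrated coordinates. No superimposition is applied before
averaging — images are calibrated and oriented, so raw coordinates are
directly comparable — but `align = TRUE` centres specimens first if wanted.
Persistence is plain CSV plus a JSON sidecar; reading back revalidates the
records and recomputes the centroids, refusing the database if they disagree
with the stored ones by more than 1e-9 mm.

## The four classifiers

All methods operate on per-specimen-centred coordinates: absolute position in
the image is arbitrary, but absolute **size is kept** — molar size is
diagnostic among arvicolines and the images are calibrated. This is the one
substantive choice the methods description leaves open, and it is applied
uniformly (MHD, Procrustes residuals being scale-free is inherent to that
method, LDC and SVM features).

* **Modified Hausdorff distance** (`mhd()`): the directed distance is the
  *mean* over one set of the distance to the nearest point of the other, and
  the MHD is the larger of the two directions — robust to single outlying
  points, unlike the classical maximum. `classify_mhd()` assigns the species
  of the nearest specimen (HDV) or the nearest species centroid shape (HDC).
* **Procrustes** (`procrustes_dist()`): both configurations are centred and
  scaled to unit centroid size; the rotation (reflection permitted) and scale
  minimizing the sum of squared pointwise differences are applied to the
  second; the dissimilarity is the minimized residual
  `1 - (sum of singular values)^2`, in [0, 1]. The aligned copy is returned
  for overlay plots. `classify_procrustes()` is a nearest-neighbour rule and
  also reports *which* database specimen is closest.
* **Fisher LDC** (`fit_fisher_ldc()`): with 400 features and tens of
  specimens per class the pooled within-class scatter is singular, so the
  features are first reduced by principal components to
  `p' = min(n - N, #PCs retaining >= 99% variance)` dimensions. The canonical
  variates come from the generalized eigenproblem of between- versus
  within-class scatter, `q = min(N - 1, p')` of them, scaled so the pooled
  within-class covariance in canonical space is the identity (Mahalanobis
  distance is then Euclidean there). If the reduced scatter is still
  singular, a ridge of 1e-8 x trace is added and reported. Queries go to the
  class with the smallest Mahalanobis distance to its canonical mean.
* **ECOC-SVM** (`fit_ecoc_svm()`): one binary *linear* SVM per class pair
  (N(N-1)/2 learners, the one-vs-one coding scheme) on per-feature
  standardized coordinates, uniform class priors, default 0/1
  misclassification cost; the binary solver is `e1071::svm` (libsvm).
  Decoding assigns the class with the smallest mean binary hinge loss over
  the learners that involve it; the reported score is the loss gap to the
  runner-up. Classes with a single specimen are trained but flagged.

Ties everywhere break to the first occurrence in database order, which the
sorted database makes deterministic. All four classifiers are deterministic
functions of (database, query).

## Van der Meulen indices

Measured on the full closed outline in canonical pose, mm, y up:

| segment | definition |
|---|---|
| L | anteroposterior extent (x range) of the outline |
| a | x distance from the 'a' line (through the BRA3 and LRA4 deep points) to the anterior-most point |
| W | maximal width (y extent) of the part posterior to the 'a' line |
| b | maximal width between the 'a' line and the line through the most anterior re-entrants |
| c | maximal width anterior to that second line (the anterior cap) |
| e | distance from the lowest point of T6 to the highest point of T7 |
| La, Li | distances from the anterior apex to the buccal / lingual 'a' anchors (chord by default, arc length optional) |

with the derived ratios A/L = 100 a/L, B/W and C/W recomputed from the
current segments on every access (`vdm_ratios()`), so they can never go
stale. Two numerical choices: the 'a' line's x position at a given height is
interpolated along the anchor segment and *clamped* to it, because anchors
that barely cross the midline would otherwise make the interpolation
extrapolate wildly; and T6/T7 are identified positionally as the second
buccal/lingual salients anterior of the anchors. A segment whose defining
features were not detected is reported **absent with a reason** — e.g. `e`
on a T6-less *oeconomus*-type tooth — never extrapolated; the remaining
segments are still measured. `override_segment()` replaces one segment with a
manual measurement (`value = |p1 - p2|`); overriding `"a"` reinterprets the
endpoints as new 'a'-line anchors and recomputes a, La and Li from them with
the automatic formulas, flagging the derived values.

## Evaluation

`leave_one_out()` classifies every specimen against the database minus
itself: the distance methods mask the held-out row of precomputed pairwise
matrices, the model-based methods are refitted per fold, so the held-out
specimen never influences the model it is scored against. Species with a
single specimen are excluded from their own row and reported. Accuracy
tables come per species, per source dialect (photographs versus drawings)
and per method. `exemplar_cluster()` picks, per species, the all-methods-
correct specimen nearest (Procrustes) to its species centroid, joins the
exemplars by UPGMA on pairwise Procrustes dissimilarities (linkage is
switchable), and writes newick with a disclaimer line: the cluster describes
geometric similarity of database exemplars and has no biological or
phylogenetic meaning.

## Study conditions used by the tests

The acceptance suite runs the whole pipeline at fixed, realistic conditions:
five presets x 30 specimens at noise sigma = 0.02 mm for the leave-one-out
study; photographs rendered at 0.005 mm/px (a ~3 mm tooth fills ~600 px, as
under a stereomicroscope camera) and drawings at 0.01 mm/px (a scanned
figure); 200 landmarks throughout. The raster round trip is scored in pixel
equivalents of each dialect's calibration. The two calibrations reflect how
the two dialects degrade: a filled mask loses accuracy through boundary
quantization (which fine resolution removes), a 3 px stroke midline through
arc-length drift proportional to the path length in pixels (which coarse
resolution removes). The noise-degradation check uses 5 x 6 specimens over
10 seeds per noise level, a size chosen to keep the whole suite fast; the
monotonicity conclusion (more noise never raises the median accuracy) does
not depend on the database size.

## Known limitations

* The generator's presets are schematic; none of the package's accuracy
  numbers say anything about real molars of the species the presets are
  named after.
* Drawing-mode extraction assumes the stroke encloses exactly one interior
  region; an open (broken) outline is rejected rather than repaired.
* Automatic orientation (`auto_orient()`) is advisory: the principal axis is
  robust, but the anterior/buccal disambiguation relies on the cap being
  narrower than the posterior lobe and on the lingual side carrying one fold
  more, both of which can fail on worn or atypical teeth. Explicit flags
  always win.
* The feature detector is specific to arvicoline m1 topology (>= 3 buccal and
  >= 4 lingual folds); other teeth need manual anchors.
* Size is kept in the feature representation by design; databases mixing
  calibrations that disagree systematically will classify by that artefact.
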