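---
title: "Methods: 3D reconstruction and spatial analysis of multiplexed serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D reconstruction and spatial analysis of multiplexed serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multiplexed immunofluorescence (MxIF) images a single 5 µm tissue section
through iterative stain/image/inactivate cycles, yielding a dozen or more
biomarkers on the same cells. A single section, however, is a nearly 2D
sample of an intrinsically 3D tissue: a nucleus is thinner than or
comparable to the section, blood vessels run obliquely through the cutting
plane, and any distance measured in-plane systematically overestimates the
true 3D distance to a structure that continues above or below the section.
`mxif3d` rebuilds a stack of serial MxIF sections into a physically scaled
volume and computes cell-level spatial analytics in that volume: distances
from immune cells to the nearest blood vessel, distances from
damage/proliferation-marker-positive cells to the skin surface, and
immune-cell cluster densities within a configurable radius.

The pipeline stages are: illumination correction and per-slide
normalisation; autofluorescence (AF) tissue masking; registration of every
section to a chosen reference (block-matching affine followed by B-spline
deformable refinement, both driven by the stain-independent AF channel);
nuclei detection and probabilistic marker classification per section;
fusion of per-section nuclei into 3D cells by connected components; and
spatial statistics. Every stage is exercised end-to-end on synthetic
phantoms with known ground truth.

# Preprocessing

**Illumination.** The acquisition model is
`observed = truth * field + background(exposure)`, so correction subtracts
the exposure-scaled background glass frame and divides by the unit-mean
non-uniformity field, clipping at zero. The model object validates its own
invariants (positive field, unit mean within 1e-6).

**Normalisation.** Whole-slide channels are rescaled to zero mean and unit
*population* standard deviation inside the tissue mask before mixture
fitting; out-of-mask pixels are transformed with the same affine map, so
normalisation is monotone and invertible (the map is stored as
attributes). The population SD convention makes a balanced two-level image
map exactly to ±1.

**Tissue mask.** The AF channel separates tissue from glass regardless of
staining. The mask is the largest 8-connected component of the
morphologically closed Otsu foreground. Otsu uses 256 equal-width bins
over the observed range (deterministic; ties take the lowest bin); the
closing element is a disk of radius 5 px (no radius is prescribed by the
source method, and 5 px ≈ one nucleus radius closes staining holes without
bridging tissue folds). Largest-component ties break on the raster-scan
anchor, making the output fully deterministic.

# Segmentation and classification

**Nuclei.** The default detector is classical: the maximum over scales of
the negated scale-normalised Laplacian-of-Gaussian response (`σ²∇²G`,
scales 2/3/4.5 µm) is thresholded, 4-connected components are extracted,
components containing more than one interior response maximum are split by
watershed, and an area gate of 20–2000 px (at ~1 µm/px) removes debris and
clumps. The response threshold is expressed in units of the image's robust
noise SD (first-difference MAD), so a single default (0.8) serves both
sparse and dense fields of view; thresholding in absolute response units
would couple the operating point to how much of the frame nuclei occupy. A
learned segmentation backend can be plugged in by passing its foreground
mask through the `foreground` argument; the package deliberately ships no
trained model, keeping the default deterministic and dependency-free.

**Marker probabilities.** Each normalised marker channel is modelled as a
two-component Gaussian mixture over pixel intensities — background versus
positive signal — fitted by EM with k-means++ initialisation (fixed seed),
tolerance 1e-6, at most 300 iterations. The positive class is the
component with the larger mean, and its posterior probability is returned
for every pixel. By default the two components share one variance: the
posterior is then provably monotone in intensity (a logistic function of
x), which is the property downstream thresholding relies on; a
separate-variance fit is available (`variance = "separate"`) and is
cross-checked against an independent mixture fitter in the tests.

**Calls.** A nucleus's marker call fuses the probability raster with the
segmentation: `p` is the mean positive probability over the nucleus
pixels, the overlap fraction is the share of its pixels at or above the
probability threshold, and the call is positive only if both clear their
thresholds (defaults 0.5 and 0.1; both overridable per marker, which in
practice is needed on only a small minority of slides). The overlap gate
removes imaging artifacts and debris whose mean probability is inflated by
a few bright pixels. The mean was chosen for the probability/segmentation
fusion because it is robust to single-pixel noise; max and probabilistic-OR
variants were considered and rejected as too permissive for small nuclei.

**Structures and phenotypes.** Vessels (CD31) and the epithelial band
(AE1/CK26) are contiguous structures independent of nuclei: their masks
are Otsu thresholds of the probability raster, with no largest-component
filter (vessels are legitimately multiple) and an empty-mask guard.
Phenotypes follow the precedence endothelial (CD31+) → Treg
(CD3+CD4+FOXP3+) → T helper (CD3+CD4+) → T killer (CD3+CD8+) → macrophage
(CD68+) → epithelial → other; CD4/CD8 double positives resolve toward the
larger mean probability and carry an ambiguity flag.

# Registration

All sections are registered to one reference section (user-chosen; the
middle section by default) using the masked AF channel — AF is present in
every section regardless of staining round and is structurally stable.

**Affine.** A global translation is first estimated from one large
central-crop NCC search; grid blocks (64 px, 50% stride, skipped below 25%
mask coverage) are then matched within a ±12 px local search by exhaustive
normalized cross correlation (FFT-accelerated, with parabolic sub-pixel
peak refinement), and a full 6-parameter affine is fitted by iterated
trimmed least squares (worst 20% of residuals dropped per round). A
refinement pass re-matches smaller blocks against the affinely resampled
image, which removes the bias that in-block rotation induces on
translation-only matching. Self-registration returns the identity to
within 1e-3 px; known translations and rotations are recovered to within
0.5 px and 0.2°.

**Deformable.** The residual warp is a cubic B-spline displacement field
estimated coarse-to-fine (control spacing 64 then 32 px, displacement
bounded at 30 px). Each iteration proposes an increment from local block
matching against the current warp, fits it to the control grid by weighted
ridge least squares, and accepts the largest step (1, 1/2, 1/4) that
increases the normalized mutual information (32-bin joint histogram,
`(H(A)+H(B))/H(A,B)`, soft binning) between the reference and the warped
image — so NMI is the acceptance criterion and never decreases, while the
correspondence step supplies a search direction far cheaper than a
numerical NMI gradient in the control-point space. Known smooth warps of
up to 10 px are recovered with residuals well under 2 px.

**Convention.** A transform maps reference-frame points to moving-frame
points, `T(p) = A p + D(p)` with `D` parameterised over the reference
domain (the standard resampling convention); images are pulled back
through `T`, points are pushed forward through `T` (affine then
displacement) or inverted per point by fixed-point iteration (round-trip
< 0.1 µm). Label images are resampled with nearest-neighbour
interpolation, intensities bilinearly, out-of-bounds fills with 0.

**QC.** Per-section Dice similarity of the registered tissue mask against
the reference mask, and NCC between adjacent registered AF images within
the intersection of their masks — computed post-masking because the
quantity of interest is tissue correspondence, not background agreement.

**3D refinement.** Serial-section registration to a single reference can
accumulate drift that straightens genuinely curved anatomy (the "banana
effect"). When an external reference volume of the same block exists, a
12-parameter 3D affine maximising NMI (Nelder-Mead with simplex restarts,
trilinear sampling) is estimated and applied globally to all cells and
masks. A 5° shear is recovered to within 0.5° on synthetic volumes.

# Reconstruction

Registered sections are stacked at `z = physical_index × 5 µm`; skipped
physical sections (at most two in a row between retained sections) leave
real z gaps with no interpolation. Each 2D nucleus is painted as a
one-slab-thick voxel set (sections are 5 µm and nuclei 7–11 µm, so a
nucleus is at most a little over two slabs thick). Nuclei of the same
phenotype whose footprints touch across physically adjacent sections —
26-connectivity by default, so diagonal voxel contact counts;
6-connectivity by flag — are fused into one 3D cell, preventing
double-counting. Fusion never crosses a z gap larger than `max_z_gap_um`
(default 5 µm, i.e. only physically adjacent retained sections): merging
across unobserved skipped sections would over-fuse, and the default
declines to guess. The fused cell's centroid is the voxel-weighted mean;
conservation (every nucleus in exactly one 3D cell) and equivalence to a
brute-force pairwise-overlap union-find are asserted in the tests.

Tissue volume is the AF-mask voxel count times the voxel volume; densities
are cells per cm³ (1 µm³ = 1e-12 cm³).

# Spatial analytics

**Vessel distances.** The distance from each immune cell to the nearest
structure voxel is computed twice: within the cell's own section in-plane
(2D) and through the whole volume (3D). Cells are referenced at their
section's slab z — they live on the reconstructed voxel grid — so the
same-section candidates of the 2D search are exactly the z-offset-0
candidates of the 3D search, and `d3d ≤ d2d` holds per cell by
construction. All structure-positive voxels are candidates ("nearest edge"
to within half a voxel), which avoids explicit boundary extraction at a
bounded cost of one voxel diagonal. The search applies the axis-pruning
filter — candidates whose x, y or z offset already exceeds the current
minimum cannot win and are skipped — implemented as a vectorised filter
around an initial coarse-subsample minimum; because any candidate with an
axis offset above an achieved distance is strictly farther, the result is
exactly the exhaustive minimum, which the tests assert on hundreds of
random configurations. Ties break to the lexicographically smallest
(z, y, x) witness voxel.

**Skin-surface distances.** Damage/repair/proliferation-positive cells
(p53, DDB2, Ki67) are projected to their nearest retained section and the
in-plane distance to that section's surface polyline (topmost tissue-mask
row per column) is reported; ties break to the smallest (y, x) surface
point.

**Cluster density.** For each T helper index cell, the number of distinct
neighbour cells within 15 and 30 µm (both defaults reported), same-section
in-plane (2D) and through the volume (3D), excluding the index cell. The
neighbour set defaults to T cells (helper + killer + regulatory) and can
be switched to all immune cells (`neighbor_set = "immune"`) — both
phrasings of the neighbour population are supported because either can be
wanted in practice; the default is the narrower, more specific set.

**Statistics.** Thin, typed wrappers return tibbles: two-sided two-sample
Kolmogorov–Smirnov (asymptotic p; used for 2D-vs-3D distance
distributions), Spearman rank correlation with Benjamini–Hochberg
adjustment within each hypothesis family (covariate screens), and the
two-sided Wilcoxon rank-sum test (exact for small untied samples). The BH
step-up is asserted against a hand construction in the tests.

# The phantom: what it emulates, and what it does not

The generator builds a reference-frame tissue — sinusoidal skin surface,
~35 µm epidermis band, dermal vessel tubes meandering through z, nuclei as
spheres of radius 3.6–5.4 µm intersecting one to three 5 µm sections —
renders DAPI (Gaussian bumps), AF, and marker channels (near-uniform
nuclear plateaus, since nuclear markers fill the nucleus), then perturbs
every section except the reference with a stored affine jitter (≤3°,
≤10 px), a bounded smooth B-spline deformation (≤10 px) and Gaussian
noise, quantised to the 16-bit unsigned scale of microscopy TIFFs. The
same seed reproduces the stack bit-for-bit. Marker positivity follows the
phenotype table; positive plateaus sit `marker_snr` noise-SDs above
background (default 6), the two-component structure the mixture model
assumes.

The AF texture deserves its own note because no texture statistics are
prescribed by the source method. It is a sum of smoothed Gaussian random
fields: a component that persists through the entire block (itself
two-scale, ~22 px and ~8 px feature sizes, 55% of variance) and a fine
component that decorrelates along z with a ~15 µm correlation length (45%).
Both ingredients are physically motivated — dermal collagen bundles span
the block while fine texture turns over within a few sections — and both
are *necessary*: without a persistent component, sections far from the
reference share no content and registration to a single reference is
ill-posed (interior correspondence cannot be recovered from data that does
not contain it); without the transient component, adjacent-section NCC
would be trivially ≈1 and meaningless as a QC surrogate. The z-correlation
length is configurable (`af_z_corr_sections`).

What passing tests on phantoms do **not** show: robustness to real
acquisition pathology (folds, tears, debris, bubbles, illumination drift
within a slide), to antibody-specific staining variability, or to nuclei
morphologies far from blob-shaped (elongated fibroblasts, mitotic
figures). The phantom's classification results (≈100% at SNR 6) should be
read as "the algorithmic chain is lossless under its stated intensity
model", not as a claim about tissue.

# Problem sizes and numerical choices

The shipped analyses use desk-scale sizes chosen to keep a full run
comfortable on one CPU: 24 sections of 192×224 px at 1 µm/px for the
registration QC (≈2–3 minutes), 500 nuclei on 384×448 px for the
classification QC (seconds), and 3–6-section stacks for end-to-end
pipeline tests. Degenerate inputs are handled explicitly: constant images
error in normalisation, Otsu and the mixture fit; empty foregrounds error
in masking; an empty DAPI frame yields zero nuclei (not an error); empty
neighbour sets count zero. All tie-breaks (Otsu bins, largest component,
distance witnesses) are deterministic, and every random draw flows from a
caller-supplied seed through `withr::with_seed`, leaving the global RNG
untouched.

# Known limitations

- Whole-cell/membrane segmentation is out of scope; markers are read over
  nuclear/peri-nuclear pixels only.
- The deformable stage models smooth fields; it cannot recover tissue
  tears or folds, and its displacement bound (30 px) is a hard cap.
- Fusion trusts the per-section phenotype: a cell called differently in
  two sections is kept as two 3D cells.
- Registration accuracy in the tissue interior degrades for sections far
  from the reference when little persistent AF structure exists; the mask
  boundary then dominates, which preserves the Dice QC but not interior
  correspondence. The 3D refinement against an external volume mitigates
  but does not remove this.
- The interactive 3D viewers of the original workflow are out of scope;
  results are exported as plain tables and static ggplots.
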