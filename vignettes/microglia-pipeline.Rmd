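---
title: "Quantifying microglia in multiplex immunofluorescence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglia in multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GliaQuant)
```

## The problem

Microglia — the brain's resident immune cells — change their surface-marker
profile as they activate: the homeostatic markers TMEM119 and P2RY12 are
lost, while Iba1 and (in iron-loaded cells) ferritin light chain (FTL) rise.
Studying this in human tissue requires (i) segmenting *whole* microglia in
2D multiplexed immunofluorescence sections, which is hard because their thin
ramified processes are dim and frequently appear disconnected from the soma
in a 5 µm section; (ii) clustering cells by their four-marker expression
profile without supervision; (iii) relating phenotypes to amyloid-β plaques
spatially; and (iv) counting iron-positive cells in bright-field Perl's
stains. GliaQuant implements this pipeline end to end, together with a
synthetic-data generator carrying full ground truth, so that every stage is
testable without tissue images.

## Staged segmentation

### Two-phase level-set model

All level-set stages minimise a two-phase piecewise-constant (Chan–Vese
type) energy over a binary foreground indicator $u$:

$$E(u) = \sum_{u=1}(I-c_1)^2 + \sum_{u=0}(I-c_0)^2
       + \nu\,w_P\,\mathrm{Per}(u) + \mu\,w_A\,|u|,$$

where $c_1, c_0$ are the foreground/background means of the
$[0,1]$-normalised intensity $I$, $\nu$ weights the perimeter term and
$\mu$ the area term. Larger $\nu$ gives smoother boundaries; larger $\mu$
shrinks the segmented area.

The discretisation matters for this cell type. We write the perimeter as
the count of disagreeing 8-neighbour pairs (an Ising pair penalty, scaled
by $1/8$) and descend the energy with deterministic checkerboard iterated
conditional modes: given $c_0, c_1$, a pixel is foreground iff

$$(I-c_0)^2 - (I-c_1)^2 + \nu\,w_P\left(\tfrac{2 n_{fg}}{8}-1\right)
  - \mu\,w_A > 0,$$

with $n_{fg}$ its currently-foreground 8-neighbours. Unlike isotropic
smoothing filters (majority vote, Gaussian-threshold, morphological
openings), whose single pass erases any 1-px-wide structure regardless of
contrast, the pair penalty for a thin line is bounded
($n_{fg} = 2 \Rightarrow$ penalty $-\nu w_P/2$), so a high-contrast 1-px
process survives while an isolated noise pixel ($n_{fg}=0$, penalty
$-\nu w_P$) does not. The scales are fixed at $w_A = 0.02$ and
$w_P = 0.03$ on $[0,1]$-normalised intensities; they place the published
stage weights ($\nu = 2$ throughout, $\mu = 3$ for nucleus/soma, $\mu = 2$
for cytoplasm) in the regime where the $\mu$ dial separates the coarse
(bright somas) from the fine (dim processes) stage.

Convergence: the sweep stops when the relative foreground change drops
below `tol` (default 1e-3) or when a period-2 boundary cycle is detected
(near-zero-force pixels can oscillate under a checkerboard sweep; the
cycle *is* the fixed point up to those pixels). A hard cap of
`maxIter = 200` returns the current mask with a warning. A foreground
that collapses entirely (very large $\mu$) returns an empty mask.

### Why the cytoplasm stage is anchored

The scene has three intensity classes — background, dim processes, bright
somas — but the model has two. Run naively, the foreground mean $c_1$ is
dominated by the somas, which pushes process pixels (closer in intensity
to background than to the soma mean) out of the foreground; the fine
stage would then recover nothing the soma stage had not. Because the
pipeline is staged, the cytoplasm stage can do better: the
already-identified somas are *anchored* as permanent foreground and
excluded from the $c_1$ estimate, so $c_1$ tracks the dim cytoplasmic
class and the evolution recovers exactly the "areas less bright than the
soma" the stage exists for. This uses only information the pipeline has
already computed; it adds no parameter.

### Initialisation and the Li switch

Stages initialise from the Otsu threshold of their input (robust to
intensity differences between grey- and white-matter fields). When a
vessel is present — detected as an autofluorescent component strictly
larger than 4000 px — the cytoplasm stage initialises from the Li
minimum-cross-entropy threshold instead, because Otsu's between-class
variance is pulled far above the dim cell signal by a vessel-scale mass
of very bright pixels, while Li's mean-based fixed point is not. Both
thresholds are computed per image; intensities therefore need no global
calibration. Otsu uses a 256-bin histogram with ties broken toward the
lowest cut; Li iterates $t \leftarrow (\mu_b-\mu_f)/(\log\mu_b-\log\mu_f)$
from the image mean to convergence at 1/65536 of the range.

### Assembly rules

* Somas/nuclei below 50/30 px are removed; by default a soma must overlap
  a nucleus (stated as a property of real somas; implemented as an
  optional filter, on by default).
* A cytoplasm component overlapping one soma joins it; overlapping
  several somas, it is split by marker-controlled watershed, implemented
  as synchronous multi-source 8-connected region growing from the
  soma-overlap seeds. Pixels are conserved exactly; where two fronts
  meet in the same ring the lower soma id wins, which makes the split
  deterministic.
* Orphan components within 10 px (Euclidean, pixel centres, distance to
  the soma *region* — the boundary, not the centroid) of a soma are
  attached as detached processes; nearest soma wins, ties to the lower
  soma id; farther orphans are discarded.
* All component labelling is 8-connected (configurable), so 1-px
  diagonal process segments stay connected.
* Plaque identification offers a threshold mode (Otsu on the Aβ plane +
  closing + minimum area, default 100 px) and a semi-supervised pixel
  classifier (random forest over intensity/Gaussian/gradient features,
  trained from sparse scribbles with an explicit seed), replacing the
  external interactive tool used originally.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| ν (all stages) | 2 | – | perimeter weight; smoothness |
| µ nucleus/soma | 3 | – | area weight; keeps compact bright blobs |
| µ cytoplasm | 2 | – | weaker shrinkage; admits dim processes |
| min soma / nucleus area | 50 / 30 | px | debris filters |
| vessel area rule | > 4000 (strict) | px | autofluorescent component size |
| process attach radius | 10 (≤) | px | detached-process re-assignment |
| pixel size | 0.5 | µm | densities, scale bars |

## Phenotyping

Per cell, the mean of each membrane marker over the full segmented area
(soma ∪ cytoplasm ∪ attached processes) is extracted and z-scored
*pooled over all cells of all subjects* — clusters are compared across
subjects, which requires one common scale (a per-subject switch exists).
Clustering follows the Phenograph recipe: Euclidean kNN graph with
k = 100 (deliberately large for a 4-marker space, to avoid
overclustering), Jaccard reweighting of edges by neighbour-set overlap
(zero-weight edges dropped), Louvain modularity maximisation at
resolution 1 under an explicit seed. Labels are renumbered by decreasing
cluster size; cluster identities should be matched to phenotypes by their
expression profiles, not by index, as community numbering is arbitrary.
Post-processing mirrors the manual curation step as config-driven rules:
clusters whose TMEM119, P2RY12 *and* Iba1 medians all sit below a z
threshold (default −0.5) are flagged non-microglial and removed; cluster
pairs with near-identical median profiles (or an explicit merge list) are
merged. As a further overclustering guard, `phenographCluster` caps the
community count (default 12) by merging the closest centroid pair until
the cap holds; on structured data the cap is never hit. t-SNE embeds the
same z-scored matrix (Rtsne, fixed seed, perplexity 30).

## Spatial analysis and statistics

A cell *infiltrates* a plaque iff its pixel set intersects the plaque
mask dilated by `dilationPx` (default 0, i.e. direct overlap — the most
conservative reading; the dilation knob covers "proximity"). A cell
touching two plaques is assigned once, to the larger overlap, ties to
the lower plaque id. A plaque is "infiltrated" with ≥ 1 infiltrating
cell. Compositions of all phenotyped cells (all-mic) versus the
infiltrating subset (Aβ-mic) are computed per subject and pooled;
subjects with no infiltrating cells are excluded from paired tests with
a message.

Group comparisons follow the test-selection rule: normality per group by
Shapiro–Wilk at α = 0.05 (the original analysis "inspected" normality
without naming a test; Shapiro–Wilk is this package's concrete choice,
overridable), then a two-tailed unpaired Student's t-test or
Mann–Whitney U; paired data use a paired t-test when the differences
pass the gate, otherwise the Wilcoxon signed-rank test. Bonferroni
correction multiplies p by a caller-defined family size m (the family —
typically the number of clusters tested — is a config input, since the
original report does not enumerate its families). Correlations are
Pearson with the two-sided p from the t distribution on n − 2 df.

## Iron-positive cell counting

Bright-field RGB images of DAB-enhanced Perl's stains are converted to
8-bit grayscale with the ITU-R BT.601 luminance weights
(0.299, 0.587, 0.114 — what ImageJ's 8-bit conversion applies), dark
pixels at or below a per-subject threshold are selected (DAB product is
dark; polarity configurable), components are labelled within the ROI and
those with area in the inclusive window [4, 100] px are counted. The
window is applied *after* labelling, so an oversized blob is excluded
whole rather than split — ImageJ particle-analyser semantics, and the
reading of "size threshold 4–100" as inclusive is documented here
because the source leaves inclusivity unstated. Per-subject manual
thresholds are inputs (they were set blinded in the original protocol);
an automatic Otsu-within-ROI mode exists but is labelled as a departure
from that protocol.

## The synthetic-data generator

`simulateImage` emulates the features the pipeline's assumptions rest
on: cells on a jittered grid, each a bright soma disk (radius 6 px ≈
113 px area, comfortably above the 50 px filter at 0.5 µm pixels), 1–3 px
wide random-walk processes at 0.45× the soma intensity (length ~22 px),
20% of processes detached by a 4 px erased root gap (within the 10 px
attachment radius), a DAPI nucleus (radius 3.5 px ≈ 38 px) inside each
soma, per-cell marker levels drawn from cluster profiles (a
homeostatic P2RY12+/TMEM119+ profile, an activated FTL+/Iba1+ profile,
an intermediate one — qualitative mimics, not measured values), Aβ
plaques as irregular blobs, vessels as > 4000 px autofluorescent bands
that bleed faintly into the membrane channels, mild optical blur
(Gaussian σ = 0.5), additive Gaussian noise (sd 0.06 against a soma
intensity of 1 — soma SNR ≈ 16, process SNR ≈ 7), clipping at 0 and
16-bit quantisation (which makes TIFF round trips bit-exact). Cohort
generators plant the group structure of interest: more plaques and a
higher activated-cluster share in the disease group, and an
`enrichment`-fold odds multiplier for the activated cluster among
plaque-adjacent cells.

What it does *not* emulate: realistic point-spread functions and
chromatic shifts, autofluorescence texture, staining and unmixing
artefacts, densely packed overlapping cells around plaques, and the
continuum (rather than discrete-mixture) structure of real microglial
phenotypes. Passing the synthetic benchmarks therefore shows the
implementation is faithful to its stated model and recovers planted
structure under controlled conditions — not that real tissue would be
segmented with the same accuracy.

Statistical calibration and power checks run at the table level
(`simulateInfiltrationCohort`: cluster labels and infiltration flags,
no rendering), with 12 subjects × 3000 cells per cohort — the order of
magnitude of cells per subject in a full-scale study — because the
contracts under test involve only composition tables.

## Problem sizes and numerical choices

The packaged checks use: 7 simulated fields × 22 cells (154 truth
cells) for the segmentation benchmark with one-to-one greedy Dice
matching at 0.5 (the correctness criterion is not stated in the source;
0.5 is this package's configurable default); a planted 5-component,
6-sd-separated Gaussian mixture (n = 2000, k = 100) for clustering
recovery; 20 enriched and 200 null table-level cohorts for power and
type-I calibration; 500 random images against a flood-fill oracle for
particle counting. Degenerate inputs are defined throughout: constant
images raise threshold errors (surfaced as empty masks with a warning
inside stages), the Dice of two empty masks is an error rather than a
convention, and zero-variance markers refuse to z-score naming the
marker.

## Known limitations

* The original level-set method is unpublished in detail; equivalence is
  claimed at the level of parameter semantics (ν/µ roles, stage
  ordering, initialisation), verified on synthetic truth — not bit-level
  reproduction.
* 2D only; no skeleton-based morphometrics (morphological subtyping was
  visual in the source study).
* Cluster counts on real data are not a validated surface; planted-truth
  recovery is.
* The CLI's `spatial` subcommand recomputes compositions from flagged
  tables; pixel-level infiltration requires the segmentation objects and
  is an R-level operation.
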