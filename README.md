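# GliaQuant

Segmentation, phenotyping and spatial analysis of microglia in multiplex
immunofluorescence images, plus particle-based counting of iron-positive
cells in bright-field Perl's stains.

Microglia are the brain's resident immune cells. In Alzheimer's disease a
subset loses the homeostatic markers TMEM119 and P2RY12, upregulates Iba1
and the iron-storage protein ferritin light chain (FTL), and accumulates
around amyloid-β plaques. Quantifying this from tissue sections requires
segmenting *whole* microglia — soma plus thin, often visually detached
processes — from multi-channel component images, clustering cells by their
marker profile, and measuring plaque infiltration per phenotype. GliaQuant
is for image-analysis and neuropathology groups who need that pipeline as
reproducible, testable code, together with a synthetic-data generator that
carries full ground truth so every stage can be validated without tissue.

## The models at the core

**Segmentation** is staged. Nuclei (DAPI) and somas (summed
TMEM119+P2RY12+FTL+Iba1 signal) come from a two-phase piecewise-constant
(Chan–Vese-type) level set minimising

E(u) = Σ_fg (I−c₁)² + Σ_bg (I−c₀)² + ν·Per(u) + µ·|u|

with ν = 2, µ = 3, initialised from the Otsu threshold; area filters
remove somas < 50 px and nuclei < 30 px. A finer pass with µ = 2 — with
the somas anchored as foreground so the model tracks the dimmer
cytoplasmic class — captures processes; it initialises from the Li
minimum-cross-entropy threshold when an autofluorescent vessel
(component > 4000 px) is present. Cytoplasm shared by several somas is
split by marker-controlled watershed; orphan components within 10 px of a
soma are attached as detached processes. Evaluation uses the Dice index
2|A∩B|/(|A|+|B|) with greedy one-to-one matching.

**Phenotyping** follows the Phenograph recipe on the four z-scored marker
means per cell: Euclidean kNN graph (k = 100), Jaccard edge reweighting,
Louvain modularity maximisation, followed by config-driven exclusion of
marker-negative clusters and merging of near-duplicates; t-SNE for
visualisation.

**Spatial statistics** compare the cluster composition of all microglia
(all-mic) with the plaque-infiltrating subset (Aβ-mic), per subject, using
the study's test-selection rule (Shapiro–Wilk gate → Student's t /
Mann–Whitney / paired t, Bonferroni across a caller-defined family) and
Pearson correlation.

**Iron counting** converts RGB Perl's scans to 8-bit grayscale
(0.299 R + 0.587 G + 0.114 B), thresholds dark DAB-positive pixels per
subject, and counts connected components with area in the inclusive
[4, 100] px window — ImageJ particle-analyser semantics.

## Worked example

Simulate a field with known ground truth, segment it, and evaluate:

```r
library(GliaQuant)

profiles <- defaultClusterProfiles()
set.seed(1)
cl <- sample(1:3, 20, replace = TRUE, prob = c(0.5, 0.3, 0.2))
specs <- lapply(seq_len(20), function(j)
  syntheticCellSpec(markerProfile = profiles[[cl[j]]], clusterId = cl[j],
                    nearPlaque = cl[j] == 2 && j %% 2 == 0))
sim <- simulateImage(c(448L, 448L), specs, nPlaques = 2, seed = 11)
seg <- segmentImage(sim$image)
matchCells(seg$cells, sim$truth@cellMasks, matchDiceMin = 0.5)
#> MatchResult: 19/20 truth cells captured, FP 0, FN 1, median Dice 0.92
```

19 of the 20 planted cells are recovered one-to-one (one plaque-adjacent
cell is missed), and the median per-cell Dice overlap with truth is 0.92.
Plaque infiltration is direct pixel overlap with the plaque mask:

```r
inf <- infiltration(seg$cells, seg$plaqueMask)
inf$perPlaque
#>   plaque_id area_px n_infiltrating infiltrated
#> 1         1     269              0       FALSE
#> 2         2     232              1        TRUE
```

Phenotype clustering at its working scale, on a planted 5-component
mixture in the 4-marker space (n = 2000, 6-sd separation):

```r
set.seed(5)
M <- matrix(rnorm(20), 5, 4) * 0.3 + 6 * rbind(diag(4), c(1, 1, 1, 1))[1:5, ]
ft <- simulateFeatureTable(2000, M, clusterSds = 1,
                           proportions = rep(0.2, 5), seed = 2)
lab <- phenographCluster(scale(as.matrix(ft$features)), k = 100, seed = 3)
max(lab)                            # 5 clusters found
adjustedRandIndex(lab, ft$labels)   # 1 — exact recovery
```

A simulated 12-subject cohort with a planted 3× infiltration-odds
enrichment of cluster 2, analysed with the paired all-mic vs Aβ-mic
comparison:

```r
co <- simulateInfiltrationCohort(nSubjects = 12, cellsPerSubject = 3000,
                                 enrichment = 3, seed = 4)
comp <- abmicComposition(co$table, co$table$cluster, co$infiltration)
round(comp$pooled, 4)
#>   cluster all_mic ab_mic fraction_infiltrating
#> 1       1  0.4504 0.2995                0.0495
#> 2       2  0.3011 0.5403                0.1335
#> 3       3  0.2485 0.1602                0.0479
bs <- comp$bySubject[comp$bySubject$cluster == 2, ]
compareGroups(bs$ab_mic, bs$all_mic, paired = TRUE)$p
#> [1] 2.33e-10
```

Cluster 2 makes up 30% of all microglia but 54% of the plaque-infiltrating
subset; the paired test detects the planted enrichment decisively. Iron
particles, counted within the inclusive [4, 100] px window:

```r
gray <- matrix(230L, 96, 96)
gray[20:21, 10:11] <- 30L   # 4 px particle
gray[40:44, 30:39] <- 30L   # 50 px particle
gray[60:75, 50:59] <- 30L   # 160 px blob, above the window
countParticles(gray, ParticleConfig(threshold = 128))[c("nParticles", "areas")]
#> $nParticles
#> [1] 2
#> $areas
#> [1]  4 50
```

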