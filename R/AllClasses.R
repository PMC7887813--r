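#' @import methods
NULL

## The four membrane markers whose mean intensities define the phenotype space.
MEMBRANE_MARKERS <- c("TMEM119", "P2RY12", "FTL", "Iba1")

## Recognised channel names; DAPI drives nucleus segmentation, Abeta the
## plaque stage, AF (autofluorescence) the vessel stage.
KNOWN_CHANNELS <- c("DAPI", MEMBRANE_MARKERS, "Abeta", "AF")

LABELMASK_KINDS <- c("nucleus", "soma", "cell", "plaque", "vessel", "component")

#' ComponentImage: aligned single-marker intensity planes
#'
#' Container for the unmixed component images of one multiplexed
#' immunofluorescence field: one non-negative grayscale plane per marker
#' channel, all of identical dimension, plus pixel-size metadata and an
#' optional grey/white-matter region mask.
#'
#' @slot planes named list of numeric matrices (one per channel), identical
#'   dimensions, finite and >= 0. Channel names must be drawn from the
#'   declared channel set (DAPI, TMEM119, P2RY12, FTL, Iba1, Abeta, AF).
#' @slot pixelSizeUm side length of one pixel in micrometres (> 0);
#'   0.5 um for the imaging setup this pipeline models.
#' @slot subjectId subject identifier.
#' @slot regionMask optional character matrix ("GM"/"WM"/"excluded") of the
#'   same dimension, or a 0-row matrix when absent (all cells then GM).
#' @export
setClass("ComponentImage",
  representation(planes = "list", pixelSizeUm = "numeric",
                 subjectId = "character", regionMask = "matrix"),
  prototype(planes = list(), pixelSizeUm = 0.5, subjectId = "unknown",
            regionMask = matrix(character(0), 0, 0)))

setValidity("ComponentImage", function(object) {
  p <- object@planes
  if (length(p) == 0L) return("no planes")
  if (is.null(names(p)) || any(!nzchar(names(p))))
    return("planes must be named by channel")
  bad <- setdiff(names(p), KNOWN_CHANNELS)
  if (length(bad)) return(paste0("unknown channel name(s): ",
                                 paste(bad, collapse = ", ")))
  dm <- dim(p[[1L]])
  for (nm in names(p)) {
    if (!is.matrix(p[[nm]]) || !is.numeric(p[[nm]]))
      return(paste0("plane ", nm, " is not a numeric matrix"))
    if (!identical(dim(p[[nm]]), dm))
      return("all planes must share one shape")
    if (any(!is.finite(p[[nm]])) || any(p[[nm]] < 0))
      return(paste0("plane ", nm, " has non-finite or negative intensities"))
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (nrow(object@regionMask) > 0L && !identical(dim(object@regionMask), dm))
    return("regionMask dimension differs from planes")
  TRUE
})

#' LabelMask: integer-labelled instance mask
#'
#' 2D instance mask with 0 = background and labels 1..n; `kind` records what
#' the instances are (nucleus, soma, cell, plaque, vessel or generic
#' component).
#'
#' @slot labels integer matrix, values >= 0.
#' @slot kind one of "nucleus", "soma", "cell", "plaque", "vessel",
#'   "component".
#' @export
setClass("LabelMask",
  representation(labels = "matrix", kind = "character"),
  prototype(labels = matrix(0L, 0, 0), kind = "component"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be numeric/integer")
  if (length(l) && (any(l < 0) || any(l != round(l))))
    return("labels must be non-negative integers")
  if (length(object@kind) != 1L || !object@kind %in% LABELMASK_KINDS)
    return(paste0("kind must be one of: ", paste(LABELMASK_KINDS, collapse = ", ")))
  TRUE
})

#' LevelSetParams: regularization weights for the two-phase level set
#'
#' @slot nu perimeter-energy weight (>= 0); larger values give smoother
#'   boundaries.
#' @slot mu area-energy weight (>= 0); larger values shrink the segmented
#'   area.
#' @slot maxIter maximum number of evolution sweeps (>= 1).
#' @slot tol convergence tolerance on the relative foreground change (> 0).
#' @export
setClass("LevelSetParams",
  representation(nu = "numeric", mu = "numeric", maxIter = "integer",
                 tol = "numeric"),
  prototype(nu = 2, mu = 3, maxIter = 200L, tol = 1e-3))

setValidity("LevelSetParams", function(object) {
  if (object@nu < 0 || object@mu < 0) return("nu and mu must be >= 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be > 0")
  TRUE
})

#' @rdname LevelSetParams-class
#' @param nu,mu,maxIter,tol see slots.
#' @export
LevelSetParams <- function(nu = 2, mu = 3, maxIter = 200L, tol = 1e-3)
  new("LevelSetParams", nu = nu, mu = mu, maxIter = as.integer(maxIter),
      tol = tol)

#' SegmentationConfig: all tunable parameters of the staged segmentation
#'
#' Defaults are the pipeline's published operating point: nucleus and soma
#' level sets at nu = 2, mu = 3; cytoplasm at nu = 2, mu = 2; somas below
#' 50 px and nuclei below 30 px removed; vessels are autofluorescent
#' components strictly larger than 4000 px; detached processes are attached
#' within a 10 px radius of a soma.
#'
#' @slot nucleusParams,somaParams,cytoplasmParams \linkS4class{LevelSetParams}
#'   per stage.
#' @slot minSomaAreaPx,minNucleusAreaPx area filters (components strictly
#'   smaller are removed).
#' @slot vesselMinAreaPx vessels must be strictly larger than this.
#' @slot processAttachRadiusPx maximum pixel-centre distance between an
#'   orphan component and a soma for attachment (<= radius attaches).
#' @slot connectivity 4 or 8 for component labelling (default 8).
#' @slot requireNucleusOverlap drop somas with zero nucleus overlap
#'   (default TRUE; a soma should contain its nucleus).
#' @slot plaqueMethod "threshold" or "classifier".
#' @slot plaqueMinAreaPx minimum plaque component area.
#' @export
setClass("SegmentationConfig",
  representation(nucleusParams = "LevelSetParams",
                 somaParams = "LevelSetParams",
                 cytoplasmParams = "LevelSetParams",
                 minSomaAreaPx = "integer", minNucleusAreaPx = "integer",
                 vesselMinAreaPx = "integer",
                 processAttachRadiusPx = "numeric",
                 connectivity = "integer",
                 requireNucleusOverlap = "logical",
                 plaqueMethod = "character", plaqueMinAreaPx = "integer"))

setValidity("SegmentationConfig", function(object) {
  if (object@minSomaAreaPx <= 0L || object@minNucleusAreaPx <= 0L ||
      object@vesselMinAreaPx <= 0L || object@plaqueMinAreaPx < 0L)
    return("area parameters must be positive")
  if (object@processAttachRadiusPx < 0) return("attachment radius must be >= 0")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (!object@plaqueMethod %in% c("threshold", "classifier"))
    return("plaqueMethod must be 'threshold' or 'classifier'")
  TRUE
})

#' @rdname SegmentationConfig-class
#' @param nucleusParams,somaParams,cytoplasmParams,minSomaAreaPx,minNucleusAreaPx,vesselMinAreaPx,processAttachRadiusPx,connectivity,requireNucleusOverlap,plaqueMethod,plaqueMinAreaPx
#'   see slots.
#' @export
SegmentationConfig <- function(nucleusParams = LevelSetParams(nu = 2, mu = 3),
                               somaParams = LevelSetParams(nu = 2, mu = 3),
                               cytoplasmParams = LevelSetParams(nu = 2, mu = 2),
                               minSomaAreaPx = 50L, minNucleusAreaPx = 30L,
                               vesselMinAreaPx = 4000L,
                               processAttachRadiusPx = 10,
                               connectivity = 8L,
                               requireNucleusOverlap = TRUE,
                               plaqueMethod = "threshold",
                               plaqueMinAreaPx = 100L) {
  new("SegmentationConfig", nucleusParams = nucleusParams,
      somaParams = somaParams, cytoplasmParams = cytoplasmParams,
      minSomaAreaPx = as.integer(minSomaAreaPx),
      minNucleusAreaPx = as.integer(minNucleusAreaPx),
      vesselMinAreaPx = as.integer(vesselMinAreaPx),
      processAttachRadiusPx = processAttachRadiusPx,
      connectivity = as.integer(connectivity),
      requireNucleusOverlap = requireNucleusOverlap,
      plaqueMethod = plaqueMethod,
      plaqueMinAreaPx = as.integer(plaqueMinAreaPx))
}

#' CellRecord: one segmented microglia
#'
#' Pixel sets are 1-based linear (column-major) indices into the image grid
#' whose dimension is carried in `imageDim`; exported coordinates are
#' (row, col), 0-based, origin top-left.
#'
#' @slot cellId integer id.
#' @slot somaPixels,cytoplasmPixels,processPixels linear pixel indices; soma
#'   and process sets are disjoint.
#' @slot nucleusId matched nucleus label (NA when none).
#' @slot centroid (row, col) 0-based centroid of the full cell area.
#' @slot totalAreaPx number of pixels in the union of the three sets.
#' @slot meanIntensity named numeric: mean intensity over the full cell area
#'   for exactly the four membrane markers.
#' @slot region "GM" or "WM".
#' @slot infiltratesPlaque logical; `plaqueId` the infiltrated plaque (NA if
#'   none).
#' @slot subjectId subject identifier.
#' @slot imageDim c(nrow, ncol) of the source image.
#' @export
setClass("CellRecord",
  representation(cellId = "integer", somaPixels = "integer",
                 cytoplasmPixels = "integer", processPixels = "integer",
                 nucleusId = "integer", centroid = "numeric",
                 totalAreaPx = "integer", meanIntensity = "numeric",
                 region = "character", infiltratesPlaque = "logical",
                 plaqueId = "integer", subjectId = "character",
                 imageDim = "integer"))

setValidity("CellRecord", function(object) {
  if (length(intersect(object@somaPixels, object@processPixels)))
    return("soma and process pixel sets must be disjoint")
  un <- unique(c(object@somaPixels, object@cytoplasmPixels,
                 object@processPixels))
  if (object@totalAreaPx != length(un))
    return("totalAreaPx must equal |soma U cytoplasm U processes|")
  if (!setequal(names(object@meanIntensity), MEMBRANE_MARKERS))
    return("meanIntensity must be defined for exactly the four membrane markers")
  if (!object@region %in% c("GM", "WM")) return("region must be GM or WM")
  TRUE
})

#' MatchResult: instance-level evaluation of a segmentation
#'
#' @slot nTruth,nCorrect,nFalsePositive,nFalseNegative counts from greedy
#'   one-to-one Dice matching.
#' @slot perCellDice Dice coefficients of the correctly matched pairs.
#' @export
setClass("MatchResult",
  representation(nTruth = "integer", nCorrect = "integer",
                 nFalsePositive = "integer", nFalseNegative = "integer",
                 perCellDice = "numeric"))

setValidity("MatchResult", function(object) {
  if (object@nCorrect > object@nTruth) return("nCorrect cannot exceed nTruth")
  if (length(object@perCellDice) &&
      (any(object@perCellDice < 0) || any(object@perCellDice > 1)))
    return("Dice values must lie in [0, 1]")
  TRUE
})

#' ParticleConfig: iron-positive particle analysis settings
#'
#' @slot threshold 8-bit gray threshold (0-255), set per subject.
#' @slot minSizePx,maxSizePx inclusive particle size window (defaults 4 and
#'   100 px).
#' @slot connectivity 4 or 8.
#' @slot polarity "dark" (DAB product, default) or "bright".
#' @export
setClass("ParticleConfig",
  representation(threshold = "integer", minSizePx = "integer",
                 maxSizePx = "integer", connectivity = "integer",
                 polarity = "character"),
  prototype(threshold = 128L, minSizePx = 4L, maxSizePx = 100L,
            connectivity = 8L, polarity = "dark"))

setValidity("ParticleConfig", function(object) {
  if (object@threshold < 0L || object@threshold > 255L)
    return("threshold must be in 0..255")
  if (object@minSizePx <= 0L || object@minSizePx > object@maxSizePx)
    return("need 0 < minSizePx <= maxSizePx")
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  if (!object@polarity %in% c("dark", "bright"))
    return("polarity must be 'dark' or 'bright'")
  TRUE
})

#' @rdname ParticleConfig-class
#' @param threshold,minSizePx,maxSizePx,connectivity,polarity see slots.
#' @export
ParticleConfig <- function(threshold, minSizePx = 4L, maxSizePx = 100L,
                           connectivity = 8L, polarity = "dark")
  new("ParticleConfig", threshold = as.integer(threshold),
      minSizePx = as.integer(minSizePx), maxSizePx = as.integer(maxSizePx),
      connectivity = as.integer(connectivity), polarity = polarity)

## ---- show methods ----

setMethod("show", "ComponentImage", function(object) {
  dm <- dim(object@planes[[1L]])
  cat("ComponentImage:", dm[1L], "x", dm[2L], "px,",
      length(object@planes), "channel(s) [",
      paste(names(object@planes), collapse = ", "), "]\n")
  cat("  subject:", object@subjectId,
      " pixel size:", object@pixelSizeUm, "um",
      if (nrow(object@regionMask)) " (+region mask)" else "", "\n")
})

setMethod("show", "LabelMask", function(object) {
  cat("LabelMask(", object@kind, "): ", nrow(object@labels), " x ",
      ncol(object@labels), " px, ", numLabels(object), " instance(s)\n",
      sep = "")
})

setMethod("show", "CellRecord", function(object) {
  cat("CellRecord #", object@cellId, ": soma ", length(object@somaPixels),
      " px, cytoplasm ", length(object@cytoplasmPixels), " px, processes ",
      length(object@processPixels), " px (total ", object@totalAreaPx,
      " px)\n", sep = "")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult: ", object@nCorrect, "/", object@nTruth,
      " truth cells captured, FP ", object@nFalsePositive, ", FN ",
      object@nFalseNegative, ", median Dice ",
      if (length(object@perCellDice)) round(stats::median(object@perCellDice), 3)
      else NA, "\n", sep = "")
})
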