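# Staged whole-microglia segmentation: nuclei (DAPI) and somas (summed
# membrane signal) from Otsu-initialized level sets; vessels from the
# autofluorescence channel; a finer cytoplasm stage with weaker
# regularization (Li-initialized when a vessel is present); assignment of
# components to somas; marker-controlled splitting of cytoplasm shared by
# several somas; and attachment of detached processes within a 10 px
# radius of each soma.

#' Pixelwise sum of the four membrane-marker planes
#'
#' The soma and cytoplasm stages operate on the summed TMEM119 + P2RY12 +
#' FTL + Iba1 signal, so every microglia is visible regardless of which
#' markers it expresses.
#'
#' @param image a \linkS4class{ComponentImage} with all four membrane
#'   planes.
#' @return numeric matrix.
#' @export
membraneSum <- function(image) {
  requireChannels(image, MEMBRANE_MARKERS)
  p <- planes(image)
  p[["TMEM119"]] + p[["P2RY12"]] + p[["FTL"]] + p[["Iba1"]]
}

## shared staged-threshold + level-set + label + area-filter step
levelSetStage <- function(pln, params, minArea, connectivity,
                          init = NULL, excludeMask = NULL, stage = "stage",
                          anchorMask = NULL) {
  empty <- matrix(0L, nrow(pln), ncol(pln))
  if (is.null(init)) {
    init <- tryCatch(otsuThreshold(pln)$mask, error = function(e) {
      warning(stage, ": thresholding failed (", conditionMessage(e),
              "); returning empty mask")
      NULL
    })
    if (is.null(init)) return(empty)
  }
  if (!any(init)) return(empty)
  u <- evolveLevelSet(pln, init, params, anchorMask = anchorMask)
  if (!is.null(excludeMask)) u <- u & !excludeMask
  lab <- labelConnected(u, connectivity)
  filterLabelsByArea(lab, min_area = minArea)
}

#' Segment microglia nuclei from the DAPI plane
#'
#' Level set (nu = 2, mu = 3) initialized from the Otsu mask of the DAPI
#' component image; connected components below 30 px are removed.
#'
#' @param image a \linkS4class{ComponentImage} with a DAPI plane.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return \linkS4class{LabelMask} of kind "nucleus".
#' @export
segmentNuclei <- function(image, config = SegmentationConfig()) {
  requireChannels(image, "DAPI")
  lab <- levelSetStage(plane(image, "DAPI"), config@nucleusParams,
                       config@minNucleusAreaPx, config@connectivity,
                       stage = "segmentNuclei")
  LabelMask(lab, "nucleus")
}

#' Segment microglia somas from the summed membrane signal
#'
#' Level set (nu = 2, mu = 3) on the membrane sum, Otsu-initialized;
#' components below 50 px are removed.
#'
#' @inheritParams segmentNuclei
#' @return \linkS4class{LabelMask} of kind "soma".
#' @export
segmentSomas <- function(image, config = SegmentationConfig()) {
  lab <- levelSetStage(membraneSum(image), config@somaParams,
                       config@minSomaAreaPx, config@connectivity,
                       stage = "segmentSomas")
  LabelMask(lab, "soma")
}

#' Detect blood vessels on the autofluorescence channel
#'
#' Otsu threshold of the autofluorescence plane; connected components
#' strictly larger than 4000 px are vessels. Without an AF channel the
#' mask is empty.
#'
#' @inheritParams segmentNuclei
#' @return \linkS4class{LabelMask} of kind "vessel".
#' @export
detectVessels <- function(image, config = SegmentationConfig()) {
  dm <- dim(planes(image)[[1L]])
  if (!"AF" %in% names(planes(image))) {
    message("detectVessels: no autofluorescence channel; empty vessel mask")
    return(LabelMask(matrix(0L, dm[1L], dm[2L]), "vessel"))
  }
  af <- plane(image, "AF")
  mask <- tryCatch(otsuThreshold(af)$mask, error = function(e) NULL)
  if (is.null(mask))
    return(LabelMask(matrix(0L, dm[1L], dm[2L]), "vessel"))
  lab <- labelConnected(mask, config@connectivity)
  lab <- filterLabelsByArea(lab, strict_min = config@vesselMinAreaPx)
  LabelMask(lab, "vessel")
}

#' Segment the full cytoplasmic area
#'
#' Repeats the soma approach with weaker regularization (nu = 2, mu = 2),
#' capturing microglia areas less bright than the soma: the
#' already-identified somas are anchored as foreground and excluded from
#' the foreground-mean estimate, so the evolution tracks the dimmer
#' cytoplasmic class. When a vessel was identified, the level set is
#' initialized from the Li threshold instead of Otsu (Li is less
#' sensitive to the very bright vessel pixels); vessel pixels are
#' excluded from the result. Components are labelled but not yet
#' assigned to somas.
#'
#' @param image a \linkS4class{ComponentImage}.
#' @param somaMask \linkS4class{LabelMask} from \code{segmentSomas}
#'   (optional; NULL runs an un-anchored evolution).
#' @param vesselMask \linkS4class{LabelMask} from \code{detectVessels}.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return \linkS4class{LabelMask} of kind "component".
#' @export
segmentCytoplasm <- function(image, somaMask = NULL, vesselMask,
                             config = SegmentationConfig()) {
  pln <- membraneSum(image)
  useLi <- numLabels(vesselMask) > 0L
  init <- tryCatch({
    if (useLi) liThreshold(pln)$mask else otsuThreshold(pln)$mask
  }, error = function(e) {
    warning("segmentCytoplasm: thresholding failed (", conditionMessage(e),
            "); returning empty mask")
    NULL
  })
  if (is.null(init))
    return(LabelMask(matrix(0L, nrow(pln), ncol(pln)), "component"))
  anchor <- if (is.null(somaMask) || numLabels(somaMask) == 0L) NULL
            else labels2d(somaMask) > 0L
  lab <- levelSetStage(pln, config@cytoplasmParams, minArea = 1L,
                       connectivity = config@connectivity, init = init,
                       excludeMask = labels2d(vesselMask) > 0L,
                       stage = "segmentCytoplasm", anchorMask = anchor)
  LabelMask(lab, "component")
}

#' Assign cytoplasm components to somas
#'
#' A component overlapping exactly one soma joins that soma's cell;
#' components overlapping no soma are candidate detached processes
#' (orphans); components overlapping two or more somas are deferred to
#' \code{splitSharedCytoplasm}.
#'
#' @param components \linkS4class{LabelMask} of kind "component".
#' @param somaMask \linkS4class{LabelMask} of kind "soma".
#' @return list with \code{assigned} (named list: soma id -> linear pixel
#'   indices), \code{shared} (list of list(pixels, somaIds)) and
#'   \code{orphans} (list of pixel-index vectors).
#' @export
assignComponents <- function(components, somaMask) {
  comp <- labels2d(components); soma <- labels2d(somaMask)
  stopifnot(identical(dim(comp), dim(soma)))
  assigned <- list(); shared <- list(); orphans <- list()
  if (max(comp) > 0L) {
    pix <- which(comp > 0L)
    bycomp <- split(pix, comp[pix])
    for (cid in names(bycomp)) {
      px <- bycomp[[cid]]
      sids <- sort(unique(soma[px]))
      sids <- sids[sids > 0L]
      if (length(sids) == 0L) {
        orphans[[length(orphans) + 1L]] <- px
      } else if (length(sids) == 1L) {
        key <- as.character(sids)
        assigned[[key]] <- c(assigned[[key]], px)
      } else {
        shared[[length(shared) + 1L]] <- list(pixels = px, somaIds = sids)
      }
    }
  }
  list(assigned = assigned, shared = shared, orphans = orphans)
}

#' Split cytoplasm shared among multiple somas
#'
#' Marker-controlled watershed implemented as synchronous multi-source
#' region growing: the component pixels overlapping each soma seed that
#' soma's region, and regions grow ring by ring (8-connected) until the
#' component is exhausted. Every component pixel ends up in exactly one
#' partition; where two fronts meet in the same ring, the lower soma id
#' wins (deterministic tie-break).
#'
#' @param sharedPixels linear pixel indices of the shared component.
#' @param somaMask \linkS4class{LabelMask} of kind "soma".
#' @return named list: soma id -> linear pixel indices; the union equals
#'   the component and partitions are pairwise disjoint.
#' @export
splitSharedCytoplasm <- function(sharedPixels, somaMask) {
  soma <- labels2d(somaMask)
  dm <- dim(soma)
  sids <- sort(unique(soma[sharedPixels]))
  sids <- sids[sids > 0L]
  if (length(sids) < 2L)
    stop("shared component must overlap at least two somas")
  inComp <- matrix(FALSE, dm[1L], dm[2L]); inComp[sharedPixels] <- TRUE
  lab <- matrix(0L, dm[1L], dm[2L])
  seed <- inComp & soma > 0L
  lab[seed] <- soma[seed]
  repeat {
    cand <- matrix(0L, dm[1L], dm[2L])
    for (i in seq_len(nrow(NEIGH8))) {
      sh <- shiftMatrix(lab, NEIGH8[i, 1L], NEIGH8[i, 2L])
      upd <- sh > 0L & (cand == 0L | sh < cand)
      cand[upd] <- sh[upd]
    }
    grow <- inComp & lab == 0L & cand > 0L
    if (!any(grow)) break
    lab[grow] <- cand[grow]
  }
  left <- inComp & lab == 0L  # pixels unreachable under 8-connectivity
  if (any(left)) lab[left] <- sids[1L]
  out <- lapply(sids, function(s) which(lab == s & inComp))
  names(out) <- as.character(sids)
  out
}

#' Attach detached processes to the nearest soma
#'
#' An orphan component whose minimum Euclidean pixel-centre distance to a
#' soma region is at most `radiusPx` (default 10) is appended to that
#' soma's cell; the nearest soma wins, ties go to the lower soma id.
#' Orphans farther than the radius from every soma are discarded.
#'
#' @param assigned named list (soma id -> cytoplasm pixel indices) from
#'   \code{assignComponents} / \code{splitSharedCytoplasm}.
#' @param orphans list of pixel-index vectors.
#' @param somaMask \linkS4class{LabelMask} of kind "soma".
#' @param radiusPx attachment radius in pixels ("within a 10 pixel
#'   radius" read as distance <= 10.0 from the soma region boundary).
#' @return list with \code{processes} (named list: soma id -> process
#'   pixel indices) and \code{nDiscarded}.
#' @export
attachProcesses <- function(assigned, orphans, somaMask, radiusPx = 10) {
  stopifnot(radiusPx >= 0)
  soma <- labels2d(somaMask)
  sids <- sort(unique(soma[soma > 0L]))
  processes <- stats::setNames(vector("list", length(sids)),
                               as.character(sids))
  nDiscarded <- 0L
  if (length(orphans) && length(sids)) {
    dmaps <- lapply(sids, function(s)
      as.matrix(EBImage::distmap(matrix(as.numeric(soma != s),
                                        nrow(soma), ncol(soma)))))
    for (px in orphans) {
      d <- vapply(dmaps, function(dm) min(dm[px]), 0)
      best <- min(d)
      if (best <= radiusPx) {
        sid <- as.character(sids[which(d == best)[1L]])  # lower id on tie
        processes[[sid]] <- c(processes[[sid]], px)
      } else {
        nDiscarded <- nDiscarded + 1L
      }
    }
  } else {
    nDiscarded <- length(orphans)
  }
  list(processes = processes, nDiscarded = nDiscarded)
}

#' Identify amyloid-beta plaques
#'
#' Threshold mode (default): Otsu on the Abeta plane, morphological
#' closing, component labelling, minimum-area filter. Classifier mode: a
#' pixel classifier trained from sparse scribble annotations (see
#' \code{trainPlaqueClassifier}) predicts the plaque probability, which is
#' thresholded at 0.5 before the same morphology and area filter.
#'
#' @param image a \linkS4class{ComponentImage} with an Abeta plane.
#' @param config a \linkS4class{SegmentationConfig}.
#' @param model optional classifier from \code{trainPlaqueClassifier};
#'   when supplied, classifier mode is used.
#' @return \linkS4class{LabelMask} of kind "plaque".
#' @export
identifyPlaques <- function(image, config = SegmentationConfig(),
                            model = NULL) {
  requireChannels(image, "Abeta")
  ab <- plane(image, "Abeta")
  empty <- LabelMask(matrix(0L, nrow(ab), ncol(ab)), "plaque")
  if (is.null(model)) {
    mask <- tryCatch(otsuThreshold(ab)$mask, error = function(e) NULL)
    if (is.null(mask)) return(empty)
  } else {
    prob <- predictPlaqueProb(model, ab)
    mask <- prob > 0.5
    if (!any(mask)) return(empty)
  }
  mask <- as.matrix(EBImage::closing(mask, EBImage::makeBrush(5, "disc"))) > 0
  lab <- labelConnected(mask, config@connectivity)
  lab <- filterLabelsByArea(lab, min_area = config@plaqueMinAreaPx)
  LabelMask(lab, "plaque")
}

## feature bank for the plaque pixel classifier
plaqueFeatures <- function(plnRaw) {
  rng <- range(plnRaw)
  pln <- if (diff(rng) > 0) (plnRaw - rng[1L]) / diff(rng) else plnRaw * 0
  g1 <- as.matrix(EBImage::gblur(pln, sigma = 1))
  g2 <- as.matrix(EBImage::gblur(pln, sigma = 2))
  g4 <- as.matrix(EBImage::gblur(pln, sigma = 4))
  gx <- shiftMatrix(pln, 0, -1) - shiftMatrix(pln, 0, 1)
  gy <- shiftMatrix(pln, -1, 0) - shiftMatrix(pln, 1, 0)
  cbind(raw = as.numeric(pln), g1 = as.numeric(g1), g2 = as.numeric(g2),
        g4 = as.numeric(g4), dog = as.numeric(g1 - g4),
        grad = as.numeric(sqrt(gx^2 + gy^2)))
}

#' Train the semi-supervised plaque pixel classifier
#'
#' Random-forest pixel classifier over a small feature bank (intensity,
#' Gaussian smoothings at sigma 1/2/4, difference of Gaussians, gradient
#' magnitude), trained from sparse scribble annotations: a label matrix
#' with 0 = unlabelled, 1 = background, 2 = plaque.
#'
#' @param image a \linkS4class{ComponentImage} with an Abeta plane.
#' @param scribbles integer matrix of the same dimension (0/1/2).
#' @param seed RNG seed for the forest (explicit; no global state
#'   assumed).
#' @param ntree number of trees.
#' @return classifier object for \code{identifyPlaques}.
#' @export
trainPlaqueClassifier <- function(image, scribbles, seed = 1L,
                                  ntree = 50L) {
  requireChannels(image, "Abeta")
  feats <- plaqueFeatures(plane(image, "Abeta"))
  sel <- which(scribbles > 0L)
  if (length(sel) < 10L) stop("need at least 10 annotated pixels")
  y <- factor(as.integer(scribbles[sel]) == 2L, levels = c(FALSE, TRUE))
  set.seed(seed)
  fit <- randomForest::randomForest(feats[sel, , drop = FALSE], y,
                                    ntree = ntree)
  structure(list(fit = fit), class = "plaqueClassifier")
}

predictPlaqueProb <- function(model, ab) {
  feats <- plaqueFeatures(ab)
  prob <- stats::predict(model$fit, feats, type = "prob")[, "TRUE"]
  matrix(prob, nrow(ab), ncol(ab))
}

#' Run the full staged microglia segmentation on one image
#'
#' Nuclei, somas (optionally filtered to those overlapping a nucleus),
#' vessels, cytoplasm, component assignment, watershed splitting of shared
#' cytoplasm, process attachment and plaque identification, producing one
#' \linkS4class{CellRecord} per microglia with mean membrane-marker
#' intensities over the full segmented cell area.
#'
#' @param image a \linkS4class{ComponentImage} (DAPI + four membrane
#'   planes required; Abeta and AF optional).
#' @param config a \linkS4class{SegmentationConfig}.
#' @param plaqueModel optional classifier for plaque identification.
#' @return list with \code{cells} (list of \linkS4class{CellRecord}),
#'   \code{cellMask}, \code{somaMask}, \code{nucleusMask},
#'   \code{plaqueMask}, \code{vesselMask}.
#' @export
segmentImage <- function(image, config = SegmentationConfig(),
                         plaqueModel = NULL) {
  requireChannels(image, c("DAPI", MEMBRANE_MARKERS))
  dm <- dim(planes(image)[[1L]])
  nucleusMask <- segmentNuclei(image, config)
  somaMask <- segmentSomas(image, config)
  if (config@requireNucleusOverlap && numLabels(somaMask) > 0L) {
    soma <- labels2d(somaMask); nuc <- labels2d(nucleusMask)
    keep <- sort(unique(soma[soma > 0L & nuc > 0L]))
    somaMask <- LabelMask(compactLabels(soma, keep), "soma")
  }
  vesselMask <- detectVessels(image, config)
  components <- segmentCytoplasm(image, somaMask, vesselMask, config)
  asg <- assignComponents(components, somaMask)
  for (sh in asg$shared) {
    parts <- splitSharedCytoplasm(sh$pixels, somaMask)
    for (sid in names(parts))
      asg$assigned[[sid]] <- c(asg$assigned[[sid]], parts[[sid]])
  }
  att <- attachProcesses(asg$assigned, asg$orphans, somaMask,
                         config@processAttachRadiusPx)
  plaqueMask <- if ("Abeta" %in% names(planes(image)))
    identifyPlaques(image, config, plaqueModel)
  else LabelMask(matrix(0L, dm[1L], dm[2L]), "plaque")

  soma <- labels2d(somaMask); nuc <- labels2d(nucleusMask)
  sids <- sort(unique(soma[soma > 0L]))
  mem <- if (length(sids)) lapply(planes(image)[MEMBRANE_MARKERS],
                                  as.numeric) else NULL
  rmask <- image@regionMask
  cells <- list(); cellLab <- matrix(0L, dm[1L], dm[2L])
  cid <- 0L
  for (s in sids) {
    somaPx <- which(soma == s)
    cytoPx <- setdiff(asg$assigned[[as.character(s)]] %||% integer(0), somaPx)
    procPx <- setdiff(att$processes[[as.character(s)]] %||% integer(0),
                      c(somaPx, cytoPx))
    allPx <- c(somaPx, cytoPx, procPx)
    rc <- ind2rc(somaPx, dm)
    region <- "GM"
    if (nrow(rmask) > 0L) {
      reg <- rmask[somaPx]
      reg <- reg[reg %in% c("GM", "WM")]
      if (length(reg) == 0L) next  # soma in excluded tissue
      region <- names(which.max(table(reg)))
    }
    nover <- nuc[somaPx]
    nucId <- if (any(nover > 0L))
      as.integer(names(which.max(table(nover[nover > 0L])))) else NA_integer_
    mi <- vapply(MEMBRANE_MARKERS,
                 function(m) mean(mem[[m]][allPx]), 0)
    cid <- cid + 1L
    cells[[cid]] <- CellRecord(cellId = cid, somaPixels = somaPx,
                               cytoplasmPixels = cytoPx,
                               processPixels = procPx, imageDim = dm,
                               meanIntensity = mi, nucleusId = nucId,
                               region = region,
                               subjectId = subjectId(image))
    cellLab[allPx] <- cid
  }
  list(cells = cells, cellMask = LabelMask(cellLab, "cell"),
       somaMask = somaMask, nucleusMask = nucleusMask,
       plaqueMask = plaqueMask, vesselMask = vesselMask)
}
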