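# Synthetic multi-channel image, feature-table and cohort generators with
# full ground truth, emulating the structure the pipeline assumes:
# ramified cells with bright somas and dimmer, partly detached processes,
# a DAPI nucleus inside each soma, marker co-expression cluster structure,
# Abeta plaques enriched for infiltration by one cluster, large
# autofluorescent vessels, and additive Gaussian noise. All generators are
# bit-reproducible given a seed and leave the caller's RNG state intact.

## evaluate `code` under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' GroundTruth: what the synthetic generator actually drew
#'
#' @slot cellMasks,nucleusMasks,plaqueMask,vesselMask
#'   \linkS4class{LabelMask} instances (cell i has label i).
#' @slot trueCluster named integer: cell id -> planted cluster.
#' @slot enrichment planted odds multiplier (>= 1) for the enriched
#'   cluster near plaques.
#' @export
setClass("GroundTruth",
  representation(cellMasks = "LabelMask", nucleusMasks = "LabelMask",
                 plaqueMask = "LabelMask", vesselMask = "LabelMask",
                 trueCluster = "integer", enrichment = "numeric"))

setValidity("GroundTruth", function(object) {
  ids <- as.integer(names(object@trueCluster))
  if (length(ids) && numLabels(object@cellMasks) < max(ids))
    return("every cell id in trueCluster must exist in cellMasks")
  if (object@enrichment < 1) return("enrichment must be >= 1")
  TRUE
})

#' Default marker co-expression profiles for the planted clusters
#'
#' Three nominal phenotypes: a homeostatic P2RY12+/TMEM119+ profile, an
#' activated FTL+/Iba1+ profile with homeostatic markers lost, and an
#' intermediate profile co-expressing everything at a moderate level.
#' Intensities are nominal (relative to the soma brightness of 1), not
#' measured values.
#'
#' @return list of 4x2 matrices (rows TMEM119/P2RY12/FTL/Iba1, columns
#'   mean/sd).
#' @export
defaultClusterProfiles <- function() {
  mk <- function(m) {
    x <- cbind(mean = m, sd = rep(0.08, 4))
    rownames(x) <- MEMBRANE_MARKERS
    x
  }
  list(homeostatic = mk(c(0.85, 0.90, 0.20, 0.30)),
       ftl_iba1    = mk(c(0.15, 0.15, 0.95, 0.85)),
       intermediate = mk(c(0.55, 0.55, 0.55, 0.55)))
}

#' Specification of one synthetic microglia
#'
#' @param somaRadiusPx soma disk radius (default 6 px, area ~113 px,
#'   comfortably above the 50 px soma filter).
#' @param nProcesses number of processes (default 3).
#' @param processLengthPx random-walk process length (default 22 px).
#' @param detachProbability probability that a process is detached from
#'   the soma by an erased root gap (default 0.2).
#' @param markerProfile 4x2 matrix (mean, sd per membrane marker).
#' @param clusterId planted cluster id.
#' @param nearPlaque place this cell overlapping a plaque boundary.
#' @return list of class "SyntheticCellSpec".
#' @export
syntheticCellSpec <- function(somaRadiusPx = 6, nProcesses = 3,
                              processLengthPx = 22, detachProbability = 0.2,
                              markerProfile = defaultClusterProfiles()[[1L]],
                              clusterId = 1L, nearPlaque = FALSE) {
  stopifnot(detachProbability >= 0, detachProbability <= 1,
            all(markerProfile[, "sd"] >= 0), somaRadiusPx > 0)
  structure(list(somaRadiusPx = somaRadiusPx, nProcesses = nProcesses,
                 processLengthPx = processLengthPx,
                 detachProbability = detachProbability,
                 markerProfile = markerProfile,
                 clusterId = as.integer(clusterId),
                 nearPlaque = nearPlaque),
            class = "SyntheticCellSpec")
}

diskPixels <- function(r0, c0, rad, dm) {
  rr <- max(1L, floor(r0 - rad)):min(dm[1L], ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(dm[2L], ceiling(c0 + rad))
  g <- expand.grid(r = rr, c = cc)
  g <- g[(g$r - r0)^2 + (g$c - c0)^2 <= rad^2, ]
  rc2ind(g$r - 1L, g$c - 1L, dm)
}

## rasterize a random-walk process; returns list(all, root) of linear idx
walkProcess <- function(r0, c0, somaR, len, width, dm) {
  ang <- stats::runif(1, 0, 2 * pi)
  # start just inside the soma so the rendered root always touches it
  pr <- r0 + (somaR - 1) * sin(ang); pc <- c0 + (somaR - 1) * cos(ang)
  pts <- matrix(0, nrow = len + 1L, ncol = 2)
  pts[1L, ] <- c(pr, pc)
  for (i in seq_len(len)) {
    ang <- ang + stats::rnorm(1, 0, 0.25)
    pr <- pr + sin(ang); pc <- pc + cos(ang)
    pts[i + 1L, ] <- c(pr, pc)
  }
  ri <- pmin(pmax(round(pts[, 1]), 1), dm[1L])
  ci <- pmin(pmax(round(pts[, 2]), 1), dm[2L])
  px <- rc2ind(ri - 1L, ci - 1L, dm)
  if (width >= 2) {
    offs <- if (width == 2) cbind(c(0, 1, 1), c(1, 0, 1)) else NEIGH8
    for (k in seq_len(nrow(offs))) {
      r2 <- pmin(pmax(ri + offs[k, 1], 1), dm[1L])
      c2 <- pmin(pmax(ci + offs[k, 2], 1), dm[2L])
      px <- c(px, rc2ind(r2 - 1L, c2 - 1L, dm))
    }
  }
  dist2 <- function(ind) {
    rc <- ind2rc(ind, dm)
    (rc[, 1L] + 1 - r0)^2 + (rc[, 2L] + 1 - c0)^2
  }
  px <- unique(px)
  list(all = px, dist2 = dist2(px))
}

#' Generate one synthetic multi-channel image with ground truth
#'
#' Cells are placed on a jittered grid (bounded capacity; an infeasible
#' request errors). Each cell gets a bright soma disk, 1-3 px wide
#' random-walk processes at lower intensity, and a DAPI nucleus inside the
#' soma; per-cell marker levels are drawn from the cell's cluster profile.
#' Plaques are irregular Abeta blobs; vessels are full-height
#' autofluorescent bands larger than 4000 px that also bleed faintly into
#' the membrane channels. Additive Gaussian noise is clipped at 0 and
#' intensities are quantized to the 16-bit grid, so written images
#' round-trip bit-identically.
#'
#' @param imageSize c(height, width) in px.
#' @param cellSpecs list of \code{syntheticCellSpec}.
#' @param nPlaques,nVessels counts.
#' @param noiseSd additive Gaussian noise sd (default 0.06 against a soma
#'   intensity of 1).
#' @param seed RNG seed (explicit; caller's RNG state is untouched).
#' @param gapWidthPx erased root gap for detached processes (default 4,
#'   within the 10 px attachment radius).
#' @param enrichment recorded planted infiltration-odds multiplier
#'   (bookkeeping only; placement enrichment is decided by the caller via
#'   `nearPlaque` flags).
#' @param pixelSizeUm,subjectIdLabel image metadata.
#' @return list(image = \linkS4class{ComponentImage},
#'   truth = \linkS4class{GroundTruth}).
#' @export
simulateImage <- function(imageSize = c(384L, 384L), cellSpecs = list(),
                          nPlaques = 0L, nVessels = 0L, noiseSd = 0.06,
                          seed = 1L, gapWidthPx = 4, enrichment = 1,
                          pixelSizeUm = 0.5, subjectIdLabel = "synthetic") {
  withSeed(seed, {
    dm <- as.integer(imageSize)
    chan <- c("DAPI", MEMBRANE_MARKERS, "Abeta", "AF")
    pl <- stats::setNames(lapply(chan, function(x) matrix(0, dm[1L], dm[2L])),
                          chan)
    cellLab <- matrix(0L, dm[1L], dm[2L])
    nucLab <- matrix(0L, dm[1L], dm[2L])
    plaqueBin <- matrix(FALSE, dm[1L], dm[2L])
    vesselBin <- matrix(FALSE, dm[1L], dm[2L])

    extent <- 34L
    xs <- seq(extent + 1L, dm[1L] - extent, by = 2L * extent + 2L)
    ys <- seq(extent + 1L, dm[2L] - extent, by = 2L * extent + 2L)
    slots <- as.matrix(expand.grid(r = xs, c = ys))

    # vessels first: full-height bands occupying (and removing) slot columns
    if (nVessels > 0L) {
      vcols <- ys[sample.int(length(ys), min(nVessels, length(ys)))]
      for (vc in vcols) {
        cc <- max(1L, vc - 7L):min(dm[2L], vc + 7L)
        vesselBin[, cc] <- TRUE
        slots <- slots[abs(slots[, "c"] - vc) > extent, , drop = FALSE]
      }
      pl[["AF"]][vesselBin] <- 0.8
      for (m in MEMBRANE_MARKERS) pl[[m]][vesselBin] <- 0.25
    }

    nearIdx <- which(vapply(cellSpecs, function(s) isTRUE(s$nearPlaque), TRUE))
    nPlaqueSlots <- max(nPlaques, 0L)
    needed <- length(cellSpecs) - length(nearIdx) + nPlaqueSlots
    if (needed > nrow(slots))
      stop("generation error: ", length(cellSpecs), " cells + ", nPlaques,
           " plaques do not fit the ", nrow(slots), " placement slots")
    ord <- sample(nrow(slots))
    plaqueSlots <- if (nPlaqueSlots > 0L)
      slots[ord[seq_len(nPlaqueSlots)], , drop = FALSE] else NULL
    freeSlots <- if (nPlaqueSlots > 0L)
      slots[ord[-seq_len(nPlaqueSlots)], , drop = FALSE]
    else slots[ord, , drop = FALSE]

    plaqueCentres <- NULL
    if (nPlaques > 0L) {
      for (p in seq_len(nPlaques)) {
        ctr <- plaqueSlots[p, ] + round(stats::runif(2, -4, 4))
        for (b in seq_len(5L)) {
          off <- stats::rnorm(2, 0, 3)
          plaqueBin[diskPixels(ctr[1L] + off[1L], ctr[2L] + off[2L],
                               stats::runif(1, 5, 8), dm)] <- TRUE
        }
        plaqueCentres <- rbind(plaqueCentres, ctr)
      }
      pl[["Abeta"]][plaqueBin] <- 0.85
    }

    freeCursor <- 0L
    for (i in seq_along(cellSpecs)) {
      sp <- cellSpecs[[i]]
      if (isTRUE(sp$nearPlaque) && !is.null(plaqueCentres)) {
        pc <- plaqueCentres[1L + (i %% nrow(plaqueCentres)), ]
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- round(pc + 9 * c(sin(ang), cos(ang)))
        ctr <- pmin(pmax(ctr, extent), c(dm[1L], dm[2L]) - extent)
      } else {
        freeCursor <- freeCursor + 1L
        if (freeCursor > nrow(freeSlots))
          stop("generation error: ran out of placement slots")
        ctr <- freeSlots[freeCursor, ] + round(stats::runif(2, -8, 8))
      }
      r0 <- ctr[1L]; c0 <- ctr[2L]
      somaPx <- diskPixels(r0, c0, sp$somaRadiusPx, dm)
      procPx <- integer(0)
      for (b in seq_len(sp$nProcesses)) {
        w <- sample(1:3, 1L)
        pr <- walkProcess(r0, c0, sp$somaRadiusPx, sp$processLengthPx, w, dm)
        px <- setdiff(pr$all, somaPx)
        if (stats::runif(1) < sp$detachProbability) {
          d2 <- (ind2rc(px, dm)[, 1L] + 1 - r0)^2 +
                (ind2rc(px, dm)[, 2L] + 1 - c0)^2
          px <- px[sqrt(d2) > sp$somaRadiusPx + gapWidthPx]
        }
        procPx <- c(procPx, px)
      }
      procPx <- setdiff(unique(procPx), somaPx)
      lv <- pmin(pmax(stats::rnorm(4, sp$markerProfile[, "mean"],
                                   sp$markerProfile[, "sd"]), 0.05), 1)
      names(lv) <- MEMBRANE_MARKERS
      for (m in MEMBRANE_MARKERS) {
        pm <- pl[[m]]
        pm[somaPx] <- pmax(pm[somaPx], lv[[m]])
        pm[procPx] <- pmax(pm[procPx], 0.45 * lv[[m]])
        pl[[m]] <- pm
      }
      nucPx <- intersect(diskPixels(r0, c0, 3.5, dm), somaPx)
      pl[["DAPI"]][nucPx] <- 0.9
      cellLab[c(somaPx, procPx)] <- i
      nucLab[nucPx] <- i
    }

    # mild optical blur, then noise, clip, 16-bit quantization
    for (m in names(pl)) {
      x <- as.matrix(EBImage::gblur(pl[[m]], sigma = 0.5))
      if (noiseSd > 0) x <- x + stats::rnorm(length(x), 0, noiseSd)
      x <- pmin(pmax(x, 0), 1)
      pl[[m]] <- matrix(round(x * 65535) / 65535, dm[1L], dm[2L])
    }

    truth <- new("GroundTruth",
                 cellMasks = LabelMask(cellLab, "cell"),
                 nucleusMasks = LabelMask(nucLab, "nucleus"),
                 plaqueMask = LabelMask(labelConnected(plaqueBin), "plaque"),
                 vesselMask = LabelMask(labelConnected(vesselBin), "vessel"),
                 trueCluster = if (length(cellSpecs))
                   stats::setNames(vapply(cellSpecs, `[[`, 1L, "clusterId"),
                                   seq_along(cellSpecs))
                 else stats::setNames(integer(0), character(0)),
                 enrichment = enrichment)
    list(image = ComponentImage(pl, pixelSizeUm = pixelSizeUm,
                                subjectId = subjectIdLabel),
         truth = truth)
  })
}

#' Generate a feature table from a planted Gaussian mixture
#'
#' Draws `nCells` cells from a mixture over the 4-marker space with the
#' given per-cluster means, sds and proportions.
#'
#' @param nCells number of cells.
#' @param clusterMeans K x 4 matrix (columns in membrane-marker order).
#' @param clusterSds K x 4 matrix, or a scalar.
#' @param proportions length-K vector summing to 1.
#' @param seed RNG seed.
#' @return list(features = data.frame with the four marker columns,
#'   labels = integer vector of true clusters).
#' @export
simulateFeatureTable <- function(nCells, clusterMeans, clusterSds = 1,
                                 proportions, seed = 1L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            nrow(clusterMeans) == length(proportions))
  K <- nrow(clusterMeans)
  if (length(clusterSds) == 1L)
    clusterSds <- matrix(clusterSds, K, ncol(clusterMeans))
  if (any(clusterSds == 0) && anyDuplicated(clusterMeans))
    warning("sd = 0 with duplicate means: clusters are indistinguishable")
  withSeed(seed, {
    labels <- sample.int(K, nCells, replace = TRUE, prob = proportions)
    X <- clusterMeans[labels, , drop = FALSE] +
      matrix(stats::rnorm(nCells * ncol(clusterMeans)), nCells) *
      clusterSds[labels, , drop = FALSE]
    colnames(X) <- if (!is.null(colnames(clusterMeans))) colnames(clusterMeans)
                   else MEMBRANE_MARKERS[seq_len(ncol(X))]
    list(features = as.data.frame(X), labels = labels)
  })
}

#' Generate a synthetic cohort of images with group structure
#'
#' AD subjects receive more plaques and a higher proportion of the
#' FTL+/Iba1+ cluster, with a planted infiltration enrichment (cells of
#' the enriched cluster are preferentially placed overlapping plaques);
#' controls receive predominantly homeostatic-profile cells.
#'
#' @param nControl,nAd subjects per group.
#' @param cellsPerImage cells per subject image.
#' @param imageSize image dimension.
#' @param clusterProportions list(control=, AD=) of length-3 proportions
#'   over \code{defaultClusterProfiles()}.
#' @param plaquesPerSubject list(control=, AD=) plaque counts.
#' @param enrichment odds multiplier (>= 1) for the FTL+/Iba1+ cluster
#'   among plaque-adjacent cells.
#' @param noiseSd,seed as \code{simulateImage}.
#' @return list of list(image, truth, meta) per subject; meta has
#'   subject_id and group.
#' @export
simulateCohort <- function(nControl = 2L, nAd = 2L, cellsPerImage = 15L,
                           imageSize = c(384L, 384L),
                           clusterProportions = list(
                             control = c(0.75, 0.05, 0.20),
                             AD = c(0.45, 0.30, 0.25)),
                           plaquesPerSubject = list(control = 0L, AD = 3L),
                           enrichment = 3, noiseSd = 0.06, seed = 1L) {
  stopifnot(enrichment >= 1,
            abs(sum(clusterProportions$control) - 1) < 1e-8,
            abs(sum(clusterProportions$AD) - 1) < 1e-8)
  profiles <- defaultClusterProfiles()
  groups <- c(rep("control", nControl), rep("AD", nAd))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    sseed <- seed * 1000L + i
    props <- clusterProportions[[g]]
    nPlq <- plaquesPerSubject[[g]]
    specs <- withSeed(sseed, {
      cl <- sample.int(3L, cellsPerImage, replace = TRUE, prob = props)
      nNear <- if (nPlq > 0L) max(1L, round(0.25 * cellsPerImage)) else 0L
      near <- rep(FALSE, cellsPerImage)
      if (nNear > 0L) {
        # enriched cluster gets `enrichment`-fold odds of plaque adjacency
        w <- ifelse(cl == 2L, enrichment, 1)
        near[sample.int(cellsPerImage, nNear, prob = w)] <- TRUE
      }
      lapply(seq_len(cellsPerImage), function(j)
        syntheticCellSpec(markerProfile = profiles[[cl[j]]],
                          clusterId = cl[j], nearPlaque = near[j]))
    })
    sim <- simulateImage(imageSize, specs, nPlaques = nPlq,
                         noiseSd = noiseSd, seed = sseed + 1L,
                         enrichment = enrichment,
                         subjectIdLabel = sprintf("%s%02d", g, i))
    out[[i]] <- list(image = sim$image, truth = sim$truth,
                     meta = data.frame(subject_id = sprintf("%s%02d", g, i),
                                       group = g,
                                       stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a phenotyped-and-spatially-resolved cohort at the table level
#'
#' Draws, for each subject, cluster labels from the given proportions and
#' per-cell plaque-infiltration indicators with a planted odds multiplier
#' for one cluster. This is the cohort model used for statistical
#' calibration and power checks of the all-mic vs Abeta-mic comparison;
#' it skips image rendering entirely.
#'
#' @param nSubjects subjects.
#' @param cellsPerSubject cells per subject (default 3000, the order of
#'   magnitude of cells per subject in a full-scale study).
#' @param proportions cluster proportions.
#' @param enrichedCluster index of the enriched cluster.
#' @param baseRate baseline per-cell infiltration probability.
#' @param enrichment infiltration odds multiplier for the enriched
#'   cluster (1 = null).
#' @param seed RNG seed.
#' @return list(table = data.frame(cell_id, subject_id, cluster),
#'   infiltration = data.frame(cell_id, infiltrates_plaque, plaque_id)).
#' @export
simulateInfiltrationCohort <- function(nSubjects = 12L,
                                       cellsPerSubject = 3000L,
                                       proportions = c(0.45, 0.30, 0.25),
                                       enrichedCluster = 2L,
                                       baseRate = 0.05, enrichment = 3,
                                       seed = 1L) {
  stopifnot(enrichment >= 1, abs(sum(proportions) - 1) < 1e-8)
  withSeed(seed, {
    n <- nSubjects * cellsPerSubject
    subj <- rep(sprintf("S%02d", seq_len(nSubjects)), each = cellsPerSubject)
    cl <- sample.int(length(proportions), n, replace = TRUE,
                     prob = proportions)
    odds0 <- baseRate / (1 - baseRate)
    odds <- ifelse(cl == enrichedCluster, odds0 * enrichment, odds0)
    p <- odds / (1 + odds)
    infil <- stats::runif(n) < p
    list(table = data.frame(cell_id = seq_len(n), subject_id = subj,
                            cluster = cl, stringsAsFactors = FALSE),
         infiltration = data.frame(cell_id = seq_len(n),
                                   infiltrates_plaque = infil,
                                   plaque_id = ifelse(infil, 1L, NA_integer_)))
  })
}
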