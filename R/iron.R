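# Iron-positive cell counting on DAB-enhanced Perl's brightfield images:
# 8-bit grayscale conversion, per-subject threshold (DAB product is dark
# on a bright background), connected-component particle analysis with an
# inclusive 4-100 px size window, mirroring ImageJ particle-analyser
# semantics (the size filter is applied after labelling).

#' Convert an RGB image to 8-bit grayscale
#'
#' Luminance conversion round(0.299 R + 0.587 G + 0.114 B), clipped to
#' [0, 255]. Accepts an H x W x 3 array with values in 0..255 or 0..1
#' (the latter is rescaled).
#'
#' @param rgb H x W x 3 numeric array.
#' @return integer H x W matrix in 0..255.
#' @export
rgbToGray8 <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  g <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  g <- matrix(pmin(pmax(round(g), 0), 255), dim(rgb)[1L], dim(rgb)[2L])
  storage.mode(g) <- "integer"
  g
}

#' Count iron-positive particles
#'
#' Thresholds the grayscale image (dark polarity selects pixels <=
#' threshold), labels connected components inside the optional ROI, and
#' counts those with area inside the inclusive [minSizePx, maxSizePx]
#' window. The size window is applied after labelling, so an
#' over-threshold blob larger than the window is excluded rather than
#' split.
#'
#' @param gray integer matrix (0..255), e.g. from \code{rgbToGray8}.
#' @param config a \linkS4class{ParticleConfig}; `threshold` is the
#'   per-subject manual threshold. For an automatic (non-manual)
#'   threshold use \code{autoThreshold = TRUE}, which applies Otsu within
#'   the ROI.
#' @param roiMask optional logical matrix restricting the analysis; an
#'   all-FALSE ROI is an error.
#' @param pixelSizeUm optional pixel size for particle density per mm2.
#' @param autoThreshold replace `config@threshold` by the ROI Otsu
#'   threshold (a convenience mode, not part of the manual-threshold
#'   protocol).
#' @return list(nParticles, areas, densityPerMm2, threshold).
#' @export
countParticles <- function(gray, config, roiMask = NULL,
                           pixelSizeUm = NULL, autoThreshold = FALSE) {
  validObject(config)
  if (!is.null(roiMask)) {
    stopifnot(identical(dim(roiMask), dim(gray)))
    if (!any(roiMask)) stop("empty ROI")
  }
  thr <- config@threshold
  if (autoThreshold) {
    vals <- if (is.null(roiMask)) gray else gray[roiMask]
    thr <- as.integer(floor(otsuThreshold(matrix(as.numeric(vals)),
                                          levels = 256L,
                                          rangeValues = c(0, 255))$threshold))
  }
  binary <- if (config@polarity == "dark") gray <= thr else gray >= thr
  if (!is.null(roiMask)) binary <- binary & roiMask
  lab <- labelConnected(binary, config@connectivity)
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab))
           else integer(0)
  keep <- areas >= config@minSizePx & areas <= config@maxSizePx
  kept <- areas[keep]
  dens <- NULL
  if (!is.null(pixelSizeUm)) {
    areaMm2 <- (if (is.null(roiMask)) length(gray) else sum(roiMask)) *
      (pixelSizeUm / 1000)^2
    dens <- length(kept) / areaMm2
  }
  list(nParticles = length(kept), areas = as.integer(kept),
       densityPerMm2 = dens, threshold = thr)
}
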