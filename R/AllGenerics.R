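#' @include AllClasses.R
NULL

#' Accessors for GliaQuant classes
#'
#' `planes` returns the named list of intensity planes, `plane` a single
#' named plane, `pixelSize` the pixel side length in micrometres,
#' `subjectId` the subject identifier, `labels` the integer label matrix of
#' a \linkS4class{LabelMask}, `maskKind` its kind, and `numLabels` the
#' number of instances.
#'
#' @param x a \linkS4class{ComponentImage} or \linkS4class{LabelMask}.
#' @param name channel name for `plane`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("planes", function(x) standardGeneric("planes"))
#' @rdname accessors
#' @export
setGeneric("plane", function(x, name) standardGeneric("plane"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))
#' @rdname accessors
#' @export
setGeneric("maskKind", function(x) standardGeneric("maskKind"))
#' @rdname accessors
#' @export
setGeneric("numLabels", function(x) standardGeneric("numLabels"))

#' @rdname accessors
#' @export
setMethod("planes", "ComponentImage", function(x) x@planes)

#' @rdname accessors
#' @export
setMethod("plane", "ComponentImage", function(x, name) {
  if (!name %in% names(x@planes))
    stop("channel '", name, "' not present in this ComponentImage")
  x@planes[[name]]
})

#' @rdname accessors
#' @export
setMethod("pixelSize", "ComponentImage", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("subjectId", "ComponentImage", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("labels2d", "LabelMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("maskKind", "LabelMask", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("numLabels", "LabelMask", function(x) {
  if (length(x@labels) == 0L) return(0L)
  as.integer(max(x@labels))
})

#' Construct a ComponentImage
#'
#' @param planes named list of numeric intensity matrices (channels drawn
#'   from DAPI, TMEM119, P2RY12, FTL, Iba1, Abeta, AF).
#' @param pixelSizeUm pixel side length in micrometres (default 0.5).
#' @param subjectId subject identifier.
#' @param regionMask optional character matrix ("GM"/"WM"/"excluded").
#' @return a validated \linkS4class{ComponentImage}.
#' @export
ComponentImage <- function(planes, pixelSizeUm = 0.5, subjectId = "unknown",
                           regionMask = NULL) {
  planes <- lapply(planes, function(p) {
    storage.mode(p) <- "double"; p
  })
  new("ComponentImage", planes = planes, pixelSizeUm = pixelSizeUm,
      subjectId = subjectId,
      regionMask = if (is.null(regionMask)) matrix(character(0), 0, 0)
                   else regionMask)
}

#' Construct a LabelMask
#'
#' @param labels integer matrix (0 = background).
#' @param kind one of nucleus, soma, cell, plaque, vessel, component.
#' @return a validated \linkS4class{LabelMask}.
#' @export
LabelMask <- function(labels, kind = "component") {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, kind = kind)
}

#' Construct a CellRecord
#'
#' @param cellId integer id.
#' @param somaPixels,cytoplasmPixels,processPixels 1-based linear pixel
#'   indices (column-major) into an image of dimension `imageDim`.
#' @param imageDim c(nrow, ncol).
#' @param meanIntensity named numeric over the four membrane markers.
#' @param nucleusId,region,infiltratesPlaque,plaqueId,subjectId metadata.
#' @return a validated \linkS4class{CellRecord}; centroid and total area are
#'   computed from the pixel sets.
#' @export
CellRecord <- function(cellId, somaPixels, cytoplasmPixels = integer(0),
                       processPixels = integer(0), imageDim,
                       meanIntensity, nucleusId = NA_integer_,
                       region = "GM", infiltratesPlaque = FALSE,
                       plaqueId = NA_integer_, subjectId = "unknown") {
  allpx <- unique(c(as.integer(somaPixels), as.integer(cytoplasmPixels),
                    as.integer(processPixels)))
  rc <- ind2rc(allpx, imageDim)
  new("CellRecord", cellId = as.integer(cellId),
      somaPixels = as.integer(somaPixels),
      cytoplasmPixels = as.integer(cytoplasmPixels),
      processPixels = as.integer(processPixels),
      nucleusId = as.integer(nucleusId),
      centroid = c(mean(rc[, 1L]), mean(rc[, 2L])),
      totalAreaPx = length(allpx),
      meanIntensity = meanIntensity[MEMBRANE_MARKERS],
      region = region, infiltratesPlaque = infiltratesPlaque,
      plaqueId = as.integer(plaqueId), subjectId = subjectId,
      imageDim = as.integer(imageDim))
}

#' All pixels of a cell (union of soma, cytoplasm and process sets)
#' @param cell a \linkS4class{CellRecord}.
#' @return integer vector of linear pixel indices.
#' @export
cellPixels <- function(cell)
  unique(c(cell@somaPixels, cell@cytoplasmPixels, cell@processPixels))
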