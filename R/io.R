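# Image, mask and table I/O. Component images and label masks travel as
# multi-page TIFF; tables as comma-separated UTF-8 CSV with '.' decimal and
# a mandatory header. Coordinates in all exports are (row, col), 0-based,
# origin top-left.

#' Read a multi-page component-image TIFF
#'
#' Each TIFF page is one marker plane; `channelMap` names the pages in
#' order. 8- and 16-bit integer pages are promoted to float in [0, 1]
#' (thresholds downstream are computed per image, so the scale is
#' immaterial); float pages are taken as-is.
#'
#' @param path TIFF file with one page per channel.
#' @param channelMap character vector of channel names, one per page used,
#'   drawn from DAPI, TMEM119, P2RY12, FTL, Iba1, Abeta, AF. Pages beyond
#'   `length(channelMap)` are ignored.
#' @param pixelSizeUm pixel side length in micrometres.
#' @param subjectId subject identifier attached to the image.
#' @param regionMask optional character matrix (GM/WM/excluded).
#' @return a \linkS4class{ComponentImage}.
#' @export
readComponentImage <- function(path, channelMap, pixelSizeUm = 0.5,
                               subjectId = "unknown", regionMask = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(channelMap) > length(pages))
    stop("channelMap names ", length(channelMap), " pages but file '",
         path, "' has only ", length(pages), " [format error]")
  bad <- setdiff(channelMap, KNOWN_CHANNELS)
  if (length(bad))
    stop("unknown channel name(s) in channelMap: ",
         paste(bad, collapse = ", "), " [config error]")
  pl <- lapply(pages[seq_along(channelMap)], function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate gray-as-RGB pages
    p
  })
  dms <- vapply(pl, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(dms)) != 1L)
    stop("TIFF pages have mismatched shapes (", paste(unique(dms),
         collapse = " vs "), ") [format error]")
  names(pl) <- channelMap
  ComponentImage(pl, pixelSizeUm = pixelSizeUm, subjectId = subjectId,
                 regionMask = regionMask)
}

#' Write a ComponentImage as a multi-page 16-bit TIFF
#'
#' Planes are written in `names(planes(x))` order; read them back with the
#' same channel map. Intensities must lie in [0, 1]; values on the 16-bit
#' grid (k/65535) round-trip bit-identically.
#'
#' @param x a \linkS4class{ComponentImage}.
#' @param path output file.
#' @return invisibly, the channel map (page order) used.
#' @export
writeComponentImage <- function(x, path) {
  pl <- planes(x)
  rng <- range(unlist(lapply(pl, range)))
  if (rng[2L] > 1 || rng[1L] < 0)
    stop("plane intensities must lie in [0, 1] for TIFF export; ",
         "rescale before writing")
  tiff::writeTIFF(unname(pl), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(names(pl))
}

#' Read / write an integer label mask TIFF
#'
#' Lossless round trip of instance labels as a single-page 16-bit (labels
#' <= 65535) or 32-bit integer TIFF.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path TIFF file.
#' @param kind label kind recorded on the mask read back.
#' @return `readLabelMask` returns a \linkS4class{LabelMask};
#'   `writeLabelMask` returns `path` invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  l <- labels2d(mask)
  mx <- if (length(l)) max(l) else 0L
  if (mx > 2^32 - 1) stop("labels exceed 32-bit range [format error]")
  bits <- if (mx <= 65535L) 16L else 32L
  denom <- 2^bits - 1
  tiff::writeTIFF(l / denom, path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path, kind = "component") {
  l <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(l)) l <- l[[1L]]
  storage.mode(l) <- "integer"
  LabelMask(l, kind = kind)
}

CELL_TABLE_COLS <- c("cell_id", "subject_id", "nucleus_id",
                     "centroid_row", "centroid_col",
                     "soma_area_px", "cytoplasm_area_px", "process_area_px",
                     "total_area_px", MEMBRANE_MARKERS,
                     "region", "cluster", "infiltrates_plaque", "plaque_id")

#' Export segmented cells as CSV
#'
#' One row per cell with the documented fixed header: ids, (row, col)
#' 0-based centroid, pixel areas, the four membrane-marker mean
#' intensities, region, cluster label (NA when unassigned) and the
#' plaque-infiltration flag.
#'
#' @param cells list of \linkS4class{CellRecord}.
#' @param path output CSV.
#' @param clusters optional integer vector of cluster labels, parallel to
#'   `cells`.
#' @return the data.frame written, invisibly.
#' @export
exportCellTable <- function(cells, path, clusters = NULL) {
  df <- cellsToDataFrame(cells, clusters)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' @rdname exportCellTable
#' @export
cellsToDataFrame <- function(cells, clusters = NULL) {
  if (length(cells) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(CELL_TABLE_COLS)), CELL_TABLE_COLS))
    return(df)
  }
  rows <- lapply(seq_along(cells), function(i) {
    cl <- cells[[i]]
    data.frame(cell_id = cl@cellId, subject_id = cl@subjectId,
               nucleus_id = cl@nucleusId,
               centroid_row = cl@centroid[1L], centroid_col = cl@centroid[2L],
               soma_area_px = length(cl@somaPixels),
               cytoplasm_area_px = length(cl@cytoplasmPixels),
               process_area_px = length(cl@processPixels),
               total_area_px = cl@totalAreaPx,
               TMEM119 = cl@meanIntensity[["TMEM119"]],
               P2RY12 = cl@meanIntensity[["P2RY12"]],
               FTL = cl@meanIntensity[["FTL"]],
               Iba1 = cl@meanIntensity[["Iba1"]],
               region = cl@region,
               cluster = if (is.null(clusters)) NA_integer_ else clusters[i],
               infiltrates_plaque = cl@infiltratesPlaque,
               plaque_id = cl@plaqueId,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a cell table CSV written by exportCellTable
#' @param path CSV file.
#' @return data.frame with the documented columns.
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(CELL_TABLE_COLS, names(df))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read subject metadata CSV
#'
#' Expects columns subject_id, group (control/AD) and optionally braak
#' (I-VI), thal (0-V), apoe, onset (EOAD/LOAD).
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
readSubjectMeta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("subject metadata needs 'subject_id' and 'group' columns")
  if (!all(df$group %in% c("control", "AD")))
    stop("group must be 'control' or 'AD'")
  if ("braak" %in% names(df)) {
    ok <- is.na(df$braak) | df$braak %in% c("I", "II", "III", "IV", "V", "VI")
    if (!all(ok)) stop("braak must be an ordinal I-VI")
  }
  if ("thal" %in% names(df)) {
    ok <- is.na(df$thal) | df$thal %in% c("0", "I", "II", "III", "IV", "V")
    if (!all(ok)) stop("thal must be an ordinal 0-V")
  }
  if ("onset" %in% names(df)) {
    ok <- is.na(df$onset) | df$onset %in% c("EOAD", "LOAD")
    if (!all(ok)) stop("onset must be EOAD or LOAD")
  }
  df
}

#' Validate that an image carries the channels a stage needs
#'
#' The phenotype space is defined by the four membrane markers, so the
#' pipeline refuses to run when any of TMEM119, P2RY12, FTL or Iba1 is
#' absent.
#'
#' @param image a \linkS4class{ComponentImage}.
#' @param channels channel names required (default the four membrane
#'   markers).
#' @return invisibly TRUE, or an error naming the missing channels.
#' @export
requireChannels <- function(image, channels = MEMBRANE_MARKERS) {
  miss <- setdiff(channels, names(planes(image)))
  if (length(miss))
    stop("required channel(s) missing: ", paste(miss, collapse = ", "),
         " [config error]")
  invisible(TRUE)
}

#' Read a pipeline configuration YAML
#'
#' The config declares the channel map (page order), pixel size and the
#' stage parameters; omitted entries fall back to the published defaults
#' (see \linkS4class{SegmentationConfig}).
#'
#' @param path YAML file.
#' @return list with elements `channelMap`, `pixelSizeUm` and `config`
#'   (a \linkS4class{SegmentationConfig}).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  lsp <- function(entry, nu, mu) {
    if (is.null(entry)) return(LevelSetParams(nu = nu, mu = mu))
    LevelSetParams(nu = entry$nu %||% nu, mu = entry$mu %||% mu,
                   maxIter = entry$max_iter %||% 200L,
                   tol = entry$tol %||% 1e-3)
  }
  cfg <- SegmentationConfig(
    nucleusParams = lsp(y$nucleus, 2, 3),
    somaParams = lsp(y$soma, 2, 3),
    cytoplasmParams = lsp(y$cytoplasm, 2, 2),
    minSomaAreaPx = y$min_soma_area_px %||% 50L,
    minNucleusAreaPx = y$min_nucleus_area_px %||% 30L,
    vesselMinAreaPx = y$vessel_min_area_px %||% 4000L,
    processAttachRadiusPx = y$process_attach_radius_px %||% 10,
    connectivity = y$connectivity %||% 8L,
    requireNucleusOverlap = y$require_nucleus_overlap %||% TRUE,
    plaqueMethod = y$plaque_method %||% "threshold",
    plaqueMinAreaPx = y$plaque_min_area_px %||% 100L)
  list(channelMap = unlist(y$channel_map),
       pixelSizeUm = y$pixel_size_um %||% 0.5,
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
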