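# Plaque-infiltration spatial analysis: which cells overlap (optionally
# dilated) Abeta plaques, the per-cluster composition of all phenotyped
# microglia (all-mic) versus the plaque-infiltrating subset (Abeta-mic),
# and a deterministic overlay export with cluster-coloured cells and
# pie-glyph plaques.

#' Assess every cell for plaque infiltration
#'
#' A cell infiltrates a plaque iff its pixel set intersects the plaque
#' mask dilated by `dilationPx` (default 0 = direct overlap, the most
#' conservative reading of proximity). A cell touching two plaques is
#' assigned once, to the plaque with the larger overlap (ties to the
#' lower plaque id).
#'
#' @param cells list of \linkS4class{CellRecord}.
#' @param plaqueMask \linkS4class{LabelMask} of kind "plaque".
#' @param dilationPx isotropic dilation radius in px.
#' @return list(perCell = data.frame(cell_id, infiltrates_plaque,
#'   plaque_id), perPlaque = data.frame(plaque_id, area_px,
#'   n_infiltrating, infiltrated)).
#' @export
infiltration <- function(cells, plaqueMask, dilationPx = 0) {
  pl <- labels2d(plaqueMask)
  nP <- numLabels(plaqueMask)
  if (dilationPx > 0 && nP > 0L) {
    ids <- seq_len(nP)
    dil <- matrix(0L, nrow(pl), ncol(pl))
    best <- matrix(Inf, nrow(pl), ncol(pl))
    for (i in ids) {  # ascending id: ties at equal distance keep lower id
      d <- as.matrix(EBImage::distmap(matrix(as.numeric(pl != i),
                                             nrow(pl), ncol(pl))))
      upd <- d <= dilationPx & d < best
      dil[upd] <- i; best[upd] <- d[upd]
    }
    plEff <- dil
  } else plEff <- pl
  perCell <- data.frame(cell_id = integer(0),
                        infiltrates_plaque = logical(0),
                        plaque_id = integer(0))
  nInf <- integer(max(nP, 1L))
  for (cl in cells) {
    px <- cellPixels(cl)
    hits <- plEff[px]; hits <- hits[hits > 0L]
    if (length(hits)) {
      ov <- table(hits)
      pid <- as.integer(names(ov)[order(-as.integer(ov),
                                        as.integer(names(ov)))][1L])
      nInf[pid] <- nInf[pid] + 1L
      perCell <- rbind(perCell, data.frame(cell_id = cl@cellId,
                                           infiltrates_plaque = TRUE,
                                           plaque_id = pid))
    } else {
      perCell <- rbind(perCell, data.frame(cell_id = cl@cellId,
                                           infiltrates_plaque = FALSE,
                                           plaque_id = NA_integer_))
    }
  }
  areas <- if (nP > 0L) tabulate(pl[pl > 0L], nbins = nP) else integer(0)
  perPlaque <- data.frame(plaque_id = seq_len(nP), area_px = areas,
                          n_infiltrating = nInf[seq_len(nP)],
                          infiltrated = nInf[seq_len(nP)] >= 1L)
  list(perCell = perCell, perPlaque = perPlaque)
}

#' All-mic vs Abeta-mic cluster composition
#'
#' For each subject, the cluster composition of all phenotyped microglia
#' (all-mic) and of the plaque-infiltrating subset (Abeta-mic), both
#' summing to 1, plus pooled compositions and the per-cluster fraction of
#' cells that infiltrate. Subjects with zero infiltrating cells get NA
#' Abeta-mic proportions (excluded from paired tests, with a message).
#'
#' @param table data.frame with cell_id and subject_id.
#' @param labels integer cluster labels parallel to the rows.
#' @param infil result of \code{infiltration} (or a data.frame with
#'   cell_id and infiltrates_plaque).
#' @return list(bySubject = data.frame(subject_id, cluster, all_mic,
#'   ab_mic), pooled = data.frame(cluster, all_mic, ab_mic,
#'   fraction_infiltrating)).
#' @export
abmicComposition <- function(table, labels, infil) {
  stopifnot(nrow(table) == length(labels))
  perCell <- if (is.data.frame(infil)) infil else infil$perCell
  inf <- perCell$infiltrates_plaque[match(table$cell_id, perCell$cell_id)]
  if (any(is.na(inf))) stop("infiltration flags missing for some cells")
  ids <- sort(unique(labels))
  fcl <- factor(labels, levels = ids)
  bySubject <- do.call(rbind, lapply(split(seq_len(nrow(table)),
                                           table$subject_id),
    function(rows) {
      allp <- prop.table(table(fcl[rows]))
      ir <- rows[inf[rows]]
      abp <- if (length(ir) == 0L) {
        message("subject ", table$subject_id[rows[1L]],
                " has no infiltrating cells; Abeta-mic undefined")
        rep(NA_real_, length(ids))
      } else as.numeric(prop.table(table(fcl[ir])))
      data.frame(subject_id = table$subject_id[rows[1L]], cluster = ids,
                 all_mic = as.numeric(allp), ab_mic = abp,
                 stringsAsFactors = FALSE)
    }))
  rownames(bySubject) <- NULL
  pooledAll <- as.numeric(prop.table(table(fcl)))
  pooledAb <- if (any(inf)) as.numeric(prop.table(table(fcl[inf])))
              else rep(NA_real_, length(ids))
  fracInf <- vapply(ids, function(i) mean(inf[labels == i]), 0)
  list(bySubject = bySubject,
       pooled = data.frame(cluster = ids, all_mic = pooledAll,
                           ab_mic = pooledAb,
                           fraction_infiltrating = fracInf))
}

#' Render a cluster/infiltration overlay map
#'
#' Static raster over the (grayscale membrane-sum) image: every cell as a
#' cluster-coloured dot at its centroid; every infiltrated plaque as a
#' pie glyph whose sectors show the cluster composition of its
#' infiltrating cells; plus a scale bar. A pure function of its inputs:
#' re-rendering the same inputs is byte-identical.
#'
#' @param image \linkS4class{ComponentImage}.
#' @param cells list of \linkS4class{CellRecord}.
#' @param labels cluster labels parallel to `cells`.
#' @param infil result of \code{infiltration}.
#' @param plaqueMask \linkS4class{LabelMask} of kind "plaque".
#' @param path optional PNG output path.
#' @param dotRadius,glyphRadius glyph geometry in px.
#' @return the H x W x 3 RGB array, invisibly.
#' @export
exportOverlay <- function(image, cells, labels, infil, plaqueMask,
                          path = NULL, dotRadius = 3, glyphRadius = 8) {
  bg <- membraneSum(image)
  bg <- bg / max(bg, 1e-12)
  dm <- dim(bg)
  arr <- array(rep(0.6 * bg, 3L), dim = c(dm, 3L))
  nCl <- max(labels, 1L)
  pal <- t(grDevices::col2rgb(clusterPalette(nCl)) / 255)
  setPx <- function(arr, px, col) {
    for (ch in 1:3) {
      p <- arr[, , ch]; p[px] <- col[ch]; arr[, , ch] <- p
    }
    arr
  }
  # infiltrated plaques as pie glyphs of their infiltrating-cluster mix
  perCell <- infil$perCell
  pl <- labels2d(plaqueMask)
  for (pid in infil$perPlaque$plaque_id[infil$perPlaque$infiltrated]) {
    cids <- perCell$cell_id[perCell$infiltrates_plaque &
                            perCell$plaque_id == pid]
    comp <- table(labels[match(cids, vapply(cells, slot, 1L, "cellId"))])
    fr <- as.numeric(comp) / sum(comp)
    clIds <- as.integer(names(comp))
    ctr <- colMeans(ind2rc(which(pl == pid), dm)) + 1
    rr <- max(1, floor(ctr[1L] - glyphRadius)):min(dm[1L], ceiling(ctr[1L] + glyphRadius))
    cc <- max(1, floor(ctr[2L] - glyphRadius)):min(dm[2L], ceiling(ctr[2L] + glyphRadius))
    g <- expand.grid(r = rr, c = cc)
    d2 <- (g$r - ctr[1L])^2 + (g$c - ctr[2L])^2
    g <- g[d2 <= glyphRadius^2, ]
    ang <- (atan2(g$r - ctr[1L], g$c - ctr[2L]) + pi) / (2 * pi)  # [0,1)
    cum <- cumsum(fr)
    sector <- findInterval(ang, c(0, cum), rightmost.closed = TRUE,
                           all.inside = TRUE)
    px <- rc2ind(g$r - 1L, g$c - 1L, dm)
    for (s in seq_along(clIds))
      arr <- setPx(arr, px[sector == s], pal[clIds[s], ])
  }
  # cells as cluster-coloured centroid dots
  for (i in seq_along(cells)) {
    ctr <- cells[[i]]@centroid + 1
    arr <- setPx(arr, diskPixels(ctr[1L], ctr[2L], dotRadius, dm),
                 pal[labels[i], ])
  }
  # scale bar: 50 um, bottom right
  barLen <- round(50 / pixelSize(image))
  rbar <- dm[1L] - 10L
  cbar <- (dm[2L] - 10L - barLen):(dm[2L] - 10L)
  cbar <- cbar[cbar >= 1L]
  for (r in rbar:(rbar + 2L))
    arr <- setPx(arr, rc2ind(rep(r - 1L, length(cbar)), cbar - 1L, dm),
                 c(1, 1, 1))
  if (!is.null(path)) png::writePNG(arr, path)
  invisible(arr)
}
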