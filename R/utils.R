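# Internal pixel-grid helpers shared by the segmentation and synthetic modules.
# Pixel sets are stored as 1-based linear indices into a column-major matrix;
# exported coordinates are (row, col), 0-based, origin top-left.

#' @import methods
NULL

## linear index <-> (row, col) for an image of dimension dm = c(nrow, ncol)
ind2rc <- function(ind, dm) {
  ind0 <- ind - 1L
  cbind(row = ind0 %% dm[1L], col = ind0 %/% dm[1L])  # 0-based
}

rc2ind <- function(row0, col0, dm) {
  as.integer(col0) * dm[1L] + as.integer(row0) + 1L
}

## shift a matrix by (dr, dc), zero-filling exposed borders
shiftMatrix <- function(m, dr, dc, fill = 0) {
  dm <- dim(m)
  out <- matrix(fill, dm[1L], dm[2L])
  sr <- max(1L, 1L + dr):min(dm[1L], dm[1L] + dr)
  sc <- max(1L, 1L + dc):min(dm[2L], dm[2L] + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L,  0L,  1L, -1L, 1L, -1L, 0L, 1L))
NEIGH4 <- cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))

## 3x3 neighbour count (including centre) by exact integer shift-sums
neighbourCount3x3 <- function(u) {
  s <- u
  for (i in seq_len(nrow(NEIGH8)))
    s <- s + shiftMatrix(u, NEIGH8[i, 1L], NEIGH8[i, 2L])
  s
}

## majority vote over the 3x3 neighbourhood (>= 5 of 9 foreground)
majoritySmooth <- function(u) neighbourCount3x3(u) >= 5

#' Label connected components of a binary mask
#'
#' Labels foreground pixels of a logical/0-1 matrix into connected
#' components under 4- or 8-connectivity. Components are numbered 1..n in
#' order of their smallest linear (column-major) pixel index, so labelling
#' is deterministic.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8 (default 8; thin diagonal structures such as
#'   1-px microglial processes stay connected only under 8-connectivity).
#' @return integer matrix of the same dimension; 0 = background.
#' @export
labelConnected <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  dm <- dim(mask)
  fg <- which(mask > 0)
  lab <- matrix(0L, dm[1L], dm[2L])
  if (length(fg) == 0L) return(lab)
  id <- integer(prod(dm)); id[fg] <- seq_along(fg)
  offs <- if (connectivity == 8) {
    cbind(dr = c(1L, 0L, 1L, -1L), dc = c(0L, 1L, 1L, 1L))  # forward half
  } else {
    cbind(dr = c(1L, 0L), dc = c(0L, 1L))
  }
  rc <- ind2rc(fg, dm)
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    r2 <- rc[, 1L] + offs[i, 1L]; c2 <- rc[, 2L] + offs[i, 2L]
    ok <- r2 >= 0L & r2 < dm[1L] & c2 >= 0L & c2 < dm[2L]
    nb <- rc2ind(r2[ok], c2[ok], dm)
    both <- id[nb] > 0L
    edges[[i]] <- cbind(id[fg[ok]][both], id[nb][both])
  }
  ed <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(ed) && nrow(ed) > 0L) g <- igraph::add_edges(g, t(ed))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in linear-index order
  first <- match(unique(memb), memb)
  newlab <- integer(max(memb)); newlab[memb[first]] <- seq_along(first)
  lab[fg] <- newlab[memb]
  lab
}

## drop labels whose area is below / not above a bound, then compact to 1..n
filterLabelsByArea <- function(lab, min_area = NULL, strict_min = NULL) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- rep(TRUE, length(areas))
  if (!is.null(min_area)) keep <- keep & areas >= min_area
  if (!is.null(strict_min)) keep <- keep & areas > strict_min
  compactLabels(lab, which(keep))
}

## keep only the given label ids, renumbering to 1..n in ascending old-id order
compactLabels <- function(lab, keep_ids) {
  newlab <- integer(max(lab, 1L))
  newlab[sort(keep_ids)] <- seq_along(keep_ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- newlab[lab[pos]]
  out
}

## small deterministic colour palette for cluster overlays
clusterPalette <- function(n) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#FFFF33", "#A65628", "#F781BF", "#66C2A5", "#FC8D62",
            "#8DA0CB", "#E78AC3")
  rep_len(base, n)
}
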