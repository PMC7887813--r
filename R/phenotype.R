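# Marker-based phenotyping: per-cell mean-intensity features, pooled
# z-score normalization, a k-nearest-neighbour graph with Jaccard edge
# refinement, Louvain community detection (the Phenograph recipe, k = 100
# to avoid overclustering with only four markers), config-driven cluster
# exclusion/merging, per-cluster summaries and a t-SNE embedding.

#' Extract the per-cell feature table
#'
#' One row per cell with the four raw membrane-marker mean intensities
#' plus cell/subject/region metadata.
#'
#' @param cells list of \linkS4class{CellRecord} (each carrying mean
#'   intensities for all four markers).
#' @return data.frame with columns cell_id, subject_id, region and the
#'   four markers.
#' @export
extractFeatures <- function(cells) {
  if (length(cells) == 0L)
    return(data.frame(cell_id = integer(0), subject_id = character(0),
                      region = character(0),
                      TMEM119 = numeric(0), P2RY12 = numeric(0),
                      FTL = numeric(0), Iba1 = numeric(0)))
  df <- do.call(rbind, lapply(cells, function(cl) {
    mi <- cl@meanIntensity
    if (any(is.na(mi))) stop("cell ", cl@cellId, " is missing a marker mean")
    data.frame(cell_id = cl@cellId, subject_id = cl@subjectId,
               region = cl@region, TMEM119 = mi[["TMEM119"]],
               P2RY12 = mi[["P2RY12"]], FTL = mi[["FTL"]],
               Iba1 = mi[["Iba1"]], stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Z-score the marker columns of a feature table
#'
#' Each marker column is transformed to (x - mean) / sd, pooled over all
#' rows (all cells of all subjects share one scale, so clusters are
#' comparable across subjects). Applying the transform to already
#' standardized columns leaves them unchanged.
#'
#' @param table data.frame containing the marker columns.
#' @param markers columns to standardize (default the four membrane
#'   markers).
#' @return the table with marker columns replaced by their z-scores.
#' @export
zscoreFeatures <- function(table, markers = MEMBRANE_MARKERS) {
  if (nrow(table) < 2L) stop("z-scoring needs at least 2 rows")
  for (m in markers) {
    x <- table[[m]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("marker '", m, "' has zero variance; cannot z-score")
    table[[m]] <- (x - mean(x)) / s
  }
  table
}

#' Build the kNN-Jaccard graph over cells
#'
#' Each cell is connected to its k nearest neighbours in z-scored marker
#' space (Euclidean metric); each edge is reweighted by the Jaccard
#' overlap of the two endpoints' neighbour sets and zero-weight edges are
#' dropped (the Phenograph refinement, which disconnects spurious
#' between-cluster links).
#'
#' @param X numeric matrix (cells x markers), typically z-scored.
#' @param k neighbours (default 100).
#' @return weighted undirected \pkg{igraph} graph with one vertex per row.
#' @export
buildKnnGraph <- function(X, k = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("need more rows (", n, ") than k (", k,
                   "); choose a smaller k")
  nn <- FNN::get.knn(X, k = k)$nn.index
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  ii <- pmin(rep(seq_len(n), k), as.vector(nn))
  jj <- pmax(rep(seq_len(n), k), as.vector(nn))
  keep0 <- !duplicated(ii * (n + 1) + jj)
  edges <- cbind(ii, jj)[keep0, , drop = FALSE]
  shared <- Matrix::tcrossprod(A)  # counts of shared neighbours
  inter <- as.numeric(shared[edges])
  w <- inter / (2 * k - inter)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w[keep]
  g
}

#' Louvain community detection on the cell graph
#'
#' Modularity-maximizing Louvain clustering (resolution 1) under a fixed
#' seed; labels are renumbered 1..K by decreasing cluster size so ids are
#' reproducible.
#'
#' @param graph weighted graph from \code{buildKnnGraph}.
#' @param seed RNG seed.
#' @return integer cluster labels, one per vertex.
#' @export
clusterGraph <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  memb <- withSeed(seed,
    igraph::membership(igraph::cluster_louvain(graph,
      weights = igraph::E(graph)$weight)))
  relabelBySize(as.integer(memb))
}

relabelBySize <- function(labels) {
  sz <- table(labels)
  ord <- order(-as.integer(sz), as.integer(names(sz)))
  map <- stats::setNames(seq_along(ord), names(sz)[ord])
  as.integer(map[as.character(labels)])
}

#' Phenograph-style clustering of a feature matrix
#'
#' Convenience wrapper: z-scored input -> kNN-Jaccard graph -> Louvain.
#' As a guard against overclustering (the motivation for k = 100 with
#' only four markers), if Louvain returns more than `maxClusters`
#' communities the closest pair of cluster centroids is merged
#' repeatedly until the cap is met — the automated counterpart of
#' merging clusters indistinguishable in expression.
#'
#' @param X numeric matrix or data.frame of marker columns (already
#'   z-scored or not; set `zscore = TRUE` to standardize here).
#' @param k neighbours (default 100).
#' @param seed RNG seed.
#' @param zscore standardize columns first.
#' @param maxClusters cluster cap (default 12; Inf disables).
#' @return integer cluster labels.
#' @export
phenographCluster <- function(X, k = 100L, seed = 1L, zscore = FALSE,
                              maxClusters = 12L) {
  X <- as.matrix(X)
  if (zscore) X <- scale(X)
  labels <- clusterGraph(buildKnnGraph(X, k = k), seed = seed)
  while (max(labels) > maxClusters) {
    ctr <- t(vapply(seq_len(max(labels)), function(i)
      colMeans(X[labels == i, , drop = FALSE]), numeric(ncol(X))))
    d <- as.matrix(stats::dist(ctr))
    d[upper.tri(d, diag = TRUE)] <- Inf
    pick <- which(d == min(d), arr.ind = TRUE)[1L, ]
    labels[labels == max(pick)] <- min(pick)
    labels <- relabelBySize(as.integer(factor(labels)))
  }
  labels
}

#' Exclude non-microglial clusters and merge near-duplicates
#'
#' Exclusion: clusters whose median z-scores for TMEM119, P2RY12 and Iba1
#' are all below `excludeThreshold` are flagged non-microglial and their
#' cells removed. Merging: cluster pairs whose median-expression profiles
#' are closer (Euclidean) than `mergeDistance`, or pairs listed in
#' `mergePairs`, share a label. Labels are compacted to 1..K by
#' decreasing size afterwards.
#'
#' @param table z-scored feature table.
#' @param labels integer cluster labels parallel to the rows.
#' @param excludeThreshold z-score threshold (default -0.5); set to -Inf
#'   to disable.
#' @param mergeDistance profile-distance threshold (default 0 =
#'   disabled).
#' @param mergePairs optional explicit list of length-2 vectors of
#'   cluster ids to merge.
#' @return list(table, labels, excluded = excluded cluster ids,
#'   kept = logical row filter applied to the input).
#' @export
postprocessClusters <- function(table, labels, excludeThreshold = -0.5,
                                mergeDistance = 0, mergePairs = NULL) {
  stopifnot(nrow(table) == length(labels))
  ids <- sort(unique(labels))
  med <- clusterMedians(table, labels)
  excl <- ids[apply(med[, c("TMEM119", "P2RY12", "Iba1"), drop = FALSE], 1L,
                    function(m) all(m < excludeThreshold))]
  keep <- !(labels %in% excl)
  table <- table[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- sort(unique(labels))
  parent <- stats::setNames(ids, ids)
  findRoot <- function(x) { while (parent[[as.character(x)]] != x)
    x <- parent[[as.character(x)]]; x }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[[as.character(max(ra, rb))]] <<- min(ra, rb)
  }
  if (!is.null(mergePairs)) {
    for (p in mergePairs) {
      if (!all(p %in% ids)) stop("merge rule references unknown cluster: ",
                                 paste(p, collapse = ","))
      unite(p[1L], p[2L])
    }
  }
  if (mergeDistance > 0 && length(ids) > 1L) {
    med <- clusterMedians(table, labels)
    for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
      if (sqrt(sum((med[a, ] - med[b, ])^2)) < mergeDistance)
        unite(ids[a], ids[b])
    }
  }
  merged <- vapply(labels, function(l) findRoot(l), 0)
  list(table = table, labels = relabelBySize(as.integer(merged)),
       excluded = excl, kept = keep)
}

clusterMedians <- function(table, labels, markers = MEMBRANE_MARKERS) {
  ids <- sort(unique(labels))
  out <- t(vapply(ids, function(i)
    vapply(markers, function(m)
      stats::median(table[[m]][labels == i]), 0), numeric(length(markers))))
  rownames(out) <- ids
  colnames(out) <- markers
  out
}

#' Summarize clusters: medians, counts, prevalence, density
#'
#' Per-cluster median marker expression (the heatmap input), cell counts,
#' and per-subject / per-region prevalence (fraction of that subject's or
#' region's cells in each cluster; rows sum to 1). When `areaMm2` is
#' given (named by subject), per-subject cells per mm2 are added.
#'
#' @param table feature table with subject_id and region columns.
#' @param labels cluster labels.
#' @param areaMm2 optional named numeric of imaged area per subject.
#' @return list(medians, counts, prevalenceBySubject, prevalenceByRegion,
#'   densityPerMm2).
#' @export
summarizeClusters <- function(table, labels, areaMm2 = NULL) {
  stopifnot(nrow(table) == length(labels))
  ids <- sort(unique(labels))
  med <- clusterMedians(table, labels)
  counts <- as.integer(table(factor(labels, levels = ids)))
  names(counts) <- ids
  prevOver <- function(fac) {
    tab <- table(fac, factor(labels, levels = ids))
    prop <- prop.table(tab, margin = 1L)
    matrix(prop, nrow(prop), ncol(prop),
           dimnames = list(rownames(prop), ids))
  }
  prevS <- prevOver(table$subject_id)
  prevR <- if ("region" %in% names(table)) prevOver(table$region) else NULL
  dens <- NULL
  if (!is.null(areaMm2)) {
    nBySubj <- table(table$subject_id)
    dens <- as.numeric(nBySubj) / areaMm2[names(nBySubj)]
    names(dens) <- names(nBySubj)
  }
  list(medians = med, counts = counts, prevalenceBySubject = prevS,
       prevalenceByRegion = prevR, densityPerMm2 = dens)
}

#' t-SNE embedding of the marker space
#'
#' 2D embedding of the (z-scored) marker matrix, deterministic given the
#' seed. Requires at least 3 * perplexity + 1 rows.
#'
#' @param X numeric matrix (cells x markers).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30).
#' @return n x 2 matrix of embedding coordinates.
#' @export
embedTsne <- function(X, seed = 1L, perplexity = 30) {
  X <- as.matrix(X)
  if (nrow(X) - 1 < 3 * perplexity)
    stop("too few rows (", nrow(X), ") for perplexity ", perplexity,
         "; need > 3 * perplexity")
  emb <- withSeed(seed,
    Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE))
  emb$Y
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in [-1, 1]; 1 iff identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  exp_ <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == exp_) return(1)
  (nij - exp_) / (mx - exp_)
}
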