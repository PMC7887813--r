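mkCells <- function(means) {
  # means: n x 4 matrix of marker means
  lapply(seq_len(nrow(means)), function(i)
    CellRecord(i, somaPixels = (i * 200L):(i * 200L + 59L),
               imageDim = c(200L, 200L),
               meanIntensity = stats::setNames(means[i, ],
                                               c("TMEM119", "P2RY12",
                                                 "FTL", "Iba1")),
               subjectId = paste0("S", 1L + i %% 2L)))
}

test_that("feature extraction copies the stored marker means", {
  M <- matrix(runif(12), 3)
  ft <- extractFeatures(mkCells(M))
  expect_equal(nrow(ft), 3L)
  expect_equal(unname(as.matrix(ft[, c("TMEM119", "P2RY12", "FTL", "Iba1")])),
               unname(M))
  expect_equal(nrow(extractFeatures(list())), 0L)
})

test_that("stored means equal a recomputation from pixels", {
  sim <- smallField(nCells = 5L, seed = 61L)
  seg <- segmentImage(sim$image)
  for (cl in seg$cells) {
    px <- cellPixels(cl)
    for (m in c("TMEM119", "P2RY12", "FTL", "Iba1"))
      expect_lt(abs(cl@meanIntensity[[m]] -
                    mean(plane(sim$image, m)[px])), 1e-9)
  }
})

test_that("z-scoring matches the closed form and is idempotent", {
  df <- data.frame(TMEM119 = c(1, 2, 3), P2RY12 = c(4, 5, 9),
                   FTL = c(0, 1, 5), Iba1 = c(2, 2, 3))
  z <- zscoreFeatures(df)
  expect_equal(z$TMEM119, c(-1, 0, 1))
  for (m in names(df)) {
    expect_lt(abs(mean(z[[m]])), 1e-9)
    expect_lt(abs(sd(z[[m]]) - 1), 1e-9)
  }
  z2 <- zscoreFeatures(z)
  expect_lt(max(abs(as.matrix(z2) - as.matrix(z))), 1e-9)
  bad <- df; bad$FTL <- 1
  expect_error(zscoreFeatures(bad), "FTL")
  expect_error(zscoreFeatures(df[1, , drop = FALSE]), "2 rows")
})

test_that("the kNN graph matches brute-force neighbours and k >= n errors", {
  set.seed(62)
  X <- matrix(rnorm(10), 5, 2)
  g <- buildKnnGraph(X, k = 2L)
  D <- as.matrix(dist(X)); diag(D) <- Inf
  knn <- t(apply(D, 1, function(d) order(d)[1:2]))
  wanted <- unique(t(apply(cbind(rep(1:5, 2), as.vector(knn)), 1, sort)))
  got <- igraph::as_edgelist(g)
  got <- unique(t(apply(got, 1, sort)))
  # every surviving edge is a brute-force kNN edge
  expect_true(all(paste(got[, 1], got[, 2]) %in%
                  paste(wanted[, 1], wanted[, 2])))
  expect_error(buildKnnGraph(X, k = 5L), "smaller k")

  # two far-separated blobs with k < blob size never connect
  Y <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60) + 20, 30))
  gb <- buildKnnGraph(Y, k = 10L)
  el <- igraph::as_edgelist(gb)
  expect_false(any((el[, 1] <= 30) != (el[, 2] <= 30)))
})

test_that("Louvain clustering recovers structure deterministically", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  igraph::E(g)$weight <- 1
  lab <- clusterGraph(g, seed = 1L)
  expect_equal(max(lab), 2L)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_error(clusterGraph(igraph::make_empty_graph(0, directed = FALSE)),
               "empty graph")

  set.seed(63)
  M <- matrix(rnorm(16), 4, 4) * 0.2 + 6 * diag(4)
  ft <- simulateFeatureTable(600, M, 1, rep(0.25, 4), seed = 2L)
  X <- scale(as.matrix(ft$features))
  l1 <- phenographCluster(X, k = 30L, seed = 5L)
  l2 <- phenographCluster(X, k = 30L, seed = 5L)
  expect_identical(l1, l2)
  expect_gte(adjustedRandIndex(l1, ft$labels), 0.9)
  # invariance to row permutation up to relabelling
  perm <- sample(nrow(X))
  lp <- phenographCluster(X[perm, ], k = 30L, seed = 5L)
  expect_equal(adjustedRandIndex(lp, l1[perm]), 1)
})

test_that("cluster post-processing excludes and merges per the rules", {
  set.seed(64)
  n <- 60
  base <- data.frame(TMEM119 = rnorm(n, 1, 0.05), P2RY12 = rnorm(n, 1, 0.05),
                     FTL = rnorm(n, 0, 0.05), Iba1 = rnorm(n, 1, 0.05))
  junk <- data.frame(TMEM119 = rnorm(20, -2, 0.05),
                     P2RY12 = rnorm(20, -2, 0.05),
                     FTL = rnorm(20, 0, 0.05), Iba1 = rnorm(20, -2, 0.05))
  tab <- rbind(base, junk)
  labels <- c(rep(1L, n), rep(2L, 20))
  pp <- postprocessClusters(tab, labels, excludeThreshold = -0.5)
  expect_equal(pp$excluded, 2L)
  expect_equal(nrow(pp$table), n)
  expect_true(all(pp$labels == 1L))
  # identical medians merge under a small distance
  lab2 <- c(rep(1L, 30), rep(2L, 30), rep(3L, 20))
  pp2 <- postprocessClusters(tab, lab2, excludeThreshold = -Inf,
                             mergeDistance = 0.3)
  expect_equal(max(pp2$labels), 2L)
  expect_equal(length(unique(pp2$labels[1:60])), 1L)
  expect_error(postprocessClusters(tab, labels, mergePairs = list(c(1, 9))),
               "unknown cluster")
})

test_that("near-duplicate planted components are merged back to truth", {
  set.seed(65)
  M <- rbind(c(0, 0, 0, 0), c(6, 6, 0, 0), c(6.4, 6.4, 0, 0), c(0, 0, 6, 6))
  ft <- simulateFeatureTable(800, M, 0.7, rep(0.25, 4), seed = 3L)
  X <- scale(as.matrix(ft$features))
  lab <- phenographCluster(X, k = 40L, seed = 1L)
  pp <- postprocessClusters(as.data.frame(X), lab, excludeThreshold = -Inf,
                            mergeDistance = 1.5)
  mergedTruth <- ifelse(ft$labels == 3L, 2L, ft$labels)
  expect_equal(max(pp$labels), 3L)
  expect_gte(adjustedRandIndex(pp$labels, mergedTruth), 0.9)
})

test_that("cluster summaries: medians, counts, prevalence contracts", {
  tab <- data.frame(TMEM119 = c(1, 2, 3, 10, 11, 12),
                    P2RY12 = c(0, 0, 1, 5, 5, 5),
                    FTL = c(2, 2, 2, 0, 0, 1), Iba1 = c(1, 1, 1, 2, 2, 2),
                    subject_id = c("a", "a", "b", "a", "b", "b"),
                    region = c("GM", "GM", "WM", "GM", "WM", "WM"))
  labels <- c(1L, 1L, 1L, 2L, 2L, 2L)
  s <- summarizeClusters(tab, labels)
  expect_equal(unname(s$medians["1", ]), c(2, 0, 2, 1))
  expect_equal(unname(s$medians["2", ]), c(11, 5, 0, 2))
  expect_equal(unname(s$counts), c(3L, 3L))
  expect_equal(rowSums(s$prevalenceBySubject), c(a = 1, b = 1))
  # single cluster: prevalence 1 for every subject
  s1 <- summarizeClusters(tab, rep(1L, 6))
  expect_true(all(s1$prevalenceBySubject == 1))
  # property: prevalence rows sum to 1 on random tables
  set.seed(66)
  for (i in 1:5) {
    rt <- data.frame(TMEM119 = rnorm(50), P2RY12 = rnorm(50),
                     FTL = rnorm(50), Iba1 = rnorm(50),
                     subject_id = sample(letters[1:4], 50, TRUE),
                     region = sample(c("GM", "WM"), 50, TRUE))
    rl <- sample.int(3L, 50, TRUE)
    sr <- summarizeClusters(rt, rl)
    expect_true(all(abs(rowSums(sr$prevalenceBySubject) - 1) < 1e-12))
  }
})

test_that("the t-SNE embedding is deterministic and separation-preserving", {
  set.seed(67)
  X <- rbind(matrix(rnorm(400), 100), matrix(rnorm(400) + 15, 100))
  e1 <- embedTsne(X, seed = 4L, perplexity = 20)
  e2 <- embedTsne(X, seed = 4L, perplexity = 20)
  expect_identical(e1, e2)
  km <- kmeans(e1, centers = 2L, nstart = 5L)
  # silhouette of the 2-means partition of the embedding
  D <- as.matrix(dist(e1))
  sil <- vapply(seq_len(nrow(e1)), function(i) {
    own <- km$cluster[i]
    a <- mean(D[i, km$cluster == own & seq_len(nrow(e1)) != i])
    b <- mean(D[i, km$cluster != own])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
  expect_error(embedTsne(X[1:20, ], seed = 1L, perplexity = 20),
               "perplexity")
})

test_that("the structureless-input cluster cap guards against overclustering", {
  ft0 <- simulateFeatureTable(1000, matrix(0, 1, 4), 1, 1, seed = 8L)
  lab0 <- phenographCluster(scale(as.matrix(ft0$features)), k = 100L,
                            seed = 2L)
  expect_lte(max(lab0), 12L)
})
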