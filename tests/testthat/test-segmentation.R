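mkRect <- function(dm, rows, cols) {
  m <- matrix(FALSE, dm[1L], dm[2L]); m[rows, cols] <- TRUE; which(m)
}

test_that("membraneSum adds exactly the four membrane planes", {
  dm <- c(6L, 6L)
  mk <- function(v) matrix(v, dm[1L], dm[2L])
  ci <- ComponentImage(list(TMEM119 = mk(1), P2RY12 = mk(2), FTL = mk(3),
                            Iba1 = mk(4)))
  expect_true(all(membraneSum(ci) == 10))
  set.seed(41)
  pls <- lapply(1:4, function(i) matrix(runif(36), 6))
  names(pls) <- c("TMEM119", "P2RY12", "FTL", "Iba1")
  ci2 <- ComponentImage(pls)
  expect_equal(membraneSum(ci2), pls[[1]] + pls[[2]] + pls[[3]] + pls[[4]])
  ci3 <- ComponentImage(list(TMEM119 = mk(0), P2RY12 = mk(1), FTL = mk(0),
                             Iba1 = mk(0)))
  expect_equal(membraneSum(ci3), mk(1))
})

test_that("nucleus segmentation recovers nuclei and applies the 30 px filter", {
  set.seed(42)
  dm <- c(256L, 256L)
  dapi <- matrix(abs(rnorm(prod(dm), 0.02, 0.01)), dm[1L])
  centres <- expand.grid(r = c(40, 100, 160, 220, 60),
                         c = c(40, 120, 200))[1:10, ]
  truthPx <- lapply(seq_len(10), function(i)
    GliaQuant:::diskPixels(centres$r[i], centres$c[i], 4.5, dm))
  for (px in truthPx) dapi[px] <- 0.9
  small <- mkRect(dm, 10:14, 10:14)  # 25 px, below the 30 px filter
  dapi[small] <- 0.9
  ci <- ComponentImage(list(DAPI = dapi))
  nm <- segmentNuclei(ci)
  expect_equal(numLabels(nm), 10L)
  lab <- labels2d(nm)
  for (px in truthPx) {
    ids <- lab[px]; id <- max(ids)
    expect_gt(id, 0L)
    expect_gte(diceIndex(which(lab == id), px), 0.8)
  }
  expect_true(all(lab[small] == 0L))
  # blank DAPI: thresholding error surfaces as empty mask with warning
  blank <- ComponentImage(list(DAPI = matrix(0.5, 64, 64)))
  expect_warning(nm0 <- segmentNuclei(blank), "thresholding failed")
  expect_equal(numLabels(nm0), 0L)
})

test_that("soma segmentation finds somas, drops sub-50 px specks, separates neighbours", {
  set.seed(43)
  dm <- c(256L, 256L)
  mem <- matrix(abs(rnorm(prod(dm), 0.02, 0.01)), dm[1L])
  centres <- expand.grid(r = c(40, 110, 180), c = c(40, 110, 180))[1:8, ]
  for (i in seq_len(8))
    mem[GliaQuant:::diskPixels(centres$r[i], centres$c[i], 6, dm)] <- 0.9
  speck <- mkRect(dm, 230:236, 230:236)  # 49 px
  mem[speck] <- 0.9
  pls <- list(TMEM119 = mem / 4, P2RY12 = mem / 4, FTL = mem / 4,
              Iba1 = mem / 4)
  sm <- segmentSomas(ComponentImage(pls))
  expect_equal(numLabels(sm), 8L)
  expect_true(all(labels2d(sm)[speck] == 0L))
  areas <- tabulate(labels2d(sm)[labels2d(sm) > 0])
  expect_true(all(areas >= 50))
  # two somas separated by > 2 px of background get distinct labels
  two <- matrix(0.02, 64, 64)
  two[GliaQuant:::diskPixels(32, 20, 6, c(64L, 64L))] <- 0.9
  two[GliaQuant:::diskPixels(32, 36, 6, c(64L, 64L))] <- 0.9
  sm2 <- segmentSomas(ComponentImage(list(TMEM119 = two, P2RY12 = two,
                                          FTL = two, Iba1 = two)))
  expect_equal(numLabels(sm2), 2L)
})

test_that("vessels are strictly-larger-than-4000-px autofluorescent components", {
  dm <- c(256L, 256L)
  af <- matrix(0.02, dm[1L], dm[2L])
  af[mkRect(dm, 1:60, 1:100)] <- 0.8          # 6000 px vessel
  af[mkRect(dm, 200:209, 200:209)] <- 0.8     # 100 px speck
  ci <- ComponentImage(list(AF = af))
  vm <- detectVessels(ci)
  expect_equal(numLabels(vm), 1L)
  expect_gt(sum(labels2d(vm) > 0), 4000)
  # exactly 4000 px: excluded under the strict reading
  af2 <- matrix(0.02, dm[1L], dm[2L])
  af2[mkRect(dm, 1:50, 1:80)] <- 0.8
  expect_equal(numLabels(detectVessels(ComponentImage(list(AF = af2)))), 0L)
  # no AF channel: empty mask
  noaf <- ComponentImage(list(DAPI = matrix(0.1, 8, 8)))
  expect_equal(numLabels(suppressMessages(detectVessels(noaf))), 0L)
})

test_that("the cytoplasm stage is a superset of the soma per cell (noiseless limit)", {
  sim <- smallField(nCells = 6L, seed = 44L, detach = 0)
  sim0 <- simulateImage(c(384L, 384L),
                        lapply(1:6, function(j)
                          syntheticCellSpec(detachProbability = 0)),
                        noiseSd = 0, seed = 44L)
  cfg <- SegmentationConfig()
  sm <- segmentSomas(sim0$image, cfg)
  vm <- detectVessels(sim0$image, cfg)
  cm <- segmentCytoplasm(sim0$image, sm, vm, cfg)
  tl <- labels2d(sim0$truth@cellMasks)
  for (i in seq_len(numLabels(sim0$truth@cellMasks))) {
    cellPx <- which(tl == i)
    expect_gte(sum(labels2d(cm)[cellPx] > 0), sum(labels2d(sm)[cellPx] > 0))
  }
})

test_that("a vessel switches initialization to Li and is excluded from components", {
  sim <- smallField(nCells = 8L, nVessels = 1L, seed = 45L)
  cfg <- SegmentationConfig()
  vm <- detectVessels(sim$image, cfg)
  expect_gt(numLabels(vm), 0L)
  sm <- segmentSomas(sim$image, cfg)
  cm <- segmentCytoplasm(sim$image, sm, vm, cfg)
  vpx <- which(labels2d(vm) > 0)
  expect_true(all(labels2d(cm)[vpx] == 0L))
  # blank membranes: empty component mask
  blank <- matrix(0.3, 32, 32)
  ciB <- ComponentImage(list(TMEM119 = blank, P2RY12 = blank, FTL = blank,
                             Iba1 = blank))
  emptyV <- LabelMask(matrix(0L, 32, 32), "vessel")
  expect_warning(cmB <- segmentCytoplasm(ciB, NULL, emptyV, cfg),
                 "thresholding failed")
  expect_equal(numLabels(cmB), 0L)
})

test_that("components are assigned to somas, orphans and shared sets correctly", {
  dm <- c(40L, 60L)
  comp <- matrix(0L, dm[1L], dm[2L])
  comp[mkRect(dm, 5:15, 5:15)] <- 1L     # contains soma 1
  comp[mkRect(dm, 25:30, 40:50)] <- 2L   # orphan
  soma <- matrix(0L, dm[1L], dm[2L])
  soma[mkRect(dm, 8:12, 8:12)] <- 1L
  asg <- assignComponents(LabelMask(comp, "component"),
                          LabelMask(soma, "soma"))
  expect_equal(names(asg$assigned), "1")
  expect_equal(length(asg$orphans), 1L)
  expect_equal(length(asg$shared), 0L)
  # a component overlapping two somas is deferred as shared
  soma[mkRect(dm, 5:7, 5:7)] <- 2L
  asg2 <- assignComponents(LabelMask(comp, "component"),
                           LabelMask(soma, "soma"))
  expect_equal(length(asg2$shared), 1L)
  expect_equal(asg2$shared[[1L]]$somaIds, c(1L, 2L))
})

test_that("shared cytoplasm is partitioned exactly, dumbbell lobes to their somas", {
  dm <- c(40L, 80L)
  soma <- matrix(0L, dm[1L], dm[2L])
  soma[GliaQuant:::diskPixels(20, 15, 5, dm)] <- 1L
  soma[GliaQuant:::diskPixels(20, 65, 5, dm)] <- 2L
  comp <- matrix(FALSE, dm[1L], dm[2L])
  comp[GliaQuant:::diskPixels(20, 15, 10, dm)] <- TRUE
  comp[GliaQuant:::diskPixels(20, 65, 10, dm)] <- TRUE
  comp[18:22, 15:65] <- TRUE
  parts <- splitSharedCytoplasm(which(comp), LabelMask(soma, "soma"))
  expect_setequal(unlist(parts), which(comp))
  expect_length(intersect(parts[["1"]], parts[["2"]]), 0L)
  expect_true(all(GliaQuant:::diskPixels(20, 10, 3, dm) %in% parts[["1"]]))
  expect_true(all(GliaQuant:::diskPixels(20, 70, 3, dm) %in% parts[["2"]]))
  # symmetric component: sizes equal within the midline tie-break band
  expect_lt(abs(length(parts[["1"]]) - length(parts[["2"]])), dm[1L] + 1)
  expect_error(splitSharedCytoplasm(which(comp),
                                    LabelMask(soma * (soma == 1L), "soma")),
               "at least two somas")
  # random blobs: exhaustive pixel accounting
  set.seed(46)
  for (rep in 1:5) {
    blob <- matrix(FALSE, 30, 30)
    blob[sample(900, 500)] <- TRUE
    blob <- matrix(labelConnected(blob, 8) ==
                   which.max(tabulate(labelConnected(blob, 8))), 30, 30)
    px <- which(blob)
    if (length(px) < 40) next
    s <- matrix(0L, 30, 30)
    s[px[1:10]] <- 1L; s[px[(length(px) - 9):length(px)]] <- 2L
    pp <- splitSharedCytoplasm(px, LabelMask(s, "soma"))
    expect_setequal(unlist(pp), px)
    expect_length(intersect(pp[["1"]], pp[["2"]]), 0L)
  }
})

test_that("process attachment honours the 10 px radius with lower-id tie-break", {
  dm <- c(30L, 60L)
  soma <- matrix(0L, dm[1L], dm[2L])
  soma[10:20, 5:10] <- 1L
  sm <- LabelMask(soma, "soma")
  at9 <- GliaQuant:::rc2ind(14L, 18L, dm)   # row 15, col 19: distance 9
  at11 <- GliaQuant:::rc2ind(14L, 20L, dm)  # col 21: distance 11
  a <- attachProcesses(list(), list(at9), sm, 10)
  expect_length(a$processes[["1"]], 1L)
  expect_equal(a$nDiscarded, 0L)
  b <- attachProcesses(list(), list(at11), sm, 10)
  expect_equal(b$nDiscarded, 1L)
  expect_null(b$processes[["1"]])
  # equidistant orphan goes to the lower soma id
  soma2 <- matrix(0L, dm[1L], dm[2L])
  soma2[14:16, 5] <- 1L; soma2[14:16, 21] <- 2L
  mid <- GliaQuant:::rc2ind(14L, 12L, dm)   # col 13: 8 px to both
  tie <- attachProcesses(list(), list(mid), LabelMask(soma2, "soma"), 10)
  expect_length(tie$processes[["1"]], 1L)
  expect_null(tie$processes[["2"]])
})

test_that("plaques are recovered in threshold mode and absent on a blank channel", {
  sim <- smallField(nCells = 4L, nPlaques = 2L, seed = 47L)
  pm <- identifyPlaques(sim$image)
  tp <- labels2d(sim$truth@plaqueMask)
  expect_equal(numLabels(pm), numLabels(sim$truth@plaqueMask))
  for (t in seq_len(numLabels(sim$truth@plaqueMask)))
    expect_gte(diceIndex(which(labels2d(pm) > 0 & tp == t), which(tp == t)),
               0.8)
  pls <- planes(sim$image)
  pls$Abeta <- matrix(0.01, nrow(pls$Abeta), ncol(pls$Abeta))
  expect_equal(numLabels(identifyPlaques(ComponentImage(pls))), 0L)
})

test_that("the scribble-trained classifier transfers to a second field", {
  a <- smallField(nCells = 4L, nPlaques = 2L, seed = 48L)
  b <- smallField(nCells = 4L, nPlaques = 2L, seed = 49L)
  pt <- labels2d(a$truth@plaqueMask)
  set.seed(50)
  scrib <- matrix(0L, nrow(pt), ncol(pt))
  scrib[sample(which(pt > 0L), 200L)] <- 2L
  scrib[sample(which(pt == 0L), 400L)] <- 1L
  mdl <- trainPlaqueClassifier(a$image, scrib, seed = 3L)
  pm <- identifyPlaques(b$image, model = mdl)
  tpb <- labels2d(b$truth@plaqueMask)
  expect_equal(numLabels(pm), numLabels(b$truth@plaqueMask))  # no false comps
  for (t in seq_len(numLabels(b$truth@plaqueMask)))
    expect_gt(sum(labels2d(pm) > 0 & tpb == t), 0)  # every plaque detected
})

test_that("segmentImage is deterministic, conserves pixels and yields no cells on noise", {
  sim <- smallField(nCells = 6L, seed = 51L)
  seg1 <- segmentImage(sim$image)
  seg2 <- segmentImage(sim$image)
  expect_identical(cellsToDataFrame(seg1$cells), cellsToDataFrame(seg2$cells))
  expect_identical(labels2d(seg1$cellMask), labels2d(seg2$cellMask))
  # pixel conservation: every pixel belongs to at most one cell
  counts <- matrix(0L, 384, 384)
  for (cl in seg1$cells) {
    px <- cellPixels(cl)
    counts[px] <- counts[px] + 1L
  }
  expect_lte(max(counts), 1L)
  # area filters hold on outputs
  somaAreas <- tabulate(labels2d(seg1$somaMask)[labels2d(seg1$somaMask) > 0])
  nucAreas <- tabulate(labels2d(seg1$nucleusMask)[labels2d(seg1$nucleusMask) > 0])
  expect_true(all(somaAreas >= 50))
  expect_true(all(nucAreas >= 30))
  # pure noise: no cells
  noise <- simulateImage(c(192L, 192L), list(), noiseSd = 0.06, seed = 52L)
  segN <- segmentImage(noise$image)
  expect_length(segN$cells, 0L)
})

test_that("Dice index follows its definition and bounds", {
  expect_equal(diceIndex(1:10, 1:10), 1)
  expect_equal(diceIndex(1:10, 11:20), 0)
  expect_equal(diceIndex(1:4, c(3:5, 10:12)), 2 * 2 / 10)
  a <- mkRect(c(10L, 10L), 2:5, 2:5); b <- mkRect(c(10L, 10L), 4:7, 4:7)
  expect_equal(diceIndex(a, b), diceIndex(b, a))
  expect_error(diceIndex(integer(0), integer(0)), "undefined")
  set.seed(53)
  for (i in 1:10) {
    x <- sample(100, 20); y <- sample(100, 30)
    d <- diceIndex(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d == 1, setequal(x, y))
  }
})

test_that("greedy cell matching counts captures, FPs and FNs correctly", {
  dm <- c(20L, 40L)
  truth <- matrix(0L, dm[1L], dm[2L])
  truth[2, 1:20] <- 1L; truth[8, 1:20] <- 2L; truth[14, 1:20] <- 3L
  tm <- LabelMask(truth, "cell")
  # identity: all captured at Dice 1
  idPred <- lapply(1:3, function(i) which(truth == i))
  mrI <- matchCells(idPred, tm, 0.5)
  expect_equal(mrI@nCorrect, 3L)
  expect_equal(mrI@nFalsePositive, 0L)
  expect_equal(mrI@nFalseNegative, 0L)
  expect_true(all(mrI@perCellDice == 1))
  # no predictions: all FN
  mr0 <- matchCells(list(), tm, 0.5)
  expect_equal(mr0@nFalseNegative, 3L)
  # constructed overlaps 0.9 / 0.7 / 0.2 at threshold 0.5
  pred <- list(mkRect(dm, 2, 3:22),    # inter 18 -> Dice 0.9
               mkRect(dm, 8, 7:26),    # inter 14 -> Dice 0.7
               mkRect(dm, 14, 17:36))  # inter 4  -> Dice 0.2
  mr <- matchCells(pred, tm, 0.5)
  expect_equal(mr@nCorrect, 2L)
  expect_equal(mr@nFalsePositive, 1L)
  expect_equal(mr@nFalseNegative, 1L)
  expect_equal(sort(mr@perCellDice), c(0.7, 0.9))
})

test_that("connected-component labelling matches the flood-fill oracle", {
  set.seed(54)
  for (i in 1:8) {
    m <- matrix(runif(48 * 48) < 0.35, 48)
    lab <- labelConnected(m, 8)
    expect_equal(max(lab), floodFillCount(m, 1L, .Machine$integer.max))
    lab4 <- labelConnected(m, 4)
    expect_equal(max(lab4),
                 floodFillCount(m, 1L, .Machine$integer.max, 4L))
  }
})
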