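# Instance-level evaluation of a segmentation against ground truth:
# per-cell Dice overlap and greedy one-to-one matching, mirroring the
# capture / false-positive / false-negative accounting used to validate
# the pipeline against manually segmented cells.

#' Dice similarity index of two pixel sets
#'
#' 2|A n B| / (|A| + |B|). Accepts linear pixel-index vectors or logical
#' masks over the same grid. Both sets empty is undefined and raises an
#' error.
#'
#' @param a,b integer index vectors or logical matrices.
#' @return Dice coefficient in [0, 1].
#' @export
diceIndex <- function(a, b) {
  if (is.matrix(a)) a <- which(a > 0)
  if (is.matrix(b)) b <- which(b > 0)
  if (length(a) == 0L && length(b) == 0L)
    stop("Dice index undefined for two empty masks")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Match predicted cells to ground-truth cells
#'
#' Computes Dice overlap between every prediction and every truth
#' instance it touches, then matches greedily by descending Dice
#' (one-to-one; ties broken by lower truth id, then lower prediction
#' index). Pairs with Dice >= `matchDiceMin` are correct; unmatched
#' predictions are false positives and unmatched truth cells false
#' negatives.
#'
#' @param predicted list of \linkS4class{CellRecord} or of linear
#'   pixel-index vectors.
#' @param truth \linkS4class{LabelMask} with one label per truth cell.
#' @param matchDiceMin Dice threshold in (0, 1] for a correct capture
#'   (default 0.5).
#' @return a \linkS4class{MatchResult}.
#' @export
matchCells <- function(predicted, truth, matchDiceMin = 0.5) {
  stopifnot(matchDiceMin > 0, matchDiceMin <= 1)
  tl <- labels2d(truth)
  nT <- numLabels(truth)
  predPx <- lapply(predicted, function(p)
    if (is(p, "CellRecord")) cellPixels(p) else as.integer(p))
  tArea <- tabulate(tl[tl > 0L], nbins = max(nT, 1L))
  cand <- list()
  for (i in seq_along(predPx)) {
    px <- predPx[[i]]
    hits <- tl[px]; hits <- hits[hits > 0L]
    if (length(hits) == 0L) next
    for (t in sort(unique(hits))) {
      inter <- sum(hits == t)
      d <- 2 * inter / (length(px) + tArea[t])
      cand[[length(cand) + 1L]] <- c(pred = i, truth = t, dice = d)
    }
  }
  dice <- numeric(0)
  usedP <- logical(length(predPx)); usedT <- logical(nT)
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, "dice"], cm[, "truth"], cm[, "pred"])
    cm <- cm[ord, , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "pred"]; t <- cm[r, "truth"]; d <- cm[r, "dice"]
      if (usedP[i] || usedT[t] || d < matchDiceMin) next
      usedP[i] <- TRUE; usedT[t] <- TRUE
      dice <- c(dice, unname(d))
    }
  }
  new("MatchResult", nTruth = as.integer(nT),
      nCorrect = as.integer(sum(usedT)),
      nFalsePositive = as.integer(sum(!usedP)),
      nFalseNegative = as.integer(sum(!usedT)),
      perCellDice = dice)
}
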