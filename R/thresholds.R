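# Global thresholding used to initialize the level sets: Otsu
# (between-class variance) for nuclei/somas, Li minimum cross-entropy for
# the cytoplasm stage when a vessel is present, because Li is less pulled
# up by the few very bright vessel pixels.

#' Otsu threshold
#'
#' Histogram-based threshold maximizing the between-class variance over
#' `levels` equal-width bins spanning `rangeValues`. The returned threshold
#' is the upper edge of the background class; the mask is `plane >
#' threshold`. Ties are broken toward the lowest cut, making the result
#' deterministic.
#'
#' @param plane numeric matrix with at least two distinct values.
#' @param levels number of histogram bins (default 256).
#' @param rangeValues histogram range (default the plane's range).
#' @return list(threshold = numeric, mask = logical matrix).
#' @export
otsuThreshold <- function(plane, levels = 256L, rangeValues = range(plane)) {
  v <- as.numeric(plane)
  if (diff(range(v)) == 0)
    stop("constant image: no threshold exists")
  breaks <- seq(rangeValues[1L], rangeValues[2L], length.out = levels + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- as.numeric(tabulate(bin, nbins = levels))
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[levels]; mt <- m[levels]
  k <- seq_len(levels - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sigma2 <- rep(-Inf, levels - 1L)
  sigma2[valid] <- (m[k][valid] * n - mt * w0[valid])^2 /
    (w0[valid] * w1[valid])
  kbest <- which.max(sigma2)  # first maximum: lowest cut wins ties
  thr <- breaks[kbest + 1L]
  list(threshold = thr, mask = matrix(plane > thr, nrow(plane), ncol(plane)))
}

#' Li minimum cross-entropy threshold
#'
#' Iterative scheme converging to a threshold minimizing the cross entropy
#' between the image and its two-level reconstruction: starting from the
#' image mean, t is repeatedly replaced by
#' (mu_bg - mu_fg) / (log mu_bg - log mu_fg), with mu_bg and mu_fg the mean
#' intensities at or below / above t. Less sensitive than Otsu to a few
#' very bright pixels. The mask is `plane > threshold`.
#'
#' @param plane numeric matrix with at least two distinct values.
#' @param tol convergence tolerance on t (default range/65536).
#' @param maxIter iteration cap.
#' @return list(threshold = numeric, mask = logical matrix).
#' @export
liThreshold <- function(plane, tol = NULL, maxIter = 200L) {
  v <- as.numeric(plane)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant image: no threshold exists")
  if (is.null(tol)) tol <- diff(rng) / 65536
  offset <- if (rng[1L] <= 0) tol - rng[1L] else 0
  x <- v + offset
  t <- mean(x)
  for (i in seq_len(maxIter)) {
    mb <- mean(x[x <= t]); mf <- mean(x[x > t])
    if (!is.finite(mb) || !is.finite(mf) || mb <= 0) break
    tn <- (mb - mf) / (log(mb) - log(mf))
    if (!is.finite(tn)) break
    if (abs(tn - t) < tol) { t <- tn; break }
    t <- tn
  }
  thr <- t - offset
  list(threshold = thr, mask = matrix(plane > thr, nrow(plane), ncol(plane)))
}
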