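# Shared fixtures, all built in code at test time.

## a small flat-intensity field with one bright disk
diskImage <- function(dm = c(64L, 64L), centre = c(32, 32), rad = 12,
                      bg = 10, fg = 200) {
  pl <- matrix(bg, dm[1L], dm[2L])
  px <- GliaQuant:::diskPixels(centre[1L], centre[2L], rad, dm)
  pl[px] <- fg
  list(plane = pl, pixels = px)
}

## a small synthetic field with n cells, optional plaques/vessel
smallField <- function(nCells = 6L, nPlaques = 0L, nVessels = 0L,
                       seed = 7L, size = if (nVessels > 0L || nPlaques > 0L)
                         c(448L, 448L) else c(384L, 384L),
                       detach = 0.2) {
  profiles <- defaultClusterProfiles()
  specs <- lapply(seq_len(nCells), function(j)
    syntheticCellSpec(markerProfile = profiles[[1L + (j %% 3L)]],
                      clusterId = 1L + (j %% 3L),
                      detachProbability = detach))
  simulateImage(size, specs, nPlaques = nPlaques, nVessels = nVessels,
                noiseSd = 0.06, seed = seed)
}

## brute-force 8-connected flood-fill particle count (independent oracle)
floodFillCount <- function(binary, minSize, maxSize, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc); areas <- integer(0)
  stack <- integer(length(binary))
  offs <- if (connectivity == 8L)
    expand.grid(dr = -1:1, dc = -1:1)[-5L, ]
  else data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  cur <- 0L
  for (start in which(binary)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L; stack[1L] <- start; lab[start] <- cur; area <- 0L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L; area <- area + 1L
      r <- (p - 1L) %% nr; c <- (p - 1L) %/% nr
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]; c2 <- c + offs$dc[k]
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) {
          p2 <- c2 * nr + r2 + 1L
          if (binary[p2] && lab[p2] == 0L) {
            lab[p2] <- cur; top <- top + 1L; stack[top] <- p2
          }
        }
      }
    }
    areas <- c(areas, area)
  }
  sum(areas >= minSize & areas <= maxSize)
}

## exhaustive between-class-variance threshold search on the package's
## 256-bin convention (independent of the cumulative-sum implementation)
bruteOtsu <- function(plane, levels = 256L, rangeValues = range(plane)) {
  breaks <- seq(rangeValues[1L], rangeValues[2L], length.out = levels + 1L)
  bin <- findInterval(as.numeric(plane), breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  best <- -Inf; bestK <- 1L
  for (k in seq_len(levels - 1L)) {
    lo <- bin <= k
    n0 <- sum(lo); n1 <- length(bin) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[!lo]])
    s <- n0 * n1 * (mu0 - mu1)^2
    if (s > best + 1e-9) { best <- s; bestK <- k }
  }
  breaks[bestK + 1L]
}

## independently coded histogram-based Li iteration (reference
## implementation for 8-bit integer images)
histLi <- function(v8) {
  h <- tabulate(v8 + 1L, nbins = 256L)
  g <- 0:255
  rng <- range(v8)
  tol <- diff(rng) / 65536
  offset <- if (rng[1L] <= 0) tol - rng[1L] else 0
  gv <- g + offset
  t <- sum(h * gv) / sum(h)
  for (i in 1:200) {
    lo <- gv <= t
    mb <- sum(h[lo] * gv[lo]) / sum(h[lo])
    mf <- sum(h[!lo] * gv[!lo]) / sum(h[!lo])
    if (!is.finite(mb) || !is.finite(mf)) break
    tn <- (mb - mf) / (log(mb) - log(mf))
    if (abs(tn - t) < tol) { t <- tn; break }
    t <- tn
  }
  t - offset
}

## plant rectangles of the given areas as dark blobs on a bright field
plantBlobs <- function(areas, dm = c(128L, 128L), gap = 6L, value = 30L) {
  g <- matrix(230L, dm[1L], dm[2L])
  r <- 5L; c <- 5L
  for (a in areas) {
    h <- min(10L, a); w <- ceiling(a / h)
    cells <- utils::head(as.matrix(expand.grid(r + seq_len(h) - 1L,
                                               c + seq_len(w) - 1L)), a)
    g[cbind(cells[, 1L], cells[, 2L])] <- value
    c <- c + w + gap
    if (c > dm[2L] - 20L) { c <- 5L; r <- r + 16L }
  }
  storage.mode(g) <- "integer"
  g
}
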