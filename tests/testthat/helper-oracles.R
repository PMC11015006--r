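## Independent brute-force oracles used to pin down expected values.
## These deliberately share no code with the package implementation.

## Exhaustive NCC block matching by plain R loops: for every block on the
## lattice, score every in-bounds integer offset and take the argmax with
## the smallest-norm-then-lexicographic tie rule.
oracleMatchBlocks <- function(fixed, moving, block, stride, radius,
                              varFloor) {
  d <- dim(fixed)
  res <- NULL
  starts <- function(n) seq(0L, n - block, by = stride)
  for (s3 in starts(d[3])) for (s2 in starts(d[2])) for (s1 in starts(d[1])) {
    fb <- fixed[(s1 + 1):(s1 + block), (s2 + 1):(s2 + block),
                (s3 + 1):(s3 + block)]
    N <- length(fb)
    vf <- sum((fb - mean(fb))^2) / N
    if (!(vf >= varFloor) || vf <= 1e-12) next
    best <- NULL
    for (d1 in -radius:radius) for (d2 in -radius:radius)
      for (d3 in -radius:radius) {
        t1 <- s1 + d1; t2 <- s2 + d2; t3 <- s3 + d3
        if (t1 < 0 || t2 < 0 || t3 < 0 || t1 + block > d[1] ||
            t2 + block > d[2] || t3 + block > d[3]) next
        mb <- moving[(t1 + 1):(t1 + block), (t2 + 1):(t2 + block),
                     (t3 + 1):(t3 + block)]
        vm <- sum((mb - mean(mb))^2) / N
        score <- if (vm <= 1e-12) -2 else {
          (sum(fb * mb) / N - mean(fb) * mean(mb)) / sqrt(vf * vm)
        }
        cand <- c(d1, d2, d3, score, d1^2 + d2^2 + d3^2)
        if (is.null(best) || score > best[4] ||
            (score == best[4] && (cand[5] < best[5] ||
              (cand[5] == best[5] &&
               (d1 < best[1] || (d1 == best[1] && (d2 < best[2] ||
                (d2 == best[2] && d3 < best[3])))))))) {
          best <- cand
        }
      }
    res <- rbind(res, c(s1, s2, s3, best[1:4]))
  }
  colnames(res) <- c("s1", "s2", "s3", "d1", "d2", "d3", "score")
  res
}

## Exhaustive between-class-variance Otsu: same 256-bin histogram
## definition, but a per-cut loop computing class weights and means from
## scratch with sum().
oracleOtsu <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  mn <- min(values); mx <- max(values)
  stopifnot(mx > mn)
  width <- (mx - mn) / nbins
  idx <- pmin(floor((values - mn) / width) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  mids <- mn + (seq_len(nbins) - 0.5) * width
  N <- sum(counts)
  bestBc <- -Inf
  bestCut <- NA_integer_
  for (t in 1:(nbins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- N - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):nbins] * mids[(t + 1):nbins]) / n1
    bc <- (n0 / N) * (n1 / N) * (mu0 - mu1)^2
    if (bc > bestBc) { bestBc <- bc; bestCut <- t }
  }
  mn + bestCut * width
}

## Plain R trilinear pull-back of one volume through an affine inverse:
## oracle for the resampling convention output(x) = moving(T^{-1}(x)).
oracleResampleAffine <- function(movArr, movSpacing, movOrigin, Tmat,
                                 refDims, refSpacing, refOrigin) {
  Ti <- solve(Tmat)
  out <- array(0, refDims)
  d <- dim(movArr)
  for (k in seq_len(refDims[3])) for (j in seq_len(refDims[2]))
    for (i in seq_len(refDims[1])) {
      x <- refOrigin + refSpacing * c(i - 1, j - 1, k - 1)
      y <- (Ti[1:3, 1:3] %*% x + Ti[1:3, 4])
      v <- (y - movOrigin) / movSpacing
      if (any(v < 0) || any(v > d - 1)) next
      i0 <- pmin(floor(v), d - 2)
      f <- v - i0
      acc <- 0
      for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
        w <- prod(ifelse(c(c1, c2, c3) == 1, f, 1 - f))
        acc <- acc + w * movArr[i0[1] + c1 + 1, i0[2] + c2 + 1,
                                i0[3] + c3 + 1]
      }
      out[i, j, k] <- acc
    }
  out
}

## A smooth random test volume: white noise box-blurred a few times.
smoothVolume <- function(n, seed, spacing = 1) {
  set.seed(seed)
  a <- array(stats::rnorm(n^3), c(n, n, n))
  for (r in 1:3) {
    a <- (a[c(1, 1:(n - 1)), , ] + a + a[c(2:n, n), , ]) / 3
    a <- (a[, c(1, 1:(n - 1)), ] + a + a[, c(2:n, n), ]) / 3
    a <- (a[, , c(1, 1:(n - 1))] + a + a[, , c(2:n, n)]) / 3
  }
  a <- (a - min(a)) / (max(a) - min(a)) * 255
  Volume(a, spacing = spacing)
}

## The spec-order cube: value = 4*(depth) + 2*(row) + (col), zero-based.
depthMajorCube <- function(spacing = 1) {
  a <- array(0, c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    a[i + 1, j + 1, k + 1] <- 4 * i + 2 * j + k
  }
  Volume(a, spacing = spacing)
}

## Jitter a landmark set: manual clicking noise.
noisyLandmarks <- function(lm, sd, seed) {
  set.seed(seed)
  n <- nrow(fixedPoints(lm))
  landmarkSet(fixedPoints(lm) + matrix(stats::rnorm(3 * n, 0, sd), n, 3),
              movingPoints(lm) + matrix(stats::rnorm(3 * n, 0, sd), n, 3))
}
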