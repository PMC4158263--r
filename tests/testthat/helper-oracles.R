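# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (double loops, direct summations) and never call the
# package's production code paths they are checking.

randomImage <- function(n, m = n, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(runif(n * m, lo, hi), n, m)
}

shiftMat <- function(x, di, dj) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(m) - 1 - dj) %% m) + 1,
    drop = FALSE]
}

## circular convolution of an image with the spatial filter whose frequency
## response is `kernel`, by direct double-loop summation
bruteCircularFilter <- function(img, kernel) {
  n <- nrow(img); m <- ncol(img)
  spatial <- fft(kernel, inverse = TRUE) / length(kernel)
  out <- matrix(complex(real = 0), n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0 + 0i
    for (p in 1:n) for (q in 1:m) {
      acc <- acc + img[p, q] * spatial[((i - p) %% n) + 1, ((j - q) %% m) + 1]
    }
    out[i, j] <- acc
  }
  out
}

bruteStd <- function(F) {
  mu <- sum(F) / length(F)
  acc <- 0
  for (i in 1:nrow(F)) for (j in 1:ncol(F)) acc <- acc + (F[i, j] - mu)^2
  sqrt(acc / length(F))
}

bruteSpatialFrequency <- function(F) {
  n <- nrow(F); m <- ncol(F)
  rf <- cf <- 0
  for (i in 1:n) for (j in 2:m) rf <- rf + (F[i, j] - F[i, j - 1])^2
  for (i in 2:n) for (j in 1:m) cf <- cf + (F[i, j] - F[i - 1, j])^2
  sqrt(rf / (n * m) + cf / (n * m))
}

bruteHistogram <- function(img, L = 256L) {
  v <- pmin(pmax(round(as.vector(img)), 0), L - 1)
  h <- numeric(L)
  for (x in v) h[x + 1] <- h[x + 1] + 1
  h / length(v)
}

bruteMIPair <- function(X, F, L = 256L) {
  x <- pmin(pmax(round(as.vector(X)), 0), L - 1)
  f <- pmin(pmax(round(as.vector(F)), 0), L - 1)
  joint <- matrix(0, L, L)
  for (k in seq_along(x)) joint[x[k] + 1, f[k] + 1] <-
      joint[x[k] + 1, f[k] + 1] + 1
  joint <- joint / length(x)
  px <- rowSums(joint); pf <- colSums(joint)
  acc <- 0
  for (a in 1:L) for (b in 1:L)
    if (joint[a, b] > 0)
      acc <- acc + joint[a, b] * log2(joint[a, b] / (px[a] * pf[b]))
  acc
}

bruteCrossEntropy <- function(src, F, L = 256L) {
  P <- bruteHistogram(src, L); Q <- bruteHistogram(F, L)
  acc <- 0
  for (l in 1:L) {
    if (P[l] > 0) {
      q <- if (Q[l] == 0) 1e-12 else Q[l]
      acc <- acc + P[l] * log2(P[l] / q)
    }
  }
  acc
}

## direct per-pixel evaluation of the edge-preservation measure with
## replicated-border Sobel gradients
bruteQabf <- function(A, B, F) {
  sobel <- function(img) {
    n <- nrow(img); m <- ncol(img)
    at <- function(i, j) img[min(max(i, 1), n), min(max(j, 1), m)]
    g <- a <- matrix(0, n, m)
    for (i in 1:n) for (j in 1:m) {
      sx <- at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1) -
            at(i - 1, j - 1) - 2 * at(i, j - 1) - at(i + 1, j - 1)
      sy <- at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1) -
            at(i - 1, j - 1) - 2 * at(i - 1, j) - at(i - 1, j + 1)
      g[i, j] <- sqrt(sx^2 + sy^2)
      ang <- atan2(sy, sx)
      if (ang > pi / 2) ang <- ang - pi
      if (ang <= -pi / 2) ang <- ang + pi
      a[i, j] <- ang
    }
    list(g = g, a = a)
  }
  sA <- sobel(A); sB <- sobel(B); sF <- sobel(F)
  q <- function(sx, sf, i, j) {
    if (sx$g[i, j] == 0 && sf$g[i, j] == 0) G <- 0
    else G <- min(sx$g[i, j], sf$g[i, j]) / max(sx$g[i, j], sf$g[i, j])
    Aang <- 1 - abs(sx$a[i, j] - sf$a[i, j]) / (pi / 2)
    (0.9994 / (1 + exp(-15 * (G - 0.5)))) *
      (0.9879 / (1 + exp(-22 * (Aang - 0.8))))
  }
  num <- den <- 0
  for (i in 1:nrow(A)) for (j in 1:ncol(A)) {
    num <- num + q(sA, sF, i, j) * sA$g[i, j] + q(sB, sF, i, j) * sB$g[i, j]
    den <- den + sA$g[i, j] + sB$g[i, j]
  }
  num / den
}
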