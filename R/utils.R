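# Internal numeric helpers shared across modules. All spatial filtering in the
# transform pipeline is circular (periodic boundaries), implemented in the
# frequency domain, so shift covariance holds to floating-point precision.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

ifft2Re <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

## Signed FFT-bin frequencies in cycles/sample: 0, 1/n, ..., -1/n.
fftFreq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

## Row/column frequency grids, radius and angle on the FFT lattice of `dm`.
freqGrid <- function(dm) {
  f1 <- fftFreq(dm[1])                      # row (vertical) frequency
  f2 <- fftFreq(dm[2])                      # column (horizontal) frequency
  F1 <- matrix(f1, dm[1], dm[2])
  F2 <- matrix(f2, dm[1], dm[2], byrow = TRUE)
  list(f1 = F1, f2 = F2,
       radius = sqrt(F1^2 + F2^2),
       angle = atan2(F1, F2))
}

## Cyclic shift of a matrix by (di, dj): entry (i, j) of the result is
## x[(i - di) mod n, (j - dj) mod m].
cyclicShift <- function(x, di, dj) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(m) - 1 - dj) %% m) + 1,
    drop = FALSE]
}

## Pad a matrix by (mi, mj) on each side under the given boundary policy.
padMatrix <- function(x, mi, mj, boundary = c("periodic", "reflect")) {
  boundary <- match.arg(boundary)
  n <- nrow(x); m <- ncol(x)
  if (mi >= n || mj >= m)
    stop("padding must be smaller than the matrix extent")
  ri <- if (boundary == "periodic") {
    c(if (mi > 0) (n - mi + 1):n, 1:n, if (mi > 0) 1:mi)
  } else {
    c(if (mi > 0) mi:1, 1:n, if (mi > 0) n:(n - mi + 1))
  }
  rj <- if (boundary == "periodic") {
    c(if (mj > 0) (m - mj + 1):m, 1:m, if (mj > 0) 1:mj)
  } else {
    c(if (mj > 0) mj:1, 1:m, if (mj > 0) m:(m - mj + 1))
  }
  x[ri, rj, drop = FALSE]
}

## Mean over the (2M+1) x (2N+1) window centred at each pixel, via an
## integral image on the padded matrix.
boxMean <- function(x, M, N, boundary = c("periodic", "reflect")) {
  boundary <- match.arg(boundary)
  if (M < 0 || N < 0) stop("window half-sizes must be non-negative")
  if (M == 0 && N == 0) return(x)
  p <- padMatrix(x, M, N, boundary)
  ## summed-area table with a zero first row/column
  S <- matrix(0, nrow(p) + 1, ncol(p) + 1)
  S[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  n <- nrow(x); m <- ncol(x)
  i1 <- seq_len(n); j1 <- seq_len(m)
  win <- S[i1 + 2 * M + 1, j1 + 2 * N + 1, drop = FALSE] -
    S[i1, j1 + 2 * N + 1, drop = FALSE] -
    S[i1 + 2 * M + 1, j1, drop = FALSE] +
    S[i1, j1, drop = FALSE]
  win / ((2 * M + 1) * (2 * N + 1))
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Validate a single-channel image matrix.
checkImage <- function(img, minDim = 1L, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix")
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values")
  if (nrow(img) < minDim || ncol(img) < minDim)
    stop(what, " must be at least ", minDim, "x", minDim)
  invisible(img)
}

checkSameShape <- function(...) {
  mats <- list(...)
  dm <- dim(mats[[1]])
  for (m in mats[-1])
    if (!identical(dim(m), dm))
      stop("inputs must all have the same dimensions")
  invisible(dm)
}
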