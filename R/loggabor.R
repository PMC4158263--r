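#' Log-Gabor filter bank parameters
#'
#' Parameters of the `U x V` (scales times orientations) Log-Gabor bank used
#' to measure high-frequency activity. A Log-Gabor filter is Gaussian on a
#' log-frequency axis, has no DC response, and here carries a one-sided
#' angular Gaussian so that filtering yields complex quadrature responses.
#'
#' @param numScales Number of scales U (default 4).
#' @param numOrientations Number of orientations V (default 6).
#' @param f0Finest Centre frequency of the finest scale, cycles/pixel,
#'   in (0, 0.5] (default 1/3).
#' @param scaleMultiplier Ratio between successive centre frequencies
#'   (> 1; default 2.1, about two octaves of coverage per step).
#' @param sigmaRatio Radial bandwidth parameter sigma/f0 in (0, 1)
#'   (default 0.55, roughly a two-octave filter).
#' @param sigmaTheta Angular Gaussian width in radians (default 0.52).
#' @return A validated parameter list of class `logGaborParams`.
#' @export
logGaborParams <- function(numScales = 4L, numOrientations = 6L,
                           f0Finest = 1 / 3, scaleMultiplier = 2.1,
                           sigmaRatio = 0.55, sigmaTheta = 0.52) {
  if (numScales < 1L || numOrientations < 1L)
    stop("numScales and numOrientations must be positive")
  if (f0Finest <= 0 || f0Finest > 0.5)
    stop("f0Finest must be in (0, 0.5]")
  if (scaleMultiplier <= 1) stop("scaleMultiplier must exceed 1")
  if (sigmaRatio <= 0 || sigmaRatio >= 1) stop("sigmaRatio must be in (0,1)")
  if (sigmaTheta <= 0) stop("sigmaTheta must be positive")
  structure(list(numScales = as.integer(numScales),
                 numOrientations = as.integer(numOrientations),
                 f0Finest = f0Finest, scaleMultiplier = scaleMultiplier,
                 sigmaRatio = sigmaRatio, sigmaTheta = sigmaTheta),
            class = "logGaborParams")
}

#' Single Log-Gabor kernel on an FFT grid
#'
#' Samples `g(f, theta) = exp(-ln(f/f0)^2 / (2 ln(sigmaRatio)^2)) *
#' exp(-(theta - theta0)^2 / (2 sigmaTheta^2))` on the FFT lattice of an
#' image of dimensions `dm`, with the angular difference wrapped to
#' (-pi, pi] (one-sided window) and the DC bin set to zero.
#'
#' @param dm Image dimensions `c(rows, cols)`, each at least 2.
#' @param f0 Radial centre frequency in cycles/pixel, in (0, 0.5].
#' @param theta0 Filter orientation in radians.
#' @param sigmaRatio Radial bandwidth ratio sigma/f0 in (0, 1).
#' @param sigmaTheta Angular width in radians.
#' @return Real non-negative matrix of dimensions `dm`.
#' @examples
#' k <- logGaborKernel(c(32, 32), f0 = 0.25, theta0 = 0)
#' k[1, 1]      # 0 at DC
#' k[1, 9]      # 1 at (f0, theta0): 8/32 = 0.25 cycles/pixel
#' @export
logGaborKernel <- function(dm, f0, theta0, sigmaRatio = 0.55,
                           sigmaTheta = 0.52) {
  dm <- as.integer(dm)
  if (any(dm < 2L)) stop("kernel grid must be at least 2 x 2")
  if (f0 <= 0 || f0 > 0.5) stop("f0 must be in (0, 0.5]")
  if (sigmaRatio <= 0 || sigmaRatio >= 1) stop("sigmaRatio must be in (0,1)")
  g <- freqGrid(dm)
  r <- g$radius
  r[1, 1] <- 1                               # placeholder; DC zeroed below
  radial <- exp(-(log(r / f0))^2 / (2 * log(sigmaRatio)^2))
  dtheta <- ((g$angle - theta0 + pi) %% (2 * pi)) - pi
  angular <- exp(-dtheta^2 / (2 * sigmaTheta^2))
  k <- radial * angular
  k[1, 1] <- 0
  k
}

#' Build a Log-Gabor bank for a fixed image shape
#'
#' Constructs all `U x V` kernels of [logGaborParams()] on the FFT grid of
#' `dm`. Scale `u` has centre frequency `f0Finest / scaleMultiplier^(u-1)`;
#' orientation `v` points at `(v - 1) * pi / V`.
#'
#' @param dm Image dimensions `c(rows, cols)`.
#' @param params A [logGaborParams()] list.
#' @return A [LogGaborBank-class].
#' @export
logGaborBank <- function(dm, params = logGaborParams()) {
  dm <- as.integer(dm)
  kernels <- vector("list", params$numScales * params$numOrientations)
  i <- 1L
  for (u in seq_len(params$numScales)) {
    f0 <- params$f0Finest / params$scaleMultiplier^(u - 1)
    for (v in seq_len(params$numOrientations)) {
      theta0 <- (v - 1) * pi / params$numOrientations
      kernels[[i]] <- logGaborKernel(dm, f0, theta0, params$sigmaRatio,
                                     params$sigmaTheta)
      i <- i + 1L
    }
  }
  new("LogGaborBank", params = unclass(params), kernels = kernels,
      imgDim = dm)
}

#' @describeIn LogGaborBank Compact description of the bank.
#' @param object A `LogGaborBank`.
#' @export
setMethod("show", "LogGaborBank", function(object) {
  p <- object@params
  cat("LogGaborBank:", p$numScales, "scales x", p$numOrientations,
      "orientations on a", paste(object@imgDim, collapse = " x "), "grid\n")
  cat(sprintf("  f0 finest %.4g c/px, multiplier %.3g, sigma/f0 %.3g, sigma_theta %.3g rad\n",
              p$f0Finest, p$scaleMultiplier, p$sigmaRatio, p$sigmaTheta))
})

#' Filter a subband with every kernel of a Log-Gabor bank
#'
#' Circular convolution of the subband with each (complex, quadrature)
#' spatial-domain Log-Gabor filter, computed as `ifft(fft(subband) *
#' kernel)`. Because the kernels are one-sided in angle, the responses are
#' complex; real and imaginary parts form even/odd symmetric pairs.
#'
#' @param subband Numeric matrix with the bank's dimensions.
#' @param bank A [LogGaborBank-class].
#' @return List of complex response matrices, one per kernel.
#' @export
logGaborResponse <- function(subband, bank) {
  checkImage(subband, what = "subband")
  if (!identical(dim(subband), bank@imgDim))
    stop("subband dimensions do not match the bank")
  X <- fft2(subband)
  lapply(bank@kernels, function(k) ifft2(X * k))
}

#' Pointwise Log-Gabor energy of a response set
#'
#' `E(i, j) = sum over scales and orientations of real(G)^2 + imag(G)^2`
#' for the complex responses `G` of [logGaborResponse()].
#'
#' @param responses Non-empty list of same-shaped complex matrices.
#' @return Non-negative matrix (the energy map).
#' @export
logGaborEnergy <- function(responses) {
  if (length(responses) == 0L) stop("response set must be non-empty")
  do.call(checkSameShape, responses)
  Reduce(`+`, lapply(responses, function(G) Re(G)^2 + Im(G)^2))
}

#' Local (window-averaged) energy map
#'
#' Averages an energy map over the `(2M+1) x (2N+1)` window centred at each
#' pixel. This windowing is what makes the high-frequency activity measure
#' respond to local texture rather than single-pixel magnitude, and is the
#' main source of its noise robustness.
#'
#' @param E Energy map (numeric matrix).
#' @param M,N Window half-height and half-width (non-negative integers;
#'   default 1, i.e. a 3 x 3 window).
#' @param boundary Border policy for the window: `"periodic"` (default;
#'   keeps the whole fusion pipeline exactly shift covariant) or
#'   `"reflect"`.
#' @return Matrix of the same shape as `E`.
#' @export
localEnergy <- function(E, M = 1L, N = 1L, boundary = "periodic") {
  checkImage(E, what = "energy map")
  if (M < 0 || N < 0) stop("window half-sizes must be non-negative")
  boxMean(E, as.integer(M), as.integer(N), boundary)
}
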