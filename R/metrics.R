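# Objective fusion-quality metrics. Histogram-based metrics quantize
# intensities to integer gray levels 0..L-1 (clipping first), matching
# 8-bit acquisition; all logs are base 2.

quantizeGray <- function(img, L = 256L) {
  v <- pmin(pmax(round(img), 0), L - 1L)
  storage.mode(v) <- "integer"
  v
}

grayHistogram <- function(img, L = 256L) {
  tabulate(as.vector(quantizeGray(img, L)) + 1L, nbins = L) / length(img)
}

#' Standard deviation of an image
#'
#' Population standard deviation about the image mean (divisor `M0 * N0`,
#' not `M0 * N0 - 1`). Larger values indicate a wider spread of gray
#' values, i.e. more contrast in the fused image.
#'
#' @param F Numeric matrix.
#' @return Non-negative scalar.
#' @export
stdMetric <- function(F) {
  checkImage(F, what = "F")
  sqrt(mean((F - mean(F))^2))
}

## Sobel gradient strength and orientation with replicated borders.
sobelGradient <- function(img) {
  p <- img[c(1, seq_len(nrow(img)), nrow(img)),
           c(1, seq_len(ncol(img)), ncol(img)), drop = FALSE]
  n <- nrow(img); m <- ncol(img)
  i <- 2:(n + 1); j <- 2:(m + 1)
  ## horizontal derivative (along columns) and vertical (along rows)
  sx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  sy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  g <- sqrt(sx^2 + sy^2)
  a <- atan2(sy, sx)
  ## fold orientation into (-pi/2, pi/2] (edge orientation, not direction)
  a[a > pi / 2] <- a[a > pi / 2] - pi
  a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
  list(strength = g, orientation = a)
}

#' Edge-based similarity measure Q^AB/F
#'
#' Xydeas-Petrovic edge-preservation measure: per pixel, the fused image's
#' Sobel gradient is compared with each source's in strength (ratio of the
#' smaller to the larger) and in orientation (normalised angular agreement);
#' both are passed through sigmoid preservation models and multiplied, and
#' the per-source preservation values are averaged with the source gradient
#' strengths as weights. The result lies in \[0, 1\]; 1 means all source
#' edge information reached the fused image.
#'
#' @param A,B Source images.
#' @param F Fused image, same shape.
#' @param gammaA,kappaA,sigmaA Strength-preservation sigmoid constants
#'   (defaults 0.9994, -15, 0.5).
#' @param gammaG,kappaG,sigmaG Orientation-preservation sigmoid constants
#'   (defaults 0.9879, -22, 0.8).
#' @return Scalar in \[0, 1\]; 0 (with a warning) when both sources are
#'   flat so that no edge information exists to preserve.
#' @export
qabf <- function(A, B, F, gammaA = 0.9994, kappaA = -15, sigmaA = 0.5,
                 gammaG = 0.9879, kappaG = -22, sigmaG = 0.8) {
  checkSameShape(A, B, F)
  gA <- sobelGradient(A); gB <- sobelGradient(B); gF <- sobelGradient(F)
  qxf <- function(gx, gf) {
    ## relative strength: smaller over larger; 0 where both vanish
    G <- matrix(0, nrow(gx$strength), ncol(gx$strength))
    nz <- gx$strength > 0 | gf$strength > 0
    G[nz] <- pmin(gx$strength, gf$strength)[nz] /
      pmax(gx$strength, gf$strength)[nz]
    Aang <- 1 - abs(gx$orientation - gf$orientation) / (pi / 2)
    Qa <- gammaA / (1 + exp(kappaA * (G - sigmaA)))
    Qg <- gammaG / (1 + exp(kappaG * (Aang - sigmaG)))
    Qa * Qg
  }
  wA <- gA$strength; wB <- gB$strength
  wTot <- sum(wA) + sum(wB)
  if (wTot == 0) {
    warning("both source images are flat; Q^AB/F is defined as 0")
    return(0)
  }
  sum(qxf(gA, gF) * wA + qxf(gB, gF) * wB) / wTot
}

mutualInformationPair <- function(X, F, L = 256L) {
  x <- as.vector(quantizeGray(X, L)); f <- as.vector(quantizeGray(F, L))
  joint <- tabulate(x * L + f + 1L, nbins = L * L) / length(x)
  px <- tabulate(x + 1L, nbins = L) / length(x)
  pf <- tabulate(f + 1L, nbins = L) / length(f)
  nz <- joint > 0
  idx <- which(nz) - 1L
  xi <- idx %/% L + 1L
  fi <- idx %% L + 1L
  sum(joint[nz] * log2(joint[nz] / (px[xi] * pf[fi])))
}

#' Mutual information between a fused image and its sources
#'
#' `MI = MI_AF + MI_BF`, each term computed from the normalised joint and
#' marginal gray-level histograms, in bits. Larger values mean the fused
#' image carries more of the sources' information.
#'
#' @param A,B Source images.
#' @param F Fused image, same shape.
#' @param L Number of gray-level bins (default 256, one per 8-bit level).
#' @return Non-negative scalar (bits).
#' @export
mutualInformation <- function(A, B, F, L = 256L) {
  checkSameShape(A, B, F)
  if (L < 1L) stop("L must be positive")
  mutualInformationPair(A, F, L) + mutualInformationPair(B, F, L)
}

crossEntropyPair <- function(src, F, L = 256L) {
  P <- grayHistogram(src, L)
  Q <- grayHistogram(F, L)
  nz <- P > 0
  Qs <- Q[nz]
  Qs[Qs == 0] <- 1e-12                      # Eq. undefined there; keep total
  sum(P[nz] * log2(P[nz] / Qs))
}

#' Histogram cross entropy between sources and fused image
#'
#' `CE(P, Q) = sum_l P_l log2(P_l / Q_l)` over gray-level histograms; the
#' reported value for a fused image is the arithmetic mean of `CE(A, F)`
#' and `CE(B, F)`. Bins with `P_l = 0` contribute zero; empty fused-image
#' bins facing occupied source bins are floored at 1e-12. Lower is better
#' (the fused histogram resembles the sources more closely).
#'
#' @param A Source image, or the single source when `B` is missing.
#' @param B Second source image (optional).
#' @param F Fused image.
#' @param L Number of gray-level bins (default 256).
#' @return Scalar (bits).
#' @export
crossEntropy <- function(A, F, B = NULL, L = 256L) {
  checkSameShape(A, F)
  if (is.null(B)) return(crossEntropyPair(A, F, L))
  checkSameShape(B, F)
  (crossEntropyPair(A, F, L) + crossEntropyPair(B, F, L)) / 2
}

#' Spatial frequency of an image
#'
#' `SF = sqrt(RF^2 + CF^2)` where the row frequency RF is the RMS of
#' first differences along rows (adjacent columns) and the column frequency
#' CF the RMS of first differences along columns (adjacent rows);
#' differences are taken over valid interior indices and normalised by the
#' full pixel count `M0 * N0`. A proxy for the amount of detail.
#'
#' @param F Numeric matrix, at least 2 x 2.
#' @return Non-negative scalar.
#' @export
spatialFrequency <- function(F) {
  checkImage(F, minDim = 2L, what = "F")
  n <- nrow(F); m <- ncol(F)
  rf2 <- sum((F[, -1] - F[, -m])^2) / (n * m)
  cf2 <- sum((F[-1, ] - F[-n, ])^2) / (n * m)
  sqrt(rf2 + cf2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` in dB against a reference image;
#' `Inf` when the images are identical.
#'
#' @param F Image under test.
#' @param ref Reference image, same shape.
#' @return Scalar in dB (possibly `Inf`).
#' @export
psnr <- function(F, ref) {
  checkSameShape(F, ref)
  mse <- mean((F - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Evaluate a fused image with the full metric suite
#'
#' @param A,B Source images.
#' @param F Fused image.
#' @param ref Optional reference image for PSNR.
#' @param L Number of gray-level bins for the histogram metrics.
#' @return A [MetricsReport-class].
#' @examples
#' ph <- makePhantomPair(size = c(64, 64), seed = 1)
#' F <- fusedImage(fuseImages(ph$A, ph$B))
#' evaluateAll(ph$A, ph$B, F)
#' @export
evaluateAll <- function(A, B, F, ref = NULL, L = 256L) {
  checkSameShape(A, B, F)
  new("MetricsReport",
      std = stdMetric(F),
      qabf = qabf(A, B, F),
      mi = mutualInformation(A, B, F, L),
      crossEntropy = crossEntropy(A, F, B = B, L = L),
      spatialFrequency = spatialFrequency(F),
      psnr = if (is.null(ref)) NA_real_ else psnr(F, ref))
}

#' @describeIn MetricsReport Print the report.
#' @param object A `MetricsReport`.
#' @export
setMethod("show", "MetricsReport", function(object) {
  cat("Fusion quality report\n")
  cat(sprintf("  STD               %8.3f\n", object@std))
  cat(sprintf("  Q^AB/F            %8.3f\n", object@qabf))
  cat(sprintf("  MI (bits)         %8.3f\n", object@mi))
  cat(sprintf("  cross entropy     %8.3f\n", object@crossEntropy))
  cat(sprintf("  spatial frequency %8.3f\n", object@spatialFrequency))
  if (!is.na(object@psnr))
    cat(sprintf("  PSNR (dB)         %8.3f\n", object@psnr))
})

#' @describeIn MetricsReport Convert to a named list.
#' @param x A `MetricsReport`.
#' @param ... Unused.
#' @export
setMethod("as.list", "MetricsReport", function(x, ...) {
  list(std = x@std, qabf = x@qabf, mi = x@mi, crossEntropy = x@crossEntropy,
       spatialFrequency = x@spatialFrequency, psnr = x@psnr)
})
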