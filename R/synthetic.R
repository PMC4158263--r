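# Deterministic multimodal phantom generator. The pair emulates a
# registered CT/MR-like acquisition of one "head": both modalities share
# the outer geometry (an elliptical rim), modality A renders dense,
# bone-like structures (bright rim, compact bright blobs and a midline
# bar), modality B renders soft-tissue-like content (dim rim, smooth
# interior with broad blobs and band-limited texture). Each modality
# carries structures the other lacks, which is the property the fusion
# rules are meant to exploit.

## isotropic FFT Gaussian blur with periodic boundaries
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- freqGrid(dim(img))
  H <- exp(-2 * pi^2 * sigma^2 * g$radius^2)
  ifft2Re(fft2(img) * H)
}

#' Generate a registered multimodal phantom pair
#'
#' Produces two single-channel images `A` (dense/CT-like) and `B`
#' (soft-tissue/MR-like) of a shared phantom geometry, plus a `composite`
#' full-information reference (the per-pixel maximum of A and B). The same
#' seed always yields bit-identical output; the caller's RNG state is left
#' untouched.
#'
#' @param size Image dimensions `c(rows, cols)`, at least 64 x 64
#'   (default `c(256, 256)`).
#' @param seed Integer seed; fully determines the phantom.
#' @param numBlobs Total number of exclusive structures split between the
#'   modalities (default 6).
#' @param contrastSplit Fraction of the structures rendered only in
#'   modality A (default 0.5).
#' @return List with matrices `A`, `B`, `composite`, values in \[0, 255\].
#' @examples
#' ph <- makePhantomPair(size = c(64, 64), seed = 42)
#' range(ph$A); range(ph$composite - ph$B)  # composite >= B everywhere
#' @export
makePhantomPair <- function(size = c(256L, 256L), seed = 1L,
                            numBlobs = 6L, contrastSplit = 0.5) {
  size <- as.integer(size)
  if (any(size < 64L))
    stop("phantom must be at least 64 x 64")
  if (numBlobs < 0L) stop("numBlobs must be non-negative")
  if (contrastSplit < 0 || contrastSplit > 1)
    stop("contrastSplit must be in [0, 1]")
  withSeed(seed, {
    h <- size[1]; w <- size[2]
    yi <- matrix(seq_len(h), h, w)
    xj <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ## shared geometry: elliptical rim, normalised radius
    rr <- sqrt(((yi - cy) / (0.42 * h))^2 + ((xj - cx) / (0.45 * w))^2)
    inside <- rr < 1
    rim <- rr >= 0.88 & rr < 1
    nA <- round(numBlobs * contrastSplit)
    nB <- numBlobs - nA
    blob <- function(amp, sx, sy, compact) {
      ## one random structure inside the rim
      th <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.55)
      by <- cy + rad * 0.42 * h * sin(th)
      bx <- cx + rad * 0.45 * w * cos(th)
      d2 <- ((yi - by) / sy)^2 + ((xj - bx) / sx)^2
      if (compact) amp * (d2 < 1) else amp * exp(-d2 / 2)
    }
    ## A: dense structures, sharp and bright on a dark interior
    A <- matrix(0, h, w)
    A[inside] <- 40
    A[rim] <- 230
    A[abs(xj - cx) < 0.015 * w & rr < 0.75] <- 210     # midline bar
    for (i in seq_len(nA))
      A <- A + blob(stats::runif(1, 120, 180),
                    stats::runif(1, 0.03, 0.08) * w,
                    stats::runif(1, 0.03, 0.08) * h, compact = TRUE) *
        inside
    A <- gaussianBlur(A, 0.8)
    ## B: soft tissue, smooth blobs plus band-limited texture
    B <- matrix(0, h, w)
    B[inside] <- 120
    B[rim] <- 60
    for (i in seq_len(nB))
      B <- B + blob(stats::runif(1, -70, 90) |> (\(a) a + sign(a) * 30)(),
                    stats::runif(1, 0.08, 0.2) * w,
                    stats::runif(1, 0.08, 0.2) * h, compact = FALSE) *
        inside
    texture <- gaussianBlur(matrix(stats::rnorm(h * w), h, w), 1.5)
    texture <- texture / stats::sd(texture) * 12
    B <- B + texture * inside
    B <- gaussianBlur(B, 1.2)
    A <- pmin(pmax(A, 0), 255)
    B <- pmin(pmax(B, 0), 255)
    list(A = A, B = B, composite = pmax(A, B))
  })
}

#' Add seeded Gaussian noise to an image
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `sigmaFraction * 255` (i.e. a fraction of the 8-bit dynamic range) and
#' clips the result to \[0, 255\]. The caller's RNG state is preserved.
#'
#' @param img Numeric matrix.
#' @param sigmaFraction Noise standard deviation as a fraction of the
#'   dynamic range; `0.05` reproduces a "5 percent" corruption
#'   (sigma = 12.75 gray levels).
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
addGaussianNoise <- function(img, sigmaFraction = 0.05, seed = 1L) {
  checkImage(img)
  if (sigmaFraction < 0) stop("sigmaFraction must be non-negative")
  if (sigmaFraction == 0) return(img)
  withSeed(seed, {
    noisy <- img + matrix(stats::rnorm(length(img), 0, sigmaFraction * 255),
                          nrow(img), ncol(img))
    pmin(pmax(noisy, 0), 255)
  })
}
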