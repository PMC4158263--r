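# Filter design for the nonsubsampled pyramid and directional banks.
#
# Pyramid stage: a two-channel undecimated bank built from a separable 2-D
# lowpass pair (analysis h0, synthesis g0) with unit DC gain; the highpass
# analysis channel is the complement 1 - G0(w) H0(w) with identity synthesis,
# so the perfect-reconstruction identity H0 G0 + H1 G1 = 1 holds exactly by
# construction at every level of the a-trous cascade.
#
# Directional stage: 2^l smooth fan windows forming an exact partition of
# unity over angle (raised-cosine crossfades), analysis windows with identity
# synthesis; the channels of any signal sum back to the signal.

## Centred symmetric 1-D lowpass prototypes, DC gain 1.
pyramidPrototype <- function(name) {
  switch(name,
    "9-7" = list(
      h0 = c(0.026748757410810, -0.016864118442875, -0.078223266528988,
             0.266864118442872,  0.602949018236358,  0.266864118442872,
             -0.078223266528988, -0.016864118442875,  0.026748757410810),
      g0 = c(-0.045635881557124, -0.028771763114250,  0.295635881557124,
             0.557543526228500,  0.295635881557124, -0.028771763114250,
             -0.045635881557124)),
    "burt" = list(
      h0 = c(0.0625, 0.25, 0.375, 0.25, 0.0625),
      g0 = c(0.0625, 0.25, 0.375, 0.25, 0.0625)),
    stop("unknown pyramid filter name: '", name,
         "' (supported: \"9-7\", \"burt\")")
  )
}

## Real DTFT of a centred symmetric odd-length filter at the n FFT bins,
## with the argument scaled by `upsample` (a-trous zero insertion).
filterDTFT <- function(h, n, upsample = 1L) {
  r <- (length(h) - 1L) / 2L
  om <- 2 * pi * (0:(n - 1)) / n * upsample
  resp <- rep(h[r + 1L], n)
  for (k in seq_len(r))
    resp <- resp + 2 * h[r + 1L + k] * cos(k * om)
  resp
}

## 2-D frequency masks of the pyramid pair at a-trous level j (filters
## upsampled by 2^j). Returns lowpass analysis H0, lowpass synthesis G0 and
## the complementary highpass analysis HP = 1 - H0 G0 on the FFT grid.
pyramidMasks <- function(dm, name, j) {
  p <- pyramidPrototype(name)
  up <- 2L^j
  H0 <- outer(filterDTFT(p$h0, dm[1], up), filterDTFT(p$h0, dm[2], up))
  G0 <- outer(filterDTFT(p$g0, dm[1], up), filterDTFT(p$g0, dm[2], up))
  list(H0 = H0, G0 = G0, HP = 1 - H0 * G0)
}

#' Design the nonsubsampled pyramid filter quadruple
#'
#' Returns the two analysis and two synthesis 2-D spatial filters of the
#' two-channel undecimated pyramid stage. The lowpass pair is the separable
#' product of the named 1-D prototype (CDF 9/7-derived by default, DC gain
#' 1); the highpass analysis filter is the complement `delta - g0 * h0`
#' (with `*` denoting 2-D convolution) and the highpass synthesis filter is
#' the identity, so the nonsubsampled perfect-reconstruction identity
#' `H0 G0 + H1 G1 = 1` is satisfied exactly.
#'
#' @param name Filter pair name: `"9-7"` (default) or `"burt"`.
#' @return A list with elements `analysisLow`, `analysisHigh`,
#'   `synthesisLow`, `synthesisHigh`, each a 2-D kernel matrix.
#' @examples
#' f <- designPyramidFilters("9-7")
#' sum(f$analysisLow)   # DC gain 1
#' sum(f$analysisHigh)  # 0: the highpass kills constants
#' @export
designPyramidFilters <- function(name = "9-7") {
  p <- pyramidPrototype(name)
  h0 <- outer(p$h0, p$h0)
  g0 <- outer(p$g0, p$g0)
  ## delta - g0 * h0, spatial-domain 2-D convolution of the separable pair
  hp1 <- convolve(p$g0, rev(p$h0), type = "open")
  hp <- -outer(hp1, hp1)
  c0 <- (length(hp1) + 1L) / 2L
  hp[c0, c0] <- hp[c0, c0] + 1
  list(analysisLow = h0, analysisHigh = hp,
       synthesisLow = g0, synthesisHigh = matrix(1, 1, 1))
}

#' Design nonsubsampled directional fan windows
#'
#' Builds the `2^exponent` frequency-domain directional windows used by the
#' nonsubsampled directional filter bank on an FFT grid of the given shape.
#' Wedges are centred at angles `(d - 1/2) * pi / 2^exponent` (modulo pi, so
#' windows are symmetric under frequency negation and the filtered subbands
#' are real) with raised-cosine crossfades; adjacent tapers are complementary
#' so the windows sum to 1 at every frequency bin, which makes the analysis
#' bank with identity synthesis perfectly reconstructing.
#'
#' @param dm Image dimensions `c(rows, cols)`.
#' @param exponent Non-negative integer; the band is split into
#'   `2^exponent` directions. `0` yields a single all-pass window.
#' @param name Realization name; only `"fan"` is supported.
#' @return List of `2^exponent` non-negative matrices summing to 1.
#' @examples
#' w <- designDirectionalWindows(c(32, 32), 2)
#' range(Reduce(`+`, w))  # both 1: exact partition of unity
#' @export
designDirectionalWindows <- function(dm, exponent, name = "fan") {
  if (!identical(name, "fan"))
    stop("unknown directional filter name: '", name, "' (supported: \"fan\")")
  if (length(exponent) != 1L || exponent < 0)
    stop("exponent must be a single non-negative integer")
  dm <- as.integer(dm)
  nd <- 2L^exponent
  if (nd == 1L)
    return(list(matrix(1, dm[1], dm[2])))
  g <- freqGrid(dm)
  ang <- g$angle %% pi                       # orientation axis, [0, pi)
  w <- pi / nd                               # wedge width
  tw <- w / 2                                # raised-cosine taper width
  lapply(seq_len(nd), function(d) {
    centre <- (d - 0.5) * w
    ## wrapped angular offset from the wedge centre, in (-pi/2, pi/2]
    delta <- ((ang - centre + pi / 2) %% pi) - pi / 2
    a <- abs(delta)
    win <- matrix(0, dm[1], dm[2])
    win[a <= (w - tw) / 2] <- 1
    sel <- a > (w - tw) / 2 & a < (w + tw) / 2
    s <- (a[sel] - (w - tw) / 2) / tw
    win[sel] <- cos(pi * s / 2)^2
    win
  })
}
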