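test_that("decomposition yields the expected subband counts and sizes", {
  img <- randomImage(64, seed = 5)
  dec <- nsctDecompose(img, nsctConfig(3, c(2, 3, 4)))
  expect_identical(dim(dec), c(64L, 64L))
  expect_identical(dim(lowBand(dec)), c(64L, 64L))
  counts <- lengths(highBands(dec))
  expect_equal(counts, c(4L, 8L, 16L))      # 2^2, 2^3, 2^4, coarse to fine
  expect_equal(sum(counts), 28L)
  for (k in 1:3)
    for (b in highBands(dec, k))
      expect_identical(dim(b), c(64L, 64L))
})

test_that("reconstruction inverts decomposition for all supported configs", {
  for (pyr in c("9-7", "burt")) {
    for (n in c(32, 64)) {
      img <- randomImage(n, seed = n + nchar(pyr))
      dec <- nsctDecompose(img, nsctConfig(3, c(2, 3, 4),
                                           pyramidFilter = pyr))
      expect_lt(max(abs(nsctReconstruct(dec) - img)), 1e-6)
    }
  }
  ## non-square, non-default direction counts
  img <- randomImage(48, 64, seed = 9)
  dec <- nsctDecompose(img, nsctConfig(2, c(0, 3)))
  expect_lt(max(abs(nsctReconstruct(dec) - img)), 1e-6)
})

test_that("constant images put everything into the low band", {
  dec <- nsctDecompose(matrix(42, 64, 64))
  for (k in 1:3)
    for (b in highBands(dec, k))
      expect_lt(max(abs(b)), 1e-8)
  expect_lt(max(abs(lowBand(dec) - 42)), 1e-8)
  ## zeroing all subbands reconstructs to zero
  zero <- nsctDecompose(matrix(0, 64, 64))
  expect_lt(max(abs(nsctReconstruct(zero))), 1e-12)
})

test_that("the transform is linear", {
  A <- randomImage(32, seed = 21)
  B <- randomImage(32, seed = 22)
  dA <- nsctDecompose(A); dB <- nsctDecompose(B); dS <- nsctDecompose(A + B)
  expect_lt(max(abs(lowBand(dS) - lowBand(dA) - lowBand(dB))), 1e-8)
  for (k in 1:3)
    for (d in seq_along(highBands(dS, k)))
      expect_lt(max(abs(highBands(dS, k)[[d]] -
                        highBands(dA, k)[[d]] -
                        highBands(dB, k)[[d]])), 1e-8)
})

test_that("decomposition is cyclically shift covariant", {
  img <- randomImage(64, seed = 31)
  dec <- nsctDecompose(img)
  dec2 <- nsctDecompose(shiftMat(img, 5, 7))
  expect_lt(max(abs(lowBand(dec2) - shiftMat(lowBand(dec), 5, 7))), 1e-6)
  for (k in 1:3)
    for (d in seq_along(highBands(dec, k)))
      expect_lt(max(abs(highBands(dec2, k)[[d]] -
                        shiftMat(highBands(dec, k)[[d]], 5, 7))), 1e-6)
  ## shift, decompose, reconstruct, unshift equals the plain round trip
  rec <- shiftMat(nsctReconstruct(dec2), -5, -7)
  expect_lt(max(abs(rec - nsctReconstruct(dec))), 1e-6)
})

test_that("invalid inputs are rejected", {
  expect_error(nsctDecompose(matrix(1, 4, 4)), "at least")
  expect_error(nsctDecompose(matrix(NA_real_, 64, 64)), "non-finite")
  expect_error(nsctConfig(3, c(2, 3)), "one entry per level")
  ## shape mismatch among subbands is caught by the class validity
  dec <- nsctDecompose(randomImage(64, seed = 1))
  broken <- dec
  broken@high[[1]][[1]] <- matrix(0, 8, 8)
  expect_error(nsctReconstruct(broken), "dimensions")
})
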