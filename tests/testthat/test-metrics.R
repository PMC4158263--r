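test_that("standard deviation matches analytic and brute-force values", {
  expect_equal(stdMetric(matrix(7, 8, 8)), 0)
  half <- rbind(matrix(0, 8, 16), matrix(255, 8, 16))
  expect_equal(stdMetric(half), 127.5)
  img <- randomImage(16, seed = 3)
  expect_equal(stdMetric(img), bruteStd(img), tolerance = 1e-10)
})

test_that("Q^AB/F is high for perfect fusion and matches the oracle", {
  ph <- makePhantomPair(size = c(64, 64), seed = 9)
  expect_gte(qabf(ph$A, ph$A, ph$A), 0.95)
  small <- ph$A[1:12, 1:12]
  small2 <- ph$B[1:12, 1:12]
  fused <- 0.5 * (small + small2)
  expect_equal(qabf(small, small2, fused), bruteQabf(small, small2, fused),
               tolerance = 1e-10)
  expect_warning(q0 <- qabf(matrix(5, 8, 8), matrix(5, 8, 8),
                            matrix(9, 8, 8)), "flat")
  expect_equal(q0, 0)
})

test_that("Q^AB/F stays in [0, 1] on fuzzed inputs", {
  for (s in 1:25) {
    A <- randomImage(10, seed = 3 * s)
    B <- randomImage(10, seed = 3 * s + 1)
    F <- randomImage(10, seed = 3 * s + 2)
    q <- qabf(A, B, F)
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("mutual information has its analytic fixed points", {
  bin <- matrix(rep(c(0, 255), each = 32), 8, 8)
  expect_equal(mutualInformation(bin, bin, bin), 2)       # 1 bit per source
  A <- randomImage(16, seed = 5)
  expect_equal(mutualInformation(A, A, matrix(100, 16, 16)), 0)
  B <- randomImage(16, seed = 6)
  F <- randomImage(16, seed = 7)
  expect_equal(mutualInformation(A, B, F),
               bruteMIPair(A, F) + bruteMIPair(B, F), tolerance = 1e-10)
  ## symmetry of the pairwise term under argument swap
  expect_equal(bruteMIPair(A, F), bruteMIPair(F, A), tolerance = 1e-12)
})

test_that("cross entropy is zero at identity and log2(L) at worst case", {
  A <- randomImage(16, seed = 8)
  expect_equal(crossEntropy(A, A), 0)
  src <- matrix(17, 16, 16)                  # single gray level
  unif <- matrix(rep(0:255, length.out = 256), 16, 16)
  expect_equal(crossEntropy(src, unif), 8)   # log2(256)
  B <- randomImage(16, seed = 9); F <- randomImage(16, seed = 10)
  expect_equal(crossEntropy(A, F, B = B),
               (bruteCrossEntropy(A, F) + bruteCrossEntropy(B, F)) / 2,
               tolerance = 1e-10)
})

test_that("spatial frequency follows the valid-index convention", {
  expect_equal(spatialFrequency(matrix(9, 16, 16)), 0)
  stripes <- matrix(rep(c(0, 255), 128), 16, 256, byrow = TRUE)
  expect_equal(spatialFrequency(stripes), 255 * sqrt(255 / 256),
               tolerance = 1e-10)
  img <- randomImage(16, seed = 11)
  expect_equal(spatialFrequency(img), bruteSpatialFrequency(img),
               tolerance = 1e-10)
})

test_that("PSNR has its sentinel and scalar fixed points", {
  A <- randomImage(16, seed = 12)
  expect_identical(psnr(A, A), Inf)
  expect_equal(psnr(A + 255, A), 0)
  expect_equal(psnr(A + 1, A), 10 * log10(255^2))
})

test_that("evaluateAll composes the individual metrics bit-for-bit", {
  ph <- makePhantomPair(size = c(64, 64), seed = 4)
  F <- 0.5 * (ph$A + ph$B)
  rep <- evaluateAll(ph$A, ph$B, F, ref = ph$A)
  expect_identical(rep@std, stdMetric(F))
  expect_identical(rep@qabf, qabf(ph$A, ph$B, F))
  expect_identical(rep@mi, mutualInformation(ph$A, ph$B, F))
  expect_identical(rep@crossEntropy, crossEntropy(ph$A, F, B = ph$B))
  expect_identical(rep@spatialFrequency, spatialFrequency(F))
  expect_identical(rep@psnr, psnr(F, ph$A))
  ## degenerate all-equal case
  repEq <- suppressWarnings(evaluateAll(ph$A, ph$A, ph$A, ref = ph$A))
  expect_equal(repEq@crossEntropy, 0)
  expect_identical(repEq@psnr, Inf)
  expect_gte(repEq@qabf, 0.95)
  const <- matrix(5, 16, 16)
  repC <- suppressWarnings(evaluateAll(const, const, const))
  expect_equal(repC@std, 0)
  expect_equal(repC@spatialFrequency, 0)
  expect_equal(repC@mi, 0)
  expect_true(is.na(repC@psnr))
})
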