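test_that("kernel attains 1 at (f0, theta0) and 0 at DC", {
  ## 8/32 = 0.25 cycles/pixel lies exactly on the grid
  k <- logGaborKernel(c(32, 32), f0 = 0.25, theta0 = 0)
  expect_equal(k[1, 9], 1)
  expect_equal(k[1, 1], 0)
  ## scalar check of the radial term at f = 0.1, f0 = 0.25, theta = theta0:
  ## the 0.1 c/px bin on a 40-wide grid is column 5
  k2 <- logGaborKernel(c(40, 40), f0 = 0.25, theta0 = 0, sigmaRatio = 0.55)
  expect_equal(k2[1, 5], exp(-log(0.4)^2 / (2 * log(0.55)^2)),
               tolerance = 1e-12)
})

test_that("every kernel of a bank is non-negative with zero DC", {
  bank <- logGaborBank(c(32, 32))
  expect_length(bank@kernels, 4 * 6)
  for (k in bank@kernels) {
    expect_true(all(k >= 0))
    expect_identical(k[1, 1], 0)
  }
  expect_error(logGaborKernel(c(1, 8), 0.25, 0), "at least 2 x 2")
})

test_that("responses match a brute-force circular convolution oracle", {
  img <- randomImage(16, seed = 8, lo = -1, hi = 1)
  bank <- logGaborBank(c(16, 16), logGaborParams(numScales = 1,
                                                 numOrientations = 2))
  resp <- logGaborResponse(img, bank)
  for (i in seq_along(resp)) {
    oracle <- bruteCircularFilter(img, bank@kernels[[i]])
    expect_lt(max(Mod(resp[[i]] - oracle)), 1e-8)
  }
})

test_that("responses are linear and vanish on the zero subband", {
  bank <- logGaborBank(c(16, 16))
  zero <- logGaborResponse(matrix(0, 16, 16), bank)
  expect_true(all(sapply(zero, function(G) max(Mod(G)) == 0)))
  img <- randomImage(16, seed = 4)
  r1 <- logGaborResponse(img, bank)
  r2 <- logGaborResponse(2.5 * img, bank)
  for (i in seq_along(r1))
    expect_lt(max(Mod(r2[[i]] - 2.5 * r1[[i]])), 1e-9)
  expect_error(logGaborResponse(matrix(0, 8, 8), bank), "do not match")
})

test_that("energy is the summed squared modulus, sign-invariant", {
  ## single response with real 3, imaginary 4 gives energy 25
  G <- matrix(complex(real = 3, imaginary = 4), 2, 2)
  expect_equal(logGaborEnergy(list(G)), matrix(25, 2, 2))
  ## random responses against a double-loop summation oracle
  set.seed(12)
  resp <- replicate(5, matrix(complex(real = rnorm(64), imaginary = rnorm(64)),
                              8, 8), simplify = FALSE)
  oracle <- matrix(0, 8, 8)
  for (r in resp) for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- oracle[i, j] + Re(r[i, j])^2 + Im(r[i, j])^2
  expect_lt(max(abs(logGaborEnergy(resp) - oracle)), 1e-10)
  expect_error(logGaborEnergy(list()), "non-empty")
  ## E(-H) = E(H) through the full response path
  bank <- logGaborBank(c(16, 16))
  img <- randomImage(16, seed = 2)
  E1 <- logGaborEnergy(logGaborResponse(img, bank))
  E2 <- logGaborEnergy(logGaborResponse(-img, bank))
  expect_lt(max(abs(E1 - E2)), 1e-9)
  expect_true(all(E1 >= 0))
})

test_that("local energy windowing averages correctly", {
  E <- randomImage(12, seed = 6, lo = 0, hi = 10)
  ## M = N = 0 is the identity
  expect_equal(localEnergy(E, 0, 0), E)
  ## constant maps are fixed points
  expect_equal(localEnergy(matrix(3.5, 9, 9), 1, 1), matrix(3.5, 9, 9))
  ## impulse at the centre of a 9x9 zero map spreads to 1/9 over 3x3
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  le <- localEnergy(imp, 1, 1)
  expected <- matrix(0, 9, 9); expected[4:6, 4:6] <- 1 / 9
  expect_equal(le, expected)
  ## range contraction: min E <= LE <= max E (both boundary policies)
  for (b in c("periodic", "reflect")) {
    le2 <- localEnergy(E, 2, 1, boundary = b)
    expect_gte(min(le2), min(E))
    expect_lte(max(le2), max(E))
  }
  expect_error(localEnergy(E, -1, 0), "non-negative")
})
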