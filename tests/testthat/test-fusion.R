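test_that("low-band rule selects by phase congruency with tie averaging", {
  LA <- matrix(10, 2, 2); LB <- matrix(20, 2, 2)
  PCA <- matrix(c(0.8, 0.1, 0.5, 0.3), 2, 2)
  PCB <- matrix(c(0.3, 0.6, 0.5, 0.3 + 1e-12), 2, 2)
  r <- fuseLow(LA, LB, PCA, PCB, tol = 1e-9)
  expect_equal(r$fused[1, 1], 10)          # PCA > PCB -> A
  expect_equal(r$fused[2, 1], 20)          # PCA < PCB -> B
  expect_equal(r$fused[1, 2], 15)          # exact tie -> average
  expect_equal(r$fused[2, 2], 15)          # within tolerance -> average
  expect_equal(r$selection, matrix(c(1, 2, 0, 0), 2, 2))
  ## identical subimages fuse to themselves whatever the maps say
  r2 <- fuseLow(LA, LA, PCA, PCB)
  expect_equal(r2$fused, LA)
  expect_error(fuseLow(LA, LB, PCA, matrix(0, 3, 3)), "same dimensions")
})

test_that("high-band rule selects by local energy, A on ties", {
  HA <- matrix(c(1, 2, 3, 4), 2, 2); HB <- -HA
  LEA <- matrix(c(5, 2, 7, 7), 2, 2)
  LEB <- matrix(c(2, 5, 7, 9), 2, 2)
  r <- fuseHigh(HA, HB, LEA, LEB)
  expect_equal(r$fused, matrix(c(1, -2, 3, -4), 2, 2))
  expect_equal(r$selection, matrix(c(1, 2, 1, 2), 2, 2))
  ## every output coefficient comes from exactly one source
  expect_true(all(r$fused == HA | r$fused == HB))
})

test_that("fusing an image with itself returns it", {
  ph <- makePhantomPair(size = c(64, 64), seed = 42)
  for (rules in c("proposed", "average_maximum")) {
    res <- fuseImages(ph$A, ph$A, fusionConfig(ruleSet = rules))
    expect_lt(max(abs(fusedImage(res) - ph$A)), 1e-4)
  }
})

test_that("fusion output has the input shape and full provenance", {
  ph <- makePhantomPair(size = c(64, 64), seed = 2)
  res <- fuseImages(ph$A, ph$B)
  expect_identical(dim(fusedImage(res)), dim(ph$A))
  sel <- selectionMaps(res)
  expect_true(all(sel$low %in% c(0, 1, 2)))
  ## verify provenance against the actual decompositions
  cfg <- fusionConfig()
  dA <- nsctDecompose(ph$A, cfg$nsct); dB <- nsctDecompose(ph$B, cfg$nsct)
  for (k in seq_along(sel$high))
    for (d in seq_along(sel$high[[k]]))
      expect_true(all(sel$high[[k]][[d]] %in% c(1, 2)))
  ## low-band values are LA, LB or their mean at the flagged pixels
  pcA <- phaseCongruency(lowBand(dA), cfg$pc)
  pcB <- phaseCongruency(lowBand(dB), cfg$pc)
  lr <- fuseLow(lowBand(dA), lowBand(dB), pcA, pcB, cfg$pcTieTolerance)
  mixed <- lr$selection == 0
  expect_equal(lr$fused[mixed],
               (0.5 * (lowBand(dA) + lowBand(dB)))[mixed])
  expect_equal(lr$fused[lr$selection == 1], lowBand(dA)[lr$selection == 1])
})

test_that("fusion is symmetric up to high-band ties", {
  ph <- makePhantomPair(size = c(64, 64), seed = 13)
  rAB <- fuseImages(ph$A, ph$B)
  rBA <- fuseImages(ph$B, ph$A)
  ## tie pixels (LEA == LEB) resolve to A in both orders; everywhere else
  ## the fused decompositions agree, so the images are nearly identical
  diff <- abs(fusedImage(rAB) - fusedImage(rBA))
  expect_lt(mean(diff > 1e-6), 0.05)
})

test_that("average-maximum rules behave as documented", {
  ph <- makePhantomPair(size = c(64, 64), seed = 5)
  cfg <- fusionConfig(ruleSet = "average_maximum")
  res <- fuseImages(ph$A, ph$B, cfg)
  dA <- nsctDecompose(ph$A, cfg$nsct); dB <- nsctDecompose(ph$B, cfg$nsct)
  ## rebuild the expected decomposition by hand and reconstruct
  highF <- highBands(dA)
  for (k in seq_along(highF))
    for (d in seq_along(highF[[k]])) {
      HA <- highBands(dA, k)[[d]]; HB <- highBands(dB, k)[[d]]
      sel <- abs(HA) >= abs(HB)
      H <- HB; H[sel] <- HA[sel]
      highF[[k]][[d]] <- H
    }
  decF <- new("NSCTDecomposition", low = 0.5 * (lowBand(dA) + lowBand(dB)),
              high = highF, config = cfg$nsct, imgDim = dim(dA))
  expect_lt(max(abs(fusedImage(res) - nsctReconstruct(decF))), 1e-10)
})

test_that("mismatched or too-small inputs fail cleanly", {
  expect_error(fuseImages(matrix(0, 64, 64), matrix(0, 32, 32)),
               "same dimensions")
  expect_error(fuseImages(matrix(1, 6, 6), matrix(2, 6, 6)), "at least")
  expect_error(fusionConfig(pcTieTolerance = -1), "non-negative")
})
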