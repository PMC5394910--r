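bank <- buildFilterBank()

test_that("filter-bank presets reconstruct perfectly and unknown names fail", {
  x <- randomImage(64, 64, 42)
  for (name in c("maxflat", "binomial3")) {
    bk <- buildFilterBank(name)
    pr <- function(a, s) {
      max(abs(conv2d(conv2d(x, a[[1]]), s[[1]]) +
              conv2d(conv2d(x, a[[2]]), s[[2]]) - x))
    }
    expect_lt(pr(bk@pyramidAnalysis, bk@pyramidSynthesis), 1e-6)
    expect_lt(pr(bk@fanAnalysis, bk@fanSynthesis), 1e-6)
  }
  expect_error(buildFilterBank("no_such_bank"), "unknown filter bank")
})

test_that("forward transform yields source-sized bands with the expected count", {
  x <- randomImage(32, 48, 1)
  d <- nsctForward(x, decompositionSpec(2, c(2, 3)), bank)
  expect_identical(bandCount(d), 1L + 4L + 8L)
  expect_identical(dim(lowBand(d)), dim(x))
  for (bands in highBands(d)) for (b in bands)
    expect_identical(dim(b), dim(x))
  # d_k = 0 keeps the stage's high band undirected
  d0 <- nsctForward(x, decompositionSpec(2, c(0, 0)), bank)
  expect_identical(bandCount(d0), 3L)
})

test_that("high-pass subbands of a constant image vanish", {
  d <- nsctForward(matrix(0.7, 32, 32), decompositionSpec(2, c(2, 2)), bank)
  for (bands in highBands(d)) for (b in bands)
    expect_lt(max(abs(b)), 1e-10)
})

test_that("round trip reconstructs the input across specs", {
  x <- randomImage(64, 64, 7)
  for (lv in 1:3) for (dd in 0:3) {
    spec <- decompositionSpec(lv, rep(dd, lv))
    rec <- nsctInverse(nsctForward(x, spec, bank), bank)
    expect_lt(max(abs(rec - x)), 1e-6)
  }
  # rectangular image, mixed directions
  y <- randomImage(40, 56, 8)
  rec <- nsctInverse(nsctForward(y, decompositionSpec(3, c(1, 2, 3)), bank), bank)
  expect_lt(max(abs(rec - y)), 1e-6)
})

test_that("transform is linear and the inverse respects scaling", {
  I <- randomImage(32, 32, 2); J <- randomImage(32, 32, 3)
  spec <- decompositionSpec(2, c(2, 1))
  dI <- nsctForward(I, spec, bank)
  dJ <- nsctForward(J, spec, bank)
  dS <- nsctForward(2 * I - 0.5 * J, spec, bank)
  expect_lt(max(abs(lowBand(dS) - (2 * lowBand(dI) - 0.5 * lowBand(dJ)))), 1e-9)
  for (k in seq_along(highBands(dS))) for (d in seq_along(highBands(dS)[[k]]))
    expect_lt(max(abs(highBands(dS)[[k]][[d]] -
                      (2 * highBands(dI)[[k]][[d]] - 0.5 * highBands(dJ)[[k]][[d]]))),
              1e-9)
  expect_lt(max(abs(nsctInverse(dS, bank) - 2 * nsctInverse(dI, bank) +
                    0.5 * nsctInverse(dJ, bank))), 1e-9)
  # all-zero decomposition inverts to the zero image
  z <- nsctForward(matrix(0, 16, 16), spec, bank)
  expect_equal(max(abs(nsctInverse(z, bank))), 0)
})

test_that("periodic-mode forward commutes with circular shifts", {
  x <- randomImage(32, 32, 5)
  spec <- decompositionSpec(2, c(2, 2))
  sh <- c(7L, -4L)
  d1 <- nsctForward(circShift(x, sh), spec, bank, "periodic")
  d2 <- nsctForward(x, spec, bank, "periodic")
  expect_lt(max(abs(lowBand(d1) - circShift(lowBand(d2), sh))), 1e-6)
  for (k in 1:2) for (d in 1:4)
    expect_lt(max(abs(highBands(d1)[[k]][[d]] -
                      circShift(highBands(d2)[[k]][[d]], sh))), 1e-6)
})

test_that("invalid inputs are rejected", {
  expect_error(nsctForward(1:10), "matrix")
  expect_error(nsctForward(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(decompositionSpec(2, c(2, 5)), "0..4")
  expect_error(decompositionSpec(2, c(2)), "levels")
  d <- nsctForward(randomImage(16, 16, 1), decompositionSpec(1, 1), bank)
  expect_error({ d@low <- matrix(0, 8, 8); validObject(d) }, "shape")
})

test_that("decompositions serialize to TIFF bands and back", {
  x <- randomImage(24, 24, 9)
  d <- nsctForward(x, decompositionSpec(2, c(1, 2)), bank)
  dir <- withr::local_tempdir()
  writeDecomposition(d, dir)
  d2 <- readDecomposition(dir)
  expect_identical(bandCount(d2), bandCount(d))
  expect_lt(max(abs(lowBand(d2) - lowBand(d))), 1e-5)
  expect_lt(max(abs(highBands(d2)[[2]][[3]] - highBands(d)[[2]][[3]])), 1e-5)
  expect_error(readDecomposition(file.path(dir, "nope")), "sidecar")
})
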