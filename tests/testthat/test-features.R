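test_that("NSML window template and operators match their printed values", {
  W <- nsctfusion:::.nsmlWeights(3L)
  expect_equal(W * 15, matrix(c(1, 2, 1, 2, 3, 2, 1, 2, 1), 3))
  expect_equal(sum(W), 1)
  ops <- eoeOperators()
  expect_equal(ops$E1, matrix(c(-1, -1, -1, 2, 2, 2, -1, -1, -1), 3, byrow = TRUE))
  expect_equal(ops$E2, matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3, byrow = TRUE))
  expect_equal(ops$E3, matrix(c(-1, 0, -1, 0, 4, 0, -1, 0, -1), 3, byrow = TRUE))
})

test_that("NSML responds to an impulse as the formula predicts", {
  expect_equal(max(abs(nsmlMap(matrix(2, 12, 12)))), 0)
  z <- matrix(0, 9, 9); z[5, 5] <- 1
  # M = 4 at the impulse, 1 at the four axial neighbours, 0 diagonally:
  # weighted squared sum = (3*16 + 2*4) / 15 = 56/15
  expect_equal(nsmlMap(z)[5, 5], 56 / 15, tolerance = 1e-12)
  expect_error(nsmlMap(z, window = 4), "odd")
  expect_error(nsmlMap(z, window = 9), "3, 5 or 7")
})

test_that("EOE vanishes on constants and lights up at a step edge", {
  expect_equal(max(abs(eoeMap(matrix(5, 10, 10)))), 0)
  # horizontal step: rows of 0 above rows of 1
  C <- rbind(matrix(0, 5, 10), matrix(1, 5, 10))
  ops <- eoeOperators()
  e1 <- conv2d(C, ops$E1)
  expect_equal(e1[5, 5], -3)  # one row above the step
  LE <- conv2d(C, ops$E1)^2 + conv2d(C, ops$E2)^2 + conv2d(C, ops$E3)^2
  expect_gte(LE[5, 5], 9)
  expect_gt(eoeMap(C)[5, 5], 0)
})

test_that("feature maps match the literal-loop oracles and scale quadratically", {
  for (seed in 1:3) {
    X <- randomImage(16, 16, seed + 50)
    expect_equal(nsmlMap(X), oracleNSML(X), tolerance = 1e-12)
    expect_equal(eoeMap(X), oracleEOE(X), tolerance = 1e-12)
    expect_true(all(nsmlMap(X) >= 0))
    expect_true(all(eoeMap(X) >= 0))
  }
  X <- randomImage(20, 20, 60)
  expect_equal(nsmlMap(3 * X), 9 * nsmlMap(X), tolerance = 1e-9)
  expect_equal(eoeMap(3 * X), 9 * eoeMap(X), tolerance = 1e-9)
})

test_that("feature maps are translation covariant away from borders", {
  X <- randomImage(24, 24, 70)
  sh <- circShift(X, c(3, 2))
  inner <- 8:16
  expect_equal(nsmlMap(sh)[inner + 3, inner + 2], nsmlMap(X)[inner, inner],
               tolerance = 1e-12)
  expect_equal(eoeMap(sh)[inner + 3, inner + 2], eoeMap(X)[inner, inner],
               tolerance = 1e-12)
})
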