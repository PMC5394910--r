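test_that("average gradient matches its formula and homogeneity", {
  expect_equal(averageGradient(matrix(4, 8, 8)), 0)
  expect_equal(averageGradient(matrix(c(0, 0, 1, 1), 2, 2)), sqrt(1 / 2),
               tolerance = 1e-12)
  X <- randomImage(32, 32, 90)
  expect_equal(averageGradient(3 * X), 3 * averageGradient(X), tolerance = 1e-12)
  expect_equal(averageGradient(X), oracleAG(X), tolerance = 1e-9)
  expect_error(averageGradient(matrix(1, 1, 1)), "2x2")
})

test_that("entropy metrics reproduce closed-form cases", {
  expect_equal(shannonEntropy(matrix(0.5, 16, 16)), 0)
  expect_equal(shannonEntropy(matrix(0:255, 16, 16)), 8)
  half <- matrix(c(0, 255), 16, 16)
  expect_equal(shannonEntropy(half), 1)
  A <- randomImage(16, 16, 91)
  expect_equal(jointEntropy(A, A), shannonEntropy(A), tolerance = 1e-12)
  expect_equal(jointEntropy(A, half), jointEntropy(half, A), tolerance = 1e-12)
  # independent binary patterns: 4 equiprobable joint cells -> 2 bits
  rows <- matrix(rep(c(0, 1), each = 8), 16, 16)
  cols <- t(rows)
  expect_equal(jointEntropy(rows, cols), 2)
})

test_that("cross entropy vanishes for identical histograms and matches a 2-bin case", {
  A <- randomImage(16, 16, 92)
  expect_equal(crossEntropy(A, A, A), 0, tolerance = 1e-12)
  # h_A = h_B = (1/2, 1/2), h_F = (1/4, 3/4)
  src <- matrix(c(rep(0, 8), rep(1, 8)), 4, 4)
  fus <- matrix(c(rep(0, 4), rep(1, 12)), 4, 4)
  expect_equal(crossEntropy(src, src, fus),
               0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75),
               tolerance = 1e-12)
  for (seed in 1:5) {
    F <- randomImage(16, 16, 300 + seed)
    expect_gte(crossEntropy(A, randomImage(16, 16, 200 + seed), F), 0)
  }
})

test_that("image quality index is 1 for self-comparison and bounded", {
  X <- randomImage(24, 24, 93)
  expect_equal(iqi(X, X), 1, tolerance = 1e-9)
  expect_equal(iqi(matrix(0.4, 16, 16), matrix(0.4, 16, 16)), 1)
  for (seed in 1:5) {
    Y <- randomImage(24, 24, 400 + seed)
    v <- iqi(X, Y)
    expect_lte(abs(v), 1)
    expect_equal(v, oracleIQI(X, Y), tolerance = 1e-6)
  }
  expect_equal(iqiFusion(X, X, X), 1, tolerance = 1e-9)
})

test_that("edge-dependent quality Q_E has its fixed points and drops the edge term at alpha 0", {
  X <- randomImage(24, 24, 94)
  expect_equal(qe(X, X, X), 1, tolerance = 1e-6)
  Y <- randomImage(24, 24, 95); F <- (X + Y) / 2
  expect_lte(qe(X, Y, F), 1)
  expect_equal(qe(X, Y, F, alpha = 0), oracleQW(X, Y, F), tolerance = 1e-6)
  expect_equal(qe(X, Y, F), oracleQE(X, Y, F), tolerance = 1e-6)
})

test_that("edge preservation Q^AB/F matches its sigmoid ceiling and floors", {
  X <- randomImage(24, 24, 96)
  # perfect preservation: G = 1 and delta-alpha = 0 at every weighted pixel
  ceiling <- (0.9994 / (1 + exp(-15 * 0.5))) * (0.9879 / (1 + exp(-22 * 0.2)))
  expect_equal(qabf(X, X, X), ceiling, tolerance = 1e-9)
  expect_lt(qabf(X, X, matrix(0.5, 24, 24)), 0.05)
  for (seed in 1:5) {
    Y <- randomImage(24, 24, 500 + seed)
    v <- qabf(X, Y, (X + Y) / 2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_equal(qabf(X, Y, (X + Y) / 2), oracleQabf(X, Y, (X + Y) / 2),
               tolerance = 1e-6)
  # printed-sum variant is larger and may exceed 1
  expect_gt(qabf(X, X, X, combine = "sum"), qabf(X, X, X))
})

test_that("the full report reduces to identities on a self-triple", {
  A <- randomImage(32, 32, 97)
  rep <- evaluateFusion(A, A, A)
  v <- metricsValues(rep)
  expect_equal(unname(v["ag"]), averageGradient(A), tolerance = 1e-12)
  expect_equal(unname(v["en"]), shannonEntropy(A), tolerance = 1e-12)
  expect_equal(unname(v["je"]), shannonEntropy(A), tolerance = 1e-12)
  expect_equal(unname(v["ce"]), 0, tolerance = 1e-12)
  expect_equal(unname(v["iqi"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["qe"]), 1, tolerance = 1e-6)
  expect_gt(unname(v["qabf"]), 0.97)
})

test_that("metric ranges hold over random triples", {
  for (seed in 1:40) {
    A <- randomImage(16, 16, 1000 + seed)
    B <- randomImage(16, 16, 2000 + seed)
    F <- 0.5 * A + 0.5 * B + 0.02 * randomImage(16, 16, 3000 + seed)
    v <- metricsValues(evaluateFusion(A, B, F))
    expect_true(all(is.finite(v)))
    expect_gte(unname(v["en"]), 0); expect_lte(unname(v["en"]), 8)
    expect_gte(unname(v["ag"]), 0)
    expect_gte(unname(v["ce"]), 0)
    expect_lte(abs(unname(v["iqi"])), 1)
    expect_gte(unname(v["qabf"]), 0); expect_lte(unname(v["qabf"]), 1)
  }
})

test_that("histogram metrics agree with the loop oracles", {
  A <- randomImage(32, 32, 98); B <- randomImage(32, 32, 99)
  F <- (A + B) / 2
  expect_equal(shannonEntropy(F), oracleEN(F), tolerance = 1e-12)
  expect_equal(jointEntropy(F, A), oracleJE(F, A), tolerance = 1e-12)
  expect_equal(crossEntropy(A, B, F), oracleCE(A, B, F), tolerance = 1e-12)
})
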