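test_that("parameter validation catches ill-formed PCNN constants", {
  expect_error(pcnnParams(alphaL = -1), "positive")
  expect_error(pcnnParams(nIter = 0), "nIter")
  k <- defaultLinkKernel(); k[2, 2] <- 1
  expect_error(pcnnParams(linkKernel = k), "center")
  expect_error(pcnnParams(linkKernel = -defaultLinkKernel()), "non-negative")
})

test_that("single neuron fires at the closed-form iteration", {
  # theta decays as exp(-0.2 n) from 1; a lone neuron (beta = 0) fires the
  # first time exp(-0.2 n) <= S, then its threshold jumps by ~20 and cannot
  # decay back within the run
  p10 <- pcnnParams(nIter = 10)
  firstFire <- function(S) {
    for (n in 1:10)
      if (runPCNN(matrix(S, 1, 1), matrix(0, 1, 1), pcnnParams(nIter = n)) > 0)
        return(n)
    Inf
  }
  expect_identical(firstFire(0.5), 4L)
  expect_identical(firstFire(0.9), 1L)
  expect_identical(as.integer(runPCNN(matrix(0.5, 1, 1), matrix(0, 1, 1), p10)), 1L)
  # zero input never reaches the strictly positive threshold
  expect_true(all(runPCNN(matrix(0, 4, 4), matrix(0, 4, 4), p10) == 0))
})

test_that("vectorized PCNN equals the scalar recursion exactly", {
  p <- pcnnParams(nIter = 25L)
  for (seed in 1:3) {
    S <- randomImage(16, 16, seed)
    set.seed(seed + 100)
    beta <- matrix(runif(256, 0, 2), 16, 16)
    expect_identical(unname(runPCNN(S, beta, p)), unname(oraclePCNN(S, beta, p)))
  }
})

test_that("firing counts stay in range, are deterministic and monotone without linking", {
  p <- pcnnParams(nIter = 40L)
  S1 <- randomImage(12, 12, 21)
  c1 <- runPCNN(S1, matrix(0, 12, 12), p)
  expect_true(all(c1 >= 0 & c1 <= 40))
  expect_identical(c1, runPCNN(S1, matrix(0, 12, 12), p))
  # raising the stimulus can only raise the firing count when beta == 0
  S2 <- pmax(S1 - 0.2, 0)
  c2 <- runPCNN(S2, matrix(0, 12, 12), p)
  expect_true(all(c1 >= c2))
  expect_identical(unname(c2), unname(oraclePCNN(S2, matrix(0, 12, 12), p)))
})

test_that("out-of-range stimulus is rejected", {
  expect_error(runPCNN(matrix(1.5, 2, 2), matrix(0, 2, 2)), "\\[0,1\\]")
  expect_error(runPCNN(matrix(-0.2, 2, 2), matrix(0, 2, 2)), "\\[0,1\\]")
  expect_error(runPCNN(matrix(0.5, 2, 2), matrix(-1, 2, 2)), "non-negative")
})

test_that("linking-strength map matches the region-average-gradient formula", {
  # constant image: all differences vanish
  expect_equal(max(abs(linkingStrengthMap(matrix(3, 8, 8)))), 0)
  # horizontal ramp C(i,j) = j: g1 = 0, g2 = 1 away from the last column
  C <- matrix(rep(1:10, each = 10), 10, 10, byrow = TRUE)
  b <- linkingStrengthMap(C)
  expect_equal(b[5, 5], sqrt(1 / 2), tolerance = 1e-12)
  expect_true(all(b >= 0))
  # literal-loop oracle on random input
  X <- randomImage(16, 16, 33)
  expect_equal(linkingStrengthMap(X), oracleBeta(X), tolerance = 1e-12)
  expect_error(linkingStrengthMap(1:5), "matrix")
})
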