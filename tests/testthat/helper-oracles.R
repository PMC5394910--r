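# Literal, loop-based reference implementations of the printed formulas.
# Deliberately naive: index folding and double loops, no shared code with
# the package internals, so they can serve as independent oracles.

# half-sample symmetric reflection of an index into 1..n
.oFold <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

.oAt <- function(C, i, j) C[.oFold(i, nrow(C)), .oFold(j, ncol(C))]

# modified Laplacian + weighted window sum (NSML)
oracleNSML <- function(C, W = matrix(c(1, 2, 1, 2, 3, 2, 1, 2, 1), 3) / 15) {
  m <- nrow(C); n <- ncol(C)
  M <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    M[i, j] <- abs(2 * C[i, j] - .oAt(C, i - 1, j) - .oAt(C, i + 1, j)) +
               abs(2 * C[i, j] - .oAt(C, i, j - 1) - .oAt(C, i, j + 1))
  }
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    s <- 0
    for (a in -1:1) for (b in -1:1)
      s <- s + W[a + 2, b + 2] * .oAt(M, i + a, j + b)^2
    out[i, j] <- s
  }
  out
}

# energy of edge from the three directional operators
oracleEOE <- function(C, W = matrix(c(1, 2, 1, 2, 3, 2, 1, 2, 1), 3) / 15) {
  E1 <- matrix(c(-1, -1, -1, 2, 2, 2, -1, -1, -1), 3, byrow = TRUE)
  E2 <- matrix(c(-1, 2, -1, -1, 2, -1, -1, 2, -1), 3, byrow = TRUE)
  E3 <- matrix(c(-1, 0, -1, 0, 4, 0, -1, 0, -1), 3, byrow = TRUE)
  m <- nrow(C); n <- ncol(C)
  conv1 <- function(E, i, j) {
    s <- 0
    for (a in -1:1) for (b in -1:1)
      s <- s + E[a + 2, b + 2] * .oAt(C, i + a, j + b)
    s
  }
  LE <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n)
    LE[i, j] <- conv1(E1, i, j)^2 + conv1(E2, i, j)^2 + conv1(E3, i, j)^2
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    s <- 0
    for (a in -1:1) for (b in -1:1)
      s <- s + W[a + 2, b + 2] * .oAt(LE, i + a, j + b)
    out[i, j] <- s
  }
  out
}

# template-weighted region energy
oracleRegionEnergy <- function(C, w) {
  m <- nrow(C); n <- ncol(C)
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    s <- 0
    for (a in -1:1) for (b in -1:1)
      s <- s + w[a + 2, b + 2] * .oAt(C, i + a, j + b)^2
    out[i, j] <- s
  }
  out
}

# region average gradient (adaptive linking strength)
oracleBeta <- function(C) {
  m <- nrow(C); n <- ncol(C)
  g <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    g1 <- if (i < m) (C[i, j] - C[i + 1, j])^2 else 0
    g2 <- if (j < n) (C[i, j] - C[i, j + 1])^2 else 0
    g[i, j] <- sqrt((g1 + g2) / 2)
  }
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    s <- 0
    for (a in -1:1) for (b in -1:1)
      s <- s + .oAt(g, i + a, j + b)
    out[i, j] <- s / 9
  }
  out
}

# scalar per-pixel, per-iteration recursion of the simplified PCNN
oraclePCNN <- function(S, beta, p) {
  m <- nrow(S); n <- ncol(S)
  W <- p@linkKernel
  L <- matrix(0, m, n); Y <- matrix(0L, m, n)
  theta <- matrix(p@thetaInit, m, n)
  counts <- matrix(0L, m, n)
  for (it in seq_len(p@nIter)) {
    Yprev <- Y
    for (i in 1:m) for (j in 1:n) {
      link <- 0
      for (a in -1:1) for (b in -1:1) {
        ii <- i + a; jj <- j + b
        if (ii >= 1 && ii <= m && jj >= 1 && jj <= n)
          link <- link + W[a + 2, b + 2] * Yprev[ii, jj]
      }
      L[i, j] <- exp(-p@alphaL) * L[i, j] + p@VL * link
      U <- S[i, j] * (1 + beta[i, j] * L[i, j])
      thdec <- exp(-p@alphaTheta) * theta[i, j]
      y <- as.integer(U >= thdec)
      theta[i, j] <- thdec + p@Vtheta * y
      Y[i, j] <- y
      counts[i, j] <- counts[i, j] + y
    }
  }
  counts
}

## ---- metric oracles -----------------------------------------------------

oracleQuantize <- function(C, L = 256L) {
  rng <- range(C)
  if (rng[2] == rng[1]) return(array(0L, dim(C)))
  array(as.integer(round((C - rng[1]) / (rng[2] - rng[1]) * (L - 1))), dim(C))
}

oracleAG <- function(C) {
  m <- nrow(C); n <- ncol(C)
  s <- 0
  for (i in 1:(m - 1)) for (j in 1:(n - 1))
    s <- s + sqrt(((C[i, j] - C[i + 1, j])^2 + (C[i, j] - C[i, j + 1])^2) / 2)
  s / ((m - 1) * (n - 1))
}

oracleEN <- function(C, L = 256L) {
  q <- oracleQuantize(C, L)
  s <- 0
  for (lev in 0:(L - 1)) {
    p <- sum(q == lev) / length(q)
    if (p > 0) s <- s - p * log2(p)
  }
  s
}

oracleJE <- function(F, A, L = 256L) {
  qf <- oracleQuantize(F, L); qa <- oracleQuantize(A, L)
  key <- paste(qf, qa)
  p <- table(key) / length(qf)
  -sum(p * log2(p))
}

oracleCE <- function(A, B, F, L = 256L) {
  h <- function(C) {
    q <- oracleQuantize(C, L)
    vapply(0:(L - 1), function(lev) sum(q == lev) / length(q), numeric(1))
  }
  hf <- pmax(h(F), 1e-12)
  rel <- function(p) {
    s <- 0
    for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / hf[i])
    s
  }
  (rel(h(A)) + rel(h(B))) / 2
}

# windowed Wang-Bovik index with population moments (nondegenerate windows)
oracleIQIMap <- function(x, y, w = 8L) {
  m <- nrow(x) - w + 1L; n <- ncol(x) - w + 1L
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    xa <- as.vector(x[i:(i + w - 1), j:(j + w - 1)])
    ya <- as.vector(y[i:(i + w - 1), j:(j + w - 1)])
    mx <- mean(xa); my <- mean(ya)
    vx <- mean(xa^2) - mx^2; vy <- mean(ya^2) - my^2
    cxy <- mean(xa * ya) - mx * my
    out[i, j] <- (4 * cxy * mx * my) / ((vx + vy) * (mx^2 + my^2))
  }
  out
}

oracleIQI <- function(x, y, w = 8L) mean(oracleIQIMap(x, y, w))

oracleQW <- function(A, B, F, w = 8L) {
  qa <- oracleIQIMap(A, F, w); qb <- oracleIQIMap(B, F, w)
  m <- nrow(qa); n <- ncol(qa)
  sal <- function(X, i, j) {
    xa <- as.vector(X[i:(i + w - 1), j:(j + w - 1)])
    mean(xa^2) - mean(xa)^2
  }
  cw <- matrix(0, m, n); lam <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    sa <- sal(A, i, j); sb <- sal(B, i, j)
    cw[i, j] <- max(sa, sb)
    lam[i, j] <- if (sa + sb > 0) sa / (sa + sb) else 0.5
  }
  cw <- cw / sum(cw)
  sum(cw * (lam * qa + (1 - lam) * qb))
}

# Sobel gradients with symmetric padding, literal loops
oracleSobel <- function(x) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  m <- nrow(x); n <- ncol(x)
  gx <- matrix(0, m, n); gy <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    ax <- 0; ay <- 0
    for (a in -1:1) for (b in -1:1) {
      v <- .oAt(x, i + a, j + b)
      ax <- ax + sx[a + 2, b + 2] * v
      ay <- ay + t(sx)[a + 2, b + 2] * v
    }
    gx[i, j] <- ax; gy[i, j] <- ay
  }
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

oracleQE <- function(A, B, F, alpha = 1, w = 8L) {
  q1 <- oracleQW(A, B, F, w)
  q2 <- oracleQW(oracleSobel(A)$mag, oracleSobel(B)$mag, oracleSobel(F)$mag, w)
  q1 * q2^alpha
}

oracleQabf <- function(A, B, F) {
  wrapAngle <- function(g) {
    a <- atan2(g$gy, g$gx)
    a[a > pi / 2] <- a[a > pi / 2] - pi
    a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
    a
  }
  sA <- oracleSobel(A); sB <- oracleSobel(B); sF <- oracleSobel(F)
  aA <- wrapAngle(sA); aB <- wrapAngle(sB); aF <- wrapAngle(sF)
  pres <- function(g1, a1) {
    m <- nrow(A); n <- ncol(A)
    Q <- matrix(0, m, n)
    for (i in 1:m) for (j in 1:n) {
      gX <- g1$mag[i, j]; gF <- sF$mag[i, j]
      G <- if (max(gX, gF) > 0) min(gX, gF) / max(gX, gF) else 1
      Aor <- 1 - abs(a1[i, j] - aF[i, j]) / (pi / 2)
      Q[i, j] <- (0.9994 / (1 + exp(-15 * (G - 0.5)))) *
                 (0.9879 / (1 + exp(-22 * (Aor - 0.8))))
    }
    Q
  }
  qaf <- pres(sA, aA); qbf <- pres(sB, aB)
  sum(qaf * sA$mag + qbf * sB$mag) / sum(sA$mag + sB$mag)
}

# seeded random test image in [0,1]
randomImage <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}
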