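# Minimal separable LeGall 5/3 (biorthogonal 2.2) wavelet transform via
# lifting with periodic extension; exact reconstruction for even-sized
# inputs. Backs the maximum-absolute-value DWT fusion baseline.

# one lifting analysis step along rows of a matrix (even row count)
.lift53AnalysisRows <- function(x) {
  m <- nrow(x)
  E <- x[seq(1L, m, 2L), , drop = FALSE]
  O <- x[seq(2L, m, 2L), , drop = FALSE]
  h <- m / 2L
  Enext <- E[c(seq_len(h)[-1L], 1L), , drop = FALSE]
  D <- O - (E + Enext) / 2
  Dprev <- D[c(h, seq_len(h - 1L)), , drop = FALSE]
  S <- E + (Dprev + D) / 4
  list(s = S, d = D)
}

.lift53SynthesisRows <- function(S, D) {
  h <- nrow(S)
  Dprev <- D[c(h, seq_len(h - 1L)), , drop = FALSE]
  E <- S - (Dprev + D) / 4
  Enext <- E[c(seq_len(h)[-1L], 1L), , drop = FALSE]
  O <- D + (E + Enext) / 2
  x <- matrix(0, 2L * h, ncol(S))
  x[seq(1L, 2L * h, 2L), ] <- E
  x[seq(2L, 2L * h, 2L), ] <- O
  x
}

# one 2-D level: rows then columns; returns LL, LH, HL, HH (half-sized)
.dwt2Level <- function(x) {
  r <- .lift53AnalysisRows(x)
  cl <- .lift53AnalysisRows(t(r$s))
  ch <- .lift53AnalysisRows(t(r$d))
  list(ll = t(cl$s), lh = t(cl$d), hl = t(ch$s), hh = t(ch$d))
}

.idwt2Level <- function(b) {
  s <- t(.lift53SynthesisRows(t(b$ll), t(b$lh)))
  d <- t(.lift53SynthesisRows(t(b$hl), t(b$hh)))
  .lift53SynthesisRows(s, d)
}

.dwt2 <- function(x, levels) {
  if (any(dim(x) %% 2L^levels != 0L))
    stop(sprintf("image dimensions must be divisible by 2^levels = %d",
                 2L^levels), call. = FALSE)
  detail <- vector("list", levels)
  ll <- x
  for (k in seq_len(levels)) {
    b <- .dwt2Level(ll)
    detail[[k]] <- b[c("lh", "hl", "hh")]
    ll <- b$ll
  }
  list(ll = ll, detail = detail)
}

.idwt2 <- function(w) {
  ll <- w$ll
  for (k in rev(seq_along(w$detail)))
    ll <- .idwt2Level(c(list(ll = ll), w$detail[[k]]))
  ll
}
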