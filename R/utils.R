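# Small numeric utilities shared across modules.

# Lawson-Hanson non-negative least squares: min ||A x - b||, x >= 0.
# Needed for the PARAFAC spectra/concentration modes; problems here are tiny
# (a handful of columns), so a plain R active-set implementation suffices.
.nnls <- function(A, b) {
  n <- ncol(A)
  P <- rep(FALSE, n)
  x <- numeric(n)
  tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  w <- drop(crossprod(A, b))
  iter <- 0L
  while (any(!P) && max(w[!P]) > tol && iter < 3L * n + 30L) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- stats::lm.fit(A[, P, drop = FALSE], b)$coefficients
      s[is.na(s)] <- 0
      if (min(s[P]) > 0) { x <- s; break }
      Q <- P & (s <= 0)
      alpha <- min(x[Q] / (x[Q] - s[Q]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (s - x)
      P[P & (x <= tol)] <- FALSE
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

# trapezoidal integral on a (possibly non-uniform) grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# cosine similarity of two vectors
.cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# central-interval quantiles of Monte Carlo draws (matrix: reps x params)
.mc_quantiles <- function(draws, level = 0.683) {
  a <- (1 - level) / 2
  q <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  rownames(q) <- c("lower", "upper")
  q
}
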