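# independent reference implementations used to cross-check the package

# Cox-de Boor recursion for one B-spline basis function B_{i,k}(x) on a
# knot vector (0-based degree k); direct textbook recursion, no vectorised
# shortcuts shared with the implementation under test
coxdeboor_basis <- function(x, knots, i, k) {
  if (k == 0) {
    # half-open support, closed at the right end of the last interval
    last <- max(which(knots < max(knots)))
    if (i == last) {
      return(as.numeric(x >= knots[i] & x <= knots[i + 1]))
    }
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * coxdeboor_basis(x, knots, i, k - 1) else 0
  t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
    coxdeboor_basis(x, knots, i + 1, k - 1) else 0
  t1 + t2
}

# full basis matrix via the recursion
coxdeboor_matrix <- function(x, domain, n_knots, degree) {
  interior <- seq(domain[1], domain[2],
                  length.out = n_knots + 2)[-c(1, n_knots + 2)]
  knots <- c(rep(domain[1], degree + 1), interior, rep(domain[2], degree + 1))
  n_basis <- n_knots + degree + 1
  sapply(seq_len(n_basis), function(i) coxdeboor_basis(x, knots, i, degree))
}

# textbook between/within-chain potential scale reduction factor
psrf_brute <- function(mat) {
  m <- ncol(mat); n <- nrow(mat)
  means <- numeric(m); vars <- numeric(m)
  for (j in seq_len(m)) {
    means[j] <- sum(mat[, j]) / n
    vars[j] <- sum((mat[, j] - means[j])^2) / (n - 1)
  }
  grand <- sum(means) / m
  B <- n / (m - 1) * sum((means - grand)^2)
  W <- sum(vars) / m
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ordinary least squares on (log raw, log gravimetric) via the closed form
power_ols_oracle <- function(raw, grav) {
  lx <- log(raw); lg <- log(grav)
  b <- sum((lx - mean(lx)) * (lg - mean(lg))) / sum((lx - mean(lx))^2)
  a <- exp(mean(lg) - b * mean(lx))
  c(a = a, b = b)
}
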