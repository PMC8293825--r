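# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: proximal-gradient (ISTA) instead of coordinate
# descent, direction enumeration instead of the rotating-plane sweep, and
# numerical quadrature instead of closed-form Gaussian moments.

# Proximal-subgradient (ISTA) oracle for the penalized objective on the
# standardized scale. Returns the objective value reached.
ista_objective <- function(X, y, spec, lambda, iters = 20000) {
  n <- nrow(X)
  center <- colMeans(X)
  scl <- sqrt(colMeans(X^2) - center^2)
  scl[scl == 0] <- 1
  Xs <- (X - rep(center, each = n)) / rep(scl, each = n)
  M <- cbind(1, Xs)
  curv <- switch(spec$family, squared = 1, huber = 1,
                 quantile = 1 / spec$gamma)
  L <- curv * max(eigen(crossprod(M) / n, symmetric = TRUE,
                        only.values = TRUE)$values)
  theta <- numeric(ncol(M))
  psi_fn <- function(e) snplasso:::solver_psi(e, spec)
  rho_fn <- function(e) snplasso:::solver_rho(e, spec)
  for (it in seq_len(iters)) {
    e <- y - as.numeric(M %*% theta)
    grad <- -as.numeric(crossprod(M, psi_fn(e))) / n
    theta <- theta - grad / L
    b <- theta[-1]
    theta[-1] <- sign(b) * pmax(abs(b) - lambda / L, 0)
  }
  e <- y - as.numeric(M %*% theta)
  mean(rho_fn(e)) + lambda * sum(abs(theta[-1]))
}

# Brute-force halfspace depth: minimum closed-halfspace count over a fine
# Fibonacci direction grid enriched with every plane through the query
# point and two data points, each perturbed by small tilts along the two
# spanning directions (the configurations where the minimum is attained).
oracle_depth <- function(P, K = 20000) {
  n <- nrow(P)
  i <- seq_len(K) - 0.5
  phi <- acos(1 - 2 * i / K)
  th <- pi * (1 + sqrt(5)) * i
  Ug <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  out <- integer(n)
  for (q in seq_len(n)) {
    D <- sweep(P, 2, P[q, ])
    nr <- sqrt(rowSums(D^2))
    best <- min(colSums((D %*% t(Ug)) >= -1e-12))
    Dn <- D[nr > 1e-12, , drop = FALSE] / nr[nr > 1e-12]
    m <- nrow(Dn)
    for (j in seq_len(m - 1)) {
      for (k in seq.int(j + 1, m)) {
        u0 <- c(Dn[j, 2] * Dn[k, 3] - Dn[j, 3] * Dn[k, 2],
                Dn[j, 3] * Dn[k, 1] - Dn[j, 1] * Dn[k, 3],
                Dn[j, 1] * Dn[k, 2] - Dn[j, 2] * Dn[k, 1])
        nu <- sqrt(sum(u0^2))
        if (nu < 1e-12) next
        u0 <- u0 / nu
        for (s1 in c(-1, 1)) {
          for (d1 in c(0, 1e-6, -1e-6)) {
            for (d2 in c(0, 1e-6, -1e-6)) {
              u <- s1 * u0 + d1 * Dn[j, ] + d2 * Dn[k, ]
              best <- min(best, sum(D %*% u >= -1e-12))
            }
          }
        }
      }
    }
    out[q] <- best
  }
  out
}

# Gaussian ARE of the Huber M-estimator by numerical quadrature,
# integrating each smooth piece separately
quadrature_efficiency <- function(cc) {
  num <- stats::integrate(dnorm, -cc, cc, rel.tol = 1e-10)$value^2
  den <- stats::integrate(function(z) z^2 * dnorm(z), -cc, cc,
                          rel.tol = 1e-10)$value +
    2 * cc^2 * stats::integrate(dnorm, cc, Inf, rel.tol = 1e-10)$value
  num / den
}
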