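#' Eigenstrat-style genotype principal component analysis
#'
#' Centers each SNP column by twice its estimated allele frequency and
#' scales by the binomial standard deviation
#' \eqn{\sqrt{2\hat p(1-\hat p)}} before the eigendecomposition, with the
#' shrunk frequency estimate \eqn{\hat p = (1 + \sum_i g_{ij}) / (2 + 2n)}
#' that avoids zero scales at rare alleles. Monomorphic SNPs are dropped
#' with a warning. Scores are computed from the eigendecomposition of the
#' individual-by-individual cross-product matrix (cheaper than a full SVD
#' when p > n) and have zero column means.
#'
#' @param G n x p dosage matrix (values in \[0, 2\]).
#' @param k number of components (default 3, the trivariate depth input).
#' @return object of class `"pca_scores"`: `scores` (n x k), `eigenvalues`
#'   (decreasing), `center`, `scale`, `dropped` (monomorphic SNP names).
#' @export
genotype_pca <- function(G, k = 3) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (n < 4L) stop("need at least 4 individuals")
  if (ncol(G) < k) stop("need at least k SNP columns")
  cm <- colMeans(G)
  mono <- (colMeans(G * G) - cm^2) <= 0
  dropped <- colnames(G)[mono]
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNPs dropped before PCA")
    G <- G[, !mono, drop = FALSE]
    if (ncol(G) < k) stop("fewer than k polymorphic SNPs")
  }
  phat <- (1 + colSums(G)) / (2 + 2 * n)
  center <- 2 * phat
  scale <- sqrt(2 * phat * (1 - phat))
  Z <- (G - rep(center, each = n)) / rep(scale, each = n)
  Z <- Z - rep(colMeans(Z), each = n) # exact zero column means for scores
  K <- tcrossprod(Z)
  ev <- eigen(K, symmetric = TRUE)
  vals <- pmax(ev$values[seq_len(k)], 0)
  scores <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals), k)
  # fix the sign convention so scores are reproducible across BLAS builds
  for (j in seq_len(k)) {
    i1 <- which.max(abs(scores[, j]))
    if (scores[i1, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, eigenvalues = vals / max(1, n - 1),
                 center = center, scale = scale, dropped = dropped),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$scores), "individuals,",
      ncol(x$scores), "components; eigenvalues:",
      paste(signif(x$eigenvalues, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Trivariate halfspace (Tukey) depth
#'
#' The depth of an observation relative to the cloud is the smallest
#' number of observations lying in any closed half-space determined by a
#' hyperplane through that observation; the count includes the
#' observation itself, so depths lie in \[1, n\]. Depth 1 marks extreme
#' ("divergent") points, high depth central ("average") points.
#'
#' The exact mode sweeps, for every query point, the pencil of planes
#' through each line joining it to another data point, which attains the
#' minimum over all halfspaces (an \eqn{O(n^2 \log n)}-per-point exact
#' algorithm). The projection mode minimizes the one-dimensional count
#' over `n_directions` seeded random unit directions; it never
#' underestimates the exact depth and converges to it as the number of
#' directions grows.
#'
#' @param scores n x 3 matrix (or a [genotype_pca()] result).
#' @param method `"exact"` (default for n <= 600) or `"projection"`.
#' @param n_directions directions for the projection mode.
#' @param seed seed for the projection directions.
#' @return object of class `"depth_result"`: integer `depth` (length n),
#'   `method`, and `n_directions` for the projection mode.
#' @export
halfspace_depth <- function(scores, method = NULL, n_directions = 5000,
                            seed = 1L) {
  if (inherits(scores, "pca_scores")) scores <- scores$scores
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 4L) stop("need at least 4 points")
  if (ncol(scores) != 3L) stop("trivariate depth needs exactly 3 columns")
  if (is.null(method)) method <- if (n <= 600) "exact" else "projection"
  method <- match.arg(method, c("exact", "projection"))
  if (method == "exact") {
    dp <- halfspace_depth_exact_cpp(scores)
    n_directions <- NA_integer_
  } else {
    U <- withr::with_seed(as.integer(seed), {
      M <- matrix(rnorm(n_directions * 3), ncol = 3)
      M / sqrt(rowSums(M^2))
    })
    dp <- halfspace_depth_projection_cpp(scores, U)
  }
  structure(list(depth = as.integer(dp), method = method,
                 n_directions = n_directions),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  cat("Halfspace depth (", x$method, "): n = ", length(x$depth),
      ", range ", min(x$depth), "-", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Leverage-extreme individuals
#'
#' Identifies the individual with the highest depth (the "average
#' genotype", a low-leverage observation) and the one with the lowest
#' depth (the "divergent genotype", a high-leverage observation). Ties are
#' broken toward the smallest index.
#'
#' @param depth_result a [halfspace_depth()] result (or integer depths).
#' @param n_each return this many individuals per extreme (default 1);
#'   used for multi-outlier scenarios (e.g. 5/500 = 1%).
#' @return list with integer vectors `low_leverage` (deepest) and
#'   `high_leverage` (shallowest).
#' @export
leverage_extremes <- function(depth_result, n_each = 1L) {
  depth <- if (inherits(depth_result, "depth_result"))
    depth_result$depth else as.integer(depth_result)
  stopifnot(n_each >= 1L, n_each <= length(depth))
  asc <- order(depth, seq_along(depth))   # shallow first, ties by index
  desc <- order(-depth, seq_along(depth)) # deep first, ties by index
  list(low_leverage = desc[seq_len(n_each)],
       high_leverage = asc[seq_len(n_each)])
}
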