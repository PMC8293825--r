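tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

test_that("analytic depth cases are exact", {
  expect_equal(halfspace_depth(tetra)$depth, rep(1L, 4))
  tc <- rbind(tetra, c(0, 0, 0))
  d <- halfspace_depth(tc)$depth
  expect_equal(d[1:4], rep(1L, 4))
  expect_gt(d[5], 1) # the centroid is interior
  expect_equal(d[5], 2L) # one vertex always stays on the positive side
})

test_that("exact depth equals the brute-force direction oracle", {
  for (s in 1:20) {
    P <- withr::with_seed(500 + s, matrix(rnorm(90), 30, 3))
    expect_equal(halfspace_depth(P)$depth, oracle_depth(P),
                 label = paste("seed", s))
  }
})

test_that("depth is invariant under rotation and translation", {
  P <- withr::with_seed(31, matrix(rnorm(120), 40, 3))
  d0 <- halfspace_depth(P)$depth
  Q <- withr::with_seed(32, qr.Q(qr(matrix(rnorm(9), 3, 3))))
  expect_equal(halfspace_depth(P %*% Q)$depth, d0)
  expect_equal(halfspace_depth(sweep(P, 2, c(10, -4, 2), "+"))$depth, d0)
})

test_that("permutation, duplication and outliers behave as sets", {
  P <- withr::with_seed(33, matrix(rnorm(90), 30, 3))
  d0 <- halfspace_depth(P)$depth
  perm <- sample(30)
  expect_equal(halfspace_depth(P[perm, ])$depth, d0[perm])
  # duplicated individual: identical rows get identical depth
  P2 <- rbind(P, P[7, ])
  d2 <- halfspace_depth(P2)$depth
  expect_equal(d2[31], d2[7])
  # a far outlier has depth 1 and raises nobody by more than 1
  P3 <- rbind(P, c(100, 100, 100))
  d3 <- halfspace_depth(P3)$depth
  expect_equal(d3[31], 1L)
  expect_true(all(d3[1:30] - d0 <= 1))
  expect_true(all(d3[1:30] - d0 >= 0))
})

test_that("degenerate coplanar and collinear clouds are handled", {
  # coplanar: matches the direction oracle restricted to the same cloud
  P <- cbind(withr::with_seed(35, matrix(rnorm(40), 20, 2)), 0)
  expect_equal(halfspace_depth(P)$depth, oracle_depth(P))
  # collinear: depth is the one-dimensional halfspace count
  t <- seq(-2, 2, length.out = 9)
  L <- cbind(t, 2 * t, -t)
  d <- halfspace_depth(L)$depth
  expect_equal(d, pmin(rank(t), rank(-t)))
})

test_that("projection mode bounds and approaches the exact depth", {
  P <- withr::with_seed(36, matrix(rnorm(150), 50, 3))
  dex <- halfspace_depth(P)$depth
  d1 <- halfspace_depth(P, method = "projection", n_directions = 50,
                        seed = 2)$depth
  d2 <- halfspace_depth(P, method = "projection", n_directions = 20000,
                        seed = 2)$depth
  expect_true(all(d1 >= dex))
  expect_true(all(d2 >= dex))
  expect_lte(mean(d2 - dex), mean(d1 - dex))
  expect_gt(mean(d2 == dex), 0.9)
})

test_that("certified extremes match the full exact computation", {
  for (s in 1:6) {
    P <- withr::with_seed(600 + s, matrix(rnorm(3 * 120), 120, 3))
    full <- leverage_extremes(halfspace_depth(P), n_each = 3)
    fast <- leverage_extremes_fast(P, n_each = 3)
    expect_identical(fast$low_leverage, full$low_leverage)
    expect_identical(fast$high_leverage, full$high_leverage)
  }
})

test_that("leverage extremes follow the depth and tie rules", {
  ext <- leverage_extremes(c(1L, 5L, 2L))
  expect_equal(ext$low_leverage, 2L)  # argmax depth: average genotype
  expect_equal(ext$high_leverage, 1L) # argmin depth: divergent genotype
  tie <- leverage_extremes(rep(3L, 6))
  expect_equal(tie$low_leverage, 1L)
  expect_equal(tie$high_leverage, 1L)
  # tetrahedron + centroid: the centroid is the low-leverage pick
  tc <- rbind(tetra, c(0, 0, 0))
  expect_equal(leverage_extremes(halfspace_depth(tc))$low_leverage, 5L)
})

test_that("genotype PCA follows the eigenstrat convention", {
  spec <- architecture_spec(snp_effect("c1", 0.3, 0.1), n_null = 120,
                            null_maf_range = c(0.1, 0.5),
                            structure = list(n_subpops = 2, fst = 0.1,
                                             mass = c(0.5, 0.5)),
                            n = 150, seed = 17)
  pool <- simulate_pool(spec)
  pca <- genotype_pca(pool$G, k = 3)
  # separation of the two Balding-Nichols subpopulations along PC1
  s1 <- pca$scores[pool$subpop == 1, 1]
  s2 <- pca$scores[pool$subpop == 2, 1]
  pooled_sd <- sqrt((var(s1) + var(s2)) / 2)
  expect_gt(abs(mean(s1) - mean(s2)), 3 * pooled_sd)
  # scores have zero column means; eigenvalues decrease
  expect_equal(colMeans(pca$scores), c(PC1 = 0, PC2 = 0, PC3 = 0),
               tolerance = 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  # the shrunk allele-frequency centering/scaling is used
  phat <- (1 + colSums(pool$G)) / (2 + 2 * nrow(pool$G))
  expect_equal(unname(pca$center), unname(2 * phat))
  expect_equal(unname(pca$scale), unname(sqrt(2 * phat * (1 - phat))))

  # permuting individuals permutes score rows identically (up to the
  # deterministic sign convention, which is permutation-invariant)
  perm <- withr::with_seed(3, sample(nrow(pool$G)))
  pca_p <- genotype_pca(pool$G[perm, ], k = 3)
  expect_equal(abs(pca_p$scores), abs(pca$scores[perm, ]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # monomorphic SNPs dropped with a warning
  G2 <- cbind(pool$G, mono = rep(2, nrow(pool$G)))
  expect_warning(genotype_pca(G2), "monomorphic")
  expect_error(genotype_pca(pool$G[1:3, ]), "at least 4")
})
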