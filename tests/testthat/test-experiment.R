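test_that("a tiny experiment populates every summary field sanely", {
  pool <- tiny_pool()
  res <- run_experiment(pool, tiny_config())
  expect_s3_class(res, "experiment_summary")
  for (nm in c("squared", "huber")) {
    pl <- res$per_loss[[nm]]
    expect_length(pl$lambda_opt, 2)
    expect_true(all(pl$fpr_iterations >= 0 & pl$fpr_iterations <= 1))
    expect_gte(pl$mean_jaccard, 0)
    expect_lte(pl$mean_jaccard, 1)
    for (s in pl$snps) {
      expect_gte(s$tpr, 0)
      expect_lte(s$tpr, 1)
    }
  }
  tab <- experiment_table(res)
  expect_equal(nrow(tab), 4) # 2 iterations x 2 losses
  expect_true(all(c("loss", "lambda_opt", "n_selected", "fpr") %in%
                    names(tab)))
})

test_that("iterations are deterministic given the iteration seed", {
  pool <- tiny_pool()
  cfg <- tiny_config(outlier_value = 5, leverage_target = "low")
  r1 <- run_iteration(pool, cfg, 777L)
  r2 <- run_iteration(pool, cfg, 777L)
  expect_identical(r1$subsample, r2$subsample)
  expect_identical(r1$targets, r2$targets)
  expect_equal(r1$per_loss$huber$lambda_opt, r2$per_loss$huber$lambda_opt)
  expect_equal(r1$per_loss$huber$coefficients,
               r2$per_loss$huber$coefficients)
})

test_that("injection hits the depth-extreme individual of the subsample", {
  pool <- tiny_pool()
  cfg <- tiny_config(outlier_value = 5, leverage_target = "low")
  prep <- snplasso:::prepare_iteration(pool, cfg, 123L, need_depth = 1L)
  inj <- snplasso:::inject_for_scenario(prep, cfg)
  # exactly one modified entry, equal to the injected value
  expect_equal(sum(inj$y != prep$y), 1)
  expect_equal(unname(inj$y[inj$targets]), 5)
  # the target is the deepest point of the subsample's trivariate PCA
  pca <- suppressWarnings(genotype_pca(prep$G, k = 3))
  full <- leverage_extremes(halfspace_depth(pca$scores))
  expect_equal(inj$targets, full$low_leverage)

  # scenario "none": phenotype passed through unchanged
  cfg0 <- tiny_config()
  inj0 <- snplasso:::inject_for_scenario(prep, cfg0)
  expect_identical(inj0$y, prep$y)
  expect_length(inj0$targets, 0)
})

test_that("paired scenarios share subsamples and fold assignments", {
  pool <- tiny_pool()
  configs <- list(none = tiny_config(),
                  inj = tiny_config(outlier_value = -5,
                                    leverage_target = "high"))
  res <- run_scenarios(pool, configs)
  expect_s3_class(res$none, "experiment_summary")
  expect_s3_class(res$inj, "experiment_summary")
  # a lone run of the injected scenario reproduces the paired one
  solo <- run_experiment(pool, configs$inj)
  expect_equal(solo$per_loss$huber$lambda_opt,
               res$inj$per_loss$huber$lambda_opt)
  expect_identical(solo$per_loss$huber$selected,
                   res$inj$per_loss$huber$selected)
  # mismatched shared fields are rejected
  bad <- tiny_config(seed = 99L)
  expect_error(run_scenarios(pool, list(a = tiny_config(), b = bad)),
               "share")
})

test_that("prediction accuracy CV predicts everyone exactly once", {
  pool <- tiny_pool()
  idx <- withr::with_seed(2, sample(nrow(pool$G), 100))
  pr <- regression_problem(pool$G[idx, ], pool$y[idx])
  acc <- prediction_accuracy_cv(pr, loss_spec("huber"), folds = 5,
                                seed = 11, inner_k = 5, nlambda = 30,
                                tol = 1e-3)
  expect_false(anyNA(acc$predictions))
  expect_length(acc$predictions, 100)
  acc2 <- prediction_accuracy_cv(pr, loss_spec("huber"), folds = 5,
                                 seed = 11, inner_k = 5, nlambda = 30,
                                 tol = 1e-3)
  expect_identical(acc$predictions, acc2$predictions)
  expect_identical(acc$squared, acc2$squared)

  # no genetic signal: near-zero squared accuracy
  sq <- vapply(1:5, function(s) {
    prn <- withr::with_seed(700 + s, regression_problem(
      matrix(rbinom(150 * 20, 2, 0.3), 150, 20,
             dimnames = list(NULL, paste0("n", 1:20))), rnorm(150)))
    prediction_accuracy_cv(prn, loss_spec("squared"), folds = 5,
                           seed = s, inner_k = 5, nlambda = 30,
                           tol = 1e-3)$squared
  }, numeric(1))
  expect_lt(median(sq), 0.02)
})

test_that("sensitivity profile tracks the injected residual grid", {
  pool <- tiny_pool()
  idx <- withr::with_seed(4, sample(nrow(pool$G), 80))
  pr <- regression_problem(pool$G[idx, ], pool$y[idx])
  grid <- seq(-5, 5, length.out = 5)
  prof <- sensitivity_profile(pr, snp = "rs9296004", target = "low",
                              residual_grid = grid,
                              cv_folds = 5, seed = 2, nlambda = 30)
  expect_equal(nrow(prof), 5 * 2) # grid values x losses
  expect_setequal(unique(prof$loss), c("squared", "huber"))
  expect_true(all(is.finite(prof$lambda_opt)))

  # injecting the individual's own residual reproduces the baseline fit
  target <- prof$target_index[1]
  prof0 <- sensitivity_profile(pr, snp = "rs9296004", target = "low",
                               residual_grid = pr$y[target],
                               cv_folds = 5, seed = 2, nlambda = 30)
  folds <- withr::with_seed(2L, sample(rep_len(1:5, pr$n)))
  base <- cross_validate(pr, loss_spec("squared"), k = 5, folds = folds,
                         nlambda = 30, lambda_min_ratio = 0.05,
                         tol = 1e-3)
  expect_equal(prof0$lambda_opt[prof0$loss == "squared"], base$lambda_opt)

  expect_error(sensitivity_profile(pr, snp = "nope", residual_grid = 0),
               "unknown SNP")
  expect_error(sensitivity_profile(pr, snp = "rs9296004",
                                   residual_grid = 7), "\\[-5, 5\\]")
})
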