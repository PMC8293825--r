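test_that("lambda_max is the exact all-zero threshold", {
  # single standardized predictor with (1/n) x'y = 0.4: closed form
  n <- 50
  x <- rep(c(-1, 1), length.out = n) # mean 0, population sd 1
  y <- 0.4 * x
  pr <- regression_problem(cbind(x, matrix(0.0, n, 0)), y,
                           snp_ids = "x1")
  expect_equal(lambda_max(pr, loss_spec("squared")), 0.4)
  # homogeneity in y for the squared loss
  pr2 <- regression_problem(cbind(x), 2 * y, snp_ids = "x1")
  expect_equal(lambda_max(pr2, loss_spec("squared")), 0.8)

  # fitting at lambda_max yields the all-zero penalized solution
  for (spec in all_losses()) {
    pr3 <- small_instance(11)
    lm3 <- lambda_max(pr3, spec)
    f <- fit_path(pr3, spec, lambda = lm3)
    expect_identical(unname(f$coefficients[, 1]),
                     rep(0, nrow(f$coefficients)))
    expect_length(selected_variables(f, lm3), 0)
  }

  expect_warning(
    lambda_max(regression_problem(matrix(rnorm(30), 15, 2), rep(1, 15)),
               loss_spec("squared")), "constant")
})

test_that("unpenalized limit matches ordinary least squares", {
  pr <- small_instance(2, n = 60, p = 6)
  grid <- c(default_grid <- exp(seq(log(0.5), log(0.005), length.out = 20)),
            0)
  f <- fit_path(pr, loss_spec("squared"), lambda = grid)
  ols <- coef(lm(pr$y ~ pr$X))
  expect_equal(unname(f$coefficients[, 21]), unname(ols[-1]),
               tolerance = 1e-6)
  expect_equal(f$intercepts[21], unname(ols[1]), tolerance = 1e-6)
  # predictions at lambda = 0 equal OLS fitted values
  expect_equal(predict(f, pr$X, lambda = 0), unname(fitted(lm(pr$y ~ pr$X))),
               tolerance = 1e-6)
})

test_that("huber path with large c collapses to the least-squares path", {
  pr <- small_instance(3, n = 80, p = 15)
  c_big <- 10 * max(abs(pr$y))
  fh <- fit_path(pr, loss_spec("huber", c = c_big), tol = 1e-8)
  fs <- fit_path(pr, loss_spec("squared"), lambda = fh$lambda, tol = 1e-8)
  expect_lt(max(abs(fh$coefficients - fs$coefficients)), 1e-5)
  expect_lt(max(abs(fh$intercepts - fs$intercepts)), 1e-5)
})

test_that("KKT conditions hold along the path for every family", {
  for (s in 1:6) {
    pr <- small_instance(100 + s)
    for (spec in all_losses()) {
      f <- fit_path(pr, spec, tol = 1e-6, max_sweeps = 2e5)
      k <- kkt_check(f, pr, tol = 1e-4)
      expect_true(all(k$ok), label = sprintf("seed %d %s", s, spec$family))
    }
  }
})

test_that("squared-loss path agrees with glmnet at fixed penalties", {
  skip_if_not_installed("glmnet")
  pr <- small_instance(7, n = 100, p = 25)
  lams <- c(0.3, 0.1, 0.03)
  f <- fit_path(pr, loss_spec("squared"), lambda = lams, tol = 1e-8)
  g <- glmnet::glmnet(pr$X, pr$y, lambda = lams, standardize = TRUE,
                      thresh = 1e-12)
  for (i in seq_along(lams)) {
    bg <- as.numeric(coef(g, s = lams[i], exact = TRUE, x = pr$X,
                          y = pr$y))
    expect_equal(unname(f$coefficients[, i]), bg[-1], tolerance = 1e-4)
  }
})

test_that("objective value is not beaten by a proximal-gradient oracle", {
  for (s in 1:3) {
    pr <- small_instance(200 + s, n = 30, p = 8)
    for (spec in all_losses()) {
      f <- fit_path(pr, spec, nlambda = 5, lambda_min_ratio = 0.05,
                    tol = 1e-8, max_sweeps = 5e5)
      obj_fit <- path_objective(f, pr)
      for (i in c(2, 4)) {
        obj_oracle <- ista_objective(pr$X, pr$y, spec, f$lambda[i])
        expect_lte(obj_fit[i], obj_oracle + 1e-6)
      }
    }
  }
})

test_that("a corrupted phenotype moves the huber fit less than squared", {
  withr::with_seed(77, {
    n <- 100
    g <- rbinom(n, 2, 0.3)
    y <- 0.5 * (g - mean(g)) + rnorm(n, sd = sqrt(1 - 0.5^2 * var(g)))
    X <- cbind(snp = g, matrix(rnorm(n * 5), n, 5,
                               dimnames = list(NULL, paste0("n", 1:5))))
  })
  pr <- regression_problem(X, y)
  y_bad <- y
  y_bad[which.min(abs(g - 1))] <- 5
  pr_bad <- regression_problem(X, y_bad)
  lam <- 0.05
  for (spec in all_losses()[c("squared", "huber")]) {
    assign(paste0("d_", spec$family),
           abs(fit_path(pr, spec, lambda = lam)$coefficients["snp", 1] -
               fit_path(pr_bad, spec, lambda = lam)$coefficients["snp", 1]))
  }
  expect_lt(d_huber, d_squared)
})

test_that("cross-validation is deterministic and sensible", {
  pr <- small_instance(42, n = 80, p = 20)
  spec <- loss_spec("huber")
  cv1 <- cross_validate(pr, spec, k = 5, seed = 9)
  cv2 <- cross_validate(pr, spec, k = 5, seed = 9)
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$cv_curve$mean, cv2$cv_curve$mean)
  # lambda_opt attains the minimum of the mean curve
  expect_equal(cv1$cv_curve$mean[cv1$lambda == cv1$lambda_opt],
               min(cv1$cv_curve$mean))

  # pure noise: few selections at the optimum (median over seeds < 0.1 p)
  nsel <- vapply(1:5, function(s) {
    prn <- withr::with_seed(300 + s, {
      X <- matrix(rnorm(100 * 30), 100, 30)
      regression_problem(X, rnorm(100))
    })
    cv <- cross_validate(prn, loss_spec("squared"), k = 5, seed = s)
    length(selected_variables(cv$fit, cv$lambda_opt))
  }, numeric(1))
  expect_lt(median(nsel), 0.1 * 30)

  # strong single predictor is selected at the optimum
  hits <- vapply(1:10, function(s) {
    prs <- withr::with_seed(400 + s, {
      X <- matrix(rnorm(300 * 10), 300, 10,
                  dimnames = list(NULL, paste0("v", 1:10)))
      y <- X[, 1] + rnorm(300) # explained variance 0.5
      regression_problem(X, y)
    })
    cv <- cross_validate(prs, loss_spec("huber"), k = 10, seed = s)
    "v1" %in% selected_variables(cv$fit, cv$lambda_opt)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("predict and selected_variables respect their contracts", {
  pr <- small_instance(8)
  f <- fit_path(pr, loss_spec("squared"), nlambda = 20)
  # all-zero solution: constant prediction equal to the intercept
  p0 <- predict(f, pr$X, lambda = f$lambda[1])
  expect_equal(p0, rep(f$intercepts[1], pr$n))
  # dosage semantics: one nonzero coefficient moves predictions by
  # beta per allele copy
  n <- 30
  dos <- cbind(a = rep(0:2, each = 10),
               b = rep(0, 30))
  yd <- 0.5 * dos[, "a"] + c(rnorm(30, sd = 0.1))
  prd <- regression_problem(dos + cbind(0, rnorm(30, sd = 1)), yd)
  lamd <- 0.01 * lambda_max(prd, loss_spec("squared"))
  fd <- fit_path(prd, loss_spec("squared"), lambda = lamd)
  newx <- matrix(c(0, 0, 1, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b")))
  pd <- predict(fd, newx, lambda = lamd)
  expect_equal(pd[2] - pd[1], unname(fd$coefficients["a", 1]))

  # unknown columns are fatal and named
  bad <- pr$X[, -1]
  expect_error(predict(f, bad, lambda = f$lambda[1]), "s01")
  # off-grid lambda requires explicit interpolation
  lam_mid <- sqrt(f$lambda[3] * f$lambda[4])
  expect_error(predict(f, pr$X, lambda = lam_mid), "interpolate")
  pi1 <- predict(f, pr$X, lambda = lam_mid, interpolate = TRUE)
  expect_length(pi1, pr$n)

  # selection: empty at lambda_max, larger at the small end
  expect_length(selected_variables(f, f$lambda[1]), 0)
  expect_gte(length(selected_variables(f, f$lambda[20])),
             length(selected_variables(f, f$lambda[1])))
  # covariates never reported as selected SNPs
  prc <- regression_problem(pr$X, pr$y, covariate_cols = "s01")
  fc <- fit_path(prc, loss_spec("squared"), nlambda = 20)
  expect_false("s01" %in% selected_variables(fc, fc$lambda[20]))
})

test_that("zero-variance columns are flagged and never selected", {
  withr::with_seed(5, {
    X <- cbind(const = rep(1, 40), matrix(rnorm(40 * 4), 40, 4,
               dimnames = list(NULL, paste0("v", 1:4))))
    y <- rnorm(40)
  })
  pr <- regression_problem(X, y)
  expect_true(pr$zero_variance["const"])
  f <- fit_path(pr, loss_spec("huber"), nlambda = 10)
  expect_equal(unname(f$coefficients["const", ]), rep(0, 10))
})

test_that("dfmax truncates the path and CV still works", {
  pr <- small_instance(13, n = 50, p = 30)
  f <- fit_path(pr, loss_spec("squared"), nlambda = 50,
                lambda_min_ratio = 0.01, dfmax = 3)
  expect_lt(length(f$lambda), 50)
  expect_true(all(colSums(f$coefficients[, -length(f$lambda)] != 0) <= 3))
  cv <- cross_validate(pr, loss_spec("squared"), k = 5, seed = 1,
                       dfmax = 10)
  expect_true(cv$lambda_opt %in% cv$lambda)
})

test_that("solver objective decreases along iterations (monitored)", {
  # warm starts mean later grid points start close; verify the reported
  # objective is monotone in lambda (a decreasing-penalty relaxation)
  pr <- small_instance(21)
  for (spec in all_losses()) {
    f <- fit_path(pr, spec, nlambda = 30, tol = 1e-7)
    obj <- path_objective(f, pr)
    penal_free <- obj - f$lambda * colSums(abs(f$coefficients * f$scale))
    expect_true(all(diff(penal_free) < 1e-8)) # data fit improves as lambda drops
  }
})
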