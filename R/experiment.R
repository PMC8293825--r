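#' Scenario configuration for the subsampling comparison protocol
#'
#' Encodes one simulation scenario of the comparison protocol: for each
#' iteration a subsample of the pool is drawn, the leverage-extreme
#' individuals are located by trivariate depth, an artificial residual is
#' (optionally) assigned to the most extreme individual(s), and every loss
#' variant is fitted with a cross-validated penalty on identical data and
#' identical fold assignments (paired design).
#'
#' @param outlier_value artificial residual in \[-5, 5\] assigned to the
#'   targeted individual(s), or `NULL` for the no-outlier scenario.
#' @param leverage_target `"low"` (average genotype, the deepest point) or
#'   `"high"` (divergent genotype, the shallowest point).
#' @param n_outliers number of targeted individuals (1, or e.g. 5 for the
#'   1%-of-500 variant; the `n_outliers` most extreme depths are used).
#' @param losses named list of [loss_spec()]s to fit; default standard
#'   LASSO and Huber-LASSO with c = 1.345.
#' @param iterations number of subsampling iterations (default 100).
#' @param subsample subsample size (default 500).
#' @param cv_folds folds for penalty selection (default 10).
#' @param prediction_folds outer folds for prediction accuracy (default 5).
#' @param compute_accuracy evaluate out-of-sample prediction accuracy per
#'   iteration (costly: `prediction_folds` x (`cv_folds` + 1) path fits
#'   per loss per iteration).
#' @param include_zero_coef aggregate coefficient means/CIs over all
#'   iterations including zeros (default), or over selected-only
#'   iterations.
#' @param nlambda,lambda_min_ratio penalty grid parameters. The default
#'   grid floor of 0.05 is the usual n < p choice; the cross-validated
#'   optimum sits well inside the grid on the emulation preset.
#' @param tol solver tolerance for experiment-scale fits; selection and
#'   penalty choice are insensitive below 1e-3 (coefficients move by less
#'   than the tolerance itself).
#' @param dfmax active-set cap that truncates the penalty path once a
#'   solution saturates; the cross-validated optimum selects an order of
#'   magnitude fewer predictors, so the cap never binds on the presets
#'   (a warning is raised if it does).
#' @param seed master seed; every downstream random draw derives from it.
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(outlier_value = NULL,
                            leverage_target = c("low", "high"),
                            n_outliers = 1L,
                            losses = list(
                              squared = loss_spec("squared"),
                              huber = loss_spec("huber", c = 1.345)),
                            iterations = 100L, subsample = 500L,
                            cv_folds = 10L, prediction_folds = 5L,
                            compute_accuracy = FALSE,
                            include_zero_coef = TRUE,
                            nlambda = 100L, lambda_min_ratio = 0.05,
                            tol = 1e-3, dfmax = 150L, seed = 1L) {
  leverage_target <- match.arg(leverage_target)
  if (!is.null(outlier_value)) {
    stopifnot(is.numeric(outlier_value), length(outlier_value) == 1L,
              outlier_value >= -5, outlier_value <= 5)
  }
  stopifnot(iterations >= 2L, n_outliers >= 1L, cv_folds >= 2L,
            all(vapply(losses, inherits, logical(1), "loss_spec")))
  if (is.null(names(losses)))
    names(losses) <- vapply(losses, loss_label, character(1))
  structure(list(outlier_value = outlier_value,
                 leverage_target = leverage_target,
                 n_outliers = as.integer(n_outliers), losses = losses,
                 iterations = as.integer(iterations),
                 subsample = as.integer(subsample),
                 cv_folds = as.integer(cv_folds),
                 prediction_folds = as.integer(prediction_folds),
                 compute_accuracy = isTRUE(compute_accuracy),
                 include_zero_coef = isTRUE(include_zero_coef),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 dfmax = if (is.null(dfmax)) NULL else as.integer(dfmax),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

loss_label <- function(spec) {
  switch(spec$family,
         squared = "squared",
         huber = sprintf("huber_c%g", spec$c),
         quantile = sprintf("quantile_tau%g", spec$tau))
}

check_pool <- function(pool) {
  stopifnot(is.list(pool), is.matrix(pool$G), is.numeric(pool$y),
            nrow(pool$G) == length(pool$y), is.data.frame(pool$meta),
            all(c("snp_id", "causal") %in% names(pool$meta)))
  invisible(pool)
}

#' Certified leverage extremes of a score cloud
#'
#' Equivalent to `leverage_extremes(halfspace_depth(scores), n_each)` but
#' avoids computing every exact depth: the shallow side scans points in
#' index order and stops once `n_each` depth-1 points are found (no later
#' point can beat them under the tie rule), and the deep side evaluates
#' exact depth only for points whose deterministic projection upper bound
#' reaches the current best (bounds from a Fibonacci-sphere direction
#' grid). Exactness of the result is certified, not approximated.
#'
#' @param scores n x 3 matrix (or [genotype_pca()] result).
#' @param n_each extremes per side.
#' @param n_directions directions for the projection bounds.
#' @return list with `low_leverage`/`high_leverage` index vectors and the
#'   corresponding exact depths.
#' @export
leverage_extremes_fast <- function(scores, n_each = 1L,
                                   n_directions = 2000L) {
  if (inherits(scores, "pca_scores")) scores <- scores$scores
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) >= 4L, ncol(scores) == 3L, n_each >= 1L)
  depth_extremes_cpp(scores, as.integer(n_each),
                     as.integer(n_directions))
}

# Draw the shared per-iteration state: subsample, derived fold seeds and
# (when any scenario injects outliers) the depth of the subsample's
# trivariate PCA scores. All scenarios and losses of a paired comparison
# see this identical state.
prepare_iteration <- function(pool, config, iteration_seed, need_depth) {
  n_pool <- nrow(pool$G)
  draws <- withr::with_seed(as.integer(iteration_seed), {
    list(idx = sample.int(n_pool, config$subsample),
         fold_seed = sample.int(.Machine$integer.max - 1L, 1L),
         acc_seed = sample.int(.Machine$integer.max - 1L, 1L))
  })
  G <- pool$G[draws$idx, , drop = FALSE]
  y <- pool$y[draws$idx]
  folds <- withr::with_seed(draws$fold_seed,
                            sample(rep_len(seq_len(config$cv_folds),
                                           config$subsample)))
  acc_folds <- withr::with_seed(draws$acc_seed,
                                sample(rep_len(
                                  seq_len(config$prediction_folds),
                                  config$subsample)))
  extremes <- NULL
  if (need_depth > 0L) {
    pca <- suppressWarnings(genotype_pca(G, k = 3))
    extremes <- leverage_extremes_fast(pca$scores, n_each = need_depth)
  }
  list(idx = draws$idx, G = G, y = y, folds = folds,
       acc_folds = acc_folds, extremes = extremes,
       acc_seed = draws$acc_seed)
}

inject_for_scenario <- function(prep, config) {
  if (is.null(config$outlier_value)) return(list(y = prep$y,
                                                 targets = integer(0)))
  targets <- if (config$leverage_target == "low")
    prep$extremes$low_leverage[seq_len(config$n_outliers)]
  else prep$extremes$high_leverage[seq_len(config$n_outliers)]
  list(y = inject_outliers(prep$y, targets, config$outlier_value),
       targets = targets)
}

#' Run one simulation iteration
#'
#' Draws the iteration's subsample with `iteration_seed`, locates the
#' leverage extremes by trivariate depth of the subsample's genotype PCA,
#' injects the scenario's artificial residual, and fits every loss variant
#' with a `cv_folds`-fold cross-validated penalty on the identical data
#' and fold assignment. Deterministic given
#' `(pool, config, iteration_seed)`.
#'
#' @param pool a [simulate_pool()] result (or compatible list with `G`,
#'   `y`, `meta`).
#' @param config a [scenario_config()].
#' @param iteration_seed integer seed for this iteration.
#' @return an `"iteration_record"`: `targets`, and per loss `lambda_opt`,
#'   `selected`, `coefficients` (at `lambda_opt`), `intercept`,
#'   `converged`, plus prediction accuracy when requested.
#' @export
run_iteration <- function(pool, config, iteration_seed) {
  check_pool(pool)
  stopifnot(inherits(config, "scenario_config"))
  prep <- prepare_iteration(pool, config, iteration_seed,
                            need_depth = if (is.null(config$outlier_value))
                              0L else config$n_outliers)
  iteration_core(pool, config, prep, iteration_seed)
}

iteration_core <- function(pool, config, prep, iteration_seed) {
  inj <- inject_for_scenario(prep, config)
  problem <- regression_problem(prep$G, inj$y)
  per_loss <- lapply(config$losses, function(spec) {
    cv <- cross_validate(problem, spec, k = config$cv_folds,
                         folds = prep$folds, nlambda = config$nlambda,
                         lambda_min_ratio = config$lambda_min_ratio,
                         tol = config$tol, dfmax = config$dfmax)
    out <- list(lambda_opt = cv$lambda_opt,
                selected = selected_variables(cv$fit, cv$lambda_opt),
                coefficients = cv$fit$coefficients[,
                  match_lambda(cv$fit, cv$lambda_opt)],
                intercept = cv$fit$intercepts[
                  match_lambda(cv$fit, cv$lambda_opt)],
                converged = all(cv$fit$converged))
    if (config$compute_accuracy) {
      acc <- prediction_accuracy_cv(problem, spec,
                                    folds = config$prediction_folds,
                                    seed = prep$acc_seed,
                                    outer_folds = prep$acc_folds,
                                    inner_k = config$cv_folds,
                                    nlambda = config$nlambda,
                                    lambda_min_ratio =
                                      config$lambda_min_ratio,
                                    tol = config$tol,
                                    dfmax = config$dfmax)
      out$accuracy <- acc[c("estimate", "squared", "degenerate")]
    }
    out
  })
  structure(list(iteration_seed = iteration_seed, subsample = prep$idx,
                 targets = inj$targets, per_loss = per_loss),
            class = "iteration_record")
}

#' Out-of-sample prediction accuracy by cross-validation
#'
#' Every individual receives exactly one out-of-sample prediction from a
#' `folds`-fold split; within each training split the penalty is re-chosen
#' by `inner_k`-fold cross-validation. The accuracy measure is the
#' Fisher-consistent Kendall correlation between observed and predicted
#' values and its square; constant predictions yield squared accuracy 0
#' with a degeneracy flag.
#'
#' @param problem a [regression_problem()].
#' @param spec a [loss_spec()].
#' @param folds number of outer folds (default 5); `n >= 5 * folds`
#'   required.
#' @param seed seed for fold assignments and derived inner seeds.
#' @param outer_folds optional explicit outer fold labels.
#' @param inner_k inner folds for penalty selection (default 10).
#' @param method rank correlation flavour, `"kendall"` or `"spearman"`.
#' @param nlambda,lambda_min_ratio,tol,dfmax penalty grid and solver
#'   parameters forwarded to [cross_validate()].
#' @return list with `estimate` (signed), `squared`, `degenerate`,
#'   `predictions`, `folds`.
#' @export
prediction_accuracy_cv <- function(problem, spec, folds = 5, seed = 1L,
                                   outer_folds = NULL, inner_k = 10,
                                   method = c("kendall", "spearman"),
                                   nlambda = 100,
                                   lambda_min_ratio = 0.01,
                                   tol = 1e-5, dfmax = NULL) {
  stopifnot(inherits(problem, "regression_problem"),
            problem$n >= 5 * folds)
  method <- match.arg(method)
  if (is.null(outer_folds)) {
    outer_folds <- withr::with_seed(as.integer(seed),
                                    sample(rep_len(seq_len(folds),
                                                   problem$n)))
  }
  preds <- rep(NA_real_, problem$n)
  for (f in seq_len(folds)) {
    tr <- outer_folds != f
    prob_tr <- regression_problem(problem$X[tr, , drop = FALSE],
                                  problem$y[tr],
                                  snp_ids = problem$snp_ids,
                                  covariate_cols = problem$covariate_cols)
    cv <- cross_validate(prob_tr, spec, k = inner_k,
                         seed = as.integer(seed) + f,
                         nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio, tol = tol,
                         dfmax = dfmax)
    preds[!tr] <- predict(cv$fit, problem$X[!tr, , drop = FALSE],
                          lambda = cv$lambda_opt)
  }
  acc <- squared_correlation(problem$y, preds, method = method)
  c(acc, list(predictions = preds, folds = outer_folds))
}

#' Run a full simulation experiment
#'
#' Executes `config$iterations` seeded iterations of the subsampling
#' protocol (see [run_iteration()]) and aggregates them into the summary
#' statistics of the comparison: per-loss median penalty, mean pairwise
#' Jaccard concordance of the selected models across iterations, median
#' and mean false-positive rate, per-causal-SNP true-positive rate and
#' coefficient mean with 95% empirical confidence interval, and (when
#' `compute_accuracy`) the squared prediction-correlation distribution
#' with two-sided paired t-tests between loss variants. Deterministic
#' given the master seed.
#'
#' For paired multi-scenario comparisons use [run_scenarios()], which
#' shares every iteration's subsample, depth and fold assignments across
#' scenarios.
#'
#' @param pool a [simulate_pool()] result.
#' @param config a [scenario_config()].
#' @param verbose emit one log line per iteration.
#' @return an object of class `"experiment_summary"`.
#' @export
run_experiment <- function(pool, config, verbose = FALSE) {
  res <- run_scenarios(pool, list(scenario = config), verbose = verbose)
  res$scenario
}

#' @rdname run_experiment
#' @param configs named list of [scenario_config()]s that differ only in
#'   their scenario fields (`outlier_value`, `leverage_target`,
#'   `n_outliers`, `compute_accuracy`).
#' @return for `run_scenarios`, a named list of `"experiment_summary"`
#'   objects (class `"scenario_comparison"`).
#' @export
run_scenarios <- function(pool, configs, verbose = FALSE) {
  check_pool(pool)
  stopifnot(is.list(configs), length(configs) >= 1L,
            !is.null(names(configs)),
            all(vapply(configs, inherits, logical(1), "scenario_config")))
  base <- configs[[1]]
  shared <- c("losses", "iterations", "subsample", "cv_folds",
              "prediction_folds", "nlambda", "lambda_min_ratio", "seed")
  for (cfg in configs[-1])
    if (!identical(cfg[shared], base[shared]))
      stop("scenario configs must share losses, sizes, folds and seed")
  iter_seeds <- withr::with_seed(base$seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            base$iterations))
  need_depth <- max(vapply(configs, function(cfg)
    if (is.null(cfg$outlier_value)) 0L else cfg$n_outliers, integer(1)))
  records <- vector("list", base$iterations)
  for (it in seq_len(base$iterations)) {
    prep <- prepare_iteration(pool, base, iter_seeds[it], need_depth)
    records[[it]] <- lapply(configs, function(cfg)
      iteration_core(pool, cfg, prep, iter_seeds[it]))
    if (verbose)
      message(sprintf(
        "iteration %d/%d seed=%d lambda[%s]", it, base$iterations,
        iter_seeds[it],
        paste(vapply(records[[it]][[1]]$per_loss,
                     function(r) signif(r$lambda_opt, 3), numeric(1)),
              collapse = ", ")))
  }
  out <- lapply(names(configs), function(nm)
    summarize_experiment(pool, configs[[nm]],
                         lapply(records, `[[`, nm)))
  names(out) <- names(configs)
  structure(out, class = "scenario_comparison")
}

summarize_experiment <- function(pool, config, records) {
  associated <- pool$meta$snp_id[pool$meta$causal]
  nulls <- pool$meta$snp_id[!pool$meta$causal]
  loss_names <- names(config$losses)
  per_loss <- lapply(loss_names, function(nm) {
    recs <- lapply(records, function(r) r$per_loss[[nm]])
    lambda_opt <- vapply(recs, `[[`, numeric(1), "lambda_opt")
    sel <- lapply(recs, `[[`, "selected")
    hist <- selection_history(sel, associated, nulls)
    fpr_it <- per_iteration_fpr(hist)
    snps <- lapply(associated, function(s) {
      coefs <- vapply(recs, function(r) r$coefficients[s], numeric(1))
      use <- if (config$include_zero_coef) rep(TRUE, length(coefs))
             else coefs != 0
      ci <- if (sum(use) >= 20) empirical_ci(coefs[use])
            else c(low = NA_real_, high = NA_real_)
      list(snp_id = s, tpr = true_positive_rate(hist, s),
           coef_mean = if (any(use)) mean(coefs[use]) else NA_real_,
           ci = ci)
    })
    names(snps) <- associated
    out <- list(lambda_opt = lambda_opt,
                median_lambda = median(lambda_opt),
                selected = sel,
                mean_jaccard = mean_pairwise_jaccard(sel),
                fpr_iterations = fpr_it,
                median_fpr = median(fpr_it),
                mean_fpr = mean(fpr_it),
                snps = snps,
                n_nonconverged = sum(!vapply(recs, `[[`, logical(1),
                                             "converged")))
    if (config$compute_accuracy) {
      out$accuracy_squared <- vapply(recs, function(r)
        r$accuracy$squared, numeric(1))
      out$accuracy_signed <- vapply(recs, function(r)
        r$accuracy$estimate, numeric(1))
      out$median_accuracy <- median(out$accuracy_squared)
    }
    out
  })
  names(per_loss) <- loss_names
  tests <- NULL
  if (config$compute_accuracy && length(loss_names) >= 2L) {
    pairs <- utils::combn(loss_names, 2, simplify = FALSE)
    tests <- lapply(pairs, function(pr) {
      tt <- t.test(per_loss[[pr[1]]]$accuracy_squared,
                   per_loss[[pr[2]]]$accuracy_squared, paired = TRUE)
      list(losses = pr, p_value = tt$p.value,
           mean_difference = unname(tt$estimate))
    })
  }
  structure(list(config = config, per_loss = per_loss,
                 accuracy_tests = tests,
                 associated = associated, n_null = length(nulls)),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  sc <- if (is.null(x$config$outlier_value)) "no injected outlier" else
    sprintf("residual %+g at %s-leverage x%d", x$config$outlier_value,
            x$config$leverage_target, x$config$n_outliers)
  cat("Experiment summary (", x$config$iterations, " iterations, ", sc,
      ")\n", sep = "")
  for (nm in names(x$per_loss)) {
    pl <- x$per_loss[[nm]]
    cat(sprintf(
      "  %-14s median lambda %.4f | Jaccard %.3f | median FPR %.4f\n",
      nm, pl$median_lambda, pl$mean_jaccard, pl$median_fpr))
    for (s in pl$snps)
      cat(sprintf("    %-12s TPR %.3f coef %.3f [%.3f, %.3f]\n",
                  s$snp_id, s$tpr, s$coef_mean, s$ci[1], s$ci[2]))
    if (!is.null(pl$median_accuracy))
      cat(sprintf("    median squared prediction correlation %.4f\n",
                  pl$median_accuracy))
  }
  invisible(x)
}

#' Tidy per-iteration results table
#'
#' One row per iteration x loss with the chosen penalty, selection counts
#' and (if computed) prediction accuracy; suitable for writing as TSV.
#'
#' @param summary an `"experiment_summary"`.
#' @return a data.frame.
#' @export
experiment_table <- function(summary) {
  stopifnot(inherits(summary, "experiment_summary"))
  do.call(rbind, lapply(names(summary$per_loss), function(nm) {
    pl <- summary$per_loss[[nm]]
    data.frame(loss = nm,
               iteration = seq_along(pl$lambda_opt),
               lambda_opt = pl$lambda_opt,
               n_selected = lengths(pl$selected),
               fpr = pl$fpr_iterations,
               accuracy_squared = if (is.null(pl$accuracy_squared))
                 NA_real_ else pl$accuracy_squared,
               stringsAsFactors = FALSE)
  }))
}

#' Sensitivity of penalty and coefficient to a single injected residual
#'
#' Reproduces the motivating single-outlier profile: for every value on
#' `residual_grid`, the phenotype of the leverage-extreme individual is
#' replaced by that value, each loss variant is refitted with a
#' cross-validated penalty (fold assignment fixed across the whole grid)
#' and the chosen penalty plus the coefficient of a named SNP are
#' recorded.
#'
#' @param problem a [regression_problem()] (one subsample).
#' @param snp SNP identifier whose coefficient is tracked.
#' @param target `"low"` or `"high"` leverage individual.
#' @param residual_grid numeric grid within \[-5, 5\].
#' @param losses named list of [loss_spec()]s.
#' @param cv_folds,seed,nlambda,lambda_min_ratio,tol as in
#'   [cross_validate()].
#' @return data.frame with one row per grid value per loss:
#'   `residual`, `loss`, `lambda_opt`, `coefficient`, `target_index`.
#' @export
sensitivity_profile <- function(problem, snp,
                                target = c("low", "high"),
                                residual_grid = seq(-5, 5, by = 0.5),
                                losses = list(
                                  squared = loss_spec("squared"),
                                  huber = loss_spec("huber", c = 1.345)),
                                cv_folds = 10, seed = 1L, nlambda = 100,
                                lambda_min_ratio = 0.05, tol = 1e-3) {
  stopifnot(inherits(problem, "regression_problem"))
  target <- match.arg(target)
  if (!snp %in% problem$snp_ids) stop("unknown SNP: ", snp)
  if (any(residual_grid < -5 | residual_grid > 5))
    stop("residual_grid must lie within [-5, 5]")
  if (is.null(names(losses)))
    names(losses) <- vapply(losses, loss_label, character(1))
  pca <- suppressWarnings(genotype_pca(problem$X[,
    setdiff(problem$snp_ids, problem$covariate_cols), drop = FALSE]))
  ext <- leverage_extremes(halfspace_depth(pca$scores))
  idx <- if (target == "low") ext$low_leverage else ext$high_leverage
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep_len(seq_len(cv_folds),
                                           problem$n)))
  rows <- list()
  for (v in residual_grid) {
    y2 <- inject_outliers(problem$y, idx, v)
    prob2 <- regression_problem(problem$X, y2,
                                snp_ids = problem$snp_ids,
                                covariate_cols = problem$covariate_cols)
    for (nm in names(losses)) {
      cv <- cross_validate(prob2, losses[[nm]], k = cv_folds,
                           folds = folds, nlambda = nlambda,
                           lambda_min_ratio = lambda_min_ratio,
                           tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        residual = v, loss = nm, lambda_opt = cv$lambda_opt,
        coefficient = cv$fit$coefficients[snp,
          match_lambda(cv$fit, cv$lambda_opt)],
        target_index = idx, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
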