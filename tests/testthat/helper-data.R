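# Shared fixtures, built in code. The emulation-scale pool and the two
# long experiment runs are memoized so the acceptance tests and the
# property tests that reuse them pay for them once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full emulation preset: 3301 x (3 causal + 1000 null)
emulation_pool <- function() {
  memo("pool", simulate_pool(defb119_architecture(seed = 1L)))
}

# small pool for smoke tests: quick to fit, same structure
tiny_pool <- function(seed = 5L) {
  causal <- snp_effect(c("rs9296004", "rs11845244", "rs12301299"),
                       maf = c(0.082, 0.354, 0.163),
                       effect = c(0.606, 0.241, 0.254))
  spec <- architecture_spec(causal, n_null = 30,
                            structure = list(n_subpops = 3, fst = 0.05,
                                             mass = c(0.49, 0.49, 0.02)),
                            n = 200, seed = seed)
  simulate_pool(spec)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(iterations = 2L, subsample = 60L, cv_folds = 5L,
         prediction_folds = 5L, nlambda = 30L, seed = 3L),
    list(...))
  do.call(scenario_config, args)
}

# random small regression instance with a couple of true effects
small_instance <- function(seed, n = 40, p = 12) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("s%02d", seq_len(p))))
    y <- 0.8 * X[, 1] - 0.5 * X[, min(5, p)] + rnorm(n)
    regression_problem(X, y)
  })
}

all_losses <- function() {
  list(squared = loss_spec("squared"),
       huber = loss_spec("huber", c = 1.345),
       quantile = loss_spec("quantile", tau = 0.5))
}
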