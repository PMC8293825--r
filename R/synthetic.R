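#' Synthetic study architecture
#'
#' Describes the statistical world the generator emulates: a set of causal
#' SNPs with stated MAFs and per-allele effects, a panel of independent
#' null SNPs, optional population substructure (so that genuinely
#' "divergent" multi-SNP genotypes exist) and the number of individuals.
#'
#' @param causal a [snp_effect()] table of causal SNPs.
#' @param n_null number of non-associated SNPs (default 1000).
#' @param null_maf_range MAF interval for null SNPs, within (0.01, 0.5).
#' @param structure `NULL` for a single panmictic (HWE) population, or a
#'   list with `n_subpops`, `fst` and `mass` (admixture fractions summing
#'   to 1). Subpopulation allele frequencies are drawn from the
#'   Balding-Nichols Beta distribution around each SNP's ancestral MAF.
#' @param n number of individuals in the pool.
#' @param seed integer seed; the generated pool is a pure function of the
#'   spec including this seed.
#' @return an object of class `"architecture_spec"`.
#' @seealso [defb119_architecture()] for the default emulation preset.
#' @export
architecture_spec <- function(causal, n_null = 1000,
                              null_maf_range = c(0.05, 0.5),
                              structure = NULL, n = 500, seed = 1L) {
  stopifnot(inherits(causal, "snp_effect") || is.data.frame(causal))
  ev <- explained_variance(causal)
  if (ev >= 1)
    stop("total explained variance of the causal set must be < 1 (got ",
         signif(ev, 3), ")")
  stopifnot(n_null >= 0, length(null_maf_range) == 2L,
            null_maf_range[1] > 0.01, null_maf_range[2] <= 0.5,
            null_maf_range[1] < null_maf_range[2], n >= 1)
  if (!is.null(structure)) {
    stopifnot(is.list(structure),
              all(c("n_subpops", "fst", "mass") %in% names(structure)),
              structure$n_subpops >= 2,
              structure$fst > 0, structure$fst < 1,
              length(structure$mass) == structure$n_subpops,
              abs(sum(structure$mass) - 1) < 1e-8, all(structure$mass > 0))
  }
  structure(list(causal = causal, n_null = as.integer(n_null),
                 null_maf_range = null_maf_range, structure = structure,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Default synthetic emulation preset
#'
#' The stated world of the simulation study: a pool of 3301 individuals
#' (from which 500-individual subsamples are drawn), three causal SNPs
#' with MAF/per-allele-effect pairs (0.082, 0.606), (0.354, 0.241),
#' (0.163, 0.254) jointly explaining 0.100 of a unit-variance phenotype,
#' and 1000 independent null SNPs with MAF uniform in (0.05, 0.5).
#' By default the pool has mild substructure (3 subpopulations,
#' F_ST = 0.05, one subpopulation carrying 2% of the mass) so an
#' identifiable divergent genotype exists in most 500-individual draws.
#'
#' @param n pool size (default 3301).
#' @param n_null number of null SNPs (default 1000).
#' @param structure substructure list as in [architecture_spec()];
#'   `NULL` disables it. The default is
#'   `list(n_subpops = 3, fst = 0.05, mass = c(0.49, 0.49, 0.02))`.
#' @param seed integer seed.
#' @return an `"architecture_spec"`.
#' @export
defb119_architecture <- function(n = 3301, n_null = 1000,
                                 structure = list(n_subpops = 3,
                                                  fst = 0.05,
                                                  mass = c(0.49, 0.49, 0.02)),
                                 seed = 1L) {
  causal <- snp_effect(c("rs9296004", "rs11845244", "rs12301299"),
                       maf = c(0.082, 0.354, 0.163),
                       effect = c(0.606, 0.241, 0.254))
  architecture_spec(causal, n_null = n_null,
                    null_maf_range = c(0.05, 0.5),
                    structure = structure, n = n, seed = seed)
}

#' Simulate genotype dosages
#'
#' Draws an n x p matrix of additive dosages (0/1/2). Causal SNPs use their
#' stated MAFs and null SNPs MAFs uniform in the spec's range. Without
#' substructure each dosage is Binomial(2, MAF) (Hardy-Weinberg); with
#' substructure, individuals are assigned to subpopulations by the stated
#' mass fractions and each subpopulation's allele frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral MAF p with the stated
#' F_ST (Balding-Nichols), clamped to (0.001, 0.999).
#'
#' @param spec an [architecture_spec()].
#' @return list with `G` (n x p dosage matrix, columns named by SNP id),
#'   `meta` (data.frame: snp_id, maf, causal flag) and, with structure,
#'   `subpop` (individual assignments).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    null_ids <- if (spec$n_null > 0)
      sprintf("null_%04d", seq_len(spec$n_null)) else character(0)
    null_maf <- runif(spec$n_null, spec$null_maf_range[1],
                      spec$null_maf_range[2])
    maf <- c(spec$causal$maf, null_maf)
    ids <- c(spec$causal$snp_id, null_ids)
    p <- length(maf)
    subpop <- NULL
    if (is.null(spec$structure)) {
      G <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), nrow = n, ncol = p)
    } else {
      st <- spec$structure
      subpop <- sample.int(st$n_subpops, n, replace = TRUE, prob = st$mass)
      a <- maf * (1 - st$fst) / st$fst
      b <- (1 - maf) * (1 - st$fst) / st$fst
      G <- matrix(0L, nrow = n, ncol = p)
      for (j in seq_len(p)) {
        q <- pmin(pmax(rbeta(st$n_subpops, a[j], b[j]), 0.001), 0.999)
        G[, j] <- rbinom(n, 2L, q[subpop])
      }
    }
    colnames(G) <- ids
    rownames(G) <- sprintf("ind_%05d", seq_len(n))
    meta <- data.frame(snp_id = ids, maf = maf,
                       causal = ids %in% spec$causal$snp_id,
                       stringsAsFactors = FALSE)
    out <- list(G = G, meta = meta)
    if (!is.null(subpop)) out$subpop <- subpop
    out
  })
}

#' Simulate a phenotype on the residual scale
#'
#' Builds \eqn{y_i = \sum_k a_k (g_{ik} - 2\,\mathrm{MAF}_k) + \epsilon_i}
#' with Gaussian noise of variance \eqn{1 - \mathrm{EV}} where EV is the
#' causal explained variance, so the phenotype has approximately unit
#' variance and zero mean (it emulates residuals from a covariate-adjusted
#' regression, which in the reference data ranged roughly -3.5 to 3.5).
#' Centering by the expected dosage removes the mean without changing the
#' per-allele effects.
#'
#' @param G dosage matrix containing the spec's causal SNP columns.
#' @param spec an [architecture_spec()].
#' @param seed optional seed for the noise draw; defaults to
#'   `spec$seed + 1` so genotypes and phenotype are jointly reproducible.
#' @return numeric phenotype vector of length `nrow(G)`.
#' @export
simulate_phenotype <- function(G, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "architecture_spec"), is.matrix(G))
  miss <- setdiff(spec$causal$snp_id, colnames(G))
  if (length(miss) > 0L)
    stop("G lacks causal SNP columns: ", paste(miss, collapse = ", "))
  ev <- explained_variance(spec$causal)
  if (ev >= 1) stop("explained variance must be < 1")
  centered <- sweep(G[, spec$causal$snp_id, drop = FALSE], 2,
                    2 * spec$causal$maf)
  signal <- as.numeric(centered %*% spec$causal$effect)
  withr::with_seed(as.integer(seed),
                   signal + rnorm(nrow(G), sd = sqrt(1 - ev)))
}

#' Simulate a complete genotype/phenotype pool
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotype()].
#'
#' @param spec an [architecture_spec()].
#' @return list with `G`, `y`, `meta`, `spec` and optionally `subpop`.
#' @export
simulate_pool <- function(spec) {
  g <- simulate_genotypes(spec)
  y <- simulate_phenotype(g$G, spec)
  names(y) <- rownames(g$G)
  c(g, list(y = y, spec = spec))
}

#' Inject outlying phenotype values
#'
#' Returns a copy of `y` in which the entries at `indices` are replaced by
#' `value` (replacement, not addition: an artificial residual is assigned
#' to the targeted individuals). The input vector is untouched.
#'
#' @param y numeric phenotype vector.
#' @param indices distinct in-range indices.
#' @param value replacement residual value (e.g. in \[-5, 5\]).
#' @return modified copy of `y`.
#' @examples
#' inject_outliers(rep(0, 10), 3, 5)
#' @export
inject_outliers <- function(y, indices, value) {
  stopifnot(is.numeric(y), is.numeric(value), length(value) == 1L,
            is.finite(value))
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("'indices' must be distinct")
  if (any(indices < 1L) || any(indices > length(y)))
    stop("outlier index out of range")
  y[indices] <- value
  y
}
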