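#' Read a genotype dosage matrix
#'
#' Supports VCF (`.vcf`/`.vcf.gz`, via VariantAnnotation; the DS format
#' field is used when present, otherwise GT genotypes are converted to
#' additive dosages) and tab-delimited matrices (header row of SNP ids,
#' first column individual id, values in \[0, 2\]).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return numeric individuals x SNPs matrix with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") return(read_genotypes_vcf(path))
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  row.names = 1L)
  G <- as.matrix(d)
  storage.mode(G) <- "double"
  if (anyNA(G)) stop("missing dosages in ", path)
  if (any(G < 0 | G > 2)) stop("dosages must lie in [0, 2]")
  G
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    G <- t(as.matrix(g$DS))
    storage.mode(G) <- "double"
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean %in% c("0/0", "0")] <- 0
    dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean %in% c("1/1", "1")] <- 2
    if (anyNA(dos)) stop("unhandled GT codes in ", path)
    G <- t(dos)
  } else stop("VCF has neither DS nor GT genotype fields")
  G
}

#' Read a phenotype vector
#'
#' Two-column tab-delimited file: individual id, value. A header line is
#' detected and skipped when the second field is non-numeric.
#'
#' @param path input file.
#' @return named numeric vector.
#' @export
read_phenotype <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- length(first) >= 2L && is.na(suppressWarnings(
    as.numeric(first[2])))
  d <- read.table(path, header = header, sep = "\t",
                  col.names = c("id", "value"),
                  colClasses = c("character", "numeric"))
  if (anyDuplicated(d$id)) stop("duplicated individual ids in ", path)
  stats::setNames(d$value, d$id)
}

#' Join genotypes and phenotype into a regression problem
#'
#' Individual ids are matched strictly: any phenotype id missing from the
#' genotype matrix (or vice versa) is fatal.
#'
#' @param G individuals x SNPs dosage matrix with rownames.
#' @param y named phenotype vector.
#' @param covariate_cols forwarded to [regression_problem()].
#' @return a [regression_problem()] in phenotype order.
#' @export
join_data <- function(G, y, covariate_cols = character(0)) {
  if (is.null(rownames(G)) || is.null(names(y)))
    stop("genotypes and phenotype must both carry individual ids")
  missing_g <- setdiff(names(y), rownames(G))
  missing_y <- setdiff(rownames(G), names(y))
  if (length(missing_g) > 0L || length(missing_y) > 0L)
    stop("id mismatch between genotypes and phenotype: ",
         length(missing_g), " phenotype ids lack genotypes, ",
         length(missing_y), " genotyped ids lack phenotypes")
  regression_problem(G[names(y), , drop = FALSE], unname(y),
                     covariate_cols = covariate_cols)
}

#' Write genotype and phenotype files
#'
#' `write_genotypes_tsv()` writes the tab-delimited matrix layout read by
#' [read_genotypes()]; `write_genotypes_vcf()` writes a minimal VCFv4.2
#' file with GT genotypes for integer dosages on synthetic coordinates
#' (chromosome 1, consecutive positions); `write_phenotype()` writes the
#' two-column layout of [read_phenotype()].
#'
#' @param G dosage matrix with dimnames (integer dosages for VCF output).
#' @param y named phenotype vector.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(G, path) {
  d <- data.frame(id = rownames(G), G, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(G, path) {
  if (!all(G %in% 0:2))
    stop("VCF output requires integer dosages 0/1/2")
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snplasso_synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G)),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(G))) {
    writeLines(paste(c("1", j, colnames(G)[j], "A", "G", ".", "PASS",
                       ".", "GT", gt[G[, j] + 1L]), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_phenotype <- function(y, path) {
  write.table(data.frame(id = names(y), value = unname(y)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`) file whose entries override the
#' defaults of [architecture_spec()] and [scenario_config()]. Recognised
#' top-level blocks: `architecture` (fields `causal` -- a table with
#' `snp_id`, `maf`, `effect` --, `n_null`, `null_maf_range`, `structure`,
#' `n`, `seed`) and `scenario` (fields of [scenario_config()], with
#' `losses` given as a list of `{family, c, tau}` entries).
#'
#' @param path configuration file.
#' @return list with `architecture` ([architecture_spec()]) and
#'   `scenario` ([scenario_config()]); missing blocks yield the presets.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- raw$architecture
  architecture <- if (is.null(arch)) defb119_architecture() else {
    causal <- if (is.null(arch$causal)) {
      defb119_architecture()$causal
    } else if (is.data.frame(arch$causal)) {
      snp_effect(arch$causal$snp_id, arch$causal$maf,
                 arch$causal$effect)
    } else {
      snp_effect(vapply(arch$causal, `[[`, "", "snp_id"),
                 vapply(arch$causal, function(x)
                   as.numeric(x$maf), numeric(1)),
                 vapply(arch$causal, function(x)
                   as.numeric(x$effect), numeric(1)))
    }
    do.call(architecture_spec, utils::modifyList(
      list(causal = causal), arch[setdiff(names(arch), "causal")]))
  }
  sc <- raw$scenario
  scenario <- if (is.null(sc)) scenario_config() else {
    if (!is.null(sc$losses)) {
      ls <- sc$losses
      if (is.data.frame(ls)) # flattened by jsonlite::simplifyVector
        ls <- lapply(seq_len(nrow(ls)), function(i)
          Filter(Negate(is.na), as.list(ls[i, ])))
      sc$losses <- lapply(ls, function(l) do.call(loss_spec, as.list(l)))
    }
    do.call(scenario_config, sc)
  }
  list(architecture = architecture, scenario = scenario)
}
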