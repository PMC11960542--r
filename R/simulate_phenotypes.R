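#' Simulate count phenotypes with planted cis effects
#'
#' Latent trait for each element = sum of planted genotype effects (on
#' standardized dosages, so effect sizes are in latent-SD units) + hidden
#' confounder loadings + a kinship-correlated polygenic term + independent
#' Gaussian noise. Observed counts follow a Poisson--log-normal model with
#' log-normal per-sample library sizes, emulating sequencing count data.
#'
#' @param panel a `genotype_panel`.
#' @param elements element table as from [layout_elements()] (columns id,
#'   type, tissue, chrom, start, end, strand, tss).
#' @param design data.frame of planted effects with columns `element`,
#'   `variant`, `effect` (latent SD units) and optionally `temporal_class`
#'   and `shared_group`; zero rows plant no effects.
#' @param n_hidden_factors number of hidden confounders.
#' @param factor_sd SD of element loadings on each hidden factor.
#' @param polygenic_sd SD of the kinship-correlated polygenic term.
#' @param noise_sd SD of the independent noise.
#' @param seed integer seed.
#' @param base_log_mean mean of per-element baseline log abundance.
#' @param libsize_sd SD of log library-size multipliers.
#' @return list with `phenotypes` (class `phenotype_set`: counts matrix
#'   elements x samples, `elements`, `lib_sizes`) and `truth` (class
#'   `ground_truth`: the planted design, hidden factor scores, the latent
#'   matrix, and per-element latent components for oracle checks).
#' @export
simulate_phenotypes <- function(panel, elements, design = NULL,
                                n_hidden_factors = 0, factor_sd = 1,
                                polygenic_sd = 0, noise_sd = 1,
                                seed = 1,
                                base_log_mean = log(200),
                                libsize_sd = 0.25) {
  set.seed(as.integer(seed))
  n <- nrow(panel$dosages)
  ne <- nrow(elements)
  if (is.null(design)) {
    design <- data.frame(element = character(), variant = character(),
                         effect = numeric())
  }
  if (nrow(design) > 0) {
    if (!all(design$element %in% elements$id)) {
      stop("design references unknown elements")
    }
    if (!all(design$variant %in% panel$variants$id)) {
      stop("design references unknown variants")
    }
    # planted causal variants must lie inside the cis window of their element
    for (r in seq_len(nrow(design))) {
      el <- elements[elements$id == design$element[r], , drop = FALSE]
      cw <- cis_window(el, panel)
      if (!(design$variant[r] %in% cw$variant_ids)) {
        stop(sprintf("causal variant %s outside the cis window of %s",
                     design$variant[r], design$element[r]))
      }
    }
  }

  genetic <- matrix(0, ne, n, dimnames = list(elements$id, panel$samples$id))
  if (nrow(design) > 0) {
    for (r in seq_len(nrow(design))) {
      g <- panel$dosages[, design$variant[r]]
      genetic[design$element[r], ] <- genetic[design$element[r], ] +
        design$effect[r] * as.numeric(scale(g))
    }
  }

  factors <- NULL
  confound <- matrix(0, ne, n)
  if (n_hidden_factors > 0) {
    factors <- matrix(stats::rnorm(n * n_hidden_factors), n, n_hidden_factors)
    loadings <- matrix(stats::rnorm(ne * n_hidden_factors, sd = factor_sd),
                       ne, n_hidden_factors)
    confound <- loadings %*% t(factors)
  }

  polygenic <- matrix(0, ne, n)
  if (polygenic_sd > 0) {
    K <- raw_kinship(panel$dosages)
    ek <- eigen(K, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    Khalf <- ek$vectors %*% (sqrt(lam) * t(ek$vectors))
    polygenic <- polygenic_sd * (matrix(stats::rnorm(ne * n), ne, n) %*% Khalf)
  }

  noise <- matrix(stats::rnorm(ne * n, sd = noise_sd), ne, n)
  latent <- genetic + confound + polygenic + noise

  lib_mult <- exp(stats::rnorm(n, 0, libsize_sd))
  base <- stats::rnorm(ne, base_log_mean, 0.5)
  mu <- exp(sweep(0.5 * latent + base, 2, log(lib_mult), "+"))
  counts <- matrix(stats::rpois(ne * n, lambda = mu), ne, n,
                   dimnames = list(elements$id, panel$samples$id))

  phen <- structure(
    list(counts = counts, elements = elements,
         lib_sizes = as.integer(round(colSums(counts)))),
    class = "phenotype_set"
  )
  truth <- structure(
    list(design = design, latent = latent, factors = factors,
         genetic = genetic, lib_mult = lib_mult),
    class = "ground_truth"
  )
  list(phenotypes = phen, truth = truth)
}

# unstandardized helper used before QC/pruning machinery is available:
# GRM from all columns with nonzero variance
raw_kinship <- function(dosages) {
  sds <- apply(dosages, 2, stats::sd)
  Z <- scale(dosages[, sds > 0, drop = FALSE])
  tcrossprod(Z) / ncol(Z)
}

#' Simulate GWAS summary statistics for a variant region
#'
#' Z-scores are drawn from a multivariate normal with mean `sqrt(N) R b` and
#' covariance `R`, where `R` is the dosage correlation matrix of the region
#' in the reference panel and `b` the standardized joint effects. Standard
#' errors follow `se = 1/sqrt(2 N p (1-p))`, betas are `z * se` and p-values
#' come from the two-sided normal tail.
#'
#' @param panel reference `genotype_panel`.
#' @param region character vector of variant ids present in the panel.
#' @param joint_effects numeric vector of standardized joint effects, same
#'   length/order as `region` (or named by variant id).
#' @param n_gwas GWAS sample size N.
#' @param seed integer seed.
#' @param trait trait label.
#' @param ridge_eps ridge added to `R` when it is numerically singular; the
#'   regularization is reported via a message.
#' @return class `gwas_summary`: data.frame (variant, chrom, pos, beta, se,
#'   z, p, N) plus attributes `trait` and `R`.
#' @export
simulate_gwas_summary <- function(panel, region, joint_effects, n_gwas,
                                  seed = 1, trait = "trait1",
                                  ridge_eps = 1e-6) {
  if (!all(region %in% panel$variants$id)) {
    stop("region contains variants absent from the panel")
  }
  set.seed(as.integer(seed))
  G <- panel$dosages[, region, drop = FALSE]
  R <- stats::cor(G)
  b <- if (!is.null(names(joint_effects))) {
    out <- stats::setNames(numeric(length(region)), region)
    out[names(joint_effects)] <- joint_effects
    out
  } else {
    stopifnot(length(joint_effects) == length(region))
    joint_effects
  }

  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    R <- R + diag(ridge_eps, nrow(R))
    R <- stats::cov2cor(R)
    message(sprintf("LD matrix ill-conditioned; ridge epsilon %g applied", ridge_eps))
  }
  L <- chol(R)
  mu <- sqrt(n_gwas) * as.numeric(R %*% b)
  z <- mu + as.numeric(t(L) %*% stats::rnorm(length(region)))

  p_af <- colMeans(G) / 2
  se <- 1 / sqrt(2 * n_gwas * p_af * (1 - p_af))
  beta <- z * se
  pval <- 2 * stats::pnorm(-abs(z))
  idx <- match(region, panel$variants$id)
  out <- data.frame(
    variant = region,
    chrom = panel$variants$chrom[idx],
    pos = panel$variants$pos[idx],
    beta = beta, se = se, z = z, p = pval, N = n_gwas,
    stringsAsFactors = FALSE
  )
  attr(out, "trait") <- trait
  attr(out, "R") <- R
  class(out) <- c("gwas_summary", "data.frame")
  out
}
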