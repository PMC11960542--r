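#' Exact Hardy-Weinberg test on heterozygote counts
#'
#' Standard exact conditional test: given minor-allele count, enumerates all
#' possible heterozygote counts and sums the probabilities of configurations
#' no more probable than the observed one.
#'
#' @param n_het observed heterozygotes.
#' @param n_hom_rare observed rare-allele homozygotes.
#' @param n_hom_common observed common-allele homozygotes.
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2L * n_hom_rare + n_het
  if (n_rare > n) { # ensure "rare" really is the minor allele
    n_rare <- 2L * n - n_rare
  }
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  # P(h | n, n_rare) = n!/(hr! h! hc!) * 2^h * n_rare!(2n - n_rare)!/(2n)!
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - logsumexp(logp))
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(prob[prob <= obs + 1e-12]))
}

#' Variant quality control
#'
#' Retains variants in Hardy-Weinberg equilibrium (exact test p >
#' `hwe_p_min`), with call rate >= `call_rate_min` and minor allele
#' frequency > `maf_min`.
#'
#' @param panel a `genotype_panel`; dosages may contain `NA` for missing
#'   calls.
#' @param hwe_p_min,call_rate_min,maf_min thresholds.
#' @return character vector of retained variant ids.
#' @export
variant_qc <- function(panel, hwe_p_min = 1e-6, call_rate_min = 0.99,
                       maf_min = 0.05) {
  G <- panel$dosages
  n <- nrow(G)
  keep <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    called <- !is.na(g)
    if (mean(called) < call_rate_min) return(FALSE)
    g <- g[called]
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    if (maf <= maf_min) return(FALSE)
    n_het <- sum(g == 1)
    n_alt <- sum(g == 2)
    n_ref <- sum(g == 0)
    hwe_exact_test(n_het, min(n_ref, n_alt), max(n_ref, n_alt)) > hwe_p_min
  }, logical(1))
  panel$variants$id[keep]
}

#' Genetic relatedness (kinship) matrix
#'
#' `K = Z Z' / m` over LD-pruned, standardized dosage columns, clipped to
#' positive semi-definite by zeroing negative eigenvalues (a message reports
#' when clipping changes the matrix).
#'
#' @param panel a `genotype_panel`.
#' @param prune list of LD-pruning parameters (`window`, `step`,
#'   `r2_threshold`) or `NULL` to use all variants.
#' @return symmetric PSD samples x samples matrix.
#' @export
build_kinship <- function(panel, prune = list(window = 50, step = 5,
                                              r2_threshold = 0.2)) {
  ids <- if (is.null(prune)) {
    panel$variants$id
  } else {
    ld_prune(panel, window = prune$window, step = prune$step,
             r2_threshold = prune$r2_threshold)
  }
  if (length(ids) < 2) stop("fewer than 2 variants after pruning")
  G <- panel$dosages[, ids, drop = FALSE]
  sds <- apply(G, 2, stats::sd)
  Z <- scale(G[, sds > 0, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  if (any(ek$values < -1e-10)) {
    message("kinship clipped to PSD (", sum(ek$values < 0),
            " negative eigenvalues zeroed)")
    K <- ek$vectors %*% (pmax(ek$values, 0) * t(ek$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(panel$samples$id, panel$samples$id)
  K
}

# drop collinear columns of a design matrix (QR pivot), with a warning
drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(drop), " collinear covariate column(s)")
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Fit the null variance components of the kinship LMM
#'
#' Model: `y = C alpha + u + e`, `u ~ N(0, sigma_u^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`. The restricted likelihood is maximized over the
#' variance ratio `delta = sigma_e^2 / sigma_u^2` on a log grid followed by
#' golden-section refinement, after a one-off eigendecomposition of `K`
#' (the standard fast-LMM device: the rotated model is heteroscedastic OLS).
#'
#' @param y response vector.
#' @param covariates covariate matrix (an intercept is appended; may have 0
#'   columns).
#' @param K kinship matrix or a precomputed `eigen()` decomposition of it.
#' @param grid_points points on the log10-delta grid over \[1e-5, 1e5\].
#' @param tol golden-section tolerance on log10(delta).
#' @return list with `delta`, `sigma_u2`, `sigma_e2`, `loglik`, and the
#'   rotated quantities `yt`, `Ct`, `S` (eigenvalues), `U` (eigenvectors),
#'   for fast per-variant generalized least squares.
#' @export
null_variance_components <- function(y, covariates, K,
                                     grid_points = 100, tol = 1e-6) {
  if (any(!is.finite(y))) stop("non-finite response")
  ek <- if (is.list(K) && !is.null(K$vectors)) K else eigen(K, symmetric = TRUE)
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  C <- drop_collinear(C)
  p <- ncol(C)
  U <- ek$vectors
  S <- pmax(ek$values, 0)
  yt <- crossprod(U, y)
  Ct <- crossprod(U, C)

  reml_ll <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (S + delta)
    sw <- sqrt(w)
    Xw <- Ct * sw
    yw <- yt * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    ldetX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(S + delta)) + ldetX)
    if (!is.finite(ll)) stop("non-finite restricted likelihood")
    as.numeric(ll)
  }

  grid <- seq(-5, 5, length.out = grid_points)
  lls <- vapply(grid, reml_ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = tol)
  log10_delta <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  delta <- 10^log10_delta

  w <- 1 / (S + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Ct * sw, yt * sw)
  sigma_u2 <- sum(fit$residuals^2) / (n - p)
  list(delta = delta, sigma_u2 = sigma_u2, sigma_e2 = delta * sigma_u2,
       loglik = reml_ll(log10_delta),
       yt = as.numeric(yt), Ct = Ct, S = S, U = U, n = n, p = p)
}

#' Per-variant association scan by rotated GLS
#'
#' With the variance ratio fixed from the null fit, each candidate variant is
#' tested by appending its (rotated) genotypes to the design and computing
#' the Wald t-test; by Frisch-Waugh this reduces to OLS of the
#' weight-whitened, covariate-residualized response on the residualized
#' genotype.
#'
#' @param fit output of [null_variance_components()].
#' @param G samples x variants dosage matrix of candidates (unrotated).
#' @param extra_covariate_genotypes optional samples x k matrix of lead
#'   genotypes to condition on (e.g. for conditional scans). Note the null
#'   variance fit should normally include these; see [scan_element()].
#' @return data.frame (variant, beta, se, t, p); collinear variants get `NA`
#'   statistics.
#' @export
association_scan <- function(fit, G, extra_covariate_genotypes = NULL) {
  sw <- sqrt(1 / (fit$S + fit$delta))
  C <- fit$Ct
  if (!is.null(extra_covariate_genotypes)) {
    C <- cbind(C, crossprod(fit$U, extra_covariate_genotypes))
    C <- drop_collinear(C)
  }
  Xw <- C * sw
  yw <- fit$yt * sw
  Q <- qr.Q(qr(Xw))
  resid_y <- yw - Q %*% crossprod(Q, yw)
  Gt <- crossprod(fit$U, G) * sw
  resid_G <- Gt - Q %*% crossprod(Q, Gt)

  gss <- colSums(resid_G^2)
  gy <- as.numeric(crossprod(resid_G, resid_y))
  ok <- gss > 1e-10
  beta <- se <- tstat <- pval <- rep(NA_real_, ncol(G))
  df <- fit$n - ncol(C) - 1
  yss <- sum(resid_y^2)
  beta[ok] <- gy[ok] / gss[ok]
  rss <- pmax(yss - beta[ok]^2 * gss[ok], 0)
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2 / gss[ok])
  tstat[ok] <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(-abs(tstat[ok]), df)
  data.frame(variant = colnames(G), beta = beta, se = se, t = tstat,
             p = pval, stringsAsFactors = FALSE)
}

#' Element-level multiple-testing correction by effective tests
#'
#' Processes cis variants in consecutive chunks; per chunk the effective
#' number of tests is the smallest number of eigenvalues of the dosage
#' correlation matrix whose cumulative fraction reaches `var_threshold`. The
#' element's minimum nominal p-value is Bonferroni-corrected by the summed
#' effective test count.
#'
#' @param G samples x variants dosage matrix of the tested variants.
#' @param p_min minimum nominal p-value over the element's variants.
#' @param var_threshold cumulative eigenvalue fraction.
#' @param chunk chunk size.
#' @return list with `m_eff` and `corrected_p = min(1, p_min * m_eff)`.
#' @export
effective_tests_correction <- function(G, p_min, var_threshold = 0.99,
                                       chunk = 200) {
  m <- ncol(G)
  if (m == 0) stop("no tested variants")
  starts <- seq(1, m, by = chunk)
  m_eff <- 0L
  for (s in starts) {
    idx <- s:min(s + chunk - 1, m)
    X <- G[, idx, drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) next
    if (ncol(X) == 1) {
      m_eff <- m_eff + 1L
      next
    }
    ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    frac <- cumsum(ev) / sum(ev)
    m_eff <- m_eff + which(frac >= var_threshold)[1]
  }
  list(m_eff = as.integer(m_eff), corrected_p = min(1, p_min * m_eff))
}

#' Genome-wide FDR over lead variants
#'
#' Benjamini-Hochberg over the element-corrected p-values of the lead
#' variants (one per element per rank).
#'
#' @param records data.frame of lead QTL records with a `corrected_p` column.
#' @param alpha significance level on q.
#' @return `records` with `q` and `significant` columns appended.
#' @export
genomewide_fdr <- function(records, alpha = 0.05) {
  records$q <- stats::p.adjust(records$corrected_p, method = "BH")
  records$significant <- records$q < alpha
  records
}
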