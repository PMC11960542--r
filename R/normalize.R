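#' TMM normalization of a count matrix
#'
#' Trimmed-mean-of-M-values between-sample normalization. The reference
#' sample is the one whose 75th percentile of counts-per-million is closest
#' to the mean 75th percentile; per-sample factors are precision-weighted
#' means of log2 ratios after trimming 30% of M-values and 5% of A-values,
#' rescaled to geometric mean 1. Computation is delegated to
#' \code{edgeR::calcNormFactors}, the field-standard implementation.
#'
#' @param counts non-negative integer matrix, elements x samples (>= 2
#'   samples).
#' @param trim_m,trim_a trim fractions for M- and A-values.
#' @return list with `factors` (named per-sample normalization factors,
#'   geometric mean 1) and `tmm` (normalized abundance matrix: counts per
#'   million of the effective library sizes).
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (is.null(names(f)) && !is.null(colnames(counts))) names(f) <- colnames(counts)
  eff_lib <- lib * f
  tmm <- sweep(counts, 2, eff_lib / 1e6, "/")
  list(factors = f, tmm = tmm)
}

#' Filter expression elements by abundance and chromosome
#'
#' Retains autosomal genes with TPM >= 0.1 in at least 20% of samples and
#' raw count >= 6 in at least 20% of samples (all thresholds inclusive).
#'
#' @param tpm TPM matrix (genes x samples).
#' @param counts raw count matrix, conformable with `tpm`.
#' @param element_meta data.frame with at least `chrom`; rows align with the
#'   matrices. Chromosomes `"chrX"`/`"chrY"` (or `"X"`/`"Y"`) are treated as
#'   sex chromosomes.
#' @param min_tpm,min_count,min_fraction thresholds.
#' @return logical retained mask with attribute `"reason"` (character vector
#'   naming the first failed criterion for removed elements).
#' @export
filter_expression_elements <- function(tpm, counts, element_meta,
                                       min_tpm = 0.1, min_count = 6,
                                       min_fraction = 0.2) {
  stopifnot(all(dim(tpm) == dim(counts)), nrow(tpm) == nrow(element_meta))
  n <- ncol(tpm)
  autosomal <- !element_meta$chrom %in% c("chrX", "chrY", "X", "Y")
  tpm_ok <- rowSums(tpm >= min_tpm) >= min_fraction * n
  count_ok <- rowSums(counts >= min_count) >= min_fraction * n
  keep <- autosomal & tpm_ok & count_ok
  reason <- rep(NA_character_, nrow(tpm))
  reason[!autosomal] <- "sex_chromosome"
  reason[autosomal & !tpm_ok] <- "low_tpm"
  reason[autosomal & tpm_ok & !count_ok] <- "low_count"
  attr(keep, "reason") <- reason
  keep
}

#' Filter peak elements by TMM abundance and chromosome
#'
#' Removes peaks on sex chromosomes or with low abundance (TMM < 1 in at
#' least 20% of samples; the TMM threshold is strict).
#'
#' @param tmm_values TMM abundance matrix (peaks x samples).
#' @param element_meta data.frame with `chrom`, rows aligned.
#' @param min_fraction fraction of samples that triggers the low-abundance
#'   removal.
#' @return logical retained mask with attribute `"reason"`.
#' @export
filter_peak_elements <- function(tmm_values, element_meta, min_fraction = 0.2) {
  stopifnot(nrow(tmm_values) == nrow(element_meta))
  n <- ncol(tmm_values)
  autosomal <- !element_meta$chrom %in% c("chrX", "chrY", "X", "Y")
  low <- rowSums(tmm_values < 1) >= min_fraction * n
  keep <- autosomal & !low
  reason <- rep(NA_character_, nrow(tmm_values))
  reason[!autosomal] <- "sex_chromosome"
  reason[autosomal & low] <- "low_accessibility"
  attr(keep, "reason") <- reason
  keep
}

#' Rank-based inverse normal transform
#'
#' Maps a vector to normal quantiles via `qnorm((rank - 0.5)/n)` with average
#' ranks for ties, so the output is invariant to any strictly monotone
#' transform of the input.
#'
#' @param row numeric vector, length >= 3.
#' @return transformed numeric vector.
#' @export
inverse_normal_transform <- function(row) {
  if (length(row) < 3) stop("need at least 3 observations")
  if (length(unique(row)) == 1L) stop("constant row cannot be transformed")
  stats::qnorm((rank(row, ties.method = "average") - 0.5) / length(row))
}

#' Normalize a phenotype set for QTL mapping
#'
#' TMM-normalizes counts, applies the abundance filter for the phenotype
#' type, and inverse-normal transforms each retained element across samples.
#'
#' @param phenotypes a `phenotype_set` (see [simulate_phenotypes()]).
#' @return list: `values` (retained elements x samples INT matrix),
#'   `factors`, `tmm`, `mask` (logical with reasons), `elements` (retained
#'   element table).
#' @export
normalize_phenotypes <- function(phenotypes) {
  counts <- phenotypes$counts
  norm <- tmm_normalize(counts)
  type <- phenotypes$elements$type[1]
  mask <- if (type == "expression") {
    # synthetic elements have no transcript structure: TPM == CPM over a
    # unit-length gene model
    cpm <- sweep(counts, 2, colSums(counts) / 1e6, "/")
    filter_expression_elements(cpm, counts, phenotypes$elements)
  } else {
    filter_peak_elements(norm$tmm, phenotypes$elements)
  }
  kept <- norm$tmm[mask, , drop = FALSE]
  values <- t(apply(kept, 1, inverse_normal_transform))
  dimnames(values) <- dimnames(kept)
  list(values = values, factors = norm$factors, tmm = norm$tmm,
       mask = mask, elements = phenotypes$elements[mask, , drop = FALSE])
}

#' Greedy LD pruning of panel variants
#'
#' Sliding-window r-squared pruning in the style of plink
#' `--indep-pairwise`: within each window, one member of every pair with
#' r^2 above the threshold is removed (the later variant), then the window
#' slides by `step` variants.
#'
#' @param panel a `genotype_panel`.
#' @param window window size in variant count.
#' @param step slide in variant count.
#' @param r2_threshold pruning threshold.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(panel, window = 50, step = 5, r2_threshold = 0.2) {
  ids <- panel$variants$id
  keep <- rep(TRUE, length(ids))
  G <- panel$dosages
  start <- 1L
  while (start <= length(ids)) {
    idx <- seq(start, min(start + window - 1L, length(ids)))
    idx <- idx[keep[idx]]
    if (length(idx) > 1) {
      r2 <- stats::cor(G[, idx, drop = FALSE])^2
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_threshold) keep[idx[b]] <- FALSE
        }
      }
    }
    if (start + window - 1L >= length(ids)) break
    start <- start + step
  }
  ids[keep]
}

#' Genotype principal components
#'
#' LD-prunes the panel, standardizes dosages and returns the top left
#' singular vectors as ancestry covariates.
#'
#' @param panel a `genotype_panel`.
#' @param n_pcs number of components (0 returns a zero-column matrix).
#' @param prune_r2,window,step LD pruning parameters.
#' @return samples x `n_pcs` matrix of principal components (unit-norm
#'   columns scaled by singular values).
#' @export
genotype_pcs <- function(panel, n_pcs = 5, prune_r2 = 0.2,
                         window = 50, step = 5) {
  if (n_pcs == 0) {
    return(matrix(numeric(0), nrow(panel$dosages), 0,
                  dimnames = list(panel$samples$id, NULL)))
  }
  kept <- ld_prune(panel, window = window, step = step,
                   r2_threshold = prune_r2)
  G <- panel$dosages[, kept, drop = FALSE]
  sds <- apply(G, 2, stats::sd)
  Z <- scale(G[, sds > 0, drop = FALSE])
  sv <- svd(Z, nu = min(n_pcs, min(dim(Z))), nv = 0)
  if (n_pcs > length(sv$d)) stop("n_pcs exceeds the rank of the genotype matrix")
  pcs <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  pcs <- pcs[, seq_len(n_pcs), drop = FALSE]
  dimnames(pcs) <- list(panel$samples$id, paste0("PC", seq_len(n_pcs)))
  pcs
}

#' Hidden-factor covariates from normalized phenotypes
#'
#' Principal components of the row-centered normalized matrix restricted to
#' the 2,000 most variable elements, used as nuisance covariates in the QTL
#' model (a deterministic surrogate for latent-factor methods, which in
#' practice track sequencing depth and sample heterogeneity).
#'
#' @param normalized elements x samples numeric matrix (e.g. `values` from
#'   [normalize_phenotypes()]).
#' @param k number of factors (`k = 0` returns a zero-column matrix).
#' @param n_top number of most-variable elements used.
#' @return samples x k matrix with orthonormal columns.
#' @export
hidden_factors <- function(normalized, k, n_top = 2000) {
  n <- ncol(normalized)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0) {
    return(matrix(numeric(0), n, 0, dimnames = list(colnames(normalized), NULL)))
  }
  v <- apply(normalized, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(normalized)))]
  X <- normalized[top, , drop = FALSE]
  X <- X - rowMeans(X)
  sv <- svd(X, nu = 0, nv = k)
  fac <- sv$v
  dimnames(fac) <- list(colnames(normalized), paste0("Factor", seq_len(k)))
  fac
}

#' Choose the number of hidden factors by pilot QTL discovery
#'
#' Runs the primary cis-QTL scan on a random pilot subset of elements for
#' each candidate factor count and returns the smallest k that attains the
#' maximum number of significant elements.
#'
#' @param panel a `genotype_panel`.
#' @param normalized normalized phenotype list from [normalize_phenotypes()].
#' @param candidate_ks integer vector of candidate factor counts.
#' @param pilot_elements number of elements in the pilot subset.
#' @param seed integer seed for the pilot subsample.
#' @param covariates optional fixed covariate matrix added to every model.
#' @param ... passed to [map_qtls()].
#' @return list with `k` (chosen count) and `curve` (data.frame k,
#'   n_significant).
#' @export
optimize_factor_count <- function(panel, normalized, candidate_ks,
                                  pilot_elements = 100, seed = 1,
                                  covariates = NULL, ...) {
  if (length(candidate_ks) == 0) stop("candidate_ks must be non-empty")
  set.seed(as.integer(seed))
  ne <- nrow(normalized$values)
  pilot <- sort(sample.int(ne, min(pilot_elements, ne)))
  counts <- integer(length(candidate_ks))
  for (i in seq_along(candidate_ks)) {
    k <- candidate_ks[i]
    fac <- hidden_factors(normalized$values, k)
    covs <- cbind(covariates, fac)
    res <- map_qtls(panel,
                    values = normalized$values[pilot, , drop = FALSE],
                    elements = normalized$elements[pilot, , drop = FALSE],
                    covariates = covs, max_conditional = 0, ...)
    counts[i] <- sum(res$records$q < 0.05 & res$records$rank == "primary",
                     na.rm = TRUE)
  }
  best <- max(counts)
  chosen <- min(candidate_ks[counts == best])
  list(k = chosen, curve = data.frame(k = candidate_ks, n_significant = counts))
}
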