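#' Squared dosage correlation between two variants
#'
#' @param g1,g2 dosage vectors (0/1/2, `NA` allowed); only samples with both
#'   calls present are used (at least 10 required).
#' @return r-squared in \[0, 1\], or `NA` (with attribute `"reason"`) if
#'   either variant has zero variance over the shared samples.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 10) stop("fewer than 10 overlapping non-missing samples")
  g1 <- g1[ok]; g2 <- g2[ok]
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero_variance"
    return(out)
  }
  stats::cor(g1, g2)^2
}

#' Normalized LD coefficient D' from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by
#' expectation-maximization over the 3x3 genotype table (double
#' heterozygotes are phase-ambiguous); `D' = |p_AB - p_A p_B| / Dmax` with
#' the standard sign-dependent Dmax.
#'
#' @param g1,g2 dosage vectors; both variants must be polymorphic.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter maximum EM iterations.
#' @return D' in \[0, 1\].
#' @export
ld_dprime <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
    stop("both variants must be polymorphic")
  }
  est <- em_haplotype_freqs(g1, g2, tol = tol, max_iter = max_iter)
  dprime_from_freqs(est)
}

# EM estimate of the four haplotype frequencies (pAB, pAb, paB, pab),
# where "A"/"a" are the alt/ref alleles of variant 1 etc.
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  n <- length(g1)
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  # unambiguous haplotype counts contributed by each genotype cell
  # cell (i,j): i copies of allele A, j copies of allele B
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  add <- function(cnt, hap, k) { cnt[hap] <- cnt[hap] + k; cnt }
  fixed <- base
  for (i in 0:2) for (j in 0:2) {
    k <- tab[i + 1, j + 1]
    if (k == 0 || (i == 1 && j == 1)) next
    # each individual contributes two haplotypes with known phase
    nAB <- min(i, j); rest_i <- i - nAB; rest_j <- j - nAB
    # for non-double-het cells phase is determined:
    h <- c(AB = nAB, Ab = rest_i, aB = rest_j, ab = 2 - nAB - rest_i - rest_j)
    fixed <- fixed + k * h
  }
  n_dh <- tab[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  p <- rep(0.25, 4); names(p) <- names(base)
  for (it in seq_len(max_iter)) {
    denom <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
    w <- if (denom > 0) p["AB"] * p["ab"] / denom else 0.5
    counts <- fixed +
      n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    p_new <- counts / (2 * n)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("EM for haplotype frequencies did not converge (",
       max_iter, " iterations); counts: ",
       paste(as.integer(tab), collapse = ","))
}

dprime_from_freqs <- function(p) {
  pA <- p["AB"] + p["Ab"]; pB <- p["AB"] + p["aB"]
  D <- p["AB"] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(0)
  unname(min(1, abs(D) / dmax))
}

#' Same-signal QTL pairs
#'
#' Two primary QTLs in the same tissue share a genetic signal when their
#' lead variants are within `max_dist` bp on the same chromosome and in high
#' LD (r^2 strictly greater than `r2_min`) in the reference panel. Pairs
#' whose lead variants are absent from the panel are skipped.
#'
#' @param records primary QTL records (data.frame with element, tissue,
#'   variant, chrom, pos).
#' @param panel reference `genotype_panel`.
#' @param r2_min LD threshold (strict).
#' @param max_dist maximum lead-to-lead distance in bp.
#' @return data.frame of pairs (element1, element2, tissue, r2, dist).
#' @export
shared_qtl_pairs <- function(records, panel, r2_min = 0.8,
                             max_dist = 100000) {
  prim <- records[records$rank == "primary", , drop = FALSE]
  out <- list()
  for (tis in unique(prim$tissue)) {
    rt <- prim[prim$tissue == tis, , drop = FALSE]
    if (nrow(rt) < 2) next
    present <- rt$variant %in% panel$variants$id
    rt <- rt[present, , drop = FALSE]
    if (nrow(rt) < 2) next
    for (a in seq_len(nrow(rt) - 1)) {
      for (b in (a + 1):nrow(rt)) {
        if (rt$chrom[a] != rt$chrom[b]) next
        d <- abs(rt$pos[a] - rt$pos[b])
        if (d > max_dist) next
        r2 <- ld_r2(panel$dosages[, rt$variant[a]],
                    panel$dosages[, rt$variant[b]])
        if (!is.na(r2) && r2 > r2_min) {
          out[[length(out) + 1L]] <- data.frame(
            element1 = rt$element[a], element2 = rt$element[b],
            tissue = tis, r2 = r2, dist = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(element1 = character(), element2 = character(),
               tissue = character(), r2 = numeric(), dist = numeric())
}
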