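# shared scenario builders and independent oracle utilities

# small cohort with two families, used across module tests
small_panel <- function(seed = 11, n = 120, blocks = 12, per_block = 5) {
  simulate_genotype_panel(
    n_founder_haplotypes = 16, n_samples = n,
    family_spec = c(4, 4), n_blocks = blocks, variants_per_block = per_block,
    recomb_between_blocks = 0.3, maf_range = c(0.1, 0.5), seed = seed
  )
}

# panel of (nearly) independent variants: one variant per block, free recomb
independent_panel <- function(seed, n, m) {
  simulate_genotype_panel(
    n_founder_haplotypes = 32, n_samples = n, family_spec = integer(),
    n_blocks = m, variants_per_block = 1, recomb_between_blocks = 0.5,
    maf_range = c(0.2, 0.5), seed = seed
  )
}

# adjusted Rand index between two labelings (Hubert & Arabie closed form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# brute-force colocalization posteriors by explicit enumeration of causal
# configurations (independent of the log-space implementation)
enumerate_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(labf1)
  b1 <- exp(labf1)
  b2 <- exp(labf2)
  s0 <- 1
  s1 <- p1 * sum(b1)
  s2 <- p2 * sum(b2)
  s3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) s3 <- s3 + p1 * p2 * b1[i] * b2[j]
  }
  s4 <- p12 * sum(b1 * b2)
  tot <- s0 + s1 + s2 + s3 + s4
  c(PP.H0 = s0, PP.H1 = s1, PP.H2 = s2, PP.H3 = s3, PP.H4 = s4) / tot
}

# step-by-step TMM re-derivation (canonical trimmed weighted mean of
# M-values with precision weights), independent of edgeR
tmm_factor_oracle <- function(counts, ref_col, obs_col,
                              trim_m = 0.30, trim_a = 0.05) {
  nO <- sum(counts[, obs_col]); nR <- sum(counts[, ref_col])
  obs <- counts[, obs_col]; ref <- counts[, ref_col]
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

tmm_factors_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_factor_oracle(counts, ref, j, trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# independent EM iteration for two-locus haplotype frequencies, written as a
# direct translation of the E/M equations over the 9 genotype cells
em_oracle <- function(g1, g2, iters = 5000) {
  n <- length(g1)
  p <- c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25)
  for (it in seq_len(iters)) {
    cnt <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
    for (k in seq_len(n)) {
      i <- g1[k]; j <- g2[k]
      if (i == 1 && j == 1) {
        den <- p["AB"] * p["ab"] + p["Ab"] * p["aB"]
        w <- if (den > 0) p["AB"] * p["ab"] / den else 0.5
        cnt <- cnt + c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
      } else {
        nAB <- min(i, j)
        cnt["AB"] <- cnt["AB"] + nAB
        cnt["Ab"] <- cnt["Ab"] + (i - nAB)
        cnt["aB"] <- cnt["aB"] + (j - nAB)
        cnt["ab"] <- cnt["ab"] + (2 - nAB - (i - nAB) - (j - nAB))
      }
    }
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < 1e-13) return(p_new)
    p <- p_new
  }
  p
}

# Monte-Carlo oracle for the exact HWE test: random pairings of the allele
# pool into genotypes, estimating P(config at most as probable as observed)
hwe_mc_oracle <- function(n_het, n_hom_rare, n_hom_common, reps = 50000,
                          seed = 42) {
  set.seed(seed)
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2 * n_hom_rare + n_het
  alleles <- c(rep(1L, n_rare), rep(0L, 2 * n - n_rare))
  hets <- replicate(reps, {
    perm <- sample(alleles)
    g <- perm[seq(1, 2 * n, by = 2)] + perm[seq(2, 2 * n, by = 2)]
    sum(g == 1L)
  })
  obs_freq <- tabulate(hets + 1L, nbins = n_rare + 1L) / reps
  p_obs <- obs_freq[n_het + 1L]
  sum(obs_freq[obs_freq <= p_obs + 1e-9])
}
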