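#' Wakefield log approximate Bayes factor
#'
#' For a quantitative trait with effect estimate `beta`, sampling variance
#' `var_beta` and normal effect prior SD `W`:
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2` with `r = W^2/(W^2 + var_beta)`
#' and `z = beta / sqrt(var_beta)`.
#'
#' @param beta effect estimates.
#' @param var_beta squared standard errors (> 0).
#' @param W prior effect SD (default 0.15, the quantitative-trait default).
#' @return vector of log ABFs.
#' @export
wakefield_log_abf <- function(beta, var_beta, W = 0.15) {
  if (any(var_beta <= 0)) stop("var_beta must be positive")
  r <- W^2 / (W^2 + var_beta)
  z2 <- beta^2 / var_beta
  0.5 * log(1 - r) + z2 * r / 2
}

#' Colocalization posteriors under the single-causal-variant model
#'
#' Enumerates the five hypotheses (H0 no association; H1/H2 one trait only;
#' H3 two distinct causal variants; H4 one shared causal variant) from
#' per-variant log ABFs of the two traits, with all sums in log space.
#'
#' @param labf1,labf2 log ABF vectors aligned on the same variants.
#' @param p1,p2 prior probability a variant is causal for trait 1/2 only.
#' @param p12 prior probability a variant is causal for both.
#' @param variant_ids optional variant names.
#' @return list with `pp` (named numeric PP.H0..PP.H4 summing to 1) and
#'   `per_variant_h4` (posterior that each variant is the shared causal one,
#'   summing to 1).
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             variant_ids = NULL) {
  if (length(labf1) != length(labf2)) stop("log ABF vectors differ in length")
  if (length(labf1) < 1) stop("need at least one shared variant")
  lsum1 <- logsumexp(labf1)
  lsum2 <- logsumexp(labf2)
  lsum12 <- logsumexp(labf1 + labf2)
  lH0 <- 0
  lH1 <- log(p1) + lsum1
  lH2 <- log(p2) + lsum2
  # sum over i != j = (sum_i)(sum_j) - sum_i (ABF1_i ABF2_i)
  lH3 <- log(p1) + log(p2) + logdiff(lsum1 + lsum2, lsum12)
  lH4 <- log(p12) + lsum12
  lall <- c(H0 = lH0, H1 = lH1, H2 = lH2, H3 = lH3, H4 = lH4)
  denom <- logsumexp(lall)
  pp <- exp(lall - denom)
  names(pp) <- paste0("PP.", names(lall))
  pv <- exp((labf1 + labf2) - lsum12)
  if (!is.null(variant_ids)) names(pv) <- variant_ids
  list(pp = pp, per_variant_h4 = pv)
}

#' Colocalize one QTL with one GWAS trait
#'
#' Intersects variants, computes Wakefield ABFs for both traits, the five
#' posterior hypothesis probabilities, the per-variant shared-causal
#' probabilities, the lead candidate causal variant, and the acceptance
#' decision.
#'
#' @param qtl_stats per-variant QTL summary statistics (`variant`, `beta`,
#'   `se`, `p`, `pos`).
#' @param gwas `gwas_summary` data.frame (`variant`, `beta`, `se`, `p`).
#' @param W,p1,p2,p12 ABF and prior parameters.
#' @param ... decision thresholds passed to [colocalization_decision()].
#' @return list of class `colocalization_result`: `pp`, `per_variant_h4`,
#'   `n_variants`, `lead_candidate` (variant, probability, gwas_p, qtl_p,
#'   pos), `decision`.
#' @export
colocalize_qtl_gwas <- function(qtl_stats, gwas, W = 0.15,
                                p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, ...) {
  shared <- intersect(qtl_stats$variant, gwas$variant)
  q <- qtl_stats[match(shared, qtl_stats$variant), , drop = FALSE]
  g <- gwas[match(shared, gwas$variant), , drop = FALSE]
  ok <- !is.na(q$beta) & !is.na(g$beta)
  q <- q[ok, ]; g <- g[ok, ]
  if (nrow(q) == 0) stop("no shared variants with complete statistics")
  labf_q <- wakefield_log_abf(q$beta, q$se^2, W = W)
  labf_g <- wakefield_log_abf(g$beta, g$se^2, W = W)
  post <- coloc_posteriors(labf_q, labf_g, p1 = p1, p2 = p2, p12 = p12,
                           variant_ids = q$variant)
  lead_i <- which.max(post$per_variant_h4)
  res <- structure(list(
    pp = post$pp,
    per_variant_h4 = post$per_variant_h4,
    n_variants = nrow(q),
    lead_candidate = data.frame(
      variant = q$variant[lead_i],
      probability = unname(post$per_variant_h4[lead_i]),
      gwas_p = g$p[lead_i], qtl_p = q$p[lead_i],
      pos = if ("pos" %in% names(q)) q$pos[lead_i] else NA_integer_,
      stringsAsFactors = FALSE)
  ), class = "colocalization_result")
  res$decision <- colocalization_decision(res, ...)
  res
}

#' Acceptance decision for a colocalization
#'
#' A colocalization passes when all five criteria hold: at least
#' `min_variants` overlapping variants; PP.H4 at least `pp_h4_min`; the lead
#' candidate causal variant genome-wide significant for the GWAS
#' (`p <= gwas_p_max`) and for the QTL (`p <= qtl_p_max`); and lead
#' candidate posterior probability at least `lead_pp_min`. All bounds are
#' inclusive.
#'
#' @param result a `colocalization_result`.
#' @param min_variants,pp_h4_min,gwas_p_max,qtl_p_max,lead_pp_min thresholds.
#' @return list with `pass` (logical) and `criteria` (named logical vector:
#'   n_variants, pp_h4, gwas_p, qtl_p, lead_pp).
#' @export
colocalization_decision <- function(result, min_variants = 50,
                                    pp_h4_min = 0.80, gwas_p_max = 5e-8,
                                    qtl_p_max = 5e-5, lead_pp_min = 0.01) {
  crit <- c(
    n_variants = result$n_variants >= min_variants,
    pp_h4 = unname(result$pp["PP.H4"]) >= pp_h4_min,
    gwas_p = result$lead_candidate$gwas_p <= gwas_p_max,
    qtl_p = result$lead_candidate$qtl_p <= qtl_p_max,
    lead_pp = result$lead_candidate$probability >= lead_pp_min
  )
  list(pass = all(crit), criteria = crit,
       reasons = names(crit)[!crit])
}

#' 99% credible set from per-variant causal probabilities
#'
#' Variants are sorted by decreasing probability and included until the
#' cumulative mass first reaches `mass` (the crossing variant is included).
#' Sets of at most `high_conf_max` variants are flagged high-confidence.
#'
#' @param per_variant_probs named probability vector (sums to 1).
#' @param mass cumulative mass target.
#' @param high_conf_max maximum size of a high-confidence set.
#' @return list with `variants` (ordered ids), `probabilities`, `size`,
#'   `high_confidence`.
#' @export
credible_set <- function(per_variant_probs, mass = 0.99, high_conf_max = 25) {
  ord <- order(per_variant_probs, decreasing = TRUE)
  p <- per_variant_probs[ord]
  k <- unname(which(cumsum(p) >= mass - 1e-12)[1])
  if (is.na(k)) k <- length(p)
  list(variants = names(p)[seq_len(k)],
       probabilities = unname(p[seq_len(k)]),
       size = k,
       high_confidence = k <= high_conf_max)
}

#' Choose the representative member of a complex-QTL module
#'
#' Uniformly among members whose lead variant is present in the reference
#' panel; if none is present, uniformly among all members. Seeded for
#' reproducibility.
#'
#' @param module_records QTL records of the module's members.
#' @param panel reference `genotype_panel`.
#' @param seed integer seed.
#' @return the chosen member's record (one-row data.frame).
#' @export
select_complex_representative <- function(module_records, panel, seed = 1) {
  if (nrow(module_records) == 0) stop("empty module")
  present <- module_records$variant %in% panel$variants$id
  pool <- if (any(present)) which(present) else seq_len(nrow(module_records))
  pick <- withr::with_seed(as.integer(seed),
                           pool[sample.int(length(pool), 1)])
  module_records[pick, , drop = FALSE]
}

#' Define independent GWAS loci by sliding-window LD pruning
#'
#' Filters to genome-wide significant variants (`p < p_max`), then applies
#' greedy pruning: within each window of `window` variants, one member of
#' every pair with r^2 above `r2_max` is removed (the smaller-MAF member;
#' ties by later position), and the window slides by `step` variants.
#' Survivors are locus index variants.
#'
#' @param gwas `gwas_summary` data.frame.
#' @param panel reference `genotype_panel` for LD and MAF.
#' @param p_max genome-wide significance threshold.
#' @param window,step pruning window and step (variant counts).
#' @param r2_max pruning r-squared threshold.
#' @return data.frame of loci (locus, variant, chrom, pos, p).
#' @export
define_gwas_loci <- function(gwas, panel, p_max = 5e-8, window = 500,
                             step = 5, r2_max = 0.1) {
  sig <- gwas[gwas$p < p_max & gwas$variant %in% panel$variants$id, ,
              drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(locus = character(), variant = character(),
                      chrom = character(), pos = integer(), p = numeric()))
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  G <- panel$dosages[, sig$variant, drop = FALSE]
  maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  keep <- rep(TRUE, nrow(sig))
  start <- 1L
  repeat {
    idx <- seq(start, min(start + window - 1L, nrow(sig)))
    live <- idx[keep[idx]]
    if (length(live) > 1) {
      repeat {
        removed <- FALSE
        for (a in seq_along(live)) {
          for (b in seq_along(live)) {
            if (b <= a) next
            ia <- live[a]; ib <- live[b]
            if (!keep[ia] || !keep[ib]) next
            r2 <- suppressWarnings(stats::cor(G[, ia], G[, ib])^2)
            if (!is.na(r2) && r2 > r2_max) {
              # drop the smaller-MAF member; ties broken by later position
              drop <- if (maf[ia] < maf[ib]) ia
                      else if (maf[ib] < maf[ia]) ib
                      else max(ia, ib)
              keep[drop] <- FALSE
              removed <- TRUE
            }
          }
        }
        live <- idx[keep[idx]]
        if (!removed || length(live) < 2) break
      }
    }
    if (start + window - 1L >= nrow(sig)) break
    start <- start + step
  }
  out <- sig[keep, c("variant", "chrom", "pos", "p")]
  out$locus <- sprintf("locus%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus", "variant", "chrom", "pos", "p")]
}

#' Assign passing colocalizations to GWAS loci
#'
#' A QTL colocalization is assigned to a locus when its lead candidate
#' causal variant is within `max_dist` bp of, and in LD (r^2 >= `r2_min`)
#' with, the locus index variant. Lead candidates absent from the panel are
#' assigned to the nearest locus by base-pair distance.
#'
#' @param colocs data.frame with one row per passing colocalization:
#'   `qtl_id`, `lead_variant`, `lead_pos`, `chrom`.
#' @param loci locus table from [define_gwas_loci()].
#' @param panel reference `genotype_panel`.
#' @param r2_min,max_dist assignment thresholds.
#' @return `colocs` with `locus` column (NA when unassignable).
#' @export
assign_colocalizations_to_loci <- function(colocs, loci, panel,
                                           r2_min = 0.7, max_dist = 350000) {
  colocs$locus <- NA_character_
  for (i in seq_len(nrow(colocs))) {
    v <- colocs$lead_variant[i]
    if (v %in% panel$variants$id) {
      g <- panel$dosages[, v]
      for (j in order(abs(loci$pos - colocs$lead_pos[i]))) {
        if (loci$chrom[j] != colocs$chrom[i]) next
        if (abs(loci$pos[j] - colocs$lead_pos[i]) > max_dist) break
        if (!loci$variant[j] %in% panel$variants$id) next
        r2 <- ld_r2(g, panel$dosages[, loci$variant[j]])
        if (!is.na(r2) && r2 >= r2_min) {
          colocs$locus[i] <- loci$locus[j]
          break
        }
      }
    } else {
      same_chrom <- loci[loci$chrom == colocs$chrom[i], , drop = FALSE]
      if (nrow(same_chrom) > 0) {
        j <- which.min(abs(same_chrom$pos - colocs$lead_pos[i]))
        colocs$locus[i] <- same_chrom$locus[j]
      }
    }
  }
  colocs
}
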