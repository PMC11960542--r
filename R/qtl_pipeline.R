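#' Build a QTL mapping context
#'
#' Performs variant QC, builds (or accepts) the kinship matrix and
#' eigendecomposes it once, so per-element model fits are fast.
#'
#' @param panel a `genotype_panel`.
#' @param values normalized phenotype matrix (elements x samples).
#' @param elements element table aligned with `values` rows.
#' @param covariates optional samples x p covariate matrix.
#' @param kinship optional precomputed kinship matrix; `"identity"` requests
#'   an identity matrix (no relatedness correction); `NULL` builds one from
#'   the QC-passing variants.
#' @param qc run [variant_qc()] (default TRUE).
#' @param exclude_intervals optional data.frame of excluded intervals
#'   (`chrom`, `start`, `end`), e.g. the MHC region on real data.
#' @return list of class `qtl_context`.
#' @export
qtl_context <- function(panel, values, elements, covariates = NULL,
                        kinship = NULL, qc = TRUE, exclude_intervals = NULL) {
  keep <- if (qc) variant_qc(panel) else panel$variants$id
  panel_qc <- subset_panel(panel, variants = keep)
  K <- if (is.null(kinship)) {
    build_kinship(panel_qc)
  } else if (identical(kinship, "identity")) {
    diag(nrow(panel_qc$dosages))
  } else {
    kinship
  }
  structure(list(
    panel = panel_qc, values = values, elements = elements,
    covariates = covariates, Keig = eigen(K, symmetric = TRUE),
    exclude_intervals = exclude_intervals
  ), class = "qtl_context")
}

#' Scan one element's cis window
#'
#' Fits the null LMM (with any conditioning genotypes as fixed covariates),
#' runs the per-variant association scan, applies the effective-tests
#' correction, and picks the lead variant (minimum corrected p, ties broken
#' by largest absolute effect size).
#'
#' @param ctx a `qtl_context`.
#' @param element_id element to scan.
#' @param condition_on character vector of variant ids to condition on.
#' @param window optional cis half-width override.
#' @return list with `stats` (per-variant data.frame with corrected p),
#'   `lead` (one-row data.frame), `m_eff`; or `NULL` if the element has no
#'   testable cis variants or is excluded.
#' @export
scan_element <- function(ctx, element_id, condition_on = character(),
                         window = NULL) {
  el <- ctx$elements[ctx$elements$id == element_id, , drop = FALSE]
  if (nrow(el) != 1) stop("unknown element: ", element_id)
  cw <- cis_window(el, ctx$panel, window = window,
                   exclude_intervals = ctx$exclude_intervals)
  if (is.null(cw) || length(cw$variant_ids) == 0) return(NULL)
  y <- ctx$values[element_id, ]
  G <- ctx$panel$dosages[, cw$variant_ids, drop = FALSE]
  covs <- ctx$covariates
  if (length(condition_on) > 0) {
    covs <- cbind(covs, ctx$panel$dosages[, condition_on, drop = FALSE])
    G <- G[, setdiff(colnames(G), condition_on), drop = FALSE]
    if (ncol(G) == 0) return(NULL)
  }
  fit <- null_variance_components(y, covs, ctx$Keig)
  st <- association_scan(fit, G)
  tested <- !is.na(st$p)
  if (!any(tested)) return(NULL)
  corr <- effective_tests_correction(G[, tested, drop = FALSE],
                                     p_min = min(st$p[tested]))
  st$corrected_p <- pmin(1, st$p * corr$m_eff)
  cand <- st[tested, ]
  best <- cand[cand$corrected_p == min(cand$corrected_p), , drop = FALSE]
  if (nrow(best) > 1) best <- best[which.max(abs(best$beta)), , drop = FALSE]
  lead <- best[1, , drop = FALSE]
  vi <- match(lead$variant, ctx$panel$variants$id)
  lead$chrom <- ctx$panel$variants$chrom[vi]
  lead$pos <- ctx$panel$variants$pos[vi]
  list(stats = st, lead = lead, m_eff = corr$m_eff)
}

new_qtl_record <- function(el, lead, rank, regressed = FALSE) {
  data.frame(
    element = el$id, tissue = el$tissue, type = el$type, rank = rank,
    variant = lead$variant, chrom = lead$chrom, pos = lead$pos,
    beta = lead$beta, se = lead$se, p = lead$p,
    corrected_p = lead$corrected_p, q = NA_real_, significant = NA,
    regressed = regressed, status = "kept", stringsAsFactors = FALSE
  )
}

#' Two-step cis-QTL mapping with conditional discovery
#'
#' Step-1 discovery: for every element, the kinship LMM scan is run over the
#' cis window; the minimum p is corrected for the effective number of tests,
#' and lead variants are FDR-corrected genome-wide (Benjamini-Hochberg,
#' q < 0.05). For significant elements, stepwise conditional scans (up to
#' `max_conditional`) add previously found leads as fixed covariates, with
#' the same two-step correction per iteration over all elements still in
#' play.
#'
#' @inheritParams qtl_context
#' @param max_conditional maximum number of conditional signals per element.
#' @param alpha genome-wide q-value significance threshold.
#' @param window optional cis half-width override (bp).
#' @return list with `records` (all lead QTL records, primary + conditional)
#'   and `context` (the `qtl_context`, for downstream filtering/regression).
#' @export
map_qtls <- function(panel, values, elements, covariates = NULL,
                     kinship = NULL, qc = TRUE, exclude_intervals = NULL,
                     max_conditional = 3, alpha = 0.05, window = NULL) {
  ctx <- qtl_context(panel, values, elements, covariates = covariates,
                     kinship = kinship, qc = qc,
                     exclude_intervals = exclude_intervals)
  primaries <- list()
  for (eid in elements$id) {
    sc <- scan_element(ctx, eid, window = window)
    if (is.null(sc)) next
    el <- elements[elements$id == eid, ]
    primaries[[eid]] <- new_qtl_record(el, sc$lead, "primary")
  }
  if (length(primaries) == 0) {
    return(list(records = empty_qtl_records(), context = ctx))
  }
  recs <- genomewide_fdr(do.call(rbind, primaries), alpha = alpha)
  all_records <- list(recs)

  active <- recs$element[recs$significant]
  leads <- stats::setNames(as.list(recs$variant), recs$element)
  if (max_conditional > 0 && length(active) > 0) {
    for (step in seq_len(max_conditional)) {
      cond <- list()
      for (eid in active) {
        sc <- scan_element(ctx, eid, condition_on = unlist(leads[[eid]]),
                           window = window)
        if (is.null(sc)) next
        el <- elements[elements$id == eid, ]
        cond[[eid]] <- new_qtl_record(el, sc$lead,
                                      paste0("conditional", step))
      }
      if (length(cond) == 0) break
      crecs <- genomewide_fdr(do.call(rbind, cond), alpha = alpha)
      sig <- crecs[crecs$significant, , drop = FALSE]
      if (nrow(sig) == 0) break
      all_records[[length(all_records) + 1L]] <- sig
      for (i in seq_len(nrow(sig))) {
        eid <- sig$element[i]
        leads[[eid]] <- c(unlist(leads[[eid]]), sig$variant[i])
      }
      active <- sig$element
    }
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  list(records = records, context = ctx)
}

empty_qtl_records <- function() {
  data.frame(element = character(), tissue = character(), type = character(),
             rank = character(), variant = character(), chrom = character(),
             pos = integer(), beta = numeric(), se = numeric(), p = numeric(),
             corrected_p = numeric(), q = numeric(), significant = logical(),
             regressed = logical(), status = character(),
             stringsAsFactors = FALSE)
}

#' Filter conditional QTLs in LD with their primary signal
#'
#' Applies the post-discovery filtering ledger against a reference panel:
#' (a) conditional leads absent from the panel are removed;
#' (b) if the primary lead is absent, the primary is kept but all its
#' conditionals are removed; (c) conditional leads with r^2 >= 0.8 or
#' D' >= 0.8 to the primary lead are removed; (d) monomorphic-in-panel
#' primary leads drop their conditionals, monomorphic conditional leads are
#' dropped; (e) survivors are renumbered sequentially. Every removal is
#' recorded with a reason code.
#'
#' @param records QTL record data.frame (significant primaries +
#'   conditionals, as from [map_qtls()]).
#' @param reference_panel a `genotype_panel` used for LD.
#' @param r2_threshold,dprime_threshold LD thresholds.
#' @return list with `records` (filtered, renumbered) and `ledger`
#'   (data.frame element, rank, variant, reason).
#' @export
filter_conditional_qtls <- function(records, reference_panel,
                                    r2_threshold = 0.8,
                                    dprime_threshold = 0.8) {
  in_panel <- function(v) v %in% reference_panel$variants$id
  monomorphic <- function(v) {
    g <- reference_panel$dosages[, v]
    length(unique(g)) == 1L
  }
  ledger <- list()
  drop_idx <- logical(nrow(records))
  is_cond <- grepl("^conditional", records$rank)

  for (el in unique(records$element)) {
    pi <- which(records$element == el & records$rank == "primary")
    ci <- which(records$element == el & is_cond)
    if (length(ci) == 0) next
    # (a) conditional leads must be present in the reference panel
    for (i in ci) {
      if (!in_panel(records$variant[i])) {
        drop_idx[i] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          element = el, rank = records$rank[i], variant = records$variant[i],
          reason = "conditional_absent_from_panel")
      }
    }
    ci <- ci[!drop_idx[ci]]
    if (length(ci) == 0) next
    pvar <- records$variant[pi]
    # (b) primary lead absent: keep primary, drop all conditionals
    if (length(pi) == 1 && !in_panel(pvar)) {
      for (i in ci) {
        drop_idx[i] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          element = el, rank = records$rank[i], variant = records$variant[i],
          reason = "primary_absent_from_panel")
      }
      next
    }
    # (d) monomorphic leads in the panel
    if (monomorphic(pvar)) {
      for (i in ci) {
        drop_idx[i] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          element = el, rank = records$rank[i], variant = records$variant[i],
          reason = "monomorphic_primary")
      }
      next
    }
    for (i in ci) {
      if (monomorphic(records$variant[i])) {
        drop_idx[i] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          element = el, rank = records$rank[i], variant = records$variant[i],
          reason = "monomorphic_conditional")
      }
    }
    ci <- ci[!drop_idx[ci]]
    # (c) LD with the primary lead: r^2 and/or D'
    g_primary <- reference_panel$dosages[, pvar]
    for (i in ci) {
      g_cond <- reference_panel$dosages[, records$variant[i]]
      r2 <- ld_r2(g_primary, g_cond)
      dp <- ld_dprime(g_primary, g_cond)
      if ((!is.na(r2) && r2 >= r2_threshold) ||
          (!is.na(dp) && dp >= dprime_threshold)) {
        drop_idx[i] <- TRUE
        ledger[[length(ledger) + 1L]] <- data.frame(
          element = el, rank = records$rank[i], variant = records$variant[i],
          reason = "ld_with_primary")
      }
    }
  }

  kept <- records[!drop_idx, , drop = FALSE]
  # (e) renumber surviving conditionals sequentially per element
  for (el in unique(kept$element)) {
    ci <- which(kept$element == el & grepl("^conditional", kept$rank))
    if (length(ci) == 0) next
    ord <- order(as.integer(sub("conditional", "", kept$rank[ci])))
    kept$rank[ci[ord]] <- paste0("conditional", seq_along(ci))
  }
  rownames(kept) <- NULL
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(element = character(), rank = character(),
               variant = character(), reason = character())
  list(records = kept, ledger = ledger)
}

#' Regress conditional signals out of primary QTLs
#'
#' For every element with at least one surviving conditional QTL, the primary
#' scan is re-run with the conditional lead genotypes as fixed covariates and
#' the lead is reassigned (minimum corrected p, |beta| tie-break); the record
#' is flagged `regressed`. Elements without conditionals pass through
#' unchanged.
#'
#' @param ctx the `qtl_context` from [map_qtls()].
#' @param records filtered QTL records (see [filter_conditional_qtls()]).
#' @param window optional cis half-width override.
#' @return `records` with regressed primary summary statistics substituted.
#' @export
regress_primary_signal <- function(ctx, records, window = NULL) {
  is_cond <- grepl("^conditional", records$rank)
  for (el in unique(records$element)) {
    ci <- which(records$element == el & is_cond)
    if (length(ci) == 0) next
    pi <- which(records$element == el & records$rank == "primary")
    if (length(pi) != 1) next
    sc <- scan_element(ctx, el, condition_on = records$variant[ci],
                       window = window)
    if (is.null(sc)) next
    records$variant[pi] <- sc$lead$variant
    records$chrom[pi] <- sc$lead$chrom
    records$pos[pi] <- sc$lead$pos
    records$beta[pi] <- sc$lead$beta
    records$se[pi] <- sc$lead$se
    records$p[pi] <- sc$lead$p
    records$corrected_p[pi] <- sc$lead$corrected_p
    records$regressed[pi] <- TRUE
  }
  records
}

#' Full per-variant summary statistics for one (possibly regressed) QTL
#'
#' Convenience wrapper used for colocalization: returns the per-variant
#' betas, standard errors and p-values of an element's cis scan, conditioning
#' on any surviving conditional lead variants.
#'
#' @param ctx a `qtl_context`.
#' @param element_id element to scan.
#' @param condition_on conditional lead variant ids (possibly empty).
#' @param window optional cis half-width override.
#' @return per-variant data.frame with `variant`, `beta`, `se`, `p`, `chrom`,
#'   `pos`.
#' @export
qtl_summary_stats <- function(ctx, element_id, condition_on = character(),
                              window = NULL) {
  sc <- scan_element(ctx, element_id, condition_on = condition_on,
                     window = window)
  if (is.null(sc)) return(NULL)
  st <- sc$stats
  vi <- match(st$variant, ctx$panel$variants$id)
  st$chrom <- ctx$panel$variants$chrom[vi]
  st$pos <- ctx$panel$variants$pos[vi]
  st
}
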