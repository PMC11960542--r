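#' Classify a SNP-eGene pair as temporally specific or shared
#'
#' A pair is early-developmental (EDev)-specific when its minimum local
#' false sign rate (LFSR) over EDev tissues is below `alpha` and its minimum
#' over adult tissues is not; adult-specific in the reverse case; shared
#' when both minima are below `alpha`; dropped when no tissue is significant.
#' LFSR exactly equal to `alpha` counts as not significant.
#'
#' @param lfsr_row named numeric vector of LFSRs (missing = untested).
#' @param tissue_stage named character vector mapping tissue to
#'   `"EDev"`/`"adult"`.
#' @param alpha significance threshold.
#' @return one of `"EDev-specific"`, `"adult-specific"`, `"shared"`,
#'   `"dropped"`.
#' @export
classify_temporal <- function(lfsr_row, tissue_stage, alpha = 0.05) {
  if (all(is.na(lfsr_row))) stop("all LFSR entries missing")
  stages <- tissue_stage[names(lfsr_row)]
  ed <- lfsr_row[stages == "EDev"]
  ad <- lfsr_row[stages == "adult"]
  if (all(is.na(ed)) || all(is.na(ad))) {
    stop("pair must be tested in at least one EDev and one adult tissue")
  }
  ed_sig <- min(ed, na.rm = TRUE) < alpha
  ad_sig <- min(ad, na.rm = TRUE) < alpha
  if (ed_sig && ad_sig) "shared"
  else if (ed_sig) "EDev-specific"
  else if (ad_sig) "adult-specific"
  else "dropped"
}

#' Classify every row of an LFSR matrix
#'
#' @param lfsr pairs x tissues LFSR matrix.
#' @param tissue_stage named stage vector (see [classify_temporal()]).
#' @param alpha significance threshold.
#' @return character vector of classes, named by pair.
#' @export
classify_temporal_matrix <- function(lfsr, tissue_stage, alpha = 0.05) {
  out <- apply(lfsr, 1, classify_temporal, tissue_stage = tissue_stage,
               alpha = alpha)
  stats::setNames(as.character(out), rownames(lfsr))
}

#' Annotate cohort eQTLs with temporal classes
#'
#' Maps pair-level classes onto the cohort's eQTLs: EDev-specific stays
#' EDev-specific, shared becomes Shared, and adult-specific, dropped,
#' class-inconsistent (the eQTL's own discovery tissue is not among the
#' significant EDev tissues) or unmatched pairs become "No Association".
#'
#' @param classes named character vector of pair classes (names are pair
#'   ids, e.g. `"<variant>:<gene>"`).
#' @param eqtls data.frame of cohort primary eQTLs with columns `pair`
#'   (matching `classes` names) and `tissue`.
#' @param sig_edev_tissues optional list mapping pair id to the character
#'   vector of EDev tissues where the pair is significant; when supplied, an
#'   eQTL whose discovery tissue is not in its pair's set is "No
#'   Association".
#' @return character vector (per eQTL) in
#'   `{"EDev-specific", "Shared", "No Association"}` with attribute
#'   `"reason"` for No Association calls.
#' @export
annotate_cohort_eqtls <- function(classes, eqtls, sig_edev_tissues = NULL) {
  out <- character(nrow(eqtls))
  reason <- rep(NA_character_, nrow(eqtls))
  for (i in seq_len(nrow(eqtls))) {
    cls <- classes[eqtls$pair[i]]
    if (is.na(cls)) {
      out[i] <- "No Association"; reason[i] <- "unmatched"
      next
    }
    if (!is.null(sig_edev_tissues)) {
      sig <- sig_edev_tissues[[eqtls$pair[i]]]
      if (cls %in% c("EDev-specific", "shared") &&
          !(eqtls$tissue[i] %in% sig)) {
        out[i] <- "No Association"; reason[i] <- "discovery_tissue_not_significant"
        next
      }
    }
    out[i] <- switch(cls,
      "EDev-specific" = "EDev-specific",
      "shared" = "Shared",
      "adult-specific" = ,
      "dropped" = "No Association")
    if (out[i] == "No Association") reason[i] <- cls
  }
  attr(out, "reason") <- reason
  out
}

#' Propagate temporal annotations through complex-QTL modules
#'
#' Members of a complex QTL share one genetic signal, so their temporal
#' annotations are reconciled: (1) if any member is "No Association", all
#' members become "No Association"; (2) otherwise a mix of "EDev-specific"
#' and "Shared" becomes all "Shared"; (3) a unanimous class is retained.
#' The operation is idempotent.
#'
#' @param annotations named character vector (element id ->
#'   `"EDev-specific"`/`"Shared"`/`"No Association"`).
#' @param modules module membership data.frame (`module`, `element`) as from
#'   [detect_complex_modules()]; elements without annotations are ignored.
#' @return reconciled named character vector.
#' @export
propagate_complex_annotation <- function(annotations, modules) {
  for (m in unique(modules$module)) {
    members <- intersect(modules$element[modules$module == m],
                         names(annotations))
    if (length(members) < 2) next
    cls <- annotations[members]
    if (any(cls == "No Association")) {
      annotations[members] <- "No Association"
    } else if (any(cls == "EDev-specific") && any(cls == "Shared")) {
      annotations[members] <- "Shared"
    }
  }
  annotations
}

#' Effect-size correlation between tissue stages, by annotation group
#'
#' For each (EDev tissue, adult tissue) combination and each group of pairs,
#' computes the squared Pearson correlation of effect sizes, and compares
#' groups by two-sided t-tests on their r-squared distributions.
#'
#' @param betas pairs x tissues matrix of effect sizes.
#' @param tissue_stage named stage vector.
#' @param groups character vector (per pair) of group labels.
#' @param min_pairs minimum pairs per cell.
#' @return list with `r2` (data.frame edev_tissue, adult_tissue, group, r2,
#'   n) and `tests` (data.frame group1, group2, t, p).
#' @export
effectsize_correlation_by_group <- function(betas, tissue_stage, groups,
                                            min_pairs = 10) {
  ed <- names(tissue_stage)[tissue_stage == "EDev"]
  ad <- names(tissue_stage)[tissue_stage == "adult"]
  rows <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    for (te in ed) for (ta in ad) {
      x <- betas[sel, te]; y <- betas[sel, ta]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_pairs) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        edev_tissue = te, adult_tissue = ta, group = g,
        r2 = stats::cor(x[ok], y[ok])^2, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  r2 <- if (length(rows)) do.call(rbind, rows) else
    data.frame(edev_tissue = character(), adult_tissue = character(),
               group = character(), r2 = numeric(), n = integer())
  tests <- list()
  gs <- unique(r2$group)
  if (length(gs) > 1) {
    for (a in seq_along(gs)[-length(gs)]) for (b in (a + 1):length(gs)) {
      xa <- r2$r2[r2$group == gs[a]]
      xb <- r2$r2[r2$group == gs[b]]
      if (length(xa) > 1 && length(xb) > 1) {
        tt <- stats::t.test(xa, xb)
        tests[[length(tests) + 1L]] <- data.frame(
          group1 = gs[a], group2 = gs[b],
          t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(group1 = character(), group2 = character(), t = numeric(),
               p = numeric())
  list(r2 = r2, tests = tests)
}
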