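#' Two-sided Fisher exact enrichment of a 2x2 table
#'
#' The two-sided exact p-value sums hypergeometric probabilities no larger
#' than the observed configuration (stats::fisher.test). The odds ratio
#' reported is the sample OR `(a d)/(b c)`; when any cell is zero, 0.5 is
#' added to all cells (Haldane-Anscombe continuity, flagged). The 95% CI on
#' the log odds is the Woolf logit interval.
#'
#' @param table 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise:
#'   rows = in-category yes/no, columns = outcome yes/no.
#' @return list of class `enrichment_result`: `table`, `odds_ratio`, `p`,
#'   `ci_low`, `ci_high`, `continuity` (logical).
#' @export
fisher_enrichment <- function(table) {
  m <- matrix(as.numeric(table), 2, 2, byrow = is.null(dim(table)))
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(m)$p.value
  cont <- any(m == 0)
  mc <- if (cont) m + 0.5 else m
  or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
  se_log <- sqrt(sum(1 / mc))
  structure(list(
    table = m,
    odds_ratio = if (degenerate) NA_real_ else or,
    p = p,
    ci_low = exp(log(or) - 1.96 * se_log),
    ci_high = exp(log(or) + 1.96 * se_log),
    continuity = cont
  ), class = "enrichment_result")
}

chromatin_state_vocabulary <- function() {
  c("TssA", "TssBiv", "TssFlnkU", "TssFlnkD", "TssFlnk",
    "EnhA1", "EnhA2", "EnhG1", "EnG2", "EnhG2", "EnhWk", "EnhBiv",
    "ReprPC", "ReprPCWk", "Het", "ZNF/Rpts",
    "Tx", "TxWk", "Quies")
}

#' Collapse 18 chromatin states into 5 categories
#'
#' Promoter (TssA, TssBiv, TssFlnkU, TssFlnkD, TssFlnk); Enhancer (EnhA1,
#' EnhA2, EnhG1, EnG2/EnhG2, EnhWk, EnhBiv); Repressed (ReprPC, ReprPCWk,
#' Het, ZNF/Rpts); Transcribed (Tx, TxWk); Quiescent (Quies). Both the
#' `EnG2` and `EnhG2` spellings of the genic enhancer state are accepted.
#'
#' @param states character vector of state labels.
#' @return character vector of collapsed categories.
#' @export
collapse_chromatin_states <- function(states) {
  map <- c(
    TssA = "Promoter", TssBiv = "Promoter", TssFlnkU = "Promoter",
    TssFlnkD = "Promoter", TssFlnk = "Promoter",
    EnhA1 = "Enhancer", EnhA2 = "Enhancer", EnhG1 = "Enhancer",
    EnG2 = "Enhancer", EnhG2 = "Enhancer", EnhWk = "Enhancer",
    EnhBiv = "Enhancer",
    ReprPC = "Repressed", ReprPCWk = "Repressed", Het = "Repressed",
    `ZNF/Rpts` = "Repressed",
    Tx = "Transcribed", TxWk = "Transcribed",
    Quies = "Quiescent"
  )
  unknown <- setdiff(states, names(map))
  if (length(unknown)) stop("unknown chromatin state(s): ",
                            paste(unknown, collapse = ", "))
  unname(map[states])
}

#' Chromatin-state enrichment of significant QTL lead variants
#'
#' Per collapsed state (and phenotype, if several are supplied), tests the
#' overlap of significant-element lead variants against the lead variants of
#' non-significant elements as background, with Benjamini-Hochberg
#' correction across all tests.
#'
#' @param fg_states collapsed state per significant ("foreground") lead.
#' @param bg_states collapsed state per background lead.
#' @param fg_pheno,bg_pheno optional phenotype labels per lead.
#' @return data.frame (phenotype, state, a, b, c, d, odds_ratio, p, p_adj).
#' @export
lead_variant_state_enrichment <- function(fg_states, bg_states,
                                          fg_pheno = NULL, bg_pheno = NULL) {
  if (is.null(fg_pheno)) fg_pheno <- rep("all", length(fg_states))
  if (is.null(bg_pheno)) bg_pheno <- rep("all", length(bg_states))
  rows <- list()
  for (ph in unique(fg_pheno)) {
    fg <- fg_states[fg_pheno == ph]
    bg <- bg_states[bg_pheno == ph]
    for (st in sort(unique(c(fg, bg)))) {
      a <- sum(fg == st); b <- sum(fg != st)
      cc <- sum(bg == st); d <- sum(bg != st)
      fr <- fisher_enrichment(c(a, b, cc, d))
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, state = st, a = a, b = b, c = cc, d = d,
        odds_ratio = fr$odds_ratio, p = fr$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Enrichment of caPeaks upstream of eGenes
#'
#' Fisher test of "gene has >= 1 caPeak in its strand-aware upstream window"
#' against eGene status. Upstream of a minus-strand gene extends to the
#' right of its TSS.
#'
#' @param genes data.frame (`id`, `chrom`, `strand`, `tss`).
#' @param is_egene logical per gene.
#' @param ca_peaks peak table (`chrom`, `start`, `end`), 0-based half-open.
#' @param window upstream window in bp.
#' @return an `enrichment_result`.
#' @export
capeak_upstream_enrichment <- function(genes, is_egene, ca_peaks,
                                       window = 1e5) {
  has_peak <- vapply(seq_len(nrow(genes)), function(i) {
    lo <- if (genes$strand[i] == "+") genes$tss[i] - window else genes$tss[i]
    hi <- if (genes$strand[i] == "+") genes$tss[i] else genes$tss[i] + window
    any(ca_peaks$chrom == genes$chrom[i] &
          ca_peaks$start < hi & ca_peaks$end > lo)
  }, logical(1))
  fisher_enrichment(c(
    sum(has_peak & is_egene), sum(has_peak & !is_egene),
    sum(!has_peak & is_egene), sum(!has_peak & !is_egene)
  ))
}

#' GWAS-colocalization enrichment of QTL categories
#'
#' For each complex/singleton composition category, Fisher test of category
#' membership against colocalization status, each category versus all
#' others. Per the study design these tests are evaluated at p < 0.05
#' without multiplicity correction.
#'
#' @param categories character vector: category per QTL (the ten
#'   complex/singleton composition classes).
#' @param colocalized logical per QTL.
#' @return data.frame (category, a, b, c, d, odds_ratio, p, significant).
#' @export
complex_vs_singleton_gwas_enrichment <- function(categories, colocalized) {
  stopifnot(length(categories) == length(colocalized))
  rows <- lapply(sort(unique(categories)), function(cat) {
    inc <- categories == cat
    a <- sum(inc & colocalized); b <- sum(inc & !colocalized)
    cc <- sum(!inc & colocalized); d <- sum(!inc & !colocalized)
    fr <- fisher_enrichment(c(a, b, cc, d))
    data.frame(category = cat, a = a, b = b, c = cc, d = d,
               odds_ratio = fr$odds_ratio, p = fr$p,
               significant = fr$p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
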