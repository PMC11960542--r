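#' Collect high-confidence credible-set variants per GWAS locus
#'
#' For each colocalized locus, takes the union of 99% credible-set variants
#' over all QTL colocalizations assigned to that locus that pass the
#' acceptance decision and have a high-confidence (<= 25 variant) credible
#' set. For complex modules this includes the representative and any
#' non-representative member colocalizing with the same locus; credible sets
#' of different qElements of one module are thereby collapsed.
#'
#' @param coloc_table data.frame with one row per QTL-GWAS colocalization:
#'   `qtl_id`, `locus`, `pass` (logical), `high_confidence` (logical).
#' @param credible_sets named list: `qtl_id` -> character vector of
#'   credible-set variant ids.
#' @return named list: locus -> character vector of variants.
#' @export
collect_high_confidence_variants <- function(coloc_table, credible_sets) {
  use <- coloc_table[coloc_table$pass & coloc_table$high_confidence &
                       !is.na(coloc_table$locus), , drop = FALSE]
  out <- list()
  for (loc in unique(use$locus)) {
    ids <- use$qtl_id[use$locus == loc]
    out[[loc]] <- sort(unique(unlist(credible_sets[ids], use.names = FALSE)))
  }
  out
}

#' Intersect credible-set variants with TF motif occurrences
#'
#' Motif intervals are 0-based half-open; a variant at 1-based position `p`
#' overlaps `[s, e)` iff `s <= p - 1 < e`. Variants hitting no motif are
#' dropped; all motif hits of a variant are recorded on one record.
#'
#' @param variants data.frame with `variant`, `chrom`, `pos` (1-based) and
#'   optionally `locus`.
#' @param motifs data.frame of motif occurrences (`chrom`, `start`, `end`,
#'   `name`, optionally `score` as bound flag).
#' @return data.frame of unranked MOPCV records: `variant`, `chrom`, `pos`,
#'   `locus` (if supplied), `motifs` (comma-separated ids), `n_motifs`.
#' @export
intersect_with_motifs <- function(variants, motifs) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    p0 <- variants$pos[i] - 1L  # 0-based coordinate of the variant base
    hit <- motifs$chrom == variants$chrom[i] &
      motifs$start <= p0 & p0 < motifs$end
    if (!any(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      variant = variants$variant[i],
      chrom = variants$chrom[i],
      pos = variants$pos[i],
      locus = if ("locus" %in% names(variants)) variants$locus[i] else NA,
      motifs = paste(motifs$name[hit], collapse = ","),
      n_motifs = sum(hit),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), chrom = character(), pos = integer(),
               locus = character(), motifs = character(), n_motifs = integer())
}

# is 1-based position p inside 0-based half-open [start, end)?
pos_in_interval <- function(p, start, end) start <= (p - 1) & (p - 1) < end

#' Priority rank of a motif-overlapping putative causal variant
#'
#' Rules evaluated in order:
#' \describe{
#'   \item{High}{the variant belongs to the credible set of a caQTL signal
#'     and lies within that signal's associated caPeak; for signals in a
#'     complex module, within any caPeak associated with the module.}
#'   \item{Moderate}{the variant belongs to a caQTL credible set and lies
#'     within a caPeak associated with a different caQTL signal.}
#'   \item{Low}{otherwise (including variants overlapping only accessibility
#'     peaks with no caQTL, and variants in no caQTL credible set).}
#' }
#'
#' @param variant variant id.
#' @param pos 1-based position.
#' @param ca_credible_sets data.frame (`signal`, `variant`): caQTL
#'   credible-set membership.
#' @param ca_signal_peaks data.frame (`signal`, `peak`): each caQTL signal's
#'   associated caPeak(s).
#' @param peaks peak table (`name`, `chrom`, `start`, `end`, `is_ca_peak`),
#'   0-based half-open.
#' @param signal_modules optional data.frame (`signal`, `module`) grouping
#'   caQTL signals into complex modules.
#' @param chrom chromosome of the variant (default: single-chromosome data).
#' @return `"High"`, `"Moderate"` or `"Low"`.
#' @export
rank_priority <- function(variant, pos, ca_credible_sets, ca_signal_peaks,
                          peaks, signal_modules = NULL, chrom = NULL) {
  my_signals <- unique(ca_credible_sets$signal[
    ca_credible_sets$variant == variant])
  if (length(my_signals) == 0) return("Low")
  if (!is.null(chrom)) peaks <- peaks[peaks$chrom == chrom, , drop = FALSE]
  covering <- peaks$name[pos_in_interval(pos, peaks$start, peaks$end)]
  if (length(covering) == 0) return("Low")
  covering_ca <- intersect(covering,
                           peaks$name[peaks$is_ca_peak %in% TRUE])

  own_signals <- my_signals
  if (!is.null(signal_modules)) {
    mods <- unique(signal_modules$module[
      signal_modules$signal %in% my_signals])
    own_signals <- unique(c(my_signals, signal_modules$signal[
      signal_modules$module %in% mods]))
  }
  own_peaks <- ca_signal_peaks$peak[ca_signal_peaks$signal %in% own_signals]
  if (any(covering_ca %in% own_peaks)) return("High")

  other_peaks <- ca_signal_peaks$peak[!ca_signal_peaks$signal %in% own_signals]
  if (any(covering_ca %in% other_peaks)) return("Moderate")
  "Low"
}

#' Summary fractions of the colocalization/MOPCV pipeline
#'
#' Computes the pipeline's headline ratios from counts (either produced by a
#' run or supplied directly, since the ratios are pure arithmetic):
#' percentages to 1 decimal (round half up) and folds to 1 decimal. Any
#' ratio whose inputs are missing, or whose denominator is zero, is `NA`.
#'
#' @param counts named list; recognized entries: `n_gwas_loci`,
#'   `n_colocalized_loci`, `n_chromatin_only_loci`, `n_eqtl_loci`,
#'   `n_edev_loci`, `n_shared_qtls`, `n_singleton_qtls`,
#'   `complex_composition` (named integer vector of module counts by
#'   category), `n_complex_modules`, `n_credible_variants`,
#'   `n_high_priority_mopcv`, `n_mopcv`, `n_multi_set_mopcv`,
#'   `n_top_variant_mopcv`.
#' @return named list of ratios: `pct_loci_colocalized`,
#'   `pct_chromatin_only_loci`, `pct_eqtl_loci`, `fold_chromatin_increase`,
#'   `pct_edev_among_eqtl_loci`, `pct_shared_qtls`, `pct_singleton_qtls`,
#'   `pct_composition` (named vector), `fold_mopcv_reduction`,
#'   `pct_mopcv_multi_set`, `pct_mopcv_top_variant`.
#' @export
locus_report <- function(counts) {
  g <- function(nm) if (!is.null(counts[[nm]])) counts[[nm]] else NA_real_
  pct <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  fold <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    round_half_up(num / den, 1)
  }
  comp <- counts$complex_composition
  n_mod <- if (!is.null(counts$n_complex_modules)) counts$n_complex_modules
           else if (!is.null(comp)) sum(comp) else NA_real_
  n_qtls <- if (!is.na(g("n_shared_qtls")) && !is.na(g("n_singleton_qtls"))) {
    g("n_shared_qtls") + g("n_singleton_qtls")
  } else NA_real_
  list(
    pct_loci_colocalized = pct(g("n_colocalized_loci"), g("n_gwas_loci")),
    pct_chromatin_only_loci = pct(g("n_chromatin_only_loci"), g("n_gwas_loci")),
    pct_eqtl_loci = pct(g("n_eqtl_loci"), g("n_gwas_loci")),
    fold_chromatin_increase = fold(g("n_colocalized_loci"), g("n_eqtl_loci")),
    pct_edev_among_eqtl_loci = pct(g("n_edev_loci"), g("n_eqtl_loci")),
    pct_shared_qtls = pct(g("n_shared_qtls"), n_qtls),
    pct_singleton_qtls = pct(g("n_singleton_qtls"), n_qtls),
    pct_composition = if (!is.null(comp)) {
      vapply(comp, pct, numeric(1), den = n_mod)
    } else NULL,
    fold_mopcv_reduction = fold(g("n_credible_variants"),
                                g("n_high_priority_mopcv")),
    pct_mopcv_multi_set = pct(g("n_multi_set_mopcv"), g("n_mopcv")),
    pct_mopcv_top_variant = pct(g("n_top_variant_mopcv"), g("n_mopcv"))
  )
}
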