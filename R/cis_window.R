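#' Cis-window size by phenotype type
#'
#' Genes use a 1 Mb window around the gene body; chromatin peaks
#' (accessibility, acetylation) use 100 kb.
#'
#' @param phenotype_type one of `"expression"`, `"accessibility"`,
#'   `"acetylation"`.
#' @return window half-width in bp.
#' @export
cis_window_size <- function(phenotype_type) {
  switch(phenotype_type,
    expression = 1e6,
    accessibility = 1e5,
    acetylation = 1e5,
    stop("unknown phenotype type: ", phenotype_type)
  )
}

#' Build the cis window for one element
#'
#' @param element one-row data.frame with `id`, `type`, `chrom`, `start`,
#'   `end`.
#' @param panel a `genotype_panel` supplying candidate variants.
#' @param window half-width in bp; defaults to [cis_window_size()] of the
#'   element type.
#' @param exclude_intervals optional data.frame (`chrom`, `start`, `end`) of
#'   intervals (e.g. the MHC region) whose neighbourhood disqualifies the
#'   element; an element within `window` of such an interval returns `NULL`.
#' @return list with `element_id`, `chrom`, `start`, `end` and `variant_ids`
#'   (candidate variants inside the window), or `NULL` if excluded.
#' @export
cis_window <- function(element, panel, window = NULL, exclude_intervals = NULL) {
  if (is.null(window)) window <- cis_window_size(element$type)
  lo <- element$start - window
  hi <- element$end + window
  if (!is.null(exclude_intervals) && nrow(exclude_intervals) > 0) {
    excl <- exclude_intervals[exclude_intervals$chrom == element$chrom, , drop = FALSE]
    if (nrow(excl) > 0 && any(lo <= excl$end & hi >= excl$start)) {
      return(NULL)
    }
  }
  v <- panel$variants
  ids <- v$id[v$chrom == element$chrom & v$pos >= lo & v$pos <= hi]
  list(element_id = element$id, chrom = element$chrom,
       start = lo, end = hi, variant_ids = ids)
}

#' Lay out phenotype elements along the simulated chromosome
#'
#' Places `n_elements` elements at evenly spaced positions spanning the
#' panel's variants, so that every element has cis variants.
#'
#' @param panel a `genotype_panel`.
#' @param n_elements number of elements.
#' @param type phenotype type for all elements.
#' @param tissue tissue label.
#' @param width element width in bp.
#' @return data.frame with columns id, type, tissue, chrom, start, end,
#'   strand, tss (`NA` for non-expression elements).
#' @export
layout_elements <- function(panel, n_elements, type = "expression",
                            tissue = "T1", width = 2000L) {
  pos <- panel$variants$pos
  centers <- as.integer(round(seq(min(pos), max(pos), length.out = n_elements)))
  strand <- rep_len(c("+", "-"), n_elements)
  start <- pmax(1L, centers - as.integer(width / 2))
  end <- start + as.integer(width)
  prefix <- switch(type, expression = "gene", accessibility = "apeak",
                   acetylation = "hpeak", "elem")
  data.frame(
    id = sprintf("%s%04d_%s", prefix, seq_len(n_elements), tissue),
    type = type,
    tissue = tissue,
    chrom = panel$variants$chrom[1],
    start = start,
    end = end,
    strand = strand,
    tss = ifelse(type == "expression",
                 ifelse(strand == "+", start, end), NA_integer_),
    stringsAsFactors = FALSE
  )
}
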