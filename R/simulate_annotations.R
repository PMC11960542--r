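#' Simulate interval annotations and MOPCV rank fixtures
#'
#' Emits peak, TF-motif occurrence, chromatin-state, and gene-model interval
#' tables (0-based half-open coordinates) for a synthetic chromosome,
#' together with constructed variant/peak/motif configurations whose correct
#' motif-overlapping-putative-causal-variant (MOPCV) priority rank is known
#' by construction:
#' \describe{
#'   \item{High}{the variant is in its own caQTL signal's credible set and
#'     lies inside that signal's associated caPeak (which carries a motif).}
#'   \item{Moderate}{the variant is in signal A's credible set but lies
#'     inside the caPeak associated with a different signal B.}
#'   \item{Low}{the variant is in a caQTL credible set but lies inside an
#'     accessibility peak with no caQTL.}
#' }
#'
#' @param panel a `genotype_panel` supplying variants for the fixtures.
#' @param elements element table (coordinates are reused for gene models).
#' @param mopcv_fixtures character vector of requested rank labels, each of
#'   `"High"`, `"Moderate"`, `"Low"` (repeats allowed).
#' @param seed integer seed.
#' @return list with interval data.frames `peaks`, `motifs`, `states`,
#'   `genes` (all BED-convention 0-based half-open) and `fixtures`: a list
#'   with `variants` (variant, pos, expected_rank), `ca_credible_sets`
#'   (signal, variant), `ca_signal_peaks` (signal, peak) suitable for
#'   [rank_priority()].
#' @export
simulate_annotations <- function(panel, elements, mopcv_fixtures = character(),
                                 seed = 1) {
  set.seed(as.integer(seed))
  stopifnot(all(mopcv_fixtures %in% c("High", "Moderate", "Low")))
  chrom <- panel$variants$chrom[1]
  chrom_len <- max(panel$variants$pos) + 10000L

  # chromatin states tile the chromosome in 2 kb segments
  starts <- seq(0L, chrom_len - 1L, by = 2000L)
  states <- data.frame(
    chrom = chrom, start = starts, end = pmin(starts + 2000L, chrom_len),
    name = sample(chromatin_state_vocabulary(), length(starts), replace = TRUE),
    stringsAsFactors = FALSE
  )

  genes <- elements[elements$type == "expression", , drop = FALSE]
  gene_models <- if (nrow(genes) > 0) {
    data.frame(chrom = genes$chrom, start = genes$start - 1L, end = genes$end,
               name = genes$id, score = 0L, strand = genes$strand,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  }

  peaks <- list()
  motifs <- list()
  fx_var <- list()
  fx_cs <- list()
  fx_sp <- list()

  # reserve well-separated variants for the fixtures
  nfix <- length(mopcv_fixtures)
  if (nfix > 0) {
    m <- nrow(panel$variants)
    grid <- round(seq(1, m, length.out = max(nfix * 3, 6)))
    picks <- panel$variants[grid[seq(1, by = 3, length.out = nfix)], , drop = FALSE]
    for (i in seq_len(nfix)) {
      lab <- mopcv_fixtures[i]
      v <- picks[i, ]
      sig <- sprintf("ca_signal_%02d", i)
      own_peak <- sprintf("fx_capeak_%02d", i)
      # 0-based half-open interval containing 1-based position p: [p-1, p)
      cover <- c(v$pos - 1L - 50L, v$pos + 50L)
      away <- c(v$pos + 5000L, v$pos + 5400L)  # interval NOT containing v
      if (lab == "High") {
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = cover[1], end = cover[2], name = own_peak,
          score = 0L, strand = ".", is_ca_peak = TRUE, ca_signal = sig)
        fx_sp[[length(fx_sp) + 1L]] <- data.frame(signal = sig, peak = own_peak)
      } else if (lab == "Moderate") {
        # signal i's own caPeak is elsewhere; the covering peak belongs to
        # a different caQTL signal
        other_sig <- sprintf("ca_signal_%02d_other", i)
        other_peak <- sprintf("fx_capeak_%02d_other", i)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = away[1], end = away[2], name = own_peak,
          score = 0L, strand = ".", is_ca_peak = TRUE, ca_signal = sig)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = cover[1], end = cover[2], name = other_peak,
          score = 0L, strand = ".", is_ca_peak = TRUE, ca_signal = other_sig)
        fx_sp[[length(fx_sp) + 1L]] <- data.frame(
          signal = c(sig, other_sig), peak = c(own_peak, other_peak))
      } else { # Low
        plain_peak <- sprintf("fx_atacpeak_%02d", i)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = away[1], end = away[2], name = own_peak,
          score = 0L, strand = ".", is_ca_peak = TRUE, ca_signal = sig)
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = chrom, start = cover[1], end = cover[2], name = plain_peak,
          score = 0L, strand = ".", is_ca_peak = FALSE, ca_signal = NA)
        fx_sp[[length(fx_sp) + 1L]] <- data.frame(signal = sig, peak = own_peak)
      }
      # every fixture variant sits inside a motif occurrence
      motifs[[length(motifs) + 1L]] <- data.frame(
        chrom = chrom, start = v$pos - 1L - 5L, end = v$pos + 5L,
        name = sprintf("MOTIF%02d", i), score = sample(0:1, 1), strand = "+",
        stringsAsFactors = FALSE)
      fx_var[[length(fx_var) + 1L]] <- data.frame(
        variant = v$id, pos = v$pos, expected_rank = lab,
        stringsAsFactors = FALSE)
      fx_cs[[length(fx_cs) + 1L]] <- data.frame(signal = sig, variant = v$id,
                                                stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  list(
    peaks = bind(peaks, data.frame(chrom = character(), start = integer(),
                                   end = integer(), name = character(),
                                   score = integer(), strand = character(),
                                   is_ca_peak = logical(), ca_signal = character())),
    motifs = bind(motifs, data.frame(chrom = character(), start = integer(),
                                     end = integer(), name = character(),
                                     score = integer(), strand = character())),
    states = states,
    genes = gene_models,
    fixtures = list(
      variants = bind(fx_var, data.frame(variant = character(), pos = integer(),
                                         expected_rank = character())),
      ca_credible_sets = bind(fx_cs, data.frame(signal = character(),
                                                variant = character())),
      ca_signal_peaks = bind(fx_sp, data.frame(signal = character(),
                                               peak = character()))
    )
  )
}

#' Simulate an LFSR matrix from planted temporal classes
#'
#' Local false sign rates for tissues where a pair's effect is planted as
#' active are drawn from U(0, 0.02); inactive tissues from U(0.2, 1), so the
#' 0.05 significance boundary cleanly separates the planted states.
#'
#' @param classes character vector of planted classes per pair, each of
#'   `"EDev-specific"`, `"adult-specific"`, `"shared"`, `"dropped"`.
#' @param edev_tissues,adult_tissues tissue labels for the two stages.
#' @param seed integer seed.
#' @return list with `lfsr` (pairs x tissues matrix), `tissue_stage` (named
#'   character: `"EDev"`/`"adult"` per column), `classes` (the planted truth).
#' @export
simulate_lfsr_matrix <- function(classes,
                                 edev_tissues = c("iPSC", "CVPC", "PPC"),
                                 adult_tissues = c("Adult1", "Adult2"),
                                 seed = 1) {
  set.seed(as.integer(seed))
  tissues <- c(edev_tissues, adult_tissues)
  stage <- stats::setNames(
    c(rep("EDev", length(edev_tissues)), rep("adult", length(adult_tissues))),
    tissues)
  np <- length(classes)
  active <- function(k) stats::runif(k, 0, 0.02)
  inactive <- function(k) stats::runif(k, 0.2, 1)
  lfsr <- matrix(NA_real_, np, length(tissues),
                 dimnames = list(sprintf("pair%04d", seq_len(np)), tissues))
  for (i in seq_len(np)) {
    ed_on <- switch(classes[i],
      "EDev-specific" = TRUE, "shared" = TRUE,
      "adult-specific" = FALSE, "dropped" = FALSE,
      stop("unknown class: ", classes[i]))
    ad_on <- classes[i] %in% c("adult-specific", "shared")
    lfsr[i, edev_tissues] <- if (ed_on) {
      # at least one EDev tissue active
      c(active(1), inactive(length(edev_tissues) - 1))[
        sample.int(length(edev_tissues))]
    } else inactive(length(edev_tissues))
    lfsr[i, adult_tissues] <- if (ad_on) {
      c(active(1), inactive(length(adult_tissues) - 1))[
        sample.int(length(adult_tissues))]
    } else inactive(length(adult_tissues))
  }
  list(lfsr = lfsr, tissue_stage = stage, classes = classes)
}
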