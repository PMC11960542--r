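#' Write a genotype panel to VCF
#'
#' Emits a minimal VCFv4.2 with a contig line per chromosome and unphased GT
#' genotypes derived from dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#'
#' @param panel a `genotype_panel`.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  gt <- c("0/0", "0/1", "1/1")[t(panel$dosages) + 1L]
  gt <- matrix(gt, nrow = nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", unique(v$chrom),
            vapply(unique(v$chrom),
                   function(ch) max(v$pos[v$chrom == ch]) + 1L, integer(1))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$id), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Uses the vcfR package to parse the file and reconstructs a
#' `genotype_panel` (family/role metadata is not stored in VCF and is set to
#' unrelated founders unless `samples` is supplied).
#'
#' @param path VCF file path.
#' @param samples optional sample metadata data.frame (id, family, role).
#' @return a `genotype_panel`.
#' @export
read_panel_vcf <- function(path, samples = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vc, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  lv <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
          "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos[] <- lv[t(gt)]
  fx <- vcfR::getFIX(vc)
  variants <- data.frame(
    id = fx[, "ID"], chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
    ref = fx[, "REF"], alt = fx[, "ALT"],
    af = colMeans(dos, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL
  if (is.null(samples)) {
    samples <- data.frame(id = rownames(dos), family = "U", role = "founder",
                          stringsAsFactors = FALSE)
  }
  structure(list(dosages = dos, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' Write intervals as BED6
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `name`, and optionally `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  score <- if ("score" %in% names(intervals)) intervals$score else 0L
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  utils::write.table(
    data.frame(intervals$chrom, intervals$start, intervals$end,
               intervals$name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file path.
#' @return data.frame (chrom, start, end, name, score, strand).
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[
    seq_len(ncol(df))]
  df
}

#' Write a phenotype count matrix as TSV (first column = element id)
#'
#' @param phenotypes a `phenotype_set` or a counts matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(phenotypes, path) {
  counts <- if (inherits(phenotypes, "phenotype_set")) phenotypes$counts
            else phenotypes
  df <- data.frame(element = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype count matrix from TSV
#'
#' @param path TSV with element ids in the first column.
#' @return integer matrix with element rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Serialize ground truth to JSON (schema versioned)
#'
#' @param truth a `ground_truth` (the latent matrix is omitted; it is
#'   reconstructible from the seed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    schema_version = "1.0",
    design = truth$design
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON file
#'
#' @param path JSON path.
#' @return list with `schema_version` and `design` data.frame.
#' @export
read_ground_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(out$schema_version)) stop("missing schema_version")
  out
}
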