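#' Simulate a family-structured genotype panel with block LD
#'
#' Generates diploid dosages for a single synthetic chromosome using a
#' founder-mosaic model: a small pool of founder haplotype templates is
#' recombined at block boundaries, so linkage disequilibrium is strong within
#' a block and decays with the number of block boundaries crossed. Families
#' are built by transmitting (recombined) haplotypes from two in-family
#' founders to offspring, which induces realistic kinship structure.
#'
#' @param n_founder_haplotypes number of founder haplotype templates (>= 2).
#' @param n_samples total number of samples.
#' @param family_spec integer vector of family sizes; each family consists of
#'   two founders and `size - 2` offspring. Samples not covered by
#'   `family_spec` are unrelated founders.
#' @param n_blocks number of LD blocks.
#' @param variants_per_block variants per block.
#' @param recomb_between_blocks probability of switching haplotype template
#'   (or parental haplotype, during transmission) at each block boundary.
#' @param maf_range length-2 numeric in (0, 0.5]; target allele frequencies
#'   are drawn uniformly from this interval.
#' @param seed integer seed; output is deterministic given the seed.
#' @param chrom chromosome name for the variant table.
#' @param bp_spacing distance in bp between adjacent variants.
#'
#' @return an object of class `genotype_panel`: a list with `dosages`
#'   (samples x variants matrix of 0/1/2), `variants` (data.frame: id, chrom,
#'   pos, ref, alt, af, block), and `samples` (data.frame: id, family, role).
#' @export
simulate_genotype_panel <- function(n_founder_haplotypes,
                                    n_samples,
                                    family_spec = integer(),
                                    n_blocks = 10,
                                    variants_per_block = 10,
                                    recomb_between_blocks = 0.1,
                                    maf_range = c(0.1, 0.5),
                                    seed = 1,
                                    chrom = "chrS",
                                    bp_spacing = 1000L) {
  stopifnot_scalar_count(n_founder_haplotypes, "n_founder_haplotypes")
  stopifnot_scalar_count(n_samples, "n_samples")
  stopifnot_scalar_count(n_blocks, "n_blocks")
  stopifnot_scalar_count(variants_per_block, "variants_per_block")
  if (n_founder_haplotypes < 2) stop("need at least 2 founder haplotypes")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval within (0, 0.5]")
  }
  if (any(family_spec < 2)) stop("families need at least 2 members (the founders)")
  if (sum(family_spec) > n_samples) {
    stop("family sizes sum to more than `n_samples`")
  }

  set.seed(as.integer(seed))
  H <- n_founder_haplotypes
  m <- n_blocks * variants_per_block
  block_of <- rep(seq_len(n_blocks), each = variants_per_block)

  target_af <- stats::runif(m, maf_range[1], maf_range[2])
  # founder haplotype templates: H x m binary matrix
  templ <- matrix(stats::rbinom(H * m, 1L, rep(target_af, each = H)), nrow = H)

  # a haplotype is a template-id vector over blocks
  draw_mosaic <- function() {
    ids <- integer(n_blocks)
    ids[1] <- sample.int(H, 1L)
    if (n_blocks > 1) {
      for (b in 2:n_blocks) {
        ids[b] <- if (stats::runif(1) < recomb_between_blocks) {
          sample.int(H, 1L)
        } else {
          ids[b - 1]
        }
      }
    }
    ids
  }
  # transmit one haplotype from a parent's two haplotypes (block-level meiosis)
  transmit <- function(h1, h2) {
    pick <- integer(n_blocks)
    pick[1] <- sample.int(2L, 1L)
    if (n_blocks > 1) {
      for (b in 2:n_blocks) {
        pick[b] <- if (stats::runif(1) < recomb_between_blocks) {
          sample.int(2L, 1L)
        } else {
          pick[b - 1]
        }
      }
    }
    ifelse(pick == 1L, h1, h2)
  }

  hap1 <- matrix(0L, n_samples, n_blocks)
  hap2 <- matrix(0L, n_samples, n_blocks)
  family <- character(n_samples)
  role <- character(n_samples)

  idx <- 1L
  for (f in seq_along(family_spec)) {
    fam_id <- sprintf("F%02d", f)
    p1 <- idx
    p2 <- idx + 1L
    for (p in c(p1, p2)) {
      hap1[p, ] <- draw_mosaic()
      hap2[p, ] <- draw_mosaic()
      family[p] <- fam_id
      role[p] <- "founder"
    }
    n_off <- family_spec[f] - 2L
    if (n_off > 0) {
      for (k in seq_len(n_off)) {
        o <- idx + 1L + k
        hap1[o, ] <- transmit(hap1[p1, ], hap2[p1, ])
        hap2[o, ] <- transmit(hap1[p2, ], hap2[p2, ])
        family[o] <- fam_id
        role[o] <- "offspring"
      }
    }
    idx <- idx + family_spec[f]
  }
  while (idx <= n_samples) {
    hap1[idx, ] <- draw_mosaic()
    hap2[idx, ] <- draw_mosaic()
    family[idx] <- "U"
    role[idx] <- "founder"
    idx <- idx + 1L
  }

  lookup <- function(tm) {
    # dosage matrix given the template allele matrix
    d <- matrix(0L, n_samples, m)
    for (b in seq_len(n_blocks)) {
      cols <- which(block_of == b)
      d[, cols] <- tm[hap1[, b], cols, drop = FALSE] +
        tm[hap2[, b], cols, drop = FALSE]
    }
    d
  }
  dos <- lookup(templ)

  # re-draw template alleles at sites that came out monomorphic in the cohort
  mono <- which(apply(dos, 2, function(x) length(unique(x)) == 1L))
  for (v in mono) {
    b <- block_of[v]
    used <- unique(c(hap1[, b], hap2[, b]))
    for (try in 1:200) {
      templ[, v] <- stats::rbinom(H, 1L, target_af[v])
      col <- templ[hap1[, b], v] + templ[hap2[, b], v]
      if (length(unique(col)) > 1L) break
    }
    if (length(unique(templ[used, v])) == 1L && length(used) > 1L) {
      # deterministic fallback: split the templates actually in use
      templ[used, v] <- rep_len(c(1L, 0L), length(used))
    }
    dos[, v] <- templ[hap1[, b], v] + templ[hap2[, b], v]
  }

  variants <- data.frame(
    id = sprintf("var%05d", seq_len(m)),
    chrom = chrom,
    pos = as.integer(seq_len(m)) * as.integer(bp_spacing),
    ref = "A",
    alt = "G",
    af = colMeans(dos) / 2,
    block = block_of,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    id = sprintf("S%03d", seq_len(n_samples)),
    family = family,
    role = role,
    stringsAsFactors = FALSE
  )
  rownames(dos) <- samples$id
  colnames(dos) <- variants$id

  panel <- structure(
    list(dosages = dos, variants = variants, samples = samples),
    class = "genotype_panel"
  )
  validate_genotype_panel(panel)
  panel
}

#' Validate the invariants of a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @return the panel, invisibly; errors if an invariant is violated.
#' @export
validate_genotype_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (!all(d %in% c(0L, 1L, 2L))) stop("dosages must be 0, 1 or 2")
  v <- panel$variants
  for (chr in unique(v$chrom)) {
    p <- v$pos[v$chrom == chr]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome")
  }
  af <- colMeans(d) / 2
  if (any(af <= 0 | af >= 1)) stop("allele frequencies must lie in (0, 1)")
  if (max(abs(af - v$af)) > 1e-12) stop("stored af must equal column mean / 2")
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d variants (%d families, %d founders)\n",
    nrow(x$dosages), ncol(x$dosages),
    length(setdiff(unique(x$samples$family), "U")),
    sum(x$samples$role == "founder")
  ))
  invisible(x)
}

#' Subset a genotype panel by samples and/or variants
#'
#' @param panel a `genotype_panel`.
#' @param samples sample ids or indices (default: all).
#' @param variants variant ids or indices (default: all).
#' @return a `genotype_panel` restricted to the selection; allele frequencies
#'   are recomputed on the subset (monomorphic variants are allowed here and
#'   should be handled by [variant_qc()]).
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  d <- panel$dosages
  samp <- panel$samples
  vars <- panel$variants
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, samp$id) else samples
    d <- d[i, , drop = FALSE]
    samp <- samp[i, , drop = FALSE]
  }
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, vars$id) else variants
    d <- d[, j, drop = FALSE]
    vars <- vars[j, , drop = FALSE]
  }
  vars$af <- colMeans(d) / 2
  structure(list(dosages = d, variants = vars, samples = samp),
            class = "genotype_panel")
}
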