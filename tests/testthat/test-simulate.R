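test_that("genotype panel is deterministic, valid, and seed-sensitive", {
  p1 <- small_panel(seed = 3)
  p2 <- small_panel(seed = 3)
  p3 <- small_panel(seed = 4)
  expect_identical(p1$dosages, p2$dosages)
  expect_false(identical(p1$dosages, p3$dosages))
  expect_true(all(p1$dosages %in% 0:2))
  expect_true(all(diff(p1$variants$pos) > 0))
  # no monomorphic sites and stored af consistent with dosages
  af <- colMeans(p1$dosages) / 2
  expect_true(all(af > 0 & af < 1))
  expect_equal(unname(af), p1$variants$af)
  expect_invisible(validate_genotype_panel(p1))
})

test_that("panel constructor rejects invalid arguments", {
  expect_error(simulate_genotype_panel(1, 10), "at least 2 founder")
  expect_error(simulate_genotype_panel(8, 10, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotype_panel(8, 10, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(simulate_genotype_panel(8, 10, family_spec = c(1)),
               "at least 2 members")
  expect_error(simulate_genotype_panel(8, 10, family_spec = c(6, 6)),
               "more than")
  expect_error(simulate_genotype_panel(8, 10.5), "positive integer")
})

test_that("validate_genotype_panel catches corrupted panels", {
  p <- small_panel()
  bad <- p
  bad$dosages[1, 1] <- 3L
  expect_error(validate_genotype_panel(bad), "0, 1 or 2")
  bad2 <- p
  bad2$variants$af[1] <- 0.9
  expect_error(validate_genotype_panel(bad2), "column mean")
})

test_that("LD decays with block distance", {
  p <- simulate_genotype_panel(8, 200, n_blocks = 10, variants_per_block = 8,
                               recomb_between_blocks = 0.1, seed = 21)
  G <- p$dosages
  blk <- p$variants$block
  within <- c()
  far <- c()
  for (b in 1:5) {
    i <- which(blk == b)
    j <- which(blk == b + 5)
    within <- c(within, stats::cor(G[, i])[upper.tri(diag(length(i)))]^2)
    far <- c(far, as.numeric(stats::cor(G[, i], G[, j]))^2)
  }
  expect_gt(mean(within, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("parent-offspring kinship matches the pedigree expectation", {
  # closed form: GRM entry for a parent-offspring pair has expectation
  # 2 * (kinship coefficient 1/4) = 0.5
  p <- simulate_genotype_panel(
    40, 120, family_spec = rep(3, 30), n_blocks = 150,
    variants_per_block = 4, recomb_between_blocks = 0.5, seed = 9)
  K <- build_kinship(p, prune = NULL)
  po <- c()
  un <- c()
  fams <- unique(p$samples$family)
  fams <- fams[fams != "U"]
  for (f in fams) {
    idx <- which(p$samples$family == f)
    # family layout: two founders then offspring
    po <- c(po, K[idx[1], idx[3]], K[idx[2], idx[3]])
  }
  off <- which(p$samples$role == "offspring")
  for (a in off[1:10]) {
    other_fam <- which(p$samples$family != p$samples$family[a])
    un <- c(un, K[a, other_fam[1:5]])
  }
  expect_equal(mean(po), 0.5, tolerance = 0.08)
  expect_lt(abs(mean(un)), 0.1)
})

test_that("subset_panel recomputes allele frequencies and keeps alignment", {
  p <- small_panel()
  s <- subset_panel(p, samples = p$samples$id[1:30],
                    variants = p$variants$id[c(5, 10)])
  expect_equal(dim(s$dosages), c(30L, 2L))
  expect_equal(s$variants$af, unname(colMeans(s$dosages) / 2))
  expect_equal(rownames(s$dosages), p$samples$id[1:30])
})

test_that("simulate_phenotypes plants effects on the latent scale", {
  p <- small_panel(seed = 2, n = 150)
  els <- layout_elements(p, 6)
  design <- data.frame(element = els$id[2], variant = "var00010", effect = 1.5)
  sim <- simulate_phenotypes(p, els, design, noise_sd = 0.05, seed = 5)
  expect_s3_class(sim$phenotypes, "phenotype_set")
  expect_equal(dim(sim$phenotypes$counts), c(6L, 150L))
  expect_equal(sim$phenotypes$lib_sizes,
               as.integer(colSums(sim$phenotypes$counts)))
  # OLS on the latent scale recovers the planted effect (standardized units)
  g <- as.numeric(scale(p$dosages[, "var00010"]))
  fit <- stats::lm(sim$truth$latent[2, ] ~ g)
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 0.05)
  # genetic component is exactly effect * standardized dosage
  expect_equal(sim$truth$genetic[2, ], 1.5 * g,
               ignore_attr = TRUE, tolerance = 1e-12)
  # elements without planted effects have zero genetic component
  expect_true(all(sim$truth$genetic[c(1, 3:6), ] == 0))
})

test_that("simulate_phenotypes validates the design", {
  p <- small_panel()
  els <- layout_elements(p, 3)
  expect_error(
    simulate_phenotypes(p, els, data.frame(element = "nope",
                                           variant = "var00001", effect = 1)),
    "unknown elements")
  expect_error(
    simulate_phenotypes(p, els, data.frame(element = els$id[1],
                                           variant = "nope", effect = 1)),
    "unknown variants")
  # a variant outside the element's cis window is rejected
  els2 <- els
  els2$chrom <- "other"
  expect_error(
    simulate_phenotypes(p, els2, data.frame(element = els2$id[1],
                                            variant = "var00001", effect = 1)),
    "outside the cis window")
})

test_that("hidden confounders induce cross-element correlation", {
  p <- small_panel(seed = 13, n = 100)
  els <- layout_elements(p, 12)
  sim <- simulate_phenotypes(p, els, n_hidden_factors = 2, factor_sd = 3,
                             noise_sd = 0.5, seed = 13)
  cors <- stats::cor(t(sim$truth$latent))
  off <- abs(cors[upper.tri(cors)])
  sim0 <- simulate_phenotypes(p, els, n_hidden_factors = 0,
                              noise_sd = 0.5, seed = 13)
  cors0 <- stats::cor(t(sim0$truth$latent))
  off0 <- abs(cors0[upper.tri(cors0)])
  expect_gt(mean(off), mean(off0) + 0.2)
  expect_equal(dim(sim$truth$factors), c(100L, 2L))
})

test_that("GWAS summary statistics follow the closed-form moments", {
  p <- independent_panel(seed = 8, n = 300, m = 12)
  region <- p$variants$id
  b <- numeric(12); b[4] <- 0.08
  gw <- simulate_gwas_summary(p, region, b, n_gwas = 50000, seed = 1)
  expect_s3_class(gw, "gwas_summary")
  # se closed form
  paf <- colMeans(p$dosages) / 2
  expect_equal(gw$se, 1 / sqrt(2 * 50000 * paf * (1 - paf)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gw$beta, gw$z * gw$se, tolerance = 1e-12)
  expect_equal(gw$p, 2 * stats::pnorm(-abs(gw$z)), tolerance = 1e-12)
  # Monte-Carlo mean of z matches sqrt(N) R b
  R <- attr(gw, "R")
  mu <- sqrt(50000) * as.numeric(R %*% b)
  zs <- sapply(1:300, function(s) {
    simulate_gwas_summary(p, region, b, n_gwas = 50000, seed = s)$z
  })
  expect_equal(rowMeans(zs), mu, tolerance = 4 / sqrt(300) + 0.15)
  expect_error(simulate_gwas_summary(p, c("nope"), 0, 1000),
               "absent from the panel")
})

test_that("annotation fixtures carry their constructed MOPCV ranks", {
  p <- small_panel(seed = 6, n = 60, blocks = 20, per_block = 5)
  els <- layout_elements(p, 4)
  ann <- simulate_annotations(p, els,
                              mopcv_fixtures = c("High", "Moderate", "Low"),
                              seed = 2)
  fx <- ann$fixtures
  expect_equal(nrow(fx$variants), 3L)
  got <- vapply(seq_len(nrow(fx$variants)), function(i) {
    rank_priority(fx$variants$variant[i], fx$variants$pos[i],
                  fx$ca_credible_sets, fx$ca_signal_peaks, ann$peaks)
  }, character(1))
  expect_identical(got, fx$variants$expected_rank)
  # interval tables are 0-based half-open with end > start
  for (tab in list(ann$peaks, ann$motifs, ann$states)) {
    expect_true(all(tab$end > tab$start))
    expect_true(all(tab$start >= 0))
  }
  # gene models mirror expression elements
  expect_equal(nrow(ann$genes), sum(els$type == "expression"))
})

test_that("simulated LFSR matrices separate planted classes at 0.05", {
  classes <- rep(c("EDev-specific", "adult-specific", "shared", "dropped"), 25)
  sim <- simulate_lfsr_matrix(classes, seed = 10)
  expect_equal(dim(sim$lfsr), c(100L, 5L))
  expect_true(all(sim$lfsr >= 0 & sim$lfsr <= 1))
  # active draws < 0.05 < inactive draws by construction
  expect_true(all(sim$lfsr < 0.02 | sim$lfsr >= 0.2))
  got <- classify_temporal_matrix(sim$lfsr, sim$tissue_stage)
  expect_identical(unname(got), classes)
})
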