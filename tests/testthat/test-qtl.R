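test_that("exact HWE test matches a Monte-Carlo pairing oracle", {
  expect_equal(hwe_exact_test(20, 5, 25), hwe_mc_oracle(20, 5, 25),
               tolerance = 0.02)
  expect_equal(hwe_exact_test(30, 10, 60), hwe_mc_oracle(30, 10, 60),
               tolerance = 0.02)
  # perfect-HWE-looking configuration has a large p
  expect_gt(hwe_exact_test(50, 25, 25), 0.5)
  # strong excess heterozygosity is near-impossible under HWE
  expect_lt(hwe_exact_test(40, 0, 0), 1e-4)
  # p is a valid probability and label order of homozygotes cannot matter
  expect_equal(hwe_exact_test(12, 4, 30), hwe_exact_test(12, 30, 4),
               tolerance = 1e-12)
  expect_lte(hwe_exact_test(3, 1, 5), 1)
})

test_that("variant_qc removes low call rate, low MAF, and HWE violations", {
  p <- independent_panel(seed = 40, n = 200, m = 10)
  ids <- p$variants$id
  p$dosages[1:5, 1] <- NA_integer_           # call rate 0.975 < 0.99
  p$dosages[, 2] <- c(rep(1L, 6), rep(0L, 194))  # MAF 0.015 <= 0.05
  p$dosages[, 3] <- rep(1L, 200)             # all het: extreme HWE violation
  keep <- variant_qc(p)
  expect_false(any(ids[1:3] %in% keep))
  expect_true(all(ids[4:10] %in% keep))
})

test_that("kinship matrix is symmetric PSD with duplicate-sample check", {
  p <- small_panel(seed = 31, n = 60)
  K <- build_kinship(p)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # a duplicated sample has GRM entry equal to its own diagonal
  p2 <- p
  p2$dosages[2, ] <- p2$dosages[1, ]
  p2$variants$af <- colMeans(p2$dosages) / 2
  K2 <- build_kinship(p2, prune = NULL)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
})

test_that("identity-kinship LMM equals OLS to 1e-8", {
  set.seed(42)
  n <- 80
  covs <- cbind(age = rnorm(n), batch = rbinom(n, 1, 0.5))
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * g + 0.2 * covs[, 1] + rnorm(n)
  fit <- null_variance_components(y, covs, diag(n))
  sc <- association_scan(fit, cbind(var1 = g))
  ols <- summary(stats::lm(y ~ covs + g))$coefficients["g", ]
  expect_equal(sc$beta, unname(ols["Estimate"]), tolerance = 1e-8)
  expect_equal(sc$se, unname(ols["Std. Error"]), tolerance = 1e-8)
  expect_equal(sc$t, unname(ols["t value"]), tolerance = 1e-8)
  expect_equal(sc$p, unname(ols["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("association scan is scale-equivariant and flags collinearity", {
  set.seed(43)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  y <- 0.3 * g + rnorm(n)
  fit1 <- null_variance_components(y, NULL, diag(n))
  fit2 <- null_variance_components(3 * y, NULL, diag(n))
  G <- cbind(v = g, const = rep(1L, n))
  s1 <- association_scan(fit1, G)
  s2 <- association_scan(fit2, G)
  expect_equal(s2$beta[1], 3 * s1$beta[1], tolerance = 1e-10)
  expect_equal(s2$p[1], s1$p[1], tolerance = 1e-10)
  # a constant genotype column is collinear with the intercept -> NA
  expect_true(is.na(s1$p[2]))
})

test_that("REML recovers a meaningful variance ratio under polygenic signal", {
  p <- simulate_genotype_panel(20, 150, family_spec = rep(5, 20),
                               n_blocks = 60, variants_per_block = 3,
                               recomb_between_blocks = 0.5, seed = 44)
  K <- build_kinship(p, prune = NULL)
  ek <- eigen(K, symmetric = TRUE)
  set.seed(44)
  Khalf <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  u <- as.numeric(Khalf %*% rnorm(150))
  y_gen <- 2 * u + 0.5 * rnorm(150)     # heritable
  y_env <- rnorm(150)                   # pure noise
  f_gen <- null_variance_components(y_gen, NULL, ek)
  f_env <- null_variance_components(y_env, NULL, ek)
  # delta = sigma_e^2/sigma_u^2 is small when genetics dominate
  expect_lt(f_gen$delta, 1)
  expect_gt(f_env$delta, f_gen$delta)
})

test_that("effective tests correction respects redundancy and chunking", {
  p <- independent_panel(seed = 50, n = 200, m = 12)
  G <- p$dosages
  base <- effective_tests_correction(G, p_min = 0.001)
  # duplicating every column leaves the effective test count unchanged
  Gdup <- cbind(G, G)
  colnames(Gdup) <- paste0("v", seq_len(ncol(Gdup)))
  dup <- effective_tests_correction(Gdup, p_min = 0.001)
  expect_equal(dup$m_eff, base$m_eff)
  # independent variants: m_eff close to (and never above) m
  expect_lte(base$m_eff, 12L)
  expect_gte(base$m_eff, 10L)
  # single variant
  one <- effective_tests_correction(G[, 1, drop = FALSE], p_min = 0.2)
  expect_equal(one$m_eff, 1L)
  expect_equal(one$corrected_p, 0.2)
  # corrected p caps at 1
  expect_equal(effective_tests_correction(G, p_min = 0.5)$corrected_p, 1)
  # chunked computation adds per-chunk counts
  ch <- effective_tests_correction(G, p_min = 0.001, chunk = 4)
  manual <- sum(vapply(c(1, 5, 9), function(s) {
    effective_tests_correction(G[, s:(s + 3)], p_min = 1)$m_eff
  }, integer(1)))
  expect_equal(ch$m_eff, as.integer(manual))
})

test_that("genome-wide FDR equals a hand-written Benjamini-Hochberg", {
  set.seed(51)
  recs <- data.frame(corrected_p = c(runif(20)^2, 1e-6, 3e-4))
  out <- genomewide_fdr(recs)
  # hand BH: sort, q_i = min_{j >= i} p_(j) * n / j
  p <- recs$corrected_p
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q_hand <- numeric(n)
  q_hand[o] <- pmin(1, q_sorted)
  expect_equal(out$q, q_hand, tolerance = 1e-12)
  expect_equal(out$significant, out$q < 0.05)
})

test_that("map_qtls recovers planted effects and calibrates nulls", {
  p <- simulate_genotype_panel(20, 150, family_spec = c(4, 4, 3),
                               n_blocks = 20, variants_per_block = 5,
                               recomb_between_blocks = 0.3, seed = 7)
  els <- layout_elements(p, 10)
  design <- data.frame(element = els$id[c(2, 5)],
                       variant = c("var00010", "var00050"),
                       effect = c(1, 1))
  sim <- simulate_phenotypes(p, els, design, seed = 7)
  nm <- normalize_phenotypes(sim$phenotypes)
  # no confounders are planted, so only ancestry PCs enter the model
  # (hidden factors estimated from 10 elements would overfit noise)
  covs <- genotype_pcs(p, 3)
  res <- map_qtls(p, nm$values, nm$elements, covariates = covs,
                  max_conditional = 1)
  prim <- res$records[res$records$rank == "primary", ]
  sig <- prim$element[prim$significant]
  expect_setequal(sig, els$id[c(2, 5)])
  # lead variants tag the planted truth in high LD
  for (i in c(2, 5)) {
    lead <- prim$variant[prim$element == els$id[i]]
    r2 <- ld_r2(p$dosages[, lead], p$dosages[, design$variant[design$element == els$id[i]]])
    expect_gt(r2, 0.8)
  }
  # record schema
  expect_true(all(c("element", "tissue", "type", "rank", "variant", "chrom",
                    "pos", "beta", "se", "p", "corrected_p", "q",
                    "significant", "regressed", "status") %in%
                    names(res$records)))
})

test_that("scan_element lead is the minimum corrected p and excludes conditioned variants", {
  p <- small_panel(seed = 61, n = 100)
  els <- layout_elements(p, 4)
  design <- data.frame(element = els$id[2], variant = "var00020", effect = 1.2)
  sim <- simulate_phenotypes(p, els, design, seed = 61)
  nm <- normalize_phenotypes(sim$phenotypes)
  ctx <- qtl_context(p, nm$values, nm$elements)
  sc <- scan_element(ctx, els$id[2])
  expect_equal(sc$lead$corrected_p, min(sc$stats$corrected_p, na.rm = TRUE))
  sc2 <- scan_element(ctx, els$id[2], condition_on = sc$lead$variant)
  expect_false(sc$lead$variant %in% sc2$stats$variant)
})

test_that("filter_conditional_qtls applies the removal ledger", {
  # hand-built panel: v1, v2 = duplicate of v1 (r^2 = 1), v3 independent,
  # v4 monomorphic
  set.seed(62)
  g1 <- rbinom(40, 2, 0.4)
  g3 <- rbinom(40, 2, 0.4)
  dos <- cbind(v1 = g1, v2 = g1, v3 = g3, v4 = rep(1L, 40))
  panel <- structure(list(
    dosages = dos,
    variants = data.frame(id = colnames(dos), chrom = "chrS",
                          pos = c(100L, 200L, 300L, 400L), ref = "A",
                          alt = "G", af = colMeans(dos) / 2),
    samples = data.frame(id = sprintf("S%02d", 1:40), family = "U",
                         role = "founder")), class = "genotype_panel")
  rec <- function(el, rank, var) {
    data.frame(element = el, tissue = "T1", type = "expression", rank = rank,
               variant = var, chrom = "chrS", pos = 1L, beta = 1, se = 0.1,
               p = 1e-8, corrected_p = 1e-6, q = 1e-4, significant = TRUE,
               regressed = FALSE, status = "kept", stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("gA", "primary", "v1"), rec("gA", "conditional1", "v2"),  # LD
    rec("gA", "conditional2", "v3"),                               # survives
    rec("gB", "primary", "v1"), rec("gB", "conditional1", "vX"),   # absent
    rec("gC", "primary", "vY"), rec("gC", "conditional1", "v3"),   # prim absent
    rec("gD", "primary", "v4"), rec("gD", "conditional1", "v3"),   # prim mono
    rec("gE", "primary", "v1"), rec("gE", "conditional1", "v4")    # cond mono
  )
  out <- filter_conditional_qtls(records, panel)
  led <- out$ledger
  expect_equal(led$reason[led$element == "gA"], "ld_with_primary")
  expect_equal(led$reason[led$element == "gB"], "conditional_absent_from_panel")
  expect_equal(led$reason[led$element == "gC"], "primary_absent_from_panel")
  expect_equal(led$reason[led$element == "gD"], "monomorphic_primary")
  expect_equal(led$reason[led$element == "gE"], "monomorphic_conditional")
  # 100% of planted LD-redundant conditionals removed; survivor renumbered
  kept <- out$records
  ka <- kept[kept$element == "gA" & grepl("conditional", kept$rank), ]
  expect_equal(ka$variant, "v3")
  expect_equal(ka$rank, "conditional1")
  # primaries are never removed
  expect_equal(sum(kept$rank == "primary"), 5L)
})

test_that("regress_primary_signal re-scans only elements with conditionals", {
  p <- small_panel(seed = 63, n = 120)
  els <- layout_elements(p, 4)
  design <- data.frame(element = rep(els$id[2], 2),
                       variant = c("var00015", "var00045"),
                       effect = c(1.2, 1.2))
  sim <- simulate_phenotypes(p, els, design, seed = 63)
  nm <- normalize_phenotypes(sim$phenotypes)
  res <- map_qtls(p, nm$values, nm$elements, max_conditional = 1)
  flt <- filter_conditional_qtls(
    res$records[res$records$significant, , drop = FALSE], p)
  out <- regress_primary_signal(res$context, flt$records)
  has_cond <- unique(out$element[grepl("conditional", out$rank)])
  for (el in unique(out$element)) {
    prim <- out[out$element == el & out$rank == "primary", ]
    expect_equal(prim$regressed, el %in% has_cond)
  }
})

test_that("excluded intervals disqualify overlapping elements", {
  p <- small_panel(seed = 64, n = 80)
  els <- layout_elements(p, 3)
  sim <- simulate_phenotypes(p, els, seed = 64)
  nm <- normalize_phenotypes(sim$phenotypes)
  excl <- data.frame(chrom = els$chrom[1], start = els$start[1],
                     end = els$end[1])
  ctx <- qtl_context(p, nm$values, nm$elements, exclude_intervals = excl)
  expect_null(scan_element(ctx, els$id[1]))
})
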