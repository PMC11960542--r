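test_that("Wakefield log ABF matches numerical integration of the marginal", {
  W <- 0.15
  for (cfg in list(c(0.12, 0.04), c(-0.3, 0.08), c(0.01, 0.02),
                   c(0.5, 0.05))) {
    beta <- cfg[1]; se <- cfg[2]
    num <- stats::integrate(function(b) {
      stats::dnorm(beta, b, se) * stats::dnorm(b, 0, W)
    }, -3, 3, rel.tol = 1e-12)$value / stats::dnorm(beta, 0, se)
    expect_equal(wakefield_log_abf(beta, se^2, W), log(num),
                 tolerance = 1e-8)
  }
  expect_error(wakefield_log_abf(0.1, 0), "positive")
})

test_that("coloc posteriors equal brute-force configuration enumeration", {
  set.seed(90)
  for (m in 1:6) {
    for (rep in 1:5) {
      l1 <- rnorm(m, 2, 4)
      l2 <- rnorm(m, 2, 4)
      out <- coloc_posteriors(l1, l2, variant_ids = paste0("v", seq_len(m)))
      en <- enumerate_coloc(l1, l2)
      expect_equal(out$pp, en, tolerance = 1e-12)
      expect_equal(sum(out$pp), 1, tolerance = 1e-12)
      expect_equal(sum(out$per_variant_h4), 1, tolerance = 1e-12)
      # per-variant H4 by direct arithmetic
      expect_equal(unname(out$per_variant_h4),
                   exp(l1 + l2) / sum(exp(l1 + l2)), tolerance = 1e-12)
    }
  }
})

test_that("coloc posteriors: trait swap exchanges H1/H2 and extreme ABFs dominate", {
  l1 <- c(10, 1, 0); l2 <- c(0.5, 0.2, 0.1)
  a <- coloc_posteriors(l1, l2)$pp
  b <- coloc_posteriors(l2, l1)$pp
  expect_equal(unname(a["PP.H1"]), unname(b["PP.H2"]), tolerance = 1e-12)
  expect_equal(unname(a["PP.H3"]), unname(b["PP.H3"]), tolerance = 1e-12)
  expect_equal(unname(a["PP.H4"]), unname(b["PP.H4"]), tolerance = 1e-12)
  # both traits strongly associated at the same variant -> H4 dominates
  strong <- coloc_posteriors(c(40, 0, 0), c(38, 0, 0))$pp
  expect_gt(strong["PP.H4"], 0.9)
  # strong but at different variants -> H3 dominates
  dist <- coloc_posteriors(c(40, 0, 0), c(0, 38, 0))$pp
  expect_gt(dist["PP.H3"], 0.9)
  # no signal -> H0 dominates
  null <- coloc_posteriors(c(0, 0, 0), c(0, 0, 0))$pp
  expect_gt(null["PP.H0"], 0.99)
})

test_that("colocalize_qtl_gwas intersects variants and reports the lead", {
  qtl <- data.frame(variant = c("v1", "v2", "v3", "vq"),
                    beta = c(0.9, 0.1, 0.05, 1),
                    se = c(0.1, 0.1, 0.1, 0.1),
                    p = c(1e-15, 0.3, 0.6, 1e-9),
                    pos = c(100L, 200L, 300L, 400L))
  gwas <- data.frame(variant = c("v1", "v2", "v3", "vg"),
                     beta = c(0.08, 0.01, 0.005, 0.2),
                     se = c(0.008, 0.008, 0.008, 0.01),
                     p = c(1e-20, 0.2, 0.5, 1e-10))
  res <- colocalize_qtl_gwas(qtl, gwas, min_variants = 3)
  expect_s3_class(res, "colocalization_result")
  expect_equal(res$n_variants, 3L)   # vq/vg not shared
  expect_equal(res$lead_candidate$variant, "v1")
  expect_equal(res$lead_candidate$pos, 100L)
  expect_equal(unname(res$lead_candidate$probability),
               unname(res$per_variant_h4["v1"]))
  expect_error(colocalize_qtl_gwas(qtl[4, ], gwas[4, ]), "no shared variants")
})

test_that("colocalization decision thresholds are all inclusive", {
  mk <- function(n, h4, gp, qp, lp) {
    structure(list(pp = c(PP.H0 = 0, PP.H1 = 0, PP.H2 = 0,
                          PP.H3 = 1 - h4, PP.H4 = h4),
                   n_variants = n,
                   lead_candidate = data.frame(variant = "v", probability = lp,
                                               gwas_p = gp, qtl_p = qp,
                                               pos = 1L)),
              class = "colocalization_result")
  }
  at <- colocalization_decision(mk(50, 0.80, 5e-8, 5e-5, 0.01))
  expect_true(at$pass)
  expect_equal(length(at$reasons), 0L)
  for (fail in list(mk(49, 0.9, 1e-9, 1e-6, 0.5),
                    mk(60, 0.799, 1e-9, 1e-6, 0.5),
                    mk(60, 0.9, 6e-8, 1e-6, 0.5),
                    mk(60, 0.9, 1e-9, 6e-5, 0.5),
                    mk(60, 0.9, 1e-9, 1e-6, 0.009))) {
    d <- colocalization_decision(fail)
    expect_false(d$pass)
    expect_equal(length(d$reasons), 1L)
  }
})

test_that("credible sets include the first crossing and flag confidence", {
  cs <- credible_set(c(a = 0.6, b = 0.3, c = 0.09, d = 0.01))
  expect_equal(cs$variants, c("a", "b", "c"))
  expect_equal(cs$size, 3L)
  expect_true(cs$high_confidence)
  expect_equal(credible_set(c(x = 0.995, y = 0.005))$size, 1L)
  # uniform over 100: need 99 variants, not high-confidence
  u <- credible_set(stats::setNames(rep(0.01, 100), paste0("v", 1:100)))
  expect_equal(u$size, 99L)
  expect_false(u$high_confidence)
  # exact boundary: cumulative mass exactly 0.99 stops there
  cs2 <- credible_set(c(a = 0.99, b = 0.01))
  expect_equal(cs2$size, 1L)
  # probabilities reported in decreasing order
  expect_equal(cs$probabilities, sort(cs$probabilities, decreasing = TRUE))
})

test_that("complex representative selection is seeded and prefers in-panel leads", {
  p <- small_panel(seed = 91, n = 40)
  recs <- data.frame(element = c("e1", "e2", "e3"),
                     variant = c("zzz_absent", p$variants$id[2], "also_absent"),
                     stringsAsFactors = FALSE)
  pick <- select_complex_representative(recs, p, seed = 3)
  expect_equal(pick$element, "e2")
  expect_identical(pick, select_complex_representative(recs, p, seed = 3))
  # all absent: falls back to any member, deterministically
  recs2 <- recs
  recs2$variant <- paste0("none", 1:3)
  pick2 <- select_complex_representative(recs2, p, seed = 5)
  expect_identical(pick2, select_complex_representative(recs2, p, seed = 5))
  expect_error(select_complex_representative(recs[0, ], p), "empty module")
})

test_that("define_gwas_loci prunes by LD keeping the larger-MAF member", {
  set.seed(92)
  # v1 common, v2 = v1 with a few hets removed (lower MAF, r^2 high),
  # v3 independent, v4 exact duplicate of v3 (tie -> later position dropped)
  g1 <- rbinom(300, 2, 0.45)
  g2 <- g1; g2[which(g2 == 1)[1:6]] <- 0L
  g3 <- rbinom(300, 2, 0.4)
  dos <- cbind(v1 = g1, v2 = g2, v3 = g3, v4 = g3)
  panel <- structure(list(
    dosages = dos,
    variants = data.frame(id = colnames(dos), chrom = "chrS",
                          pos = c(1000L, 2000L, 50000L, 60000L), ref = "A",
                          alt = "G", af = colMeans(dos) / 2),
    samples = data.frame(id = sprintf("S%03d", 1:300), family = "U",
                         role = "founder")), class = "genotype_panel")
  gwas <- data.frame(variant = c("v1", "v2", "v3", "v4"), chrom = "chrS",
                     pos = panel$variants$pos, beta = 1, se = 0.1,
                     z = 10, p = c(1e-20, 1e-18, 1e-15, 1e-15), N = 1e5)
  loci <- define_gwas_loci(gwas, panel)
  expect_equal(sort(loci$variant), c("v1", "v3"))
  expect_equal(loci$locus, sprintf("locus%03d", seq_len(nrow(loci))))
  # non-significant variants never become loci
  gwas2 <- gwas; gwas2$p <- 0.5
  expect_equal(nrow(define_gwas_loci(gwas2, panel)), 0L)
})

test_that("colocalizations are assigned to loci by LD with distance fallback", {
  set.seed(93)
  g1 <- rbinom(200, 2, 0.4)
  g2 <- rbinom(200, 2, 0.4)
  dos <- cbind(idx1 = g1, near1 = g1, idx2 = g2)
  panel <- structure(list(
    dosages = dos,
    variants = data.frame(id = colnames(dos), chrom = "chrS",
                          pos = c(1000L, 3000L, 900000L), ref = "A",
                          alt = "G", af = colMeans(dos) / 2),
    samples = data.frame(id = sprintf("S%03d", 1:200), family = "U",
                         role = "founder")), class = "genotype_panel")
  loci <- data.frame(locus = c("locus001", "locus002"),
                     variant = c("idx1", "idx2"), chrom = "chrS",
                     pos = c(1000L, 900000L), p = 1e-10)
  colocs <- data.frame(
    qtl_id = c("q_ld", "q_absent", "q_far"),
    lead_variant = c("near1", "ghost", "idx2"),
    lead_pos = c(3000L, 5000L, 400000L),
    chrom = "chrS", stringsAsFactors = FALSE)
  out <- assign_colocalizations_to_loci(colocs, loci, panel)
  expect_equal(out$locus[out$qtl_id == "q_ld"], "locus001")       # r^2 = 1
  expect_equal(out$locus[out$qtl_id == "q_absent"], "locus001")   # nearest
  # in panel but not in LD with any index within 350 kb -> unassigned
  expect_true(is.na(out$locus[out$qtl_id == "q_far"]))
})
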