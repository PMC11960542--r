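# moqtl

Multiomic QTL mapping, complex-QTL networks, and GWAS colocalization — a
tested, self-contained R implementation of a molecular quantitative trait
locus (QTL) integration pipeline with a synthetic-data module for
end-to-end validation against known ground truth.

## What the package does

Molecular QTLs associate genetic variants with molecular phenotypes — gene
expression (eQTLs), chromatin accessibility (caQTLs), and histone
acetylation (haQTLs). `moqtl` implements the full integration chain:

1. **Synthetic data** (`simulate_genotype_panel`, `simulate_phenotypes`,
   `simulate_gwas_summary`, `simulate_annotations`): family-structured
   genotypes with block LD from a founder-mosaic model; Poisson–log-normal
   count phenotypes with planted cis effects, hidden confounders and
   polygenic background; GWAS summary statistics drawn at the z-score
   level; interval annotations with known-answer prioritization fixtures.
2. **Phenotype processing** (`tmm_normalize`, `inverse_normal_transform`,
   `filter_expression_elements`, `hidden_factors`,
   `optimize_factor_count`): TMM scaling (via edgeR), element filters,
   rank-based inverse normal transform, PCA confounder estimation with
   discovery-maximizing factor-count selection.
3. **QTL mapping** (`map_qtls`, `null_variance_components`,
   `association_scan`, `effective_tests_correction`, `genomewide_fdr`):
   kinship linear mixed model fit by REML with the one-off
   eigendecomposition trick; two-step multiple-testing correction
   (effective-tests Bonferroni within element, Benjamini–Hochberg across
   elements, q < 0.05); stepwise conditional discovery up to 3 signals.
4. **LD and complex QTLs** (`ld_r2`, `ld_dprime`,
   `filter_conditional_qtls`, `shared_qtl_pairs`,
   `detect_complex_modules`, `louvain_communities`): EM-based D′ from
   unphased genotypes; a fully ledgered conditional-QTL filter; per-tissue
   shared-signal graphs (lead r² > 0.8, ≤ 100 kb) partitioned into
   complex-QTL modules by deterministic multi-restart Louvain community
   detection, verified against exhaustive modularity maximization.
5. **Temporal classification** (`classify_temporal_matrix`,
   `annotate_cohort_eqtls`, `propagate_complex_annotation`): local false
   sign rate (LFSR < 0.05) classification of SNP–eGene pairs into
   early-developmental-specific, adult-specific, shared, or dropped, with
   module-level reconciliation rules.
6. **Colocalization** (`wakefield_log_abf`, `coloc_posteriors`,
   `colocalize_qtl_gwas`, `credible_set`, `define_gwas_loci`):
   hand-written log-space Wakefield-ABF colocalization (priors 1e-4 /
   1e-4 / 1e-5), a five-criterion acceptance decision, calibrated 99%
   credible sets, and LD-based assignment of colocalizations to pruned
   GWAS loci.
7. **MOPCV prioritization** (`collect_high_confidence_variants`,
   `intersect_with_motifs`, `rank_priority`, `locus_report`):
   motif-overlapping putative causal variants ranked High / Moderate /
   Low by caQTL credible-set and caPeak membership; report arithmetic with
   1-decimal round-half-up.
8. **Enrichment** (`fisher_enrichment`, `collapse_chromatin_states`,
   `lead_variant_state_enrichment`): exact Fisher tests with Woolf
   confidence intervals and explicit continuity-correction rules;
   18-to-5 chromatin-state collapse.

See the methods vignette (`vignettes/multiomic-qtl-methods.Rmd`) for the
statistical details and modeling conventions.

## Worked example

Percentages and folds from a locus-report count summary (values printed by
the code below):

```r
library(moqtl)
rep1 <- locus_report(list(
  n_gwas_loci = 5192, n_colocalized_loci = 540,
  n_chromatin_only_loci = 301, n_eqtl_loci = 239, n_edev_loci = 13,
  n_shared_qtls = 13604, n_singleton_qtls = 46702,
  n_credible_variants = 6164, n_high_priority_mopcv = 167,
  n_mopcv = 548, n_multi_set_mopcv = 72, n_top_variant_mopcv = 84))
rep1$pct_loci_colocalized     # 10.4  (540 of 5192 GWAS loci colocalized)
rep1$fold_chromatin_increase  # 2.3   (540 vs 239 eQTL-only loci)
rep1$pct_shared_qtls          # 22.6  (13604 of 60306 QTLs in complex modules)
rep1$fold_mopcv_reduction     # 36.9  (6164 credible variants -> 167 high-priority)
```

End-to-end on synthetic data — plant one cis effect, map it, and
colocalize with a GWAS trait sharing the causal variant:

```r
panel <- simulate_genotype_panel(24, 200, n_blocks = 10,
                                 variants_per_block = 5,
                                 recomb_between_blocks = 0.5, seed = 7)
elements <- layout_elements(panel, 10)
design <- data.frame(element = elements$id[4], variant = "var00025",
                     effect = 1)
sim <- simulate_phenotypes(panel, elements, design, seed = 7)
norm <- normalize_phenotypes(sim$phenotypes)
qtls <- map_qtls(panel, norm$values, norm$elements)
qtls$records[qtls$records$significant,
             c("element", "rank", "variant", "beta", "p", "q")]
#>      element    rank  variant      beta            p            q
#>  gene0004_T1 primary var00025 0.9856544 8.487384e-25 4.073944e-22

stats <- qtl_summary_stats(qtls$context, "gene0004_T1")
af <- mean(panel$dosages[, "var00025"]) / 2
eff <- setNames(numeric(nrow(panel$variants)), panel$variants$id)
eff["var00025"] <- 0.1 * sqrt(2 * af * (1 - af))
gwas <- simulate_gwas_summary(panel, panel$variants$id, eff,
                              n_gwas = 50000, seed = 8)
cl <- colocalize_qtl_gwas(stats, gwas)
round(cl$pp, 4)
#> PP.H0 PP.H1 PP.H2 PP.H3 PP.H4
#>     0     0     0     0     1
cl$decision$pass
#> [1] TRUE
credible_set(cl$per_variant_h4)$variants
#> [1] "var00025"
```

The scan recovers the planted variant exactly (lead in perfect LD with the
truth), the colocalization passes all five acceptance criteria, and the
99% credible set pinpoints the causal variant.

## Reproduction

The acceptance script recomputes the headline quantities against the
installed package and writes them as bare JSON numbers:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`. With seed 1 the script reports,
among others: `null_fraction_significant` 0 (FDR calibration on 300
all-null elements), `planted_effect_power` 0.96 and
`planted_effect_mean_beta` 1.024 (25 replicates of a planted 1-SD
effect), `conditional_recovery_rate` 0.867, `module_recovery_ari` 1,
`credible_set_coverage` 1, `mopcv_rank_accuracy` 1,
`temporal_class_recovery` 1, and enumeration deviations for the
colocalization and Fisher modules at machine precision (< 1e-15).

## License

MIT (see `LICENSE`).
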