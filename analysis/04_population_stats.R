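#!/usr/bin/env Rscript
# Statistical layer. (1) Kruskal-Wallis of per-gene functional-variant
# counts across the six families. (2) OLS regressions of per-gene total,
# missense and deleterious-missense counts on gene length, Bonferroni
# threshold 0.05/18. (3) Pairwise allele-frequency comparisons against the
# reference population, chi-square or Fisher on reconstructed allele
# counts, Bonferroni threshold 0.05/72 — run on the simulated population
# table and on the packaged table of eight clinically relevant variants
# (published frequencies; gnomAD allele numbers are plausible synthetic
# stand-ins, so significance calls there are illustrative).

suppressMessages(library(pgxlandscape))

panel <- read_gene_panel("results/sim/panel.tsv")
gs <- readr::read_tsv("results/landscape/gene_summaries.tsv",
                      show_col_types = FALSE, progress = FALSE)

kw <- kruskal_wallis_by_family(gs$n_functional, gs$family)
cat(sprintf("Kruskal-Wallis on functional counts: H = %.2f, df = %d, p = %.4g\n",
            kw$H, kw$df, kw$p_value))

reg <- regress_families(gs, panel)
cat("length regressions significant at 0.05/18:",
    sum(reg$significant), "of", nrow(reg), "\n")
sig <- reg[reg$significant, c("family", "response", "slope", "r_squared", "p_value")]
print(as.data.frame(sig), digits = 3)

sim_pops <- read_population_table("results/sim/populations.tsv")
cmp_sim <- compare_population_table(sim_pops, "POP1", m = 72)
cat(sprintf("simulated populations: %d comparisons, %d significant at 0.05/72 (FST %.2g)\n",
            nrow(cmp_sim), sum(cmp_sim$significant), 0.1))

clinical <- read_population_table(system.file(
  "extdata", "population_vaf_clinical_synthetic_an.tsv",
  package = "pgxlandscape"))
cmp <- compare_population_table(clinical, "CMDB_Chinese", m = 72)
cat(sprintf("clinical table: %d comparisons, %d significant at %.4g\n",
            nrow(cmp), sum(cmp$significant), unique(cmp$alpha_adjusted)))
rs671 <- cmp[cmp$variant_key == "chr12:112241766:G:A", ]
cat("rs671 (ALDH2): significant against",
    sum(rs671$significant), "of 9 populations;",
    "non-significant:", paste(rs671$population_b[!rs671$significant],
                              collapse = ", "), "\n")

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(reg, "results/stats/regressions.tsv", progress = FALSE)
readr::write_tsv(cmp_sim, "results/stats/comparisons_simulated.tsv", progress = FALSE)
readr::write_tsv(cmp, "results/stats/comparisons_clinical.tsv", progress = FALSE)
cat("wrote regression and comparison tables under results/stats\n")
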