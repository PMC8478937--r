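#!/usr/bin/env Rscript
# Summarize the classified cohort: cohort overview (novel/rare/exonic
# fractions), substitution spectrum with Ti/Tv, per-gene summaries with the
# aggregated functional-variant frequency, per-family summaries, and the
# fold between the most and least functionally polymorphic genes.

suppressMessages(library(pgxlandscape))

panel <- read_gene_panel("results/sim/panel.tsv")
classified <- readr::read_tsv(
  "results/landscape/classified.tsv", show_col_types = FALSE,
  progress = FALSE,
  col_types = readr::cols(cadd_phred = "d", vqsr_score = "d",
                          variant_id = "c"))

ov <- cohort_overview(classified)
cat(sprintf("cohort: %d variants | %.1f%% novel | %.1f%% rare | %.1f%% exonic\n",
            ov$n_total, ov$novel_pct, ov$rare_pct, ov$exonic_pct))

sp <- substitution_spectrum(classified)
top <- sp$spectrum[order(-sp$spectrum$count), ][1:2, ]
cat(sprintf("spectrum: Ti/Tv = %.2f; top types %s (%.1f%%), %s (%.1f%%)\n",
            sp$titv_ratio, top$substitution[1], 100 * top$fraction[1],
            top$substitution[2], 100 * top$fraction[2]))

gs <- summarize_genes(classified, panel)
fs <- summarize_families(gs)
cat("functional variants per gene, by family (mean +/- sample SD):\n")
for (i in seq_len(nrow(fs))) {
  cat(sprintf("  %-17s %4.1f +/- %.2f over %d genes\n", fs$family[i],
              fs$functional_per_gene_mean[i], fs$functional_per_gene_sd[i],
              fs$n_genes[i]))
}

fr <- fold_range(gs)
cat(sprintf("aggregated functional frequency: max %s (%.2f%%), min %s (%.2f%%), fold %.1f\n",
            fr$max_symbol, fr$max_pct, fr$min_symbol, fr$min_pct,
            fr$fold_rounded))

dir.create("results/landscape", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(gs, "results/landscape/gene_summaries.tsv", progress = FALSE)
readr::write_tsv(fs, "results/landscape/family_summaries.tsv", progress = FALSE)
readr::write_tsv(sp$spectrum, "results/landscape/spectrum.tsv", progress = FALSE)
cat("wrote gene/family/spectrum tables under results/landscape\n")
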