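#!/usr/bin/env Rscript
# Read the simulated inputs back through the standard-format readers, apply
# the VQSR quality filter (threshold 35), resolve records against the gene
# panel, and run the classification cascade: rarity at VAF < 1%, consensus
# missense deleteriousness (>= 50% of available predictors damaging), and
# putative loss-of-function categories.

suppressMessages(library(pgxlandscape))

panel <- read_gene_panel("results/sim/panel.tsv")
records <- read_variant_table("results/sim/variants.vcf",
                              "results/sim/annotations.tsv")
cat("read", nrow(records), "annotated records\n")

flt <- filter_vqsr(records, threshold = 35)
cat("VQSR filter: kept", nrow(flt$kept), "dropped", nrow(flt$dropped),
    "unscored", flt$n_unscored, "\n")

routed <- resolve_panel(flt$kept, panel)
classified <- classify_variants(routed$accepted)

cat("functional classes:\n")
print(table(classified$functional_class))
cat("rare fraction:", round(mean(classified$rarity == "RARE"), 4), "\n")
fun <- classified[classified$is_functional, ]
cat("functional variants:", nrow(fun), "of which rare:",
    round_pct(mean(fun$rarity == "RARE")), "%\n")

dir.create("results/landscape", recursive = TRUE, showWarnings = FALSE)
readr::write_tsv(classified, "results/landscape/classified.tsv",
                 progress = FALSE)
cat("wrote results/landscape/classified.tsv\n")
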