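# In-code fixtures shared across test files.

# Minimal variant-record tibble; defaults give a valid single missense record.
make_records <- function(n = 1,
                         chrom = "chr1", pos = seq_len(n) * 100L,
                         variant_id = paste0("rs", seq_len(n)),
                         ref = "G", alt = "A",
                         gene_symbol = "GENEA", vaf = 0.005,
                         vqsr_score = 60, consequence = "missense",
                         sift = "damaging", polyphen2 = "damaging",
                         provean = "tolerated", cadd_phred = NA_real_) {
  tibble::tibble(chrom = chrom, pos = pos, variant_id = variant_id,
                 ref = ref, alt = alt, gene_symbol = gene_symbol, vaf = vaf,
                 vqsr_score = vqsr_score, consequence = consequence,
                 sift = sift, polyphen2 = polyphen2, provean = provean,
                 cadd_phred = cadd_phred)
}

make_panel <- function(symbols = "GENEA", family = "ABC",
                       chrom = "chr1", start = 1L, end = 100000L) {
  tibble::tibble(symbol = symbols, family = family, chrom = chrom,
                 start = start, end = end,
                 length_kb = (end - start + 1) / 1000)
}

# All 27 predictor-call triples.
call_triples <- function() {
  tok <- c("damaging", "tolerated", "missing")
  expand.grid(sift = tok, polyphen2 = tok, provean = tok,
              stringsAsFactors = FALSE)
}

# Independent statement of the consensus rule: drop missing calls, compare
# the damaging share of what remains to one half.
consensus_oracle <- function(s, p, v) {
  calls <- c(s, p, v)
  calls <- calls[calls != "missing"]
  if (length(calls) == 0) return("UNCLASSIFIED_MISSENSE")
  if (sum(calls == "damaging") / length(calls) >= 0.5) {
    "DELETERIOUS_MISSENSE"
  } else {
    "NEUTRAL_MISSENSE"
  }
}

# Two-sided Fisher p by full enumeration of tables with the observed
# margins: sum the hypergeometric probabilities of all tables no more
# probable than the observed one (with fisher.test's relative tolerance).
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ])   # row 1 total
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  x <- seq(max(0, k - n), min(k, m))
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

demo_path <- function(file) {
  system.file("extdata", "demo", file, package = "pgxlandscape")
}
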