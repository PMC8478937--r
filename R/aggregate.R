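# Per-gene, per-family and cohort-level summaries: region counts, novel
# fraction, substitution spectrum with Ti/Tv, functional-variant tallies,
# aggregated functional-variant frequency, rare/common fractions, and the
# max/min fold across genes.

#' Per-gene summaries
#'
#' One row per panel gene (genes with no variants included), tallying
#' consequence categories, novel and rare records, the functional-class
#' partition, and the aggregated functional-variant frequency: the sum of
#' the allele frequencies of the gene's functional variants, in percent.
#' Genes without functional variants get an aggregated frequency of 0 and an
#' undefined (`NA`) rare fraction.
#'
#' @param classified Classified variant tibble from [classify_variants()].
#' @param panel Gene-panel tibble.
#' @param fraction_weighting How the rare fraction of the functional
#'   variation is weighted: by variant `"count"` (default) or by allele
#'   frequency (`"vaf"`).
#' @param freq_aggregation How per-variant frequencies combine into the
#'   aggregated frequency: plain `"sum"` (default; additive, can exceed
#'   100%) or `"union"` (`1 - prod(1 - vaf)`, the chance a random haplotype
#'   carries at least one functional allele under independence).
#' @return Tibble with one row per panel gene.
#' @export
summarize_genes <- function(classified, panel,
                            fraction_weighting = c("count", "vaf"),
                            freq_aggregation = c("sum", "union")) {
  fraction_weighting <- match.arg(fraction_weighting)
  freq_aggregation <- match.arg(freq_aggregation)
  stray <- setdiff(unique(classified$gene_symbol), panel$symbol)
  if (length(stray) > 0) {
    stop("classified records carry gene symbol(s) not in the panel: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  sym <- factor(classified$gene_symbol, levels = panel$symbol)
  cnt <- function(mask) as.integer(table(sym[mask]))
  conseq_counts <- lapply(consequence_vocab(), function(cc) {
    cnt(classified$consequence == cc)
  })
  names(conseq_counts) <- paste0("n_", consequence_vocab())

  fun <- classified$is_functional
  rare <- classified$rarity == "RARE"
  out <- tibble::tibble(
    symbol = panel$symbol,
    family = panel$family,
    n_total = as.integer(table(sym)),
    !!!conseq_counts,
    n_novel = cnt(is.na(classified$variant_id)),
    n_rare = cnt(rare),
    n_deleterious_missense = cnt(classified$functional_class == "DELETERIOUS_MISSENSE"),
    n_deleterious_missense_rare = cnt(classified$functional_class == "DELETERIOUS_MISSENSE" & rare),
    n_neutral_missense = cnt(classified$functional_class == "NEUTRAL_MISSENSE"),
    n_unclassified_missense = cnt(classified$functional_class == "UNCLASSIFIED_MISSENSE"),
    n_lof = cnt(classified$functional_class == "LOF"),
    n_functional = cnt(fun),
    n_functional_rare = cnt(fun & rare),
    n_functional_common = cnt(fun & !rare)
  )
  agg <- tapply(ifelse(fun, classified$vaf, 0), sym, sum, default = 0)
  if (freq_aggregation == "union") {
    agg <- 1 - tapply(1 - ifelse(fun, classified$vaf, 0), sym, prod,
                      default = 1)
  }
  out$aggregated_functional_freq_pct <- 100 * as.numeric(agg)
  if (fraction_weighting == "count") {
    out$rare_fraction_of_functional <-
      ifelse(out$n_functional > 0, out$n_functional_rare / out$n_functional, NA_real_)
  } else {
    rare_vaf <- tapply(ifelse(fun & rare, classified$vaf, 0), sym, sum, default = 0)
    tot_vaf <- as.numeric(agg)
    out$rare_fraction_of_functional <-
      ifelse(tot_vaf > 0, as.numeric(rare_vaf) / tot_vaf, NA_real_)
  }
  out
}

#' @rdname summarize_genes
#' @param gene A single-row panel tibble; all records must carry its symbol.
#' @export
summarize_gene <- function(classified, gene,
                           fraction_weighting = c("count", "vaf")) {
  stopifnot(nrow(gene) == 1L)
  if (nrow(classified) > 0 && any(classified$gene_symbol != gene$symbol)) {
    stop("records from another gene passed to summarize_gene: ",
         paste(setdiff(unique(classified$gene_symbol), gene$symbol),
               collapse = ", "), call. = FALSE)
  }
  summarize_genes(classified, gene, fraction_weighting)
}

#' Per-family summaries
#'
#' Aggregates gene summaries within each family: number of genes and
#' variants, LoF count, mean and sample (n - 1) standard deviation of the
#' per-gene functional-variant count (SD undefined for a single gene), and
#' the count and percentage of deleterious missense variants that are rare.
#'
#' @param gene_summaries Output of [summarize_genes()].
#' @return Tibble with one row per family present.
#' @export
summarize_families <- function(gene_summaries) {
  gs <- gene_summaries
  split_idx <- split(seq_len(nrow(gs)), gs$family)
  rows <- lapply(names(split_idx), function(fam) {
    i <- split_idx[[fam]]
    n_del <- sum(gs$n_deleterious_missense[i])
    n_del_rare <- sum(gs$n_deleterious_missense_rare[i])
    tibble::tibble(
      family = fam,
      n_genes = length(i),
      n_variants = sum(gs$n_total[i]),
      n_lof = sum(gs$n_lof[i]),
      functional_per_gene_mean = mean(gs$n_functional[i]),
      functional_per_gene_sd = if (length(i) > 1) stats::sd(gs$n_functional[i]) else NA_real_,
      deleterious_missense_count = n_del,
      deleterious_missense_rare_count = n_del_rare,
      deleterious_missense_rare_pct = if (n_del > 0) round_pct(n_del_rare / n_del) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname summarize_families
#' @details `summarize_family()` requires all gene summaries to share one
#'   family and returns a single row.
#' @export
summarize_family <- function(gene_summaries) {
  if (length(unique(gene_summaries$family)) != 1L) {
    stop("summarize_family() requires gene summaries from a single family; got: ",
         paste(unique(gene_summaries$family), collapse = ", "), call. = FALSE)
  }
  summarize_families(gene_summaries)
}

#' Single-nucleotide substitution spectrum
#'
#' Counts the twelve ordered substitution types over SNVs (indels are
#' excluded and tallied separately) and computes the transition/transversion
#' ratio, where transitions are A<->G and C<->T. With transitions but no
#' transversions the ratio is reported as `Inf`.
#'
#' @param records Variant-record tibble.
#' @return List with `spectrum` (tibble: substitution, count, fraction),
#'   `titv_ratio`, `n_snv`, `n_indel`.
#' @export
substitution_spectrum <- function(records) {
  bases <- c("A", "C", "G", "T")
  is_snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% bases & records$alt %in% bases
  types <- as.vector(t(outer(bases, bases, function(r, a) paste0(r, ">", a))))
  types <- types[substr(types, 1, 1) != substr(types, 3, 3)]
  obs <- paste0(records$ref[is_snv], ">", records$alt[is_snv])
  count <- as.integer(table(factor(obs, levels = types)))
  n_snv <- sum(count)
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  ti <- sum(count[types %in% transitions])
  tv <- n_snv - ti
  titv <- if (n_snv == 0L) NA_real_ else if (tv == 0L) Inf else ti / tv
  list(
    spectrum = tibble::tibble(
      substitution = types,
      count = count,
      fraction = if (n_snv > 0) count / n_snv else rep(NA_real_, length(types))
    ),
    titv_ratio = titv,
    n_snv = n_snv,
    n_indel = nrow(records) - n_snv
  )
}

#' Cohort-level overview
#'
#' Totals and the headline fractions: novel (no external identifier), rare
#' (VAF < 1%), and exonic (missense, synonymous, UTR and the four LoF
#' categories; UTR counts as exonic by convention here). Percentages are
#' rounded half-up to one decimal for the report while the full-precision
#' fractions are retained.
#'
#' @param classified Classified variant tibble.
#' @return List of counts, fractions and rounded percentages.
#' @export
cohort_overview <- function(classified) {
  n <- nrow(classified)
  n_novel <- sum(is.na(classified$variant_id))
  n_rare <- sum(classified$rarity == "RARE")
  n_exonic <- sum(classified$consequence %in% exonic_consequences())
  cls <- table(factor(classified$functional_class,
                      levels = c("DELETERIOUS_MISSENSE", "NEUTRAL_MISSENSE",
                                 "UNCLASSIFIED_MISSENSE", "LOF", "NON_FUNCTIONAL")))
  frac <- function(k) if (n > 0) k / n else 0
  list(
    n_total = n,
    n_novel = n_novel, novel_frac = frac(n_novel), novel_pct = round_pct(frac(n_novel)),
    n_rare = n_rare, rare_frac = frac(n_rare), rare_pct = round_pct(frac(n_rare)),
    n_exonic = n_exonic, exonic_frac = frac(n_exonic), exonic_pct = round_pct(frac(n_exonic)),
    n_functional = sum(classified$is_functional),
    class_counts = as.list(cls)
  )
}

#' Fold between the highest and lowest aggregated functional frequencies
#'
#' Ratio of the largest to the smallest positive aggregated
#' functional-variant frequency across genes; genes at exactly zero are
#' excluded from the minimum.
#'
#' @param gene_summaries Output of [summarize_genes()].
#' @return List with the fold (full precision and rounded to one decimal)
#'   and the two gene symbols with their frequencies.
#' @export
fold_range <- function(gene_summaries) {
  pos <- gene_summaries$aggregated_functional_freq_pct > 0
  if (sum(pos) < 2L) {
    stop("fold_range() needs at least two genes with a positive aggregated ",
         "functional-variant frequency; found ", sum(pos), call. = FALSE)
  }
  gs <- gene_summaries[pos, ]
  i_max <- which.max(gs$aggregated_functional_freq_pct)
  i_min <- which.min(gs$aggregated_functional_freq_pct)
  fold <- gs$aggregated_functional_freq_pct[i_max] /
    gs$aggregated_functional_freq_pct[i_min]
  list(
    fold = fold,
    fold_rounded = round_half_up(fold, 1),
    max_symbol = gs$symbol[i_max], max_pct = gs$aggregated_functional_freq_pct[i_max],
    min_symbol = gs$symbol[i_min], min_pct = gs$aggregated_functional_freq_pct[i_min]
  )
}
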