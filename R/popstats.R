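# Statistical layer: Kruskal-Wallis across families, OLS regressions of
# per-gene variant counts on gene length, and pairwise population VAF
# comparison on reconstructed allele counts, all with Bonferroni-adjusted
# significance thresholds.

#' Reconstruct allele counts from a frequency
#'
#' Alternate-allele count is the half-up rounding of `vaf * n_alleles`;
#' the reference count is the remainder.
#'
#' @param vaf Allele frequency in `[0, 1]`.
#' @param n_alleles Total observed allele count (positive integer).
#' @return List with `alt` and `ref` integer vectors.
#' @export
vaf_to_counts <- function(vaf, n_alleles) {
  check_vaf(vaf)
  if (any(is.na(n_alleles)) || any(n_alleles <= 0)) {
    stop("n_alleles must be positive", call. = FALSE)
  }
  alt <- as.integer(round_half_up(vaf * n_alleles, 0))
  list(alt = alt, ref = as.integer(n_alleles) - alt)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param family_wise_alpha Family-wise error rate in (0, 1); default 0.05.
#' @param m Number of tests (>= 1).
#' @return `family_wise_alpha / m` at full precision.
#' @export
bonferroni_alpha <- function(family_wise_alpha = 0.05, m = 1L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (family_wise_alpha <= 0 || family_wise_alpha >= 1) {
    stop("family_wise_alpha must lie in (0, 1)", call. = FALSE)
  }
  family_wise_alpha / m
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Thin wrapper over [stats::fisher.test()] exposing the conditional
#' two-sided p-value used by [compare_populations()], so that it can be
#' checked against exhaustive hypergeometric enumeration.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return P-value.
#' @export
fisher_exact_p <- function(tab) {
  stats::fisher.test(tab)$p.value
}

#' Compare a variant's allele frequency between two populations
#'
#' Reconstructs a 2x2 allele-count table with [vaf_to_counts()] and tests
#' equality of frequencies: Fisher's exact test (two-sided) when any
#' expected cell count is below 5, otherwise Pearson's chi-square without
#' continuity correction. A degenerate table (an all-zero allele column)
#' yields p = 1 with a degenerate flag instead of an error.
#'
#' @param a,b Single population observations: lists or one-row tibbles with
#'   fields `population`, `vaf`, `n_alleles` (and optionally chrom/pos/
#'   ref/alt for the variant key).
#' @param alpha_adjusted Significance threshold after multiplicity
#'   adjustment (see [bonferroni_alpha()]).
#' @param correct Apply the Yates continuity correction to the chi-square
#'   test; off by default.
#' @return One-row tibble: variant key, populations, the four counts, test
#'   used, statistic (chi-square only), p-value, threshold, significance and
#'   degeneracy flags.
#' @export
compare_populations <- function(a, b, alpha_adjusted = 0.05, correct = FALSE) {
  key <- if (!is.null(a$chrom)) {
    variant_key(a$chrom, a$pos, a$ref, a$alt)
  } else {
    NA_character_
  }
  ca <- vaf_to_counts(a$vaf, a$n_alleles)
  cb <- vaf_to_counts(b$vaf, b$n_alleles)
  tab <- matrix(c(ca$alt, ca$ref, cb$alt, cb$ref), nrow = 2, byrow = TRUE)

  degenerate <- any(colSums(tab) == 0L) || any(rowSums(tab) == 0L)
  if (degenerate) {
    test_used <- NA_character_
    statistic <- NA_real_
    p <- 1
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test_used <- "fisher_exact"
      statistic <- NA_real_
      p <- fisher_exact_p(tab)
    } else {
      test_used <- "chi_square"
      ht <- stats::chisq.test(tab, correct = correct)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  }
  tibble::tibble(
    variant_key = key,
    population_a = as.character(a$population),
    population_b = as.character(b$population),
    alt_a = tab[1, 1], ref_a = tab[1, 2],
    alt_b = tab[2, 1], ref_b = tab[2, 2],
    test_used = test_used,
    statistic = statistic,
    p_value = p,
    alpha_adjusted = alpha_adjusted,
    significant = p < alpha_adjusted,
    degenerate = degenerate
  )
}

#' Compare every population against a reference, per variant
#'
#' Runs [compare_populations()] for each variant between the reference
#' population and every other population in a long-format VAF table. The
#' Bonferroni divisor defaults to the number of comparisons performed.
#'
#' @param pop_table Tibble from [read_population_table()].
#' @param reference Reference population label.
#' @param family_wise_alpha Family-wise error rate (default 0.05).
#' @param m Bonferroni divisor; `NULL` uses the number of comparisons.
#' @return Tibble of comparison results.
#' @export
compare_population_table <- function(pop_table, reference,
                                     family_wise_alpha = 0.05, m = NULL) {
  if (!reference %in% pop_table$population) {
    stop("reference population not present: ", reference, call. = FALSE)
  }
  pop_table$.key <- variant_key(pop_table$chrom, pop_table$pos,
                                pop_table$ref, pop_table$alt)
  others <- pop_table[pop_table$population != reference, ]
  refs <- pop_table[pop_table$population == reference, ]
  if (is.null(m)) m <- nrow(others)
  alpha <- bonferroni_alpha(family_wise_alpha, m)
  rows <- lapply(seq_len(nrow(others)), function(i) {
    b <- others[i, ]
    a <- refs[refs$.key == b$.key, ]
    if (nrow(a) != 1L) {
      stop("variant ", b$.key, " has ", nrow(a),
           " rows for reference population ", reference, call. = FALSE)
    }
    compare_populations(a, b, alpha)
  })
  dplyr::bind_rows(rows)
}

#' Kruskal-Wallis test of per-gene counts across families
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' (groups - 1) degrees of freedom, via [stats::kruskal.test()].
#'
#' @param counts Numeric vector of per-gene counts.
#' @param families Grouping vector of the same length (or, alternatively,
#'   pass a named list of numeric vectors as `counts` and omit `families`).
#' @return List with `H`, `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis_by_family <- function(counts, families = NULL) {
  if (is.list(counts) && is.null(families)) {
    families <- rep(names(counts), lengths(counts))
    counts <- unlist(counts, use.names = FALSE)
  }
  groups <- unique(families[!is.na(counts)])
  if (length(groups) < 2L) {
    stop("Kruskal-Wallis needs at least two non-empty groups; found ",
         length(groups), call. = FALSE)
  }
  if (length(unique(counts)) == 1L) {
    # all observations tied: no rank variation, H is 0 by convention
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                n_groups = length(groups)))
  }
  ht <- stats::kruskal.test(counts, factor(families))
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n_groups = length(groups))
}

#' OLS regression of variant counts on gene length
#'
#' Ordinary least squares of a per-gene count on gene length in kb, with a
#' two-sided t-test of zero slope and a Bonferroni-adjusted threshold
#' (default 0.05/18: six families times three response types).
#'
#' @param length_kb Gene lengths (kb).
#' @param count Per-gene variant counts (same length; >= 3 genes).
#' @param response Response label, e.g. "total", "missense", "deleterious".
#' @param family Family label carried into the result.
#' @param alpha_adjusted Adjusted significance threshold.
#' @return One-row tibble with slope (variants per kb), intercept,
#'   r_squared, the slope's 95% CI, p_value, threshold and significance.
#' @export
regress_counts_on_length <- function(length_kb, count, response = "total",
                                     family = NA_character_,
                                     alpha_adjusted = bonferroni_alpha(0.05, 18)) {
  if (length(length_kb) < 3L) {
    stop("regression needs at least 3 genes; got ", length(length_kb),
         call. = FALSE)
  }
  if (stats::var(length_kb) == 0) {
    stop("gene lengths have zero variance; slope is not identifiable",
         call. = FALSE)
  }
  if (stats::var(count) == 0) {
    # constant response: zero slope, no explained variance
    return(tibble::tibble(
      family = family, response = response, n_genes = length(length_kb),
      slope = 0, intercept = mean(count), r_squared = 0,
      slope_ci_low = 0, slope_ci_high = 0,
      p_value = 1, alpha_adjusted = alpha_adjusted, significant = FALSE))
  }
  fit <- stats::lm(count ~ length_kb)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, "length_kb", level = 0.95)
  p <- co["length_kb", "Pr(>|t|)"]
  tibble::tibble(
    family = family,
    response = response,
    n_genes = length(length_kb),
    slope = unname(co["length_kb", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    r_squared = sm$r.squared,
    slope_ci_low = ci[1], slope_ci_high = ci[2],
    p_value = p,
    alpha_adjusted = alpha_adjusted,
    significant = p < alpha_adjusted
  )
}

#' Length regressions for every family and response type
#'
#' Fits [regress_counts_on_length()] within each family for the three
#' response types (total, missense, deleterious missense), mirroring the
#' 18-test design behind the 0.05/18 threshold.
#'
#' @param gene_summaries Output of [summarize_genes()].
#' @param panel Gene panel (provides length_kb).
#' @param family_wise_alpha Family-wise error rate.
#' @param m Bonferroni divisor; `NULL` uses families x responses.
#' @return Tibble with one row per (family, response) fit.
#' @export
regress_families <- function(gene_summaries, panel, family_wise_alpha = 0.05,
                             m = NULL) {
  gs <- dplyr::left_join(gene_summaries,
                         panel[, c("symbol", "length_kb")], by = "symbol")
  responses <- c(total = "n_total", missense = "n_missense",
                 deleterious = "n_deleterious_missense")
  fams <- unique(gs$family)
  if (is.null(m)) m <- length(fams) * length(responses)
  alpha <- bonferroni_alpha(family_wise_alpha, m)
  rows <- list()
  for (fam in fams) {
    sub <- gs[gs$family == fam, ]
    for (resp in names(responses)) {
      rows[[length(rows) + 1L]] <- regress_counts_on_length(
        sub$length_kb, sub[[responses[[resp]]]], response = resp,
        family = fam, alpha_adjusted = alpha)
    }
  }
  dplyr::bind_rows(rows)
}
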