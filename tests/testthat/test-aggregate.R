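test_that("gene summaries tally classes and sum functional VAFs into percent", {
  records <- make_records(
    5,
    consequence = c("missense", "missense", "stop_gained", "synonymous",
                    "missense"),
    vaf = c(0.01, 0.005, 0.002, 0.3, 0.05),
    sift = c("damaging", "damaging", "missing", "missing", "tolerated"),
    polyphen2 = c("damaging", "damaging", "missing", "missing", "tolerated"),
    provean = c("damaging", "damaging", "missing", "missing", "tolerated"))
  cl <- classify_variants(records)
  gs <- summarize_genes(cl, make_panel())
  # two functional missense at 0.01 + 0.005 plus one LoF at 0.002
  expect_equal(gs$n_functional, 3L)
  expect_equal(gs$aggregated_functional_freq_pct, 1.7)
  expect_equal(gs$n_functional_rare, 2L)
  expect_equal(gs$rare_fraction_of_functional, 2 / 3)
  expect_equal(gs$n_functional_rare + gs$n_functional_common, gs$n_functional)
  # union aggregation multiplies complements instead of summing
  gs_u <- summarize_genes(cl, make_panel(), freq_aggregation = "union")
  expect_equal(gs_u$aggregated_functional_freq_pct,
               100 * (1 - 0.99 * 0.995 * 0.998))
  # consequence counts sum to the total
  conseq_cols <- paste0("n_", consequence_vocab())
  expect_equal(sum(unlist(gs[, conseq_cols])), gs$n_total)

  # a gene with no functional variants: zero percent, undefined fraction
  neutral <- classify_variants(make_records(2, consequence = "synonymous",
                                            vaf = 0.2))
  gs0 <- summarize_genes(neutral, make_panel())
  expect_equal(gs0$aggregated_functional_freq_pct, 0)
  expect_true(is.na(gs0$rare_fraction_of_functional))

  # records from a foreign gene are refused by the single-gene summary
  expect_error(summarize_gene(cl, make_panel("OTHERGENE")), "another gene")
})

test_that("adding one functional variant raises the aggregated frequency by 100v", {
  set.seed(11)
  panel <- make_panel()
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    cl <- classify_variants(make_records(
      n, consequence = "missense", vaf = runif(n, 0, 0.3),
      sift = sample(c("damaging", "tolerated"), n, replace = TRUE),
      polyphen2 = sample(c("damaging", "tolerated"), n, replace = TRUE),
      provean = sample(c("damaging", "tolerated"), n, replace = TRUE)))
    v <- runif(1, 0, 0.2)
    extra <- classify_variants(make_records(
      1, pos = 99999L, vaf = v, consequence = "stop_gained",
      sift = "missing", polyphen2 = "missing", provean = "missing"))
    before <- summarize_genes(cl, panel)
    after <- summarize_genes(dplyr::bind_rows(cl, extra), panel)
    expect_equal(after$aggregated_functional_freq_pct,
                 before$aggregated_functional_freq_pct + 100 * v)
    expect_gte(after$n_functional_rare, before$n_functional_rare)
    expect_gte(after$n_functional_common, before$n_functional_common)
  }
})

test_that("family summaries compute per-gene means, sample SD and rare percentages", {
  gs <- tibble::tibble(
    symbol = c("A1", "A2", "A3"), family = "ABC",
    n_total = c(10L, 20L, 30L), n_lof = c(1L, 2L, 0L),
    n_functional = c(2L, 4L, 6L),
    n_deleterious_missense = c(60L, 60L, 43L),
    n_deleterious_missense_rare = c(55L, 60L, 42L))
  fs <- summarize_family(gs)
  expect_equal(fs$functional_per_gene_mean, 4.0)
  expect_equal(fs$functional_per_gene_sd, 2.0)
  # 157 rare of 163 deleterious missense reports as 96.3%
  expect_equal(fs$deleterious_missense_rare_count, 157L)
  expect_equal(fs$deleterious_missense_count, 163L)
  expect_equal(fs$deleterious_missense_rare_pct, 96.3)

  single <- summarize_family(gs[1, ])
  expect_true(is.na(single$functional_per_gene_sd))

  gs$family <- c("ABC", "ABC", "SLC")
  expect_error(summarize_family(gs), "single family")
})

test_that("substitution spectrum counts the 12 SNV types and the Ti/Tv ratio", {
  # transitions only: infinite sentinel, C>T carries 3 of 4 SNVs
  rec <- make_records(4, ref = c("C", "C", "C", "G"),
                      alt = c("T", "T", "T", "A"))
  sp <- substitution_spectrum(rec)
  expect_equal(sp$titv_ratio, Inf)
  expect_equal(sp$spectrum$fraction[sp$spectrum$substitution == "C>T"], 0.75)

  # 2 transitions vs 1 transversion
  rec2 <- make_records(3, ref = "A", alt = c("G", "G", "C"))
  expect_equal(substitution_spectrum(rec2)$titv_ratio, 2.0)

  # one of each of the 12 ordered types: 4 transitions over 8 transversions
  bases <- c("A", "C", "G", "T")
  all12 <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  all12 <- all12[all12$ref != all12$alt, ]
  rec12 <- make_records(12, ref = all12$ref, alt = all12$alt)
  sp12 <- substitution_spectrum(rec12)
  expect_equal(sp12$titv_ratio, 0.5)
  expect_equal(sum(sp12$spectrum$fraction), 1)

  # indels are excluded from the spectrum but counted
  mixed <- make_records(3, ref = c("A", "AT", "G"), alt = c("G", "A", "C"))
  spm <- substitution_spectrum(mixed)
  expect_equal(spm$n_snv, 2L)
  expect_equal(spm$n_indel, 1L)
  expect_equal(sum(spm$spectrum$fraction), 1)
})

test_that("cohort overview reproduces headline fractions from raw tallies", {
  n <- 38188L
  consequence <- rep("intronic", n)
  consequence[1:2554] <- c(rep("missense", 1063), rep("utr", 799),
                           rep("synonymous", 638), rep("stop_gained", 54))
  cl <- tibble::tibble(
    variant_id = c(rep(NA_character_, 1038), paste0("rs", seq_len(n - 1038))),
    consequence = consequence,
    rarity = c(rep("RARE", 14294), rep("COMMON", n - 14294)),
    functional_class = "NON_FUNCTIONAL",
    is_functional = FALSE)
  ov <- cohort_overview(cl)
  expect_equal(ov$novel_pct, 2.7)
  expect_equal(ov$rare_pct, 37.4)
  expect_equal(ov$exonic_pct, 6.7)
  expect_equal(ov$n_exonic, 2554L)

  empty <- cohort_overview(cl[0, ])
  expect_equal(empty$novel_pct, 0.0)
  expect_equal(empty$rare_pct, 0.0)
})

test_that("fold range takes max over min of positive aggregated frequencies", {
  gs <- tibble::tibble(symbol = c("GSTA5", "IFNL3"),
                       aggregated_functional_freq_pct = c(88.17, 0.09))
  fr <- fold_range(gs)
  expect_equal(fr$fold_rounded, 979.7)
  expect_equal(fr$max_symbol, "GSTA5")
  expect_equal(fr$min_symbol, "IFNL3")

  same <- tibble::tibble(symbol = c("A", "B"),
                         aggregated_functional_freq_pct = c(5, 5))
  expect_equal(fold_range(same)$fold, 1.0)

  with_zero <- tibble::tibble(symbol = c("A", "B", "C"),
                              aggregated_functional_freq_pct = c(2, 0, 1))
  expect_equal(fold_range(with_zero)$fold, 2.0)

  expect_error(fold_range(with_zero[1:2, ]), "at least two")
})

test_that("percentages round half-up to one decimal", {
  expect_equal(round_pct(562 / 617), 91.1)
  expect_equal(round_pct(53 / 54), 98.1)
  expect_equal(round_pct(31 / 32), 96.9)   # 96.875 rounds up
  expect_equal(round_pct(36 / 40), 90.0)
  expect_equal(round_pct(0.0005), 0.1)     # exact .05 boundary goes up
  expect_equal(round_pct(0), 0)
  expect_equal(round_pct(1), 100)
})
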