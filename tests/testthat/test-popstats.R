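test_that("allele counts reconstruct from frequencies with half-up rounding", {
  expect_equal(vaf_to_counts(0.5, 100), list(alt = 50L, ref = 50L))
  expect_equal(vaf_to_counts(0, 282862), list(alt = 0L, ref = 282862L))
  # 0.2021 x 282,862 = 57,166.4 rounds to 57,166
  expect_equal(vaf_to_counts(0.2021, 282862), list(alt = 57166L, ref = 225696L))
  expect_error(vaf_to_counts(1.2, 100), "\\[0, 1\\]")
  expect_error(vaf_to_counts(0.5, 0), "positive")
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 18), 0.05 / 18)
  expect_equal(bonferroni_alpha(0.05, 72), 0.05 / 72)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
  expect_error(bonferroni_alpha(1.2, 3), "family_wise_alpha")
  # the threshold shrinks monotonically in the number of tests
  alphas <- sapply(1:50, function(m) bonferroni_alpha(0.05, m))
  expect_true(all(diff(alphas) < 0))
})

test_that("population comparison picks the test, flags degeneracy, is symmetric", {
  a <- list(population = "P1", vaf = 0.1, n_alleles = 2000)
  b <- list(population = "P2", vaf = 0.1, n_alleles = 2000)
  same <- compare_populations(a, b, 0.05)
  expect_equal(same$test_used, "chi_square")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # small expected cells trigger Fisher; p agrees with full enumeration
  small_a <- list(population = "P1", vaf = 1 / 10, n_alleles = 10)
  small_b <- list(population = "P2", vaf = 2 / 10, n_alleles = 10)
  res <- compare_populations(small_a, small_b, 0.05)
  expect_equal(res$test_used, "fisher_exact")
  expect_equal(res$p_value,
               fisher_enum_p(matrix(c(1, 9, 2, 8), 2, byrow = TRUE)))

  # absent in both populations: degenerate, p = 1, no exception
  zero <- compare_populations(list(population = "P1", vaf = 0, n_alleles = 912),
                              list(population = "P2", vaf = 0, n_alleles = 316),
                              0.05)
  expect_true(zero$degenerate)
  expect_equal(zero$p_value, 1)

  # swapping the populations never changes the p-value
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    x <- list(population = "A", vaf = sample(0:n1, 1) / n1, n_alleles = n1)
    y <- list(population = "B", vaf = sample(0:n2, 1) / n2, n_alleles = n2)
    expect_equal(compare_populations(x, y, 0.05)$p_value,
                 compare_populations(y, x, 0.05)$p_value)
  }
})

test_that("reference comparisons over the clinical table mirror the 72-test design", {
  path <- system.file("extdata", "population_vaf_clinical_synthetic_an.tsv",
                      package = "pgxlandscape")
  tab <- read_population_table(path)
  cmp <- compare_population_table(tab, "CMDB_Chinese", m = 72)
  expect_equal(nrow(cmp), 72L)  # 8 variants x 9 non-reference populations
  expect_equal(unique(cmp$alpha_adjusted), 0.05 / 72)
  expect_true(all(cmp$significant == (cmp$p_value < 0.05 / 72)))
  # allele counts add back to each population's allele number
  expect_equal(unique(cmp$alt_a + cmp$ref_a), 282862L)
  # rs671 is common in the Chinese cohort but absent or very rare elsewhere
  rs671 <- cmp[cmp$variant_key == "chr12:112241766:G:A", ]
  expect_true(all(rs671$significant[rs671$population_b != "East_Asian"]))
})

test_that("Kruskal-Wallis matches direct rank arithmetic and handles ties", {
  groups <- list(a = 1:3, b = 4:6, c = 7:9)
  kw <- kruskal_wallis_by_family(groups)
  # direct computation on the 9 ranks: H = 12/(N(N+1)) sum R_j^2/n_j - 3(N+1)
  expect_equal(kw$H, 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10)
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  flat <- kruskal_wallis_by_family(list(a = c(5, 5), b = c(5, 5)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p_value, 1)

  # tie correction divides by a factor <= 1, so H can only grow
  x <- c(1, 2, 2, 3, 5, 6)
  fam <- c("a", "a", "a", "b", "b", "b")
  r <- rank(x)
  n <- length(x)
  h_uncorrected <- 12 / (n * (n + 1)) *
    sum(tapply(r, fam, sum)^2 / tapply(r, fam, length)) - 3 * (n + 1)
  expect_gte(kruskal_wallis_by_family(x, fam)$H, h_uncorrected)

  expect_error(kruskal_wallis_by_family(list(a = 1:3)), "two")
})

test_that("length regression recovers exact fits and flags degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  # summary.lm warns on a residual-free fit; the point estimates are exact
  exact <- suppressWarnings(regress_counts_on_length(x, 2 * x + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- regress_counts_on_length(x, rep(7, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_false(flat$significant)

  expect_error(regress_counts_on_length(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regress_counts_on_length(rep(2, 5), 1:5), "zero variance")

  # parameter recovery: 50 genes at 5 variants/kb plus Poisson noise
  set.seed(202)
  len <- runif(50, 5, 100)
  cnt <- rpois(50, 5 * len)
  fit <- regress_counts_on_length(len, cnt, response = "total", family = "SLC")
  expect_true(fit$slope_ci_low <= 5 && 5 <= fit$slope_ci_high)
  expect_true(fit$significant)
})

test_that("family regressions cover six families by three responses", {
  cfg <- sim_config(seed = 9)
  panel <- generate_panel(cfg)
  cl <- classify_variants(generate_variants(panel, cfg)$variants)
  gs <- summarize_genes(cl, panel)
  reg <- regress_families(gs, panel)
  expect_equal(nrow(reg), 18L)
  expect_equal(unique(reg$alpha_adjusted), 0.05 / 18)
  expect_setequal(unique(reg$response), c("total", "missense", "deleterious"))
  expect_true(all(reg$r_squared >= 0 & reg$r_squared <= 1))
  # counts scale with length, so the total-variant slopes sit near the
  # generating density
  tot <- reg[reg$response == "total", ]
  expect_true(all(abs(tot$slope - cfg$variants_per_kb) < 1))
})
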