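test_that("VQSR filter keeps scores at or above threshold and unscored records", {
  records <- make_records(4, vqsr_score = c(36, 34.9, 35, NA))
  flt <- filter_vqsr(records, 35)
  expect_equal(flt$kept$vqsr_score, c(36, 35, NA))
  expect_equal(flt$dropped$vqsr_score, 34.9)
  expect_equal(flt$n_unscored, 1L)
  expect_equal(nrow(flt$kept) + nrow(flt$dropped), nrow(records))
  expect_error(filter_vqsr(records, -1), "non-negative")
})

test_that("rarity is a strict 1% threshold with the boundary on the common side", {
  expect_equal(classify_rarity(0.005), "RARE")
  expect_equal(classify_rarity(0.0871), "COMMON")
  expect_equal(classify_rarity(0.01), "COMMON")
  expect_error(classify_rarity(-0.1), "\\[0, 1\\]")
  expect_error(classify_rarity(1.1), "\\[0, 1\\]")

  set.seed(101)
  v <- c(runif(500), 0, 1, 0.01, 0.00999999)
  expect_equal(classify_rarity(v) == "RARE", v < 0.01)
})

test_that("consensus rule matches brute-force enumeration over all 27 call triples", {
  triples <- call_triples()
  got <- consensus_missense(triples$sift, triples$polyphen2, triples$provean)
  want <- mapply(consensus_oracle, triples$sift, triples$polyphen2,
                 triples$provean, USE.NAMES = FALSE)
  expect_equal(got, want)
  # the spot checks behind the rule
  expect_equal(consensus_missense("damaging", "damaging", "tolerated"),
               "DELETERIOUS_MISSENSE")
  expect_equal(consensus_missense("tolerated", "tolerated", "tolerated"),
               "NEUTRAL_MISSENSE")
  # one damaging of two available calls is exactly 50%
  expect_equal(consensus_missense("damaging", "tolerated", "missing"),
               "DELETERIOUS_MISSENSE")
  expect_equal(consensus_missense("missing", "missing", "missing"),
               "UNCLASSIFIED_MISSENSE")
  expect_error(consensus_missense("bad_token", "missing", "missing"),
               "bad_token")
})

test_that("turning a tolerated call damaging never demotes the consensus", {
  rank <- c(NEUTRAL_MISSENSE = 1, UNCLASSIFIED_MISSENSE = 1,
            DELETERIOUS_MISSENSE = 2)
  triples <- call_triples()
  for (i in seq_len(nrow(triples))) {
    before <- consensus_missense(triples$sift[i], triples$polyphen2[i],
                                 triples$provean[i])
    for (j in 1:3) {
      if (triples[i, j] == "tolerated") {
        flipped <- triples[i, ]
        flipped[j] <- "damaging"
        after <- consensus_missense(flipped$sift, flipped$polyphen2,
                                    flipped$provean)
        expect_gte(rank[[after]], rank[[before]])
      }
    }
  }
})

test_that("LoF assignment covers the four categories with optional CADD demotion", {
  expect_true(classify_lof("splice_donor"))
  expect_true(classify_lof("stop_gained"))
  expect_true(classify_lof("start_lost"))
  expect_false(classify_lof("missense"))
  expect_false(classify_lof("synonymous"))

  # splice variant below the CADD threshold is demoted and logged
  res <- suppressMessages(
    classify_lof("splice_acceptor", cadd_phred = 5, cadd_threshold = 20))
  expect_false(as.logical(res))
  expect_equal(attr(res, "n_demoted"), 1L)
  # without the optional threshold all splice variants stay LoF
  expect_true(classify_lof("splice_acceptor", cadd_phred = 5))
  # stop gained is LoF regardless of CADD
  expect_true(as.logical(classify_lof("stop_gained", cadd_phred = 1,
                                      cadd_threshold = 20)))
})

test_that("full classification composes rarity and function into one partition", {
  records <- make_records(
    5,
    consequence = c("missense", "synonymous", "stop_gained", "missense",
                    "intronic"),
    vaf = c(0.002, 0.3, 0.0001, 0.05, 0.01),
    sift = c("damaging", "missing", "missing", "tolerated", "missing"),
    polyphen2 = c("damaging", "missing", "missing", "tolerated", "missing"),
    provean = c("damaging", "missing", "missing", "tolerated", "missing"))
  cl <- classify_variants(records)
  expect_equal(cl$rarity,
               c("RARE", "COMMON", "RARE", "COMMON", "COMMON"))
  expect_equal(cl$functional_class,
               c("DELETERIOUS_MISSENSE", "NON_FUNCTIONAL", "LOF",
                 "NEUTRAL_MISSENSE", "NON_FUNCTIONAL"))
  expect_equal(cl$is_functional, c(TRUE, FALSE, TRUE, FALSE, FALSE))

  # partition: every variant lands in exactly one class, tallies conserve n
  set.seed(7)
  cfg <- sim_config(seed = 7, genes_per_family = c(ABC = 2L, SLC = 2L,
                                                   PHASE1 = 1L, PHASE2 = 1L,
                                                   NUCLEAR_RECEPTOR = 1L,
                                                   OTHER = 1L))
  sim <- generate_variants(generate_panel(cfg), cfg)
  big <- classify_variants(sim$variants)
  classes <- c("DELETERIOUS_MISSENSE", "NEUTRAL_MISSENSE",
               "UNCLASSIFIED_MISSENSE", "LOF", "NON_FUNCTIONAL")
  expect_true(all(big$functional_class %in% classes))
  expect_equal(sum(table(big$functional_class)), nrow(big))
  expect_equal(big$is_functional,
               big$functional_class %in% c("DELETERIOUS_MISSENSE", "LOF"))
  # missense-only classes sit on missense consequences, LoF on LoF categories
  expect_true(all(big$consequence[big$functional_class %in%
    c("DELETERIOUS_MISSENSE", "NEUTRAL_MISSENSE", "UNCLASSIFIED_MISSENSE")] ==
      "missense"))
  expect_true(all(big$consequence[big$functional_class == "LOF"] %in%
                    lof_consequences()))
})
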