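# Synthetic cohort generator: a gene panel, an annotated variant table with
# a latent-deleteriousness truth table, and a multi-population VAF table
# under Balding-Nichols divergence. Defaults emulate the magnitudes of a
# large biobank pharmacogene screen (~38,000 variants over 125 genes,
# ~37.4% rare, ~2.7% novel, transition-dominated substitutions).

#' Simulation configuration
#'
#' Builds and validates the full parameterization of the synthetic
#' variant-table generator. Defaults describe a 125-gene panel (16 ABC, 50
#' SLC, 17 phase 1, 26 phase 2, 9 nuclear receptor, 7 other) observed in a
#' cohort of 141,431 diploid genomes, with a 37.4% rare-variant target, a
#' 2.7% novel-identifier rate, a consequence mix that is ~93% non-coding,
#' and a transition-biased substitution model.
#'
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @param genes_per_family Named integer vector over the six families.
#' @param length_kb_meanlog,length_kb_sdlog Log-normal parameters of gene
#'   length in kb.
#' @param variants_per_kb Expected variants per kb of gene length (Poisson).
#' @param rare_target Intended fraction of variants with VAF < 1%.
#' @param n_cohort_alleles Cohort allele count (2 x diploid sample size);
#'   sets the lower bound 1/n of the rare VAF bin.
#' @param consequence_probs Named multinomial over the ten consequence
#'   categories (normalized internally).
#' @param p_deleterious_latent Probability a missense variant is truly
#'   deleterious.
#' @param predictor_accuracy Per-tool probability of calling the latent
#'   state correctly (scalar or named vector over sift/polyphen2/provean).
#' @param p_missing_call Per-tool probability a call is missing.
#' @param p_novel Probability a variant lacks an external identifier.
#' @param transition_prob Probability a substitution is the transition
#'   partner of the reference base.
#' @param vqsr_mean,vqsr_sd Normal parameters of the Phred-scaled VQSR
#'   score.
#' @param fst Balding-Nichols divergence for the population table, in
#'   `[0, 1)`.
#' @param n_populations,n_alleles_per_population Population-table shape.
#' @param vaf_model `"uniform_bins"` (rare VAFs uniform on `[1/n, 0.01)`,
#'   common uniform on `[0.01, 0.5]`) or `"beta"` (a Beta(0.2, 2) spectrum
#'   truncated to the same bins, for stress tests).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genes_per_family = c(ABC = 16L, SLC = 50L, PHASE1 = 17L,
                                            PHASE2 = 26L, NUCLEAR_RECEPTOR = 9L,
                                            OTHER = 7L),
                       length_kb_meanlog = log(40), length_kb_sdlog = 0.8,
                       variants_per_kb = 5.5,
                       rare_target = 0.374,
                       n_cohort_alleles = 282862L,
                       consequence_probs = c(intronic = 0.8500, upstream = 0.0450,
                                             downstream = 0.0381, utr = 0.0210,
                                             missense = 0.0279, synonymous = 0.0167,
                                             splice_acceptor = 0.00010,
                                             splice_donor = 0.00011,
                                             start_lost = 0.00026,
                                             stop_gained = 0.00094),
                       p_deleterious_latent = 0.58,
                       predictor_accuracy = 0.95,
                       p_missing_call = 0.05,
                       p_novel = 0.027,
                       transition_prob = 0.67,
                       vqsr_mean = 60, vqsr_sd = 10,
                       fst = 0.1,
                       n_populations = 4L,
                       n_alleles_per_population = 10000L,
                       vaf_model = c("uniform_bins", "beta")) {
  vaf_model <- match.arg(vaf_model)
  if (!setequal(names(genes_per_family), family_levels())) {
    stop("genes_per_family must be named by the six family labels", call. = FALSE)
  }
  if (sum(genes_per_family) <= 0) stop("zero genes in panel", call. = FALSE)
  if (!setequal(names(consequence_probs), consequence_vocab())) {
    stop("consequence_probs must be named by the consequence vocabulary",
         call. = FALSE)
  }
  if (any(consequence_probs < 0)) stop("consequence_probs must be >= 0", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  probs <- c(rare_target, p_deleterious_latent, p_missing_call, p_novel,
             transition_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (variants_per_kb <= 0) stop("variants_per_kb must be positive", call. = FALSE)
  acc <- predictor_accuracy
  if (length(acc) == 1L) acc <- stats::setNames(rep(acc, 3), predictor_names())
  if (!setequal(names(acc), predictor_names()) || any(acc < 0 | acc > 1)) {
    stop("predictor_accuracy must be a scalar or named over the three tools, in [0, 1]",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    genes_per_family = genes_per_family,
    length_kb_meanlog = length_kb_meanlog, length_kb_sdlog = length_kb_sdlog,
    variants_per_kb = variants_per_kb,
    rare_target = rare_target,
    n_cohort_alleles = as.integer(n_cohort_alleles),
    consequence_probs = consequence_probs / sum(consequence_probs),
    p_deleterious_latent = p_deleterious_latent,
    predictor_accuracy = acc,
    p_missing_call = p_missing_call,
    p_novel = p_novel,
    transition_prob = transition_prob,
    vqsr_mean = vqsr_mean, vqsr_sd = vqsr_sd,
    fst = fst,
    n_populations = as.integer(n_populations),
    n_alleles_per_population = as.integer(n_alleles_per_population),
    vaf_model = vaf_model
  ), class = "sim_config")
}

# Each generator seeds its own substream from the config seed so the three
# artifacts are independently reproducible.
sim_seed <- function(config, stream) {
  offset <- c(panel = 101L, variants = 211L, populations = 307L)[[stream]]
  (config$seed * 1000L + offset) %% .Machine$integer.max
}

#' Generate a synthetic gene panel
#'
#' Samples log-normal gene lengths per family and lays the genes out on
#' per-family synthetic chromosomes with non-overlapping coordinates.
#'
#' @param config A [sim_config()].
#' @return Gene-panel tibble (symbol, family, chrom, start, end, length_kb).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "panel"))
  fams <- rep(names(config$genes_per_family), config$genes_per_family)
  n <- length(fams)
  if (n == 0L) stop("zero genes in panel", call. = FALSE)
  length_bp <- pmax(1000L, as.integer(round(
    1000 * stats::rlnorm(n, config$length_kb_meanlog, config$length_kb_sdlog))))
  panel <- tibble::tibble(
    symbol = paste0(fams, sprintf("%03d", stats::ave(seq_len(n), fams,
                                                     FUN = seq_along))),
    family = fams,
    chrom = paste0("chr", match(fams, family_levels()))
  )
  # lay genes end to end with a 10 kb spacer per chromosome
  start <- integer(n)
  for (ch in unique(panel$chrom)) {
    i <- which(panel$chrom == ch)
    start[i] <- cumsum(c(1L, utils::head(length_bp[i], -1L) + 10000L))
  }
  panel$start <- start
  panel$end <- start + length_bp - 1L
  validate_panel(panel)
}

#' Generate a synthetic annotated variant table with ground truth
#'
#' Per gene the variant count is Poisson in the gene length; positions are
#' uniform within the gene; substitutions are transition-biased; VAFs come
#' from the configured rare/common mixture; consequences are multinomial;
#' missense variants receive a latent deleterious state and three noisy
#' predictor calls. The latent states are returned in a separate truth
#' table that the pipeline never reads.
#'
#' @param panel Gene panel from [generate_panel()].
#' @param config A [sim_config()].
#' @return List with `variants` (annotated record tibble) and `truth`
#'   (per-variant latent state).
#' @export
generate_variants <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "variants"))
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")

  n_per_gene <- stats::rpois(nrow(panel), panel$length_kb * config$variants_per_kb)
  g <- rep(seq_len(nrow(panel)), n_per_gene)
  n <- length(g)
  pos <- panel$start[g] +
    floor(stats::runif(n) * (panel$end[g] - panel$start[g] + 1))
  ref <- sample(bases, n, replace = TRUE)
  is_ti <- stats::runif(n) < config$transition_prob
  alt <- character(n)
  alt[is_ti] <- transition_of[ref[is_ti]]
  tv_choice <- stats::runif(n) < 0.5
  for (b in bases) {
    i <- !is_ti & ref == b
    tvs <- setdiff(bases, c(b, transition_of[[b]]))
    alt[i] <- ifelse(tv_choice[i], tvs[1], tvs[2])
  }

  is_rare <- stats::runif(n) < config$rare_target
  lo <- 1 / config$n_cohort_alleles
  vaf <- numeric(n)
  if (config$vaf_model == "uniform_bins") {
    vaf[is_rare] <- stats::runif(sum(is_rare), lo, 0.01)
    vaf[!is_rare] <- stats::runif(sum(!is_rare), 0.01, 0.5)
  } else {
    draw_bin <- function(k, lower, upper) {
      out <- numeric(k)
      todo <- seq_len(k)
      while (length(todo) > 0) {
        x <- stats::rbeta(length(todo), 0.2, 2) / 2
        ok <- x >= lower & x < upper
        out[todo[ok]] <- x[ok]
        todo <- todo[!ok]
      }
      out
    }
    vaf[is_rare] <- draw_bin(sum(is_rare), lo, 0.01)
    vaf[!is_rare] <- draw_bin(sum(!is_rare), 0.01, 0.5)
  }

  consequence <- sample(names(config$consequence_probs), n, replace = TRUE,
                        prob = config$consequence_probs)
  novel <- stats::runif(n) < config$p_novel
  variant_id <- ifelse(novel, NA_character_,
                       paste0("rs", 10000000L + seq_len(n)))
  vqsr <- pmax(1, stats::rnorm(n, config$vqsr_mean, config$vqsr_sd))

  mis <- consequence == "missense"
  latent <- rep(NA, n)
  latent[mis] <- stats::runif(sum(mis)) < config$p_deleterious_latent
  calls <- matrix("missing", n, 3, dimnames = list(NULL, predictor_names()))
  for (p in predictor_names()) {
    u_miss <- stats::runif(n) < config$p_missing_call
    u_correct <- stats::runif(n) < config$predictor_accuracy[[p]]
    truth_call <- ifelse(latent, "damaging", "tolerated")
    noisy <- ifelse(u_correct, truth_call,
                    ifelse(truth_call == "damaging", "tolerated", "damaging"))
    calls[mis & !u_miss, p] <- noisy[mis & !u_miss]
  }
  splice <- consequence %in% c("splice_acceptor", "splice_donor")
  cadd <- rep(NA_real_, n)
  cadd[splice] <- stats::runif(sum(splice), 20, 40)

  variants <- tibble::tibble(
    chrom = panel$chrom[g],
    pos = as.integer(pos),
    variant_id = variant_id,
    ref = ref, alt = alt,
    gene_symbol = panel$symbol[g],
    vaf = vaf,
    vqsr_score = round(vqsr, 2),
    consequence = consequence,
    sift = calls[, "sift"], polyphen2 = calls[, "polyphen2"],
    provean = calls[, "provean"],
    cadd_phred = round(cadd, 2)
  )
  # uniform position draws can collide; keep one record per site key
  keep <- !duplicated(variant_key(variants$chrom, variants$pos,
                                  variants$ref, variants$alt))
  variants <- variants[keep, ]
  latent <- latent[keep]
  truth <- tibble::tibble(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    gene_symbol = variants$gene_symbol,
    latent_deleterious = latent,
    true_rare = variants$vaf < 0.01
  )
  list(variants = variants, truth = truth)
}

#' Generate a multi-population VAF table under Balding-Nichols divergence
#'
#' For each variant with ancestral frequency p, each population's frequency
#' is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`, converted
#' to an allele count at the population's allele number (half-up) and back
#' to a frequency. As `fst` approaches 0 all populations share p.
#'
#' @param variants Variant-record tibble (uses chrom, pos, ref, alt, vaf).
#' @param config A [sim_config()].
#' @return Long-format population VAF tibble.
#' @export
generate_population_table <- function(variants, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, "populations"))
  fst <- config$fst
  n_pop <- config$n_populations
  n_all <- config$n_alleles_per_population
  pops <- sprintf("POP%d", seq_len(n_pop))
  p <- pmin(pmax(variants$vaf, 1e-9), 1 - 1e-9)
  m <- length(p)
  draw <- function(p) {
    if (fst < 1e-12) return(rep(p, n_pop))
    stats::rbeta(n_pop, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  }
  pk <- t(vapply(p, draw, numeric(n_pop)))
  alt_counts <- matrix(round_half_up(pk * n_all, 0), m, n_pop)
  tibble::tibble(
    chrom = rep(variants$chrom, each = n_pop),
    pos = rep(variants$pos, each = n_pop),
    ref = rep(variants$ref, each = n_pop),
    alt = rep(variants$alt, each = n_pop),
    population = rep(pops, m),
    vaf = as.vector(t(alt_counts)) / n_all,
    n_alleles = n_all
  )
}

#' Hudson-style FST estimate from a population VAF table
#'
#' Mean-of-ratios estimator over all population pairs and variants:
#' `sum((p1-p2)^2 - corrections) / sum(p1(1-p2) + p2(1-p1))`, with the
#' usual finite-sample corrections `p(1-p)/(n-1)` per population.
#'
#' @param pop_table Long-format population VAF tibble.
#' @return Scalar FST estimate.
#' @export
estimate_fst <- function(pop_table) {
  pop_table$.key <- variant_key(pop_table$chrom, pop_table$pos,
                                pop_table$ref, pop_table$alt)
  wide <- split(pop_table, pop_table$.key)
  num <- 0
  den <- 0
  for (v in wide) {
    k <- nrow(v)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        p1 <- v$vaf[i]; p2 <- v$vaf[j]
        n1 <- v$n_alleles[i]; n2 <- v$n_alleles[j]
        num <- num + (p1 - p2)^2 -
          p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
        den <- den + p1 * (1 - p2) + p2 * (1 - p1)
      }
    }
  }
  num / den
}

#' Write a simulated input bundle to disk
#'
#' Writes `variants.vcf`, `annotations.tsv`, `panel.tsv`, `populations.tsv`
#' and `truth.tsv` (the latent ground truth, which the pipeline never
#' reads).
#'
#' @param sim List with `variants`, `truth` (from [generate_variants()]),
#'   `panel`, and optionally `populations`.
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_variant_vcf(sim$variants, file.path(out_dir, "variants.vcf"))
  write_annotation_tsv(sim$variants, file.path(out_dir, "annotations.tsv"))
  write_panel_tsv(sim$panel, file.path(out_dir, "panel.tsv"))
  if (!is.null(sim$populations)) {
    readr::write_tsv(sim$populations, file.path(out_dir, "populations.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  invisible(out_dir)
}
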