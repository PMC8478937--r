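# End-to-end orchestration: simulate or read inputs, VQSR-filter, resolve
# against the panel, classify, aggregate, run the statistical layer, and
# write the report bundle with a stage-count manifest.

#' Run the full variant-landscape pipeline
#'
#' A single reproducible run over either a simulation block or real input
#' files. Configuration is a nested list (or a path to a YAML file with the
#' same shape):
#'
#' \preformatted{
#' simulate:            # either this block ...
#'   <sim_config() arguments>
#' inputs:              # ... or this one
#'   vcf: in.vcf
#'   annotations: annot.tsv
#'   panel: panel.tsv
#'   populations: pops.tsv      # optional
#' classify:
#'   vqsr_threshold: 35
#'   cadd_threshold: ~          # optional splice demotion
#' aggregate:
#'   fraction_weighting: count
#' stats:
#'   m_regressions: 18
#'   m_comparisons: ~           # default: number of comparisons run
#'   reference_population: POP1
#' }
#'
#' Every stage count (input, post-VQSR, accepted, rejected) is recorded in
#' the manifest and satisfies `accepted + rejected = post-VQSR`. Reruns
#' with identical inputs and seed produce byte-identical tables.
#'
#' @param config Nested list or YAML path.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param seed Overrides `config$simulate$seed`.
#' @return Invisibly, a list with the report bundle and the manifest
#'   counts.
#' @export
run_landscape <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    cfg <- stage("simulate", do.call(sim_config, sim_args))
    seed <- cfg$seed
    panel <- stage("simulate", generate_panel(cfg))
    gen <- stage("simulate", generate_variants(panel, cfg))
    records <- gen$variants
    pop_table <- if (cfg$n_populations > 0) {
      common_fun <- records[records$vaf >= 0.01, ]
      idx <- utils::head(order(-common_fun$vaf), 50L)
      stage("simulate", generate_population_table(common_fun[idx, ], cfg))
    }
    sim <- list(config = cfg)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (need in c("vcf", "annotations", "panel")) {
      if (is.null(inp[[need]])) {
        stop("pipeline stage 'inputs' failed: config is missing '", need, "'",
             call. = FALSE)
      }
    }
    panel <- stage("inputs", read_gene_panel(inp$panel))
    records <- stage("inputs", read_variant_table(inp$vcf, inp$annotations))
    pop_table <- if (!is.null(inp$populations)) {
      stage("inputs", read_population_table(inp$populations))
    }
  } else {
    stop("pipeline stage 'config' failed: need a 'simulate' or 'inputs' block",
         call. = FALSE)
  }

  vqsr_threshold <- config$classify$vqsr_threshold %||% 35
  cadd_threshold <- config$classify$cadd_threshold
  fraction_weighting <- config$aggregate$fraction_weighting %||% "count"

  n_input <- nrow(records)
  flt <- stage("classify", filter_vqsr(records, vqsr_threshold))
  routed <- stage("classify", resolve_panel(flt$kept, panel))
  classified <- stage("classify",
                      classify_variants(routed$accepted, cadd_threshold))

  gene_summaries <- stage("aggregate",
                          summarize_genes(classified, panel, fraction_weighting))
  family_summaries <- stage("aggregate", summarize_families(gene_summaries))
  spectrum <- stage("aggregate", substitution_spectrum(classified))
  overview <- stage("aggregate", cohort_overview(classified))
  fold <- if (sum(gene_summaries$aggregated_functional_freq_pct > 0) >= 2) {
    stage("aggregate", fold_range(gene_summaries))
  }

  kw <- if (length(unique(gene_summaries$family)) >= 2) {
    stage("stats", kruskal_wallis_by_family(gene_summaries$n_functional,
                                            gene_summaries$family))
  }
  m_reg <- config$stats$m_regressions %||% 18L
  regressions <- stage("stats", tryCatch(
    regress_families(gene_summaries, panel, m = m_reg),
    error = function(e) NULL))
  comparisons <- NULL
  if (!is.null(pop_table)) {
    ref_pop <- config$stats$reference_population %||% pop_table$population[1]
    comparisons <- stage("stats", compare_population_table(
      pop_table, ref_pop, m = config$stats$m_comparisons))
  }

  counts <- list(
    input = n_input,
    post_vqsr = nrow(flt$kept),
    vqsr_dropped = nrow(flt$dropped),
    unscored = flt$n_unscored,
    accepted = nrow(routed$accepted),
    rejected = nrow(routed$rejected),
    classified = nrow(classified)
  )
  stopifnot(counts$accepted + counts$rejected == counts$post_vqsr)

  bundle <- list(
    classified = classified,
    rejected = routed$rejected,
    gene_summaries = gene_summaries,
    family_summaries = family_summaries,
    spectrum = spectrum,
    overview = overview,
    fold = fold,
    kruskal_wallis = kw,
    regressions = regressions,
    comparisons = comparisons,
    config = config_for_manifest(config),
    seed = seed,
    counts = counts,
    log = list(n_demoted = attr(classified, "n_demoted"),
               n_unscored = flt$n_unscored)
  )
  if (!is.null(sim)) bundle$sim_truth <- NULL  # truth never enters the bundle

  if (!is.null(out_dir)) {
    stage("report", write_report(bundle, out_dir))
  }
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sim_config carries a class attribute and named vectors that serialize
# poorly; flatten for the manifest.
config_for_manifest <- function(config) {
  rapply(config, f = function(x) if (is.numeric(x) || is.character(x)) x else x,
         how = "replace")
}
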