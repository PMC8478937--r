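# Readers and writers for the external representations: minimal VCF plus
# annotation TSV, gene panel (TSV or BED), long-format population VAF
# table, and the report bundle.

# Left-trim the shared prefix of an allele pair (minimal representation for
# the annotation join key); the position advances by the trimmed length.
normalize_allele_pair <- function(pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  for (i in seq_along(ref)) {
    while (nchar(ref[i]) > 1L && nchar(alt[i]) > 1L &&
           substr(ref[i], 1L, 1L) == substr(alt[i], 1L, 1L)) {
      ref[i] <- substr(ref[i], 2L, nchar(ref[i]))
      alt[i] <- substr(alt[i], 2L, nchar(alt[i]))
      pos[i] <- pos[i] + 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", toupper(ref), ":", toupper(alt))
}

#' Read a variant table from a minimal VCF plus annotation TSV
#'
#' Parses the VCF fixed columns and the `INFO/AF` field, splits
#' multi-allelic rows into one record per ALT allele, and joins each record
#' to its annotation row on the (chrom, pos, ref, alt) key after uppercasing
#' alleles and left-trimming any shared allele prefix. Records without an
#' annotation are routed to the `rejected` attribute rather than silently
#' dropped.
#'
#' The annotation TSV must carry columns `chrom`, `pos`, `ref`, `alt`,
#' `gene_symbol`, `consequence`, `sift`, `polyphen2`, `provean`, and
#' optionally `cadd_phred` and `vqsr_score`. Predictor columns may hold
#' categorical calls (damaging/tolerated/missing) or raw scores, which are
#' converted at each tool's published cutoff (see [as_predictor_call()]).
#'
#' @param vcf_path Path to a VCF 4.x file (plain or bgzipped).
#' @param annotation_path Path to the annotation TSV.
#' @return A tibble of variant records (one row per ALT allele) with an
#'   attribute `rejected` holding the unannotated records.
#' @export
read_variant_table <- function(vcf_path, annotation_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    empty <- empty_variant_table()
    attr(empty, "rejected") <- empty_variant_table()
    return(empty)
  }
  af_raw <- vcfR::extract.info(vcf, element = "AF")
  missing_af <- which(is.na(af_raw) | af_raw == "")
  if (length(missing_af) > 0) {
    stop("missing INFO/AF on VCF data line(s): ",
         paste(utils::head(missing_af, 5), collapse = ", "), call. = FALSE)
  }

  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  af_split <- strsplit(af_raw, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  if (any(lengths(af_split) != n_alt)) {
    bad <- which(lengths(af_split) != n_alt)
    stop("INFO/AF arity does not match ALT allele count on VCF data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  idx <- rep(seq_len(nrow(fix)), n_alt)
  id <- fix[idx, "ID"]
  id[!is.na(id) & (id == "." | id == "")] <- NA_character_
  records <- tibble::tibble(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    variant_id = id,
    ref = toupper(fix[idx, "REF"]),
    alt = toupper(unlist(alt_split)),
    vaf = as.numeric(unlist(af_split))
  )
  check_vaf(records$vaf, "INFO/AF")
  if (any(records$ref == records$alt)) {
    stop("REF and ALT alleles are identical on data line(s): ",
         paste(utils::head(idx[records$ref == records$alt], 5),
               collapse = ", "), call. = FALSE)
  }
  norm <- normalize_allele_pair(records$pos, records$ref, records$alt)
  records$pos <- norm$pos
  records$ref <- norm$ref
  records$alt <- norm$alt

  annot <- read_annotation_tsv(annotation_path)
  records$.key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  hit <- match(records$.key, annot$.key)
  rejected <- records[is.na(hit), setdiff(names(records), ".key")]
  kept <- records[!is.na(hit), ]
  annot_rows <- annot[hit[!is.na(hit)], ]
  out <- tibble::tibble(
    chrom = kept$chrom, pos = kept$pos, variant_id = kept$variant_id,
    ref = kept$ref, alt = kept$alt,
    gene_symbol = annot_rows$gene_symbol,
    vaf = kept$vaf,
    vqsr_score = annot_rows$vqsr_score,
    consequence = annot_rows$consequence,
    sift = annot_rows$sift, polyphen2 = annot_rows$polyphen2,
    provean = annot_rows$provean,
    cadd_phred = annot_rows$cadd_phred
  )
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " variant record(s) had no annotation and were rejected")
  }
  attr(out, "rejected") <- rejected
  out
}

empty_variant_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), variant_id = character(),
    ref = character(), alt = character(), gene_symbol = character(),
    vaf = numeric(), vqsr_score = numeric(), consequence = character(),
    sift = character(), polyphen2 = character(), provean = character(),
    cadd_phred = numeric()
  )
}

read_annotation_tsv <- function(path) {
  # read as character and coerce below: numeric columns can be all-NA for
  # thousands of leading rows, which defeats type guessing
  annot <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()))
  required <- c("chrom", "pos", "ref", "alt", "gene_symbol", "consequence",
                "sift", "polyphen2", "provean")
  miss <- setdiff(required, names(annot))
  if (length(miss) > 0) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  annot$chrom <- as.character(annot$chrom)
  annot$pos <- as.integer(annot$pos)
  norm <- normalize_allele_pair(annot$pos, as.character(annot$ref),
                                as.character(annot$alt))
  annot$pos <- norm$pos
  annot$ref <- norm$ref
  annot$alt <- norm$alt
  check_consequence(annot$consequence)
  for (p in predictor_names()) {
    annot[[p]] <- as_predictor_call(annot[[p]], p)
  }
  if (!"cadd_phred" %in% names(annot)) annot$cadd_phred <- NA_real_
  if (!"vqsr_score" %in% names(annot)) annot$vqsr_score <- NA_real_
  annot$cadd_phred <- as.numeric(annot$cadd_phred)
  annot$vqsr_score <- as.numeric(annot$vqsr_score)
  annot$.key <- variant_key(annot$chrom, annot$pos, annot$ref, annot$alt)
  if (anyDuplicated(annot$.key)) {
    stop("annotation key collision for: ",
         paste(utils::head(annot$.key[duplicated(annot$.key)], 5),
               collapse = ", "), call. = FALSE)
  }
  annot
}

#' Read the gene panel
#'
#' Accepts either a TSV with a header row (`symbol`, `family`, `chrom`,
#' `start`, `end`; 1-based inclusive coordinates) or a headerless BED file
#' (`chrom`, `start`, `end`, `symbol`, `family`; 0-based half-open, detected
#' by the `.bed` extension and converted on read). Gene length in kb is
#' derived as `(end - start + 1) / 1000`.
#'
#' @param path Path to the panel file.
#' @return Tibble with columns symbol, family, chrom, start, end, length_kb.
#' @export
read_gene_panel <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                               "symbol", "family"),
                           show_col_types = FALSE, progress = FALSE)
    raw$start <- as.integer(raw$start) + 1L  # BED is 0-based half-open
    raw$end <- as.integer(raw$end)
    panel <- raw[, c("symbol", "family", "chrom", "start", "end")]
  } else {
    panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(c("symbol", "family", "chrom", "start", "end"), names(panel))
    if (length(miss) > 0) {
      stop("gene panel lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    panel <- panel[, c("symbol", "family", "chrom", "start", "end")]
    panel$start <- as.integer(panel$start)
    panel$end <- as.integer(panel$end)
  }
  validate_panel(panel)
}

validate_panel <- function(panel) {
  check_family(panel$family)
  if (any(panel$end < panel$start)) {
    stop("gene panel has end < start for: ",
         paste(panel$symbol[panel$end < panel$start], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$symbol)) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(panel$symbol[duplicated(panel$symbol)]), collapse = ", "),
         call. = FALSE)
  }
  panel$chrom <- as.character(panel$chrom)
  panel$length_kb <- (panel$end - panel$start + 1) / 1000
  tibble::as_tibble(panel)
}

#' Read a long-format population VAF table
#'
#' One row per (variant, population) with the observed variant allele
#' frequency and the total number of observed alleles (2 x diploid sample
#' size for autosomes).
#'
#' @param path TSV with columns chrom, pos, ref, alt, population, vaf,
#'   n_alleles.
#' @return Validated tibble.
#' @export
read_population_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "population", "vaf", "n_alleles")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop("population table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  check_vaf(tab$vaf)
  tab$n_alleles <- as.integer(tab$n_alleles)
  if (any(is.na(tab$n_alleles)) || any(tab$n_alleles <= 0L)) {
    stop("n_alleles must be a positive integer", call. = FALSE)
  }
  tibble::as_tibble(tab[, required])
}

#' Split variant records by panel membership
#'
#' Records whose gene symbol resolves against the panel are accepted; the
#' rest are routed to a reject set so that accepted + rejected = input.
#'
#' @param records Variant-record tibble.
#' @param panel Gene-panel tibble from [read_gene_panel()].
#' @return List with elements `accepted` and `rejected`.
#' @export
resolve_panel <- function(records, panel) {
  ok <- records$gene_symbol %in% panel$symbol
  list(accepted = records[ok, , drop = FALSE],
       rejected = records[!ok, , drop = FALSE])
}

# --- writers -----------------------------------------------------------

fmt_num <- function(x, digits = 10) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else sprintf("%.*g", digits, v)
  }, character(1))
  out
}

#' Write variant records as a minimal VCF
#'
#' Emits the seven fixed columns plus `INFO/AF`; a missing `variant_id`
#' becomes the VCF missing marker `.`.
#'
#' @param records Variant-record tibble (one row per ALT allele).
#' @param path Output path.
#' @export
write_variant_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  id <- ifelse(is.na(records$variant_id), ".", records$variant_id)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tAF=%s",
                  records$chrom, records$pos, id, records$ref, records$alt,
                  fmt_num(records$vaf))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
write_annotation_tsv <- function(records, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene_symbol", "consequence",
            "sift", "polyphen2", "provean", "cadd_phred", "vqsr_score")
  readr::write_tsv(records[, intersect(cols, names(records))], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
write_panel_tsv <- function(panel, path) {
  readr::write_tsv(panel[, c("symbol", "family", "chrom", "start", "end")],
                   path, progress = FALSE)
  invisible(path)
}

#' Write the report bundle
#'
#' Writes deterministic TSVs (variant-level classifications, rejected
#' records, gene summaries, family summaries, substitution spectrum, and,
#' when present, regression and population-comparison tables) plus a JSON
#' manifest holding the configuration, seed, stage counts, cohort overview
#' and software version. Given identical inputs and seed the TSV bytes are
#' identical across runs.
#'
#' @param bundle List as assembled by [run_landscape()]; recognised elements:
#'   classified, rejected, gene_summaries, family_summaries, spectrum,
#'   overview, regressions, comparisons, fold, config, seed, counts, log.
#' @param out_dir Output directory (created if needed).
#' @param timestamp Record a wall-clock timestamp in the manifest; off by
#'   default so reruns are byte-identical.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, out_dir, timestamp = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$classified)) put(bundle$classified, "variant_classifications.tsv")
  if (!is.null(bundle$rejected)) put(bundle$rejected, "rejected_variants.tsv")
  if (!is.null(bundle$gene_summaries)) put(bundle$gene_summaries, "gene_summaries.tsv")
  if (!is.null(bundle$family_summaries)) put(bundle$family_summaries, "family_summaries.tsv")
  if (!is.null(bundle$spectrum)) put(bundle$spectrum$spectrum, "spectrum.tsv")
  if (!is.null(bundle$regressions)) put(bundle$regressions, "regressions.tsv")
  if (!is.null(bundle$comparisons)) put(bundle$comparisons, "population_comparisons.tsv")

  manifest <- list(
    package = "pgxlandscape",
    version = as.character(utils::packageVersion("pgxlandscape")),
    seed = bundle$seed,
    config = bundle$config,
    counts = bundle$counts,
    overview = bundle$overview,
    titv_ratio = if (!is.null(bundle$spectrum)) bundle$spectrum$titv_ratio,
    fold = bundle$fold,
    log = bundle$log,
    zero_records = isTRUE(is.null(bundle$classified) || nrow(bundle$classified) == 0L)
  )
  if (timestamp) manifest$created <- format(Sys.time(), tz = "UTC")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(c(paths, mp))
}
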