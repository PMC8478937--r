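# Classification cascade: VQSR quality filter, rarity at the 1% VAF
# threshold, consensus missense deleteriousness over SIFT/PolyPhen2/PROVEAN,
# loss-of-function assignment, and the combined functional label.

#' Convert predictor calls or raw scores to categorical calls
#'
#' Accepts categorical tokens (damaging/tolerated/missing, case-insensitive)
#' or numeric scores, which are dichotomised at each tool's published
#' default cutoff: SIFT < 0.05, PolyPhen2 >= 0.446, PROVEAN <= -2.5 are
#' damaging. `NA` becomes "missing".
#'
#' @param x Character or numeric vector.
#' @param predictor One of "sift", "polyphen2", "provean".
#' @return Character vector over damaging/tolerated/missing.
#' @export
as_predictor_call <- function(x, predictor = c("sift", "polyphen2", "provean")) {
  predictor <- match.arg(predictor)
  if (is.numeric(x)) {
    damaging <- switch(predictor,
      sift = x < 0.05,
      polyphen2 = x >= 0.446,
      provean = x <= -2.5
    )
    return(ifelse(is.na(x), "missing", ifelse(damaging, "damaging", "tolerated")))
  }
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == "" | x == "."] <- "missing"
  num <- suppressWarnings(as.numeric(x))
  if (any(!is.na(num))) {
    # mixed column: numeric-looking entries are scores
    x[!is.na(num)] <- as_predictor_call(num[!is.na(num)], predictor)
  }
  bad <- setdiff(unique(x), predictor_call_tokens())
  if (length(bad) > 0) {
    stop("unknown predictor call token(s) for ", predictor, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' VQSR quality filter
#'
#' Keeps records with a Phred-scaled VQSR score at or above the threshold
#' (default 35). Records without a score pass the filter and are tallied in
#' the `unscored` attribute, since summary-level sources often do not carry
#' per-variant scores.
#'
#' @param records Variant-record tibble.
#' @param threshold Non-negative score threshold.
#' @return List with `kept`, `dropped` (disjoint, union = input) and
#'   `n_unscored`.
#' @export
filter_vqsr <- function(records, threshold = 35) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("VQSR threshold must be a single non-negative number", call. = FALSE)
  }
  unscored <- is.na(records$vqsr_score)
  keep <- unscored | records$vqsr_score >= threshold
  list(kept = records[keep, , drop = FALSE],
       dropped = records[!keep, , drop = FALSE],
       n_unscored = sum(unscored))
}

#' Rarity at the 1% VAF threshold
#'
#' A variant is RARE when its allele frequency is strictly below 1%,
#' otherwise COMMON; a VAF of exactly 1% is COMMON, closing the gap left by
#' the strict "less than 1%" definition of rare.
#'
#' @param vaf Numeric vector of allele frequencies in `[0, 1]`.
#' @return Character vector over RARE/COMMON.
#' @export
classify_rarity <- function(vaf) {
  check_vaf(vaf)
  ifelse(vaf < 0.01, "RARE", "COMMON")
}

#' Consensus missense deleteriousness
#'
#' A missense variant is deleterious when at least half of the available
#' (non-missing) predictor calls are damaging. Missing calls shrink the
#' denominator; with no available call the variant is UNCLASSIFIED and is
#' excluded from both the deleterious and neutral tallies.
#'
#' @param sift,polyphen2,provean Call vectors over
#'   damaging/tolerated/missing (equal length, recycled scalars allowed).
#' @return Character vector over DELETERIOUS_MISSENSE / NEUTRAL_MISSENSE /
#'   UNCLASSIFIED_MISSENSE.
#' @export
consensus_missense <- function(sift, polyphen2, provean) {
  calls <- cbind(check_call(sift), check_call(polyphen2), check_call(provean))
  n_avail <- rowSums(calls != "missing")
  n_damaging <- rowSums(calls == "damaging")
  out <- rep("UNCLASSIFIED_MISSENSE", nrow(calls))
  avail <- n_avail > 0
  out[avail] <- ifelse(n_damaging[avail] / n_avail[avail] >= 0.5,
                       "DELETERIOUS_MISSENSE", "NEUTRAL_MISSENSE")
  out
}

check_call <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), predictor_call_tokens())
  if (length(bad) > 0) {
    stop("unknown predictor call token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(predictor_call_tokens(), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Loss-of-function assignment
#'
#' Splice acceptor, splice donor, start lost and stop gained variants are
#' putatively loss-of-function. Optionally, splice variants carrying a CADD
#' PHRED score below `cadd_threshold` are demoted (the default keeps all
#' splice variants, reflecting that CADD judged every splice variant in the
#' motivating cohort deleterious).
#'
#' @param consequence Consequence vector from the closed vocabulary.
#' @param cadd_phred Optional numeric vector of CADD PHRED scores.
#' @param cadd_threshold Optional single threshold enabling the demotion.
#' @return Logical vector; attribute `n_demoted` counts demoted splice
#'   variants.
#' @export
classify_lof <- function(consequence, cadd_phred = NULL, cadd_threshold = NULL) {
  check_consequence(consequence)
  is_lof <- consequence %in% lof_consequences()
  n_demoted <- 0L
  if (!is.null(cadd_threshold)) {
    splice <- consequence %in% c("splice_acceptor", "splice_donor")
    demote <- splice & !is.na(cadd_phred) & cadd_phred < cadd_threshold
    n_demoted <- sum(demote)
    if (n_demoted > 0) {
      message(n_demoted, " splice variant(s) demoted from LoF by CADD < ",
              cadd_threshold)
    }
    is_lof <- is_lof & !demote
  }
  structure(is_lof, n_demoted = n_demoted)
}

#' Classify variant records
#'
#' Applies rarity and the functional cascade to every record: missense
#' variants get the predictor consensus; LoF-category consequences become
#' LOF (subject to the optional CADD demotion); everything else is
#' NON_FUNCTIONAL. A variant is functional iff it is deleterious missense
#' or LoF.
#'
#' @param records Variant-record tibble (post VQSR filtering).
#' @param cadd_threshold Optional CADD PHRED demotion threshold for splice
#'   variants; `NULL` (default) disables the demotion.
#' @return The input tibble with columns `rarity`, `functional_class` and
#'   `is_functional` appended.
#' @export
classify_variants <- function(records, cadd_threshold = NULL) {
  check_consequence(records$consequence)
  rarity <- classify_rarity(records$vaf)
  functional_class <- rep("NON_FUNCTIONAL", nrow(records))

  mis <- records$consequence == "missense"
  if (any(mis)) {
    functional_class[mis] <- consensus_missense(
      records$sift[mis], records$polyphen2[mis], records$provean[mis])
  }
  lof <- classify_lof(records$consequence, records$cadd_phred, cadd_threshold)
  functional_class[lof] <- "LOF"

  out <- records
  out$rarity <- rarity
  out$functional_class <- functional_class
  out$is_functional <- functional_class %in% c("DELETERIOUS_MISSENSE", "LOF")
  attr(out, "n_demoted") <- attr(lof, "n_demoted")
  out
}
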