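# Closed vocabularies shared across the pipeline.

#' Consequence vocabulary
#'
#' The ten gene-region / functional-consequence categories a variant may
#' carry. `exonic_consequences()` follows the convention that UTR variants
#' count as exonic even though they are non-coding; `lof_consequences()` is
#' the putative loss-of-function set (splice acceptor, splice donor, start
#' lost, stop gained).
#'
#' @return Character vector of category labels.
#' @export
consequence_vocab <- function() {
  c("intronic", "upstream", "downstream", "utr", "missense", "synonymous",
    "splice_acceptor", "splice_donor", "start_lost", "stop_gained")
}

#' @rdname consequence_vocab
#' @export
lof_consequences <- function() {
  c("splice_acceptor", "splice_donor", "start_lost", "stop_gained")
}

#' @rdname consequence_vocab
#' @export
exonic_consequences <- function() {
  c("missense", "synonymous", "utr", lof_consequences())
}

#' Gene family labels
#'
#' The six pharmacogene families: ABC transporters, SLC transporters,
#' phase 1 enzymes, phase 2 enzymes, nuclear receptors, and a residual
#' "other" group.
#'
#' @return Character vector of family labels.
#' @export
family_levels <- function() {
  c("ABC", "SLC", "PHASE1", "PHASE2", "NUCLEAR_RECEPTOR", "OTHER")
}

#' @rdname consequence_vocab
#' @export
predictor_names <- function() c("sift", "polyphen2", "provean")

predictor_call_tokens <- function() c("damaging", "tolerated", "missing")

check_consequence <- function(x) {
  bad <- setdiff(unique(x), consequence_vocab())
  if (length(bad) > 0) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(consequence_vocab(), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

check_family <- function(x) {
  bad <- setdiff(unique(x), family_levels())
  if (length(bad) > 0) {
    stop("unknown family label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(family_levels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

check_vaf <- function(vaf, what = "vaf") {
  if (any(is.na(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    stop(what, " must lie in [0, 1]; offending value(s): ",
         paste(utils::head(vaf[is.na(vaf) | vaf < 0 | vaf > 1], 5),
               collapse = ", "),
         call. = FALSE)
  }
  invisible(vaf)
}

# Half-up rounding; an epsilon absorbs binary representation error in
# ratios like 36/40 whose decimal expansion is exact.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Report a fraction as a percentage, rounded half-up to one decimal
#'
#' All percentages in the report layer go through this function so that
#' printed values like 91.1 or 37.4 are reproducible from their
#' numerator/denominator pairs.
#'
#' @param x Fraction in `[0, 1]` (vectorized).
#' @return Numeric percentage with one decimal place.
#' @export
round_pct <- function(x) round_half_up(100 * x, 1)
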