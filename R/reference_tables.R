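#' Reference tables from a published turmeric MET
#'
#' Three small plain-text tables transcribed from a published multi-year
#' turmeric genotype evaluation ship with the package and serve two roles:
#' as validation fixtures (their derived columns can be recomputed from
#' their own printed inputs) and as realistic parameter sources for
#' [table1_like_config()].
#'
#' * `reference_genetic_parameters()` — per trait and season: genotype-mean
#'   max/min/mean, SE, CV%, critical differences, the variance components
#'   (sigma2_e, sigma2_g, sigma2_p), ECV/GCV/PCV, broad-sense heritability,
#'   genetic advance and genetic gain for twelve traits over three seasons.
#' * `reference_gai_ranks()` — the per-trait GAI rank matrix for the 53
#'   genotypes (twelve traits), with the published mean rank (MR), re-rank
#'   (R.MR) and top-10 occurrence columns.
#' * `reference_gxy_anova()` — the combined genotype-by-year ANOVA for
#'   fresh yield (df, SS, MS, % of total SS).
#'
#' @return A data frame (see above).
#' @name reference_tables
NULL

.ref_path <- function(file) {
  p <- system.file("extdata", file, package = "metbiom")
  if (p == "") stop("reference table not found: ", file)
  p
}

#' @rdname reference_tables
#' @export
reference_genetic_parameters <- function() {
  utils::read.delim(.ref_path("genetic_parameter_reference.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_gai_ranks <- function() {
  utils::read.delim(.ref_path("gai_rank_reference.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reference_tables
#' @export
reference_gxy_anova <- function() {
  utils::read.delim(.ref_path("gxy_anova_reference.tsv"),
                    stringsAsFactors = FALSE)
}
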