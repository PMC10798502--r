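#' Coefficients of variation from variance components
#'
#' `GCV = 100 sqrt(sigma2_g) / mean`, `PCV = 100 sqrt(sigma2_p) / mean`,
#' `ECV = 100 sqrt(sigma2_e) / mean`. Because
#' `sigma2_p = sigma2_g + sigma2_e`, the identity
#' `PCV^2 = GCV^2 + ECV^2` holds exactly.
#'
#' @param vc A [variance_components()] object.
#' @return Named numeric vector `c(ECV, GCV, PCV)`, in percent.
#' @export
coefficients_of_variation <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(vc$grand_mean) || vc$grand_mean <= 0) {
    stop("CV undefined: grand mean must be > 0")
  }
  c(ECV = 100 * sqrt(vc$sigma2_e) / vc$grand_mean,
    GCV = 100 * sqrt(vc$sigma2_g) / vc$grand_mean,
    PCV = 100 * sqrt(vc$sigma2_p) / vc$grand_mean)
}

#' Broad-sense heritability with Robinson-style classification
#'
#' `h2b = sigma2_g / sigma2_p`, classified on the percent scale into low
#' (0-30%), moderate (30-60%) and high (>60%) bands.
#'
#' @param vc A [variance_components()] object.
#' @param bands Upper bounds (percent) of the low and moderate bands.
#' @return List with `h2b` (in `[0, 1]`, or `NA` with `defined = FALSE`
#'   when `sigma2_p` is zero) and `class`.
#' @export
broad_sense_heritability <- function(vc, bands = c(low = 30, moderate = 60)) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma2_p <= 0) {
    return(list(h2b = NA_real_, class = NA_character_, defined = FALSE))
  }
  h2 <- vc$sigma2_g / vc$sigma2_p
  pct <- 100 * h2
  cls <- if (pct <= bands[["low"]]) "low"
         else if (pct <= bands[["moderate"]]) "moderate" else "high"
  list(h2b = h2, class = cls, defined = TRUE)
}

#' Genetic advance and genetic gain
#'
#' Expected response to selecting the best fraction of genotypes:
#' `GA = k * h2b * sqrt(sigma2_p)` in trait units, and the genetic gain
#' `GG = 100 * GA / mean` in percent of the trait mean. The default
#' standardized selection differential `k = 2.06` corresponds to 5%
#' selection intensity.
#'
#' @param vc A [variance_components()] object.
#' @param k Standardized selection differential.
#' @return List `GA`, `GG`, `k`.
#' @export
genetic_advance <- function(vc, k = 2.06) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma2_p <= 0) return(list(GA = 0, GG = 0, k = k))
  h2 <- vc$sigma2_g / vc$sigma2_p
  ga <- k * h2 * sqrt(vc$sigma2_p)
  gg <- if (!is.null(vc$grand_mean) && vc$grand_mean > 0) {
    100 * ga / vc$grand_mean
  } else NA_real_
  list(GA = ga, GG = gg, k = k)
}

#' Full genetic-parameter table, one row per trait per environment
#'
#' Chains [fit_rcbd_anova()], [variance_components()], [precision_stats()],
#' [coefficients_of_variation()], [broad_sense_heritability()] and
#' [genetic_advance()] for every trait in every environment of a balanced
#' table. Max/min/mean are taken over replicate-averaged genotype means.
#' All columns are carried at full precision; round only at report time.
#'
#' @param x A balanced [trait_table].
#' @param k Selection differential passed to [genetic_advance()].
#' @param alpha_levels Passed to [precision_stats()].
#' @return Data frame with columns `environment`, `trait`, `max`, `min`,
#'   `mean`, `SE`, `CV`, `CD5`, `CD1`, `sigma2_e`, `sigma2_g`, `sigma2_p`,
#'   `ECV`, `GCV`, `PCV`, `h2b`, `h2b_class`, `GA`, `GG`, `F_genotype`,
#'   `p_genotype`, `sigma2_g_truncated`.
#' @export
build_table1 <- function(x, k = 2.06, alpha_levels = c(0.05, 0.01)) {
  rows <- list()
  for (env in environments(x)) {
    for (tr in traits(x)) {
      an <- fit_rcbd_anova(x, tr, env)
      gmeans <- rowMeans(.slice_matrix(x, tr, env))
      vc <- variance_components(an)
      ps <- precision_stats(vc, alpha_levels)
      cv3 <- coefficients_of_variation(vc)
      h2 <- broad_sense_heritability(vc)
      ga <- genetic_advance(vc, k)
      rows[[length(rows) + 1L]] <- data.frame(
        environment = env, trait = tr,
        max = max(gmeans), min = min(gmeans), mean = attr(an, "grand_mean"),
        SE = ps$SE, CV = ps$CV_percent,
        CD5 = ps$CD[[1L]], CD1 = ps$CD[[2L]],
        sigma2_e = vc$sigma2_e, sigma2_g = vc$sigma2_g,
        sigma2_p = vc$sigma2_p,
        ECV = cv3[["ECV"]], GCV = cv3[["GCV"]], PCV = cv3[["PCV"]],
        h2b = h2$h2b, h2b_class = if (h2$defined) h2$class else NA_character_,
        GA = ga$GA, GG = ga$GG,
        F_genotype = an$F[an$source == "Genotype"],
        p_genotype = an$p[an$source == "Genotype"],
        sigma2_g_truncated = vc$truncated,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify a coefficient of variation
#'
#' Conventional bands used when narrating GCV/PCV magnitudes: low below
#' 10%, moderate 10-20%, high above 20%.
#'
#' @param cv Coefficient of variation in percent.
#' @param bands Upper bounds of the low and moderate bands.
#' @return Character vector of class labels.
#' @export
classify_cv <- function(cv, bands = c(low = 10, moderate = 20)) {
  ifelse(cv < bands[["low"]], "low",
         ifelse(cv <= bands[["moderate"]], "moderate", "high"))
}
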