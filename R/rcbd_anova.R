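#' Per-environment RCBD analysis of variance
#'
#' Fits the standard two-way fixed-effects decomposition for one trait in
#' one environment of a balanced randomized complete block design:
#' sources are replication (df R-1), genotype (df G-1) and error
#' (df (G-1)(R-1)). The genotype F statistic tests MS_genotype against
#' MS_error.
#'
#' @param x A balanced [trait_table].
#' @param trait Trait identifier.
#' @param environment Environment (year) identifier.
#' @return An object of class `anova_table`: a data frame with columns
#'   `source`, `df`, `SS`, `MS`, `F`, `p` plus attributes `total_df`,
#'   `total_SS`, `grand_mean`, `n_genotypes`, `n_replicates`.
#' @examples
#' df <- expand.grid(genotype = c("A", "B"), environment = "E1",
#'                   replicate = 1:2, trait = "PH",
#'                   stringsAsFactors = FALSE)
#' df$value <- c(1, 3, 1, 3)
#' fit_rcbd_anova(trait_table(df), "PH", "E1")
#' @export
fit_rcbd_anova <- function(x, trait, environment) {
  m <- .slice_matrix(x, trait, environment)
  G <- nrow(m); R <- ncol(m)
  if (G < 2L) stop("need >= 2 genotypes")
  if (R < 2L) stop("need >= 2 replicates (zero error df otherwise)")
  grand <- mean(m)
  gm <- rowMeans(m); rm_ <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_gen <- R * sum((gm - grand)^2)
  ss_rep <- G * sum((rm_ - grand)^2)
  ss_err <- ss_total - ss_gen - ss_rep
  df <- c(R - 1L, G - 1L, (G - 1L) * (R - 1L))
  ss <- c(ss_rep, ss_gen, ss_err)
  ms <- ss / df
  Fg <- ms[2L] / ms[3L]
  Fr <- ms[1L] / ms[3L]
  out <- data.frame(source = c("Replication", "Genotype", "Error"),
                    df = df, SS = ss, MS = ms,
                    F = c(Fr, Fg, NA),
                    p = c(stats::pf(Fr, df[1L], df[3L], lower.tail = FALSE),
                          stats::pf(Fg, df[2L], df[3L], lower.tail = FALSE),
                          NA),
                    stringsAsFactors = FALSE)
  structure(out, total_df = sum(df), total_SS = ss_total, grand_mean = grand,
            n_genotypes = G, n_replicates = R,
            class = c("anova_table", "data.frame"))
}

#' Moment estimators of variance components from an RCBD ANOVA
#'
#' Classical expected-mean-squares estimators: `sigma2_e = MS_error`,
#' `sigma2_g = (MS_genotype - MS_error) / r`, and
#' `sigma2_p = sigma2_g + sigma2_e`. A negative genotypic moment estimate
#' is truncated to zero and flagged (`truncated = TRUE`), keeping
#' heritability inside `[0, 1]`.
#'
#' @param anova An [fit_rcbd_anova()] result (or any `anova_table` with
#'   `Genotype` and `Error` rows).
#' @param r Number of replicates; defaults to the value recorded on
#'   `anova`.
#' @param grand_mean Trait grand mean; defaults to the value recorded on
#'   `anova`.
#' @return Object of class `variance_components`: list with `sigma2_e`,
#'   `sigma2_g`, `sigma2_p`, `r`, `df_error`, `grand_mean`, `truncated`.
#' @export
variance_components <- function(anova, r = attr(anova, "n_replicates"),
                                grand_mean = attr(anova, "grand_mean")) {
  if (is.null(r) || r < 2) stop("r must be >= 2 (sigma2_g not estimable)")
  ms_gen <- anova$MS[anova$source == "Genotype"]
  err_row <- anova$source %in% c("Error", "Residual")
  ms_err <- anova$MS[err_row]
  df_err <- anova$df[err_row]
  if (!length(ms_gen) || !length(ms_err)) {
    stop("anova table must contain Genotype and Error sources")
  }
  s2g_raw <- (ms_gen - ms_err) / r
  truncated <- s2g_raw < 0
  s2g <- max(s2g_raw, 0)
  structure(list(sigma2_e = ms_err, sigma2_g = s2g,
                 sigma2_p = s2g + ms_err, r = r, df_error = df_err,
                 grand_mean = grand_mean, truncated = truncated),
            class = "variance_components")
}

#' Plot-mean precision statistics: SE, CV% and critical difference
#'
#' `SE = sqrt(sigma2_e / r)` (standard error of a genotype mean),
#' `CV% = 100 sqrt(sigma2_e) / grand_mean`, and the critical difference
#' (least significant difference between two genotype means)
#' `CD(alpha) = t(1 - alpha/2, df_error) * sqrt(2 sigma2_e / r)`.
#'
#' @param vc A [variance_components()] object.
#' @param alpha_levels Significance levels for CD; default 5% and 1%.
#' @return Named list `SE`, `CV_percent`, `CD` (named vector, one entry per
#'   alpha level).
#' @export
precision_stats <- function(vc, alpha_levels = c(0.05, 0.01)) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(vc$grand_mean) || vc$grand_mean <= 0) {
    stop("CV undefined: grand mean must be > 0")
  }
  se <- sqrt(vc$sigma2_e / vc$r)
  cv <- 100 * sqrt(vc$sigma2_e) / vc$grand_mean
  cd <- vapply(alpha_levels, function(a) {
    stats::qt(1 - a / 2, vc$df_error) * sqrt(2 * vc$sigma2_e / vc$r)
  }, numeric(1L))
  names(cd) <- paste0("CD", format(100 * alpha_levels, trim = TRUE), "%")
  list(SE = se, CV_percent = cv, CD = cd)
}

#' Combined genotype-by-year analysis of variance
#'
#' Pools all environments of a balanced MET into the combined decomposition
#' with replication nested within year: sources are replication-within-year
#' (df Y(R-1)), genotype (G-1), year (Y-1), genotype x year
#' ((G-1)(Y-1)) and residual. Genotype, year and interaction are F-tested
#' against the residual mean square by default; set
#' `genotype_denominator = "interaction"` for the random-year view in which
#' the genotype MS is tested against the interaction MS. A
#' `pct_total_SS` column gives each source's share of the total sum of
#' squares.
#'
#' @param x A balanced [trait_table] with at least two environments.
#' @param trait Trait identifier.
#' @param genotype_denominator `"residual"` (default) or `"interaction"`.
#' @return An `anova_table` with the extra `pct_total_SS` column.
#' @export
combined_gxy_anova <- function(x, trait,
                               genotype_denominator = c("residual",
                                                        "interaction")) {
  genotype_denominator <- match.arg(genotype_denominator)
  envs <- environments(x)
  if (length(envs) < 2L) stop("combined ANOVA needs >= 2 environments")
  slices <- lapply(envs, function(e) .slice_matrix(x, trait, e))
  G <- nrow(slices[[1L]]); R <- ncol(slices[[1L]]); Y <- length(envs)
  if (any(vapply(slices, nrow, 1L) != G) ||
      any(vapply(slices, ncol, 1L) != R)) {
    stop("environments differ in design dimensions")
  }
  gens <- rownames(slices[[1L]])
  if (!all(vapply(slices, function(s) identical(sort(rownames(s)),
                                                sort(gens)), TRUE))) {
    stop("environments differ in genotype sets")
  }
  slices <- lapply(slices, function(s) s[gens, , drop = FALSE])
  a <- array(unlist(slices), c(G, R, Y))        # genotype x rep x year
  grand <- mean(a)
  gmean <- apply(a, 1L, mean)                   # genotype means
  ymean <- apply(a, 3L, mean)                   # year means
  gymean <- apply(a, c(1L, 3L), mean)           # genotype x year cell means
  rymean <- apply(a, c(2L, 3L), mean)           # rep x year means

  ss_total <- sum((a - grand)^2)
  ss_gen <- Y * R * sum((gmean - grand)^2)
  ss_year <- G * R * sum((ymean - grand)^2)
  ss_rep <- G * sum(sweep(rymean, 2L, ymean)^2)            # rep within year
  ss_gy <- R * sum((gymean - outer(gmean, ymean, `+`) + grand)^2)
  ss_res <- ss_total - ss_gen - ss_year - ss_rep - ss_gy

  df <- c(Y * (R - 1L), G - 1L, Y - 1L, (G - 1L) * (Y - 1L),
          (G - 1L) * Y * (R - 1L))
  ss <- c(ss_rep, ss_gen, ss_year, ss_gy, ss_res)
  ms <- ss / df
  denom_gen <- if (genotype_denominator == "interaction") ms[4L] else ms[5L]
  denom_df_gen <- if (genotype_denominator == "interaction") df[4L] else df[5L]
  Fv <- c(ms[1L] / ms[5L], ms[2L] / denom_gen, ms[3L] / ms[5L],
          ms[4L] / ms[5L], NA)
  pv <- c(stats::pf(Fv[1L], df[1L], df[5L], lower.tail = FALSE),
          stats::pf(Fv[2L], df[2L], denom_df_gen, lower.tail = FALSE),
          stats::pf(Fv[3L], df[3L], df[5L], lower.tail = FALSE),
          stats::pf(Fv[4L], df[4L], df[5L], lower.tail = FALSE),
          NA)
  out <- data.frame(source = c("Replication(Year)", "Genotype", "Year",
                               "Genotype x Year", "Residual"),
                    df = df, SS = ss, MS = ms, F = Fv, p = pv,
                    pct_total_SS = 100 * ss / ss_total,
                    stringsAsFactors = FALSE)
  structure(out, total_df = sum(df), total_SS = ss_total, grand_mean = grand,
            n_genotypes = G, n_replicates = R, n_environments = Y,
            class = c("anova_table", "data.frame"))
}

#' Percent-of-total partition for arbitrary sums of squares
#'
#' Helper that turns a named vector of sums of squares into percentages of
#' their total, as displayed alongside combined ANOVA tables.
#'
#' @param ss Named numeric vector of sums of squares.
#' @return Named numeric vector summing to 100.
#' @export
pct_total_ss <- function(ss) {
  if (any(ss < 0)) stop("sums of squares must be >= 0")
  100 * ss / sum(ss)
}
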