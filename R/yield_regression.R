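#' Multiple linear regression of yield on component traits
#'
#' Ordinary least squares of the response trait (fresh yield, by
#' convention) on the remaining traits, fitted per environment on
#' replicate-averaged genotype means (n = number of genotypes). Plot-level
#' fitting is available behind `level = "plot"`. When yield-per-plant is
#' among the predictors it is structurally collinear with fresh yield; a
#' warning flags this but the model is fitted as requested.
#'
#' @param x A balanced [trait_table].
#' @param environment Environment id.
#' @param response Response trait (default `"FY"`).
#' @param predictors Predictor traits; default: every other trait, in
#'   table order.
#' @param level `"genotype_means"` (default) or `"plot"`.
#' @return Object of class `regression_result`: list with `coefficients`
#'   (data frame: term, b, se, t, p), `r2_percent`, `model_p`, `n`,
#'   `response`, `predictors`, and the underlying `lm` fit.
#' @export
fit_fy_regression <- function(x, environment, response = "FY",
                              predictors = NULL,
                              level = c("genotype_means", "plot")) {
  level <- match.arg(level)
  trs <- traits(x)
  if (!response %in% trs) stop("unknown response trait: ", response)
  if (is.null(predictors)) predictors <- setdiff(trs, response)
  if (!all(predictors %in% trs)) {
    stop("unknown predictor trait(s): ",
         paste(setdiff(predictors, trs), collapse = ", "))
  }
  if ("YPP" %in% predictors && response == "FY") {
    warning("YPP is structurally collinear with FY; slopes for the other ",
            "predictors should be interpreted with care")
  }
  cols <- lapply(c(response, predictors), function(tr) {
    m <- .slice_matrix(x, tr, environment)
    if (level == "genotype_means") rowMeans(m) else as.vector(m)
  })
  d <- as.data.frame(cols)
  names(d) <- c(response, predictors)
  n <- nrow(d)
  if (n < length(predictors) + 2L) {
    stop("need at least ", length(predictors) + 2L, " observations")
  }
  X <- as.matrix(d[predictors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)
  co <- stats::coef(sm)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  coefs <- data.frame(term = c("(Intercept)", predictors),
                      b = co[, 1L], se = co[, 2L], t = co[, 3L],
                      p = co[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 r2_percent = 100 * sm$r.squared,
                 model_p = unname(model_p),
                 n = n, response = response, predictors = predictors,
                 environment = environment, level = level, fit = fit,
                 data = d),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s (%s, %s, n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$environment,
              x$level, x$n))
  print(transform(x$coefficients, b = signif(b, 4), se = signif(se, 3),
                  t = signif(t, 3), p = signif(p, 3)))
  cat(sprintf("r2 = %.1f%%, model p = %.3g\n", x$r2_percent, x$model_p))
  invisible(x)
}

#' Per-predictor contribution to explained yield variation
#'
#' Sequential (type-I) sum-of-squares shares in the fitted predictor
#' order, expressed in percent of total variation so that the shares sum
#' exactly to the model's R-squared percentage. Standardized coefficients
#' (slopes in response-SD units per predictor SD) are attached as an
#' order-free alternative view.
#'
#' @param result A [fit_fy_regression()] result.
#' @return Data frame with `term`, `share_percent` (summing to
#'   `r2_percent`) and `std_coef`.
#' @export
contribution_profile <- function(result) {
  stopifnot(inherits(result, "regression_result"))
  an <- stats::anova(result$fit)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  ss <- an[keep, "Sum Sq"]
  sst <- sum(an[, "Sum Sq"])
  share <- 100 * ss / sst
  d <- result$data
  sdy <- stats::sd(d[[result$response]])
  b <- result$coefficients$b[-1L]
  stdc <- b * vapply(result$predictors,
                     function(p) stats::sd(d[[p]]), numeric(1L)) / sdy
  data.frame(term = gsub("`", "", terms[keep]),
             share_percent = share,
             std_coef = unname(stdc),
             stringsAsFactors = FALSE)
}
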