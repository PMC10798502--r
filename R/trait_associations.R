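#' Genotypic, environmental and phenotypic covariance components
#'
#' Analysis of covariance mirroring the RCBD ANOVA: the error covariance is
#' the error mean cross-product, the genotypic covariance is
#' `(genotype mean cross-product - error mean cross-product) / r`, and the
#' phenotypic covariance is their sum. Covariances are sign-preserving
#' (never truncated). With `trait_y` equal to `trait_x` the components
#' reduce to the trait's variance components.
#'
#' For `environment = NULL` the components come from the combined
#' multi-year model: genotype mean cross-products across the full table
#' (effective replication Y*R) against the combined-model residual
#' cross-products. In that pooled view a share of the genotype-by-year
#' cross-products (1/Y of them) travels with the genotypic component, the
#' standard behaviour of mean-cross-product estimators pooled over years.
#'
#' @param x A balanced [trait_table].
#' @param trait_x,trait_y Trait identifiers.
#' @param environment One environment id, or `NULL` for pooled-over-years.
#' @return List `cov_g`, `cov_e`, `cov_p`, `r_effective`, `n_genotypes`.
#' @export
covariance_components <- function(x, trait_x, trait_y, environment = NULL) {
  if (is.null(environment)) {
    ax <- .stack_array(x, trait_x)
    ay <- .stack_array(x, trait_y)
    if (!identical(dim(ax), dim(ay)) ||
        !identical(dimnames(ax)[[1L]], dimnames(ay)[[1L]])) {
      stop("design mismatch between traits ", trait_x, " and ", trait_y)
    }
    G <- dim(ax)[1L]; R <- dim(ax)[2L]; Y <- dim(ax)[3L]
    mcp_gen <- Y * R * sum((apply(ax, 1L, mean) - mean(ax)) *
                           (apply(ay, 1L, mean) - mean(ay))) / (G - 1)
    rx <- .combined_residuals(ax)
    ry <- .combined_residuals(ay)
    mcp_err <- sum(rx * ry) / ((G - 1) * Y * (R - 1))
    reff <- Y * R
  } else {
    mx <- .slice_matrix(x, trait_x, environment)
    my <- .slice_matrix(x, trait_y, environment)
    if (!identical(dim(mx), dim(my)) ||
        !identical(rownames(mx), rownames(my))) {
      stop("design mismatch between traits ", trait_x, " and ", trait_y)
    }
    G <- nrow(mx); R <- ncol(mx)
    mcp_gen <- R * sum((rowMeans(mx) - mean(mx)) *
                       (rowMeans(my) - mean(my))) / (G - 1)
    resid <- function(m) {
      m - outer(rowMeans(m), colMeans(m), `+`) + mean(m)
    }
    mcp_err <- sum(resid(mx) * resid(my)) / ((G - 1) * (R - 1))
    reff <- R
  }
  cov_g <- (mcp_gen - mcp_err) / reff
  list(cov_g = cov_g, cov_e = mcp_err, cov_p = cov_g + mcp_err,
       r_effective = reff, n_genotypes = G)
}

# genotype x replicate x year array for one trait
.stack_array <- function(x, trait) {
  envs <- environments(x)
  slices <- lapply(envs, function(e) .slice_matrix(x, trait, e))
  gens <- rownames(slices[[1L]])
  slices <- lapply(slices, function(s) s[gens, , drop = FALSE])
  array(unlist(slices), c(nrow(slices[[1L]]), ncol(slices[[1L]]),
                          length(envs)),
        dimnames = list(gens, NULL, envs))
}

# residuals of the combined model (genotype, year, GxY, rep-in-year removed)
.combined_residuals <- function(a) {
  cellmean <- apply(a, c(1L, 3L), mean)          # genotype x year
  repyear <- apply(a, c(2L, 3L), mean)           # rep x year
  yearmean <- apply(a, 3L, mean)
  G <- dim(a)[1L]; R <- dim(a)[2L]; Y <- dim(a)[3L]
  res <- a
  for (j in seq_len(Y)) {
    res[, , j] <- a[, , j] -
      outer(cellmean[, j], repyear[, j], `+`) + yearmean[j]
  }
  res
}

#' Genotypic and phenotypic correlation matrices
#'
#' For every trait pair: `r_g = cov_g / sqrt(sigma2_g_x * sigma2_g_y)` and
#' `r_p = cov_p / sqrt(sigma2_p_x * sigma2_p_y)` from
#' [covariance_components()]. A genotypic correlation is reported only when
#' both genotypic variances are positive; otherwise it is flagged
#' not-estimable (`NA` in the matrix). Moment estimates of `|r_g|` can
#' exceed 1; such values are capped at +/-0.99 and flagged in `capped`
#' (the behaviour of the standard MET software this mimics). Significance
#' uses `t = r sqrt(df / (1 - r^2))` with `df = G - 2`, two-sided.
#'
#' @param x A balanced [trait_table].
#' @param traits Traits to include (default: all in table order).
#' @param environment One environment id, or `NULL` for pooled-over-years.
#' @param cap Cap applied to inadmissible `|r_g| > 1` estimates.
#' @return Object of class `correlation_matrices`: list with matrices
#'   `r_g`, `r_p`, `p_g`, `p_p`, logical matrices `capped` and
#'   `estimable_g`, and a long data frame `pairs` (one row per unordered
#'   pair) with significance stars.
#' @export
correlation_matrices <- function(x, traits = NULL, environment = NULL,
                                 cap = 0.99) {
  trs <- if (is.null(traits)) metbiom::traits(x) else traits
  nt <- length(trs)
  r_g <- r_p <- p_g <- p_p <- matrix(NA_real_, nt, nt,
                                     dimnames = list(trs, trs))
  capped <- est_g <- matrix(FALSE, nt, nt, dimnames = list(trs, trs))
  diag(r_g) <- diag(r_p) <- 1
  diag(est_g) <- TRUE
  vars <- lapply(trs, function(tr) covariance_components(x, tr, tr,
                                                         environment))
  G <- vars[[1L]]$n_genotypes
  dfree <- G - 2L
  pairs <- list()
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (j >= i) next
    cc <- covariance_components(x, trs[i], trs[j], environment)
    vg_i <- vars[[i]]$cov_g; vg_j <- vars[[j]]$cov_g
    vp_i <- vars[[i]]$cov_p; vp_j <- vars[[j]]$cov_p
    rp <- if (vp_i > 0 && vp_j > 0) {
      max(min(cc$cov_p / sqrt(vp_i * vp_j), 1), -1)
    } else NA_real_
    rg <- NA_real_; cap_ij <- FALSE
    if (vg_i > 0 && vg_j > 0) {
      rg <- cc$cov_g / sqrt(vg_i * vg_j)
      if (abs(rg) > 1) {
        rg <- sign(rg) * cap
        cap_ij <- TRUE
      }
      est_g[i, j] <- est_g[j, i] <- TRUE
    }
    pg <- if (is.na(rg)) NA_real_ else .corr_pvalue(rg, dfree)
    pp <- if (is.na(rp)) NA_real_ else .corr_pvalue(rp, dfree)
    r_g[i, j] <- r_g[j, i] <- rg
    r_p[i, j] <- r_p[j, i] <- rp
    p_g[i, j] <- p_g[j, i] <- pg
    p_p[i, j] <- p_p[j, i] <- pp
    capped[i, j] <- capped[j, i] <- cap_ij
    pairs[[length(pairs) + 1L]] <- data.frame(
      trait_x = trs[j], trait_y = trs[i],
      r_g = rg, p_g = pg, stars_g = .stars(pg),
      r_p = rp, p_p = pp, stars_p = .stars(pp),
      capped = cap_ij, estimable_g = est_g[i, j],
      stringsAsFactors = FALSE)
  }
  structure(list(r_g = r_g, r_p = r_p, p_g = p_g, p_p = p_p,
                 capped = capped, estimable_g = est_g,
                 pairs = do.call(rbind, pairs),
                 environment = if (is.null(environment)) "pooled"
                               else environment,
                 n_genotypes = G),
            class = "correlation_matrices")
}

.corr_pvalue <- function(r, dfree) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(dfree / (1 - r^2))
  2 * stats::pt(abs(tval), dfree, lower.tail = FALSE)
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' @export
print.correlation_matrices <- function(x, digits = 2, ...) {
  cat("Trait correlations (", x$environment, "), ",
      x$n_genotypes, " genotypes\n", sep = "")
  cat("genotypic (lower shown):\n")
  print(round(x$r_g, digits))
  cat("phenotypic:\n")
  print(round(x$r_p, digits))
  invisible(x)
}
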