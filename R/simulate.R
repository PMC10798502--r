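#' Configure a synthetic multi-environment trial
#'
#' Builds the configuration object for [simulate_met()]. The generative
#' model per trait t is the classical MET decomposition
#' \deqn{y_{ijk}(t) = \mu_t + g_i(t) + y_j(t) + gy_{ij}(t) + \varepsilon_{ijk}(t)}
#' with the genotype effect vectors \eqn{g_i} drawn jointly across traits
#' under `genetic_correlation` (so genotypic trait correlations are
#' recoverable downstream), plot errors \eqn{\varepsilon} drawn jointly
#' under `error_correlation` (identity by default, so phenotypic
#' correlations arise mainly through the genetic channel), and year and
#' genotype-by-year effects independent per trait. Genotype effects are
#' shared across environments; all year-specific deviation is carried by
#' the interaction term.
#'
#' @param traits Data frame with one row per trait and columns `trait`,
#'   `grand_mean`, `sigma2_g`, `sigma2_e`, and optionally `sigma2_y` and
#'   `sigma2_gy` (default 0).
#' @param n_genotypes,n_environments,n_replicates Design dimensions;
#'   `n_replicates` must be at least 2.
#' @param genetic_correlation,error_correlation Trait x trait correlation
#'   matrices (unit diagonal, positive semi-definite). Scalars are expanded
#'   to exchangeable matrices; defaults are identity.
#' @param sigma2_rep Variance of replicate (block) effects nested within
#'   environment; 0 by default (block sums of squares in well-run trials of
#'   this kind are negligible).
#' @param positivity `"none"` (default) or `"truncate"`: truncate simulated
#'   values below `floor_frac * grand_mean` up to that floor, AFTER effect
#'   summation. Truncation distorts variances, so it is off by default and
#'   the number of truncated cells is recorded on the result.
#' @param floor_frac Positivity floor as a fraction of the trait grand mean.
#' @param seed Integer seed; the same seed yields a bit-identical table.
#' @return A list of class `sim_config`.
#' @seealso [simulate_met()], [table1_like_config()]
#' @export
sim_config <- function(traits, n_genotypes, n_environments, n_replicates,
                       genetic_correlation = NULL, error_correlation = NULL,
                       sigma2_rep = 0, positivity = c("none", "truncate"),
                       floor_frac = 0.01, seed = 1L) {
  positivity <- match.arg(positivity)
  traits <- as.data.frame(traits)
  need <- c("trait", "grand_mean", "sigma2_g", "sigma2_e")
  if (!all(need %in% names(traits))) {
    stop("traits must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(traits$sigma2_y)) traits$sigma2_y <- 0
  if (is.null(traits$sigma2_gy)) traits$sigma2_gy <- 0
  vcols <- c("sigma2_g", "sigma2_e", "sigma2_y", "sigma2_gy")
  if (any(unlist(traits[vcols]) < 0) || sigma2_rep < 0) {
    stop("variances must be >= 0")
  }
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (n_genotypes < 2L) stop("n_genotypes must be >= 2")
  ntr <- nrow(traits)
  genetic_correlation <- .as_corr(genetic_correlation, ntr, traits$trait)
  error_correlation <- .as_corr(error_correlation, ntr, traits$trait)
  structure(list(traits = traits,
                 n_genotypes = as.integer(n_genotypes),
                 n_environments = as.integer(n_environments),
                 n_replicates = as.integer(n_replicates),
                 genetic_correlation = genetic_correlation,
                 error_correlation = error_correlation,
                 sigma2_rep = sigma2_rep,
                 positivity = positivity,
                 floor_frac = floor_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# expand scalar rho / validate a correlation matrix
.as_corr <- function(m, n, labels) {
  if (is.null(m)) m <- diag(n)
  if (length(m) == 1L && is.numeric(m)) {
    rho <- as.numeric(m)
    m <- matrix(rho, n, n)
    diag(m) <- 1
  }
  m <- as.matrix(m)
  if (!all(dim(m) == c(n, n))) stop("correlation matrix must be ", n, "x", n)
  if (any(abs(m) > 1 + 1e-12)) stop("correlation entries must lie in [-1, 1]")
  if (max(abs(diag(m) - 1)) > 1e-12) stop("correlation diagonal must be 1")
  if (max(abs(m - t(m))) > 1e-12) stop("correlation matrix must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  dimnames(m) <- list(labels, labels)
  m
}

# draw n rows from N(0, diag(sd) %*% C %*% diag(sd)) via eigen factor
# (eigen handles PSD-but-singular C, unlike chol)
.rmvn <- function(n, sd, C) {
  p <- length(sd)
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  z <- matrix(stats::rnorm(n * p), n, p) %*% t(L)
  sweep(z, 2L, sd, `*`)
}

#' Simulate a balanced MET with known variance structure
#'
#' Generates the full G x Y x R x T plot table under the model documented in
#' [sim_config()], together with a truth ledger of the per-trait variance
#' components and derived parameters computed *analytically from the
#' configuration* (never from the realized sample), so every downstream
#' estimator has a recoverable ground truth.
#'
#' In the ledger, `sigma2_p = sigma2_g + sigma2_e` mirrors the single-year
#' RCBD decomposition in which broad-sense heritability
#' `h2b = sigma2_g / sigma2_p` lives; year and interaction variances are
#' carried separately.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [trait_table]) and `truth` (list
#'   with per-trait data frame `parameters`, the `genetic_correlation` and
#'   `error_correlation` matrices, and `n_truncated`).
#' @examples
#' cfg <- sim_config(
#'   traits = data.frame(trait = "PH", grand_mean = 100,
#'                       sigma2_g = 100, sigma2_e = 25),
#'   n_genotypes = 10, n_environments = 2, n_replicates = 2, seed = 7)
#' sim <- simulate_met(cfg)
#' sim$truth$parameters$h2b  # 0.8 by construction
#' @export
simulate_met <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$traits
  G <- config$n_genotypes; Y <- config$n_environments
  R <- config$n_replicates; Tn <- nrow(tr)
  set.seed(config$seed)

  gen_ids <- sprintf("G%03d", seq_len(G))
  env_ids <- sprintf("E%d", seq_len(Y))

  g_eff <- .rmvn(G, sqrt(tr$sigma2_g), config$genetic_correlation)   # G x T
  y_eff <- sapply(tr$sigma2_y, function(v) stats::rnorm(Y, 0, sqrt(v)))
  y_eff <- matrix(y_eff, Y, Tn)                                      # Y x T
  gy_eff <- array(stats::rnorm(G * Y * Tn), c(G, Y, Tn))
  for (t in seq_len(Tn)) gy_eff[, , t] <- gy_eff[, , t] * sqrt(tr$sigma2_gy[t])
  rep_eff <- matrix(stats::rnorm(Y * R, 0, sqrt(config$sigma2_rep)), Y, R)
  eps <- .rmvn(G * Y * R, sqrt(tr$sigma2_e), config$error_correlation)

  idx <- expand.grid(g = seq_len(G), e = seq_len(Y), r = seq_len(R),
                     KEEP.OUT.ATTRS = FALSE)
  n_truncated <- 0L
  recs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    v <- tr$grand_mean[t] + g_eff[idx$g, t] + y_eff[idx$e, t] +
      gy_eff[cbind(idx$g, idx$e, t)] + rep_eff[cbind(idx$e, idx$r)] +
      eps[, t]
    if (config$positivity == "truncate") {
      floorv <- config$floor_frac * tr$grand_mean[t]
      n_truncated <- n_truncated + sum(v < floorv)
      v <- pmax(v, floorv)
    }
    recs[[t]] <- data.frame(genotype = gen_ids[idx$g],
                            environment = env_ids[idx$e],
                            replicate = idx$r,
                            trait = tr$trait[t],
                            value = v,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  tab <- tab[order(match(tab$trait, tr$trait), match(tab$environment, env_ids),
                   tab$replicate, match(tab$genotype, gen_ids)), ]
  rownames(tab) <- NULL

  s2p <- tr$sigma2_g + tr$sigma2_e
  params <- data.frame(trait = tr$trait,
                       grand_mean = tr$grand_mean,
                       sigma2_g = tr$sigma2_g,
                       sigma2_e = tr$sigma2_e,
                       sigma2_p = s2p,
                       sigma2_y = tr$sigma2_y,
                       sigma2_gy = tr$sigma2_gy,
                       h2b = ifelse(s2p > 0, tr$sigma2_g / s2p, NA_real_),
                       GCV = 100 * sqrt(tr$sigma2_g) / tr$grand_mean,
                       ECV = 100 * sqrt(tr$sigma2_e) / tr$grand_mean,
                       PCV = 100 * sqrt(s2p) / tr$grand_mean,
                       stringsAsFactors = FALSE)
  list(table = trait_table(tab),
       truth = list(parameters = params,
                    genetic_correlation = config$genetic_correlation,
                    error_correlation = config$error_correlation,
                    n_truncated = n_truncated,
                    seed = config$seed))
}

#' Packaged simulation fixture mimicking a real turmeric trial year
#'
#' Returns a [sim_config()] whose twelve traits copy the grand means and the
#' genotypic and error variance components estimated for the 2019-20 season
#' of a published 53-genotype turmeric multi-environment trial (the
#' reference table shipped in `extdata/genetic_parameter_reference.tsv`),
#' with heritabilities spanning roughly 0.58-0.99 and genotypic
#' coefficients of variation from about 6% to 90% across the three seasons.
#' A mild exchangeable genetic correlation (default rho = 0.4) links the
#' traits so the association stage has signal to recover.
#'
#' Year and interaction variances are not published per trait; defaults are
#' calibrated so that, for the yield trait, genotype, year and
#' genotype-by-year sums of squares partition roughly as 41/26/32% of the
#' total — the pattern of the reference combined ANOVA. The same
#' variance ratios (sigma2_gy = 1.92 sigma2_g, sigma2_y = 1.51 sigma2_g)
#' are applied to every trait.
#'
#' With variance components this large relative to some trait means
#' (several traits run at 50-90% genotypic CV), a Gaussian model
#' necessarily produces occasional negative plot values and even negative
#' year means that the real, right-skewed crop data cannot; analyses that
#' need positivity (CV, GAI) should enable `positivity = "truncate"`.
#'
#' @param rho Exchangeable genetic correlation between traits.
#' @param n_genotypes,n_environments,n_replicates Design dimensions,
#'   defaulting to the reference trial's 53 x 3 x 2.
#' @param seed Seed stored in the config.
#' @param gy_ratio,year_ratio Interaction and year variances as multiples
#'   of each trait's genotypic variance.
#' @param ... Further arguments (e.g. `positivity`) passed to
#'   [sim_config()].
#' @return A [sim_config()].
#' @export
table1_like_config <- function(rho = 0.4, n_genotypes = 53,
                               n_environments = 3, n_replicates = 2,
                               seed = 1L, gy_ratio = 1.92, year_ratio = 1.51,
                               ...) {
  ref <- reference_genetic_parameters()
  ref <- ref[ref$year == "2019-20", ]
  traits <- data.frame(trait = ref$trait,
                       grand_mean = ref$mean,
                       sigma2_g = ref$sigma2_g,
                       sigma2_e = ref$sigma2_e,
                       sigma2_y = year_ratio * ref$sigma2_g,
                       sigma2_gy = gy_ratio * ref$sigma2_g,
                       stringsAsFactors = FALSE)
  sim_config(traits, n_genotypes = n_genotypes,
             n_environments = n_environments, n_replicates = n_replicates,
             genetic_correlation = rho, seed = seed, ...)
}

#' Serialize a truth ledger to a flat JSON file
#'
#' @param truth The `truth` element of a [simulate_met()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  jsonlite::write_json(
    list(parameters = truth$parameters,
         genetic_correlation = truth$genetic_correlation,
         error_correlation = truth$error_correlation,
         n_truncated = truth$n_truncated,
         seed = truth$seed),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
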