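#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()] into one validated
#' object. Can be read from a nestable JSON config file with
#' [read_pipeline_config()]; any argument supplied directly overrides the
#' file value.
#'
#' @param input Path to the long-format plot CSV (see
#'   [read_trait_table()]).
#' @param output_dir Directory for the output bundle (created if absent).
#' @param traits Traits to analyze; `NULL` means all traits in the input.
#' @param response Response trait for the regression stage.
#' @param k Selection differential for genetic advance.
#' @param alpha_levels Critical-difference significance levels.
#' @param cluster_method,cluster_k Clustering stage parameters
#'   (`cluster_k` is ignored by `"tocher"`).
#' @param min_occurrence Threshold for [select_superior()].
#' @param top_n Top-rank cutoff for occurrence counting.
#' @param seed Seed recorded in the manifest (analysis stages are
#'   deterministic; the seed matters only when the input is simulated).
#' @param mode `"full"` (full precision) or `"report"` (2-decimal
#'   rounding, matching conventional published tables).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, traits = NULL,
                            response = "FY", k = 2.06,
                            alpha_levels = c(0.05, 0.01),
                            cluster_method = "tocher", cluster_k = 5,
                            min_occurrence = 5, top_n = 10, seed = 1L,
                            mode = c("full", "report")) {
  mode <- match.arg(mode)
  structure(list(input = input, output_dir = output_dir, traits = traits,
                 response = response, k = k, alpha_levels = alpha_levels,
                 cluster_method = cluster_method, cluster_k = cluster_k,
                 min_occurrence = min_occurrence, top_n = top_n,
                 seed = as.integer(seed), mode = mode),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON config file.
#' @param ... Overrides passed to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

#' Run the full MET biometry pipeline
#'
#' Orchestrates every stage end-to-end from one input table: the
#' genetic-parameter table per trait and year, pooled and per-year
#' correlations, per-year yield regressions, divergence clustering
#' (membership, distance summary, cluster means, and a Newick dendrogram
#' for hierarchical methods), the GAI rank report with superior-genotype
#' selection, and the combined genotype-by-year ANOVA for the response
#' trait. Outputs are plain CSV plus a JSON manifest carrying the config
#' and MD5 checksums of every file; re-running with identical config and
#' input reproduces the bundle byte for byte. Any stage error aborts the
#' run and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tab <- read_trait_table(config$input)
  trs <- if (is.null(config$traits)) traits(tab) else config$traits
  unknown <- setdiff(c(trs, config$response), traits(tab))
  if (length(unknown)) {
    stop("config references unknown trait(s): ",
         paste(unknown, collapse = ", "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed in stage [", attr(e, "stage") %||% "unknown",
         "]: ", conditionMessage(e), call. = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  fmt <- function(d) {
    if (config$mode == "report") {
      num <- vapply(d, is.numeric, TRUE)
      d[num] <- lapply(d[num], round, 2)
    }
    d
  }
  emit <- function(d, file) {
    path <- file.path(config$output_dir, file)
    utils::write.csv(fmt(as.data.frame(d)), path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      attr(e, "stage") <- name
      on_fail(e)
    })
  }

  log_stage <- function(...) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
  }

  log_stage("genetic parameters (%d traits x %d environments), seed %d",
            length(trs), length(environments(tab)), config$seed)
  stage("genetic_parameters", {
    emit(build_table1(tab, k = config$k,
                      alpha_levels = config$alpha_levels),
         "genetic_parameters.csv")
  })

  log_stage("trait correlations")
  stage("correlations", {
    emit(correlation_matrices(tab, trs)$pairs, "corr_pooled.csv")
    for (env in environments(tab)) {
      emit(correlation_matrices(tab, trs, environment = env)$pairs,
           paste0("corr_", gsub("[^A-Za-z0-9_-]", "_", env), ".csv"))
    }
  })

  log_stage("yield regression")
  stage("regression", {
    for (env in environments(tab)) {
      fitr <- fit_fy_regression(tab, env, response = config$response,
                                predictors = setdiff(trs, config$response))
      co <- fitr$coefficients
      co$r2_percent <- fitr$r2_percent
      co$model_p <- fitr$model_p
      emit(co, paste0("regress_", gsub("[^A-Za-z0-9_-]", "_", env), ".csv"))
    }
  })

  log_stage("divergence clustering (%s)", config$cluster_method)
  stage("clustering", {
    means <- genotype_trait_means(tab, trs)
    D <- mahalanobis_d2(means, pooled_within_covariance(tab, trs),
                        pseudo_inverse = TRUE)
    sol <- cluster_genotypes(D, method = config$cluster_method,
                             k = config$cluster_k)
    summ <- cluster_summary(sol, D, means, scale = "sqrt")
    emit(summ$membership, "cluster_membership.csv")
    emit(cbind(cluster = rownames(summ$distance),
               as.data.frame(summ$distance)), "cluster_distances.csv")
    emit(cbind(cluster = rownames(summ$cluster_means),
               as.data.frame(summ$cluster_means)), "cluster_means.csv")
    if (!is.null(sol$hclust)) {
      path <- file.path(config$output_dir, "dendrogram.nwk")
      writeLines(hclust_newick(sol$hclust), path)
      written <<- c(written, path)
    }
  })

  log_stage("GAI ranking and selection")
  stage("gai", {
    gai <- geometric_adaptability_index(tab, trs)
    report <- consolidate_ranks(rank_by_gai(gai), top_n = config$top_n)
    emit(cbind(genotype = rownames(gai), as.data.frame(unclass(gai))),
         "gai_values.csv")
    wide <- cbind(data.frame(genotype = rownames(report$ranks)),
                  as.data.frame(report$ranks),
                  report$summary[c("MR", "R.MR", "occurrence")])
    emit(wide, "gai_ranks.csv")
    emit(select_superior(report, min_occurrence = config$min_occurrence),
         "superior_genotypes.csv")
  })

  log_stage("combined genotype x year ANOVA (%s)", config$response)
  stage("gxy_anova", {
    emit(as.data.frame(combined_gxy_anova(tab, config$response)),
         "gxy_anova.csv")
  })

  manifest <- list(
    package = "metbiom",
    version = as.character(utils::packageVersion("metbiom")),
    seed = config$seed,
    config = unclass(config),
    input_md5 = unname(tools::md5sum(config$input)),
    outputs = as.list(tools::md5sum(sort(written))))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
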