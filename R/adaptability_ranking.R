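#' Geometric Adaptability Index
#'
#' For every genotype and trait, the geometric mean of its environment
#' (year) means: `GAI = (prod_j xbar_ij)^(1/Y)`. By the AM-GM inequality
#' the GAI never exceeds the arithmetic mean across years and equals it
#' only when performance is identical in every year, so the index rewards
#' both level and cross-environment consistency. It is undefined for
#' non-positive year means; offending genotypes trigger an error unless
#' `on_nonpositive = "drop"`, in which case they are excluded and listed
#' in attribute `"excluded"`.
#'
#' @param x A balanced [trait_table].
#' @param traits Traits to include (default all).
#' @param on_nonpositive `"error"` (default) or `"drop"`.
#' @return Genotype x trait matrix of GAI values (class `gai_matrix`).
#' @export
geometric_adaptability_index <- function(x, traits = NULL,
                                         on_nonpositive = c("error",
                                                            "drop")) {
  on_nonpositive <- match.arg(on_nonpositive)
  trs <- if (is.null(traits)) metbiom::traits(x) else traits
  mats <- lapply(trs, function(tr) genotype_env_means(x, tr))
  bad_gen <- character()
  for (i in seq_along(trs)) {
    m <- mats[[i]]
    nonpos <- which(m <= 0, arr.ind = TRUE)
    if (nrow(nonpos)) {
      g <- rownames(m)[nonpos[1L, 1L]]
      e <- colnames(m)[nonpos[1L, 2L]]
      if (on_nonpositive == "error") {
        stop(sprintf(
          "GAI undefined: non-positive year mean (genotype %s, trait %s, environment %s)",
          g, trs[i], e))
      }
      bad_gen <- union(bad_gen, rownames(m)[unique(nonpos[, 1L])])
    }
  }
  keep <- setdiff(rownames(mats[[1L]]), bad_gen)
  if (length(bad_gen)) {
    message("GAI: excluding ", length(bad_gen),
            " genotype(s) with non-positive year means: ",
            paste(bad_gen, collapse = ", "))
  }
  gai <- vapply(mats, function(m) {
    exp(rowMeans(log(m[keep, , drop = FALSE])))
  }, numeric(length(keep)))
  gai <- matrix(gai, nrow = length(keep),
                dimnames = list(keep, trs))
  structure(gai, excluded = bad_gen, class = c("gai_matrix", "matrix"))
}

#' Rank genotypes by GAI, per trait
#'
#' Rank 1 is the highest GAI within each trait, for every trait; ties get
#' the average of the tied positions (so a shared second place is 2.5 and
#' each rank column sums to G(G+1)/2).
#'
#' @param gai A genotype x trait GAI matrix.
#' @return Genotype x trait matrix of ranks.
#' @export
rank_by_gai <- function(gai) {
  gai <- unclass(as.matrix(gai))
  apply(gai, 2L, function(col) rank(-col, ties.method = "average"))
}

#' Mean rank, re-rank and top-10 occurrence
#'
#' Consolidates a per-trait rank matrix: `MR` is the arithmetic mean of a
#' genotype's ranks over all traits; `R.MR` re-ranks MR ascending (1 =
#' best, average ties); `occurrence` counts the traits on which the
#' genotype ranks within the top `top_n`. R.MR is computed on unrounded
#' MR; round only for display.
#'
#' @param ranks Genotype x trait rank matrix (e.g. [rank_by_gai()]).
#' @param top_n Rank cutoff for the occurrence count (default 10).
#' @return Object of class `rank_report`: list with the `ranks` matrix and
#'   a `summary` data frame (genotype, MR, R.MR, occurrence).
#' @export
consolidate_ranks <- function(ranks, top_n = 10) {
  ranks <- as.matrix(ranks)
  mr <- rowMeans(ranks)
  rmr <- rank(mr, ties.method = "average")
  occ <- rowSums(ranks <= top_n)
  structure(list(ranks = ranks,
                 summary = data.frame(genotype = rownames(ranks),
                                      MR = mr, R.MR = rmr,
                                      occurrence = as.integer(occ),
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 top_n = top_n),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("GAI rank report: %d genotypes x %d traits (top-%d occurrence)\n",
              nrow(x$ranks), ncol(x$ranks), x$top_n))
  s <- x$summary[order(x$summary$R.MR), ]
  s$MR <- round(s$MR, 2)
  print(utils::head(s, 10L), row.names = FALSE)
  if (nrow(s) > 10L) cat("...\n")
  invisible(x)
}

#' Select superior genotypes from a rank report
#'
#' Genotypes occurring in the top ten (or `top_n`) on at least
#' `min_occurrence` traits are selected; optional auxiliary admission adds
#' the best `extra_top_k` genotypes on a named trait's rank column (e.g.
#' the yield column), each selection tagged with its admission reason.
#'
#' @param report A [consolidate_ranks()] report.
#' @param min_occurrence Minimum top-`top_n` occurrences (default 5).
#' @param extra_trait,extra_top_k Optional auxiliary criterion.
#' @return Data frame `genotype`, `reason` (`"occurrence"`,
#'   `"auxiliary"`, or `"both"`), ordered by R.MR.
#' @export
select_superior <- function(report, min_occurrence = 5,
                            extra_trait = NULL, extra_top_k = 0) {
  stopifnot(inherits(report, "rank_report"))
  s <- report$summary
  by_occ <- s$genotype[s$occurrence >= min_occurrence]
  by_aux <- character()
  if (!is.null(extra_trait) && extra_top_k > 0) {
    if (!extra_trait %in% colnames(report$ranks)) {
      stop("unknown trait in auxiliary criterion: ", extra_trait)
    }
    col <- report$ranks[, extra_trait]
    by_aux <- names(sort(col))[seq_len(min(extra_top_k, length(col)))]
  }
  sel <- union(by_occ, by_aux)
  reason <- ifelse(sel %in% by_occ & sel %in% by_aux, "both",
                   ifelse(sel %in% by_occ, "occurrence", "auxiliary"))
  out <- data.frame(genotype = sel, reason = reason,
                    stringsAsFactors = FALSE)
  out[order(s$R.MR[match(out$genotype, s$genotype)]), , drop = FALSE]
}
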