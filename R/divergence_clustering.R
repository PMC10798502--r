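#' Genotype-by-trait mean matrix
#'
#' Replicate- (and optionally year-) averaged genotype means for a set of
#' traits, the input to divergence analysis.
#'
#' @param x A balanced [trait_table].
#' @param traits Traits to include (default all).
#' @param environment One environment, or `NULL` to average across all.
#' @return Numeric matrix, genotypes x traits.
#' @export
genotype_trait_means <- function(x, traits = NULL, environment = NULL) {
  trs <- if (is.null(traits)) metbiom::traits(x) else traits
  cols <- lapply(trs, function(tr) {
    m <- genotype_env_means(x, tr)
    if (is.null(environment)) rowMeans(m) else m[, environment]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- trs
  out
}

#' Pooled within-genotype (error) covariance of traits
#'
#' Trait covariance of replicate-level residuals after removing genotype
#' and replicate effects within each environment, pooled over environments;
#' the dispersion matrix that scales Mahalanobis D-squared.
#'
#' @param x A balanced [trait_table].
#' @param traits Traits to include (default all).
#' @return Trait x trait covariance matrix with attribute `"df"` (pooled
#'   error degrees of freedom).
#' @export
pooled_within_covariance <- function(x, traits = NULL) {
  trs <- if (is.null(traits)) metbiom::traits(x) else traits
  envs <- environments(x)
  cp <- matrix(0, length(trs), length(trs), dimnames = list(trs, trs))
  dfree <- 0L
  for (env in envs) {
    res <- sapply(trs, function(tr) {
      m <- .slice_matrix(x, tr, env)
      as.vector(m - outer(rowMeans(m), colMeans(m), `+`) + mean(m))
    })
    m1 <- .slice_matrix(x, trs[1L], env)
    dfree <- dfree + (nrow(m1) - 1L) * (ncol(m1) - 1L)
    cp <- cp + crossprod(res)
  }
  out <- cp / dfree
  attr(out, "df") <- dfree
  out
}

#' Mahalanobis D-squared distance matrix
#'
#' `D2(i, j) = (x_i - x_j)' S^{-1} (x_i - x_j)` between genotype trait-mean
#' vectors, with `S` the pooled within-genotype covariance. If `S` is
#' singular, a Moore-Penrose pseudo-inverse is used when
#' `pseudo_inverse = TRUE` (with a warning), otherwise an error is raised.
#' With `S` the identity, D2 reduces to squared Euclidean distance.
#'
#' @param means Genotype x trait matrix (e.g. [genotype_trait_means()]).
#' @param pooled_cov Trait covariance matrix; identity if omitted.
#' @param pseudo_inverse Permit a pseudo-inverse for singular `pooled_cov`.
#' @return Object of class `distance_matrix`: symmetric non-negative
#'   matrix with zero diagonal and attribute `metric = "mahalanobis_D2"`.
#' @export
mahalanobis_d2 <- function(means, pooled_cov = NULL, pseudo_inverse = FALSE) {
  means <- as.matrix(means)
  p <- ncol(means)
  if (is.null(pooled_cov)) pooled_cov <- diag(p)
  pooled_cov <- as.matrix(pooled_cov)
  stopifnot(nrow(pooled_cov) == p, ncol(pooled_cov) == p)
  inv <- tryCatch(solve(pooled_cov), error = function(e) NULL)
  if (is.null(inv)) {
    if (!pseudo_inverse) {
      stop("pooled covariance is singular; set pseudo_inverse = TRUE")
    }
    warning("singular pooled covariance: using Moore-Penrose pseudo-inverse")
    inv <- .pinv(pooled_cov)
  }
  # D2(i,j) = q_i + q_j - 2 x_i' S^-1 x_j with q_i = x_i' S^-1 x_i
  xs <- means %*% inv
  q <- rowSums(xs * means)
  D <- outer(q, q, `+`) - 2 * xs %*% t(means)
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(rownames(means), rownames(means))
  structure(D, metric = "mahalanobis_D2", class = c("distance_matrix",
                                                    "matrix"))
}

.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Standardized Euclidean distances (means-only fallback)
#'
#' Squared Euclidean distance after scaling each trait to unit variance
#' across genotypes — the downgrade used when replicate-level residuals
#' (hence a pooled covariance) are unavailable.
#'
#' @param means Genotype x trait matrix.
#' @return A `distance_matrix` with metric `"standardized_euclidean"`.
#' @export
standardized_euclidean_d2 <- function(means) {
  z <- scale(as.matrix(means))
  D <- as.matrix(stats::dist(z))^2
  structure(D, metric = "standardized_euclidean",
            class = c("distance_matrix", "matrix"))
}

#' Group genotypes by divergence
#'
#' Tocher's method (default) or agglomerative hierarchical clustering on a
#' distance matrix.
#'
#' Tocher's procedure: the admission threshold is the largest of the
#' row-wise minimum distances. The first cluster is seeded with the
#' closest pair; genotypes are admitted one at a time — always the one
#' giving the smallest new average within-cluster distance, ties broken by
#' input order — while that average stays at or below the threshold. The
#' cluster is then closed and the procedure repeats on the remainder, so
#' the result is deterministic.
#'
#' @param D A `distance_matrix` (D-squared or any dissimilarity).
#' @param method `"tocher"` (default), `"ward"` or `"average"`.
#' @param k Number of clusters for the hierarchical methods (ignored by
#'   Tocher, whose cluster count is data-driven).
#' @return Object of class `cluster_solution`: list with `assignments`
#'   (named integer vector), `n_clusters`, `method`, and for hierarchical
#'   methods the `hclust` object.
#' @export
cluster_genotypes <- function(D, method = c("tocher", "ward", "average"),
                              k = NULL) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (method == "tocher") {
    assignments <- .tocher(D)
    hc <- NULL
  } else {
    if (is.null(k)) stop("k is required for hierarchical clustering")
    if (k > n) stop("k cannot exceed the number of genotypes")
    hc <- stats::hclust(stats::as.dist(D),
                        method = if (method == "ward") "ward.D2"
                                 else "average")
    assignments <- stats::cutree(hc, k = k)
  }
  names(assignments) <- labels
  structure(list(assignments = assignments,
                 n_clusters = max(assignments),
                 method = method, hclust = hc),
            class = "cluster_solution")
}

.tocher <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(1L)
  offdiag <- D + diag(Inf, n)
  threshold <- max(apply(offdiag, 1L, min))
  remaining <- seq_len(n)
  assignment <- integer(n)
  cl <- 0L
  while (length(remaining)) {
    cl <- cl + 1L
    if (length(remaining) == 1L) {
      assignment[remaining] <- cl
      break
    }
    sub <- offdiag[remaining, remaining, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]   # earliest pair
    members <- remaining[sort(ij)]
    cand <- setdiff(remaining, members)
    repeat {
      if (!length(cand)) break
      avg_new <- vapply(cand, function(cdt) {
        mem2 <- c(members, cdt)
        sum(D[mem2, mem2]) / (length(mem2) * (length(mem2) - 1L))
      }, numeric(1L))
      best <- which.min(avg_new)                         # ties: input order
      if (avg_new[best] > threshold) break
      members <- c(members, cand[best])
      cand <- cand[-best]
    }
    assignment[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  assignment
}

#' Intra/inter-cluster distances, cluster means and membership shares
#'
#' `intra(c)` is the mean pairwise distance within cluster `c` (0 for
#' singletons); `inter(c1, c2)` is the mean over all cross-pairs. Cluster
#' trait means are unweighted means of member genotype means; membership
#' percentages are `100 |c| / n`. When the distance matrix holds squared
#' distances, `scale = "sqrt"` reports distances on the D (not D-squared)
#' scale, the conventional presentation for divergence summary tables.
#'
#' @param sol A [cluster_genotypes()] solution.
#' @param D The `distance_matrix` the solution was built from.
#' @param means Optional genotype x trait matrix for cluster means.
#' @param scale `"as_is"` or `"sqrt"`.
#' @return List with `distance` (n_clusters x n_clusters matrix, intra on
#'   the diagonal), `membership` (data frame: cluster, n, percent,
#'   genotypes), and `cluster_means` (or `NULL`).
#' @export
cluster_summary <- function(sol, D, means = NULL,
                            scale = c("as_is", "sqrt")) {
  scale <- match.arg(scale)
  D <- as.matrix(D)
  asg <- sol$assignments
  if (!identical(sort(names(asg)), sort(rownames(D)))) {
    stop("solution labels do not match the distance matrix")
  }
  D <- D[names(asg), names(asg)]
  if (scale == "sqrt") D <- sqrt(D)
  ks <- sort(unique(asg))
  nc <- length(ks)
  dm <- matrix(NA_real_, nc, nc,
               dimnames = list(paste0("C", ks), paste0("C", ks)))
  for (a in seq_len(nc)) {
    ia <- which(asg == ks[a])
    dm[a, a] <- if (length(ia) < 2L) 0 else {
      sum(D[ia, ia]) / (length(ia) * (length(ia) - 1L))
    }
    for (b in seq_len(nc)) {
      if (b >= a) next
      ib <- which(asg == ks[b])
      dm[a, b] <- dm[b, a] <- mean(D[ia, ib])
    }
  }
  membership <- data.frame(
    cluster = paste0("C", ks),
    n = as.integer(table(asg)[as.character(ks)]),
    stringsAsFactors = FALSE)
  membership$percent <- 100 * membership$n / length(asg)
  membership$genotypes <- vapply(ks, function(kk) {
    paste(names(asg)[asg == kk], collapse = ", ")
  }, character(1L))
  cm <- NULL
  if (!is.null(means)) {
    means <- as.matrix(means)[names(asg), , drop = FALSE]
    cm <- t(vapply(ks, function(kk) {
      colMeans(means[asg == kk, , drop = FALSE])
    }, numeric(ncol(means))))
    rownames(cm) <- paste0("C", ks)
  }
  list(distance = dm, membership = membership, cluster_means = cm)
}

#' Export a hierarchical clustering as a Newick string
#'
#' @param hc An `hclust` object (e.g. from [cluster_genotypes()] with a
#'   hierarchical method).
#' @param digits Branch-length precision.
#' @return Single Newick string, terminated by `";"`.
#' @export
hclust_newick <- function(hc, digits = 6) {
  stopifnot(inherits(hc, "hclust"))
  # child branch length = parent height - child height (0 for leaves)
  rec <- function(node, parent_height) {
    if (node < 0) {
      lab <- gsub("[ ,();:]", "_", hc$labels[-node])
      sprintf("%s:%.*g", lab, digits, parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%.*g",
              rec(hc$merge[node, 1L], h), rec(hc$merge[node, 2L], h),
              digits, parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);", rec(hc$merge[root, 1L], h), rec(hc$merge[root, 2L], h))
}
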