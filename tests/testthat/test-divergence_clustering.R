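test_that("Mahalanobis D2 has the textbook special cases", {
  means <- matrix(c(1, 1, 2, 5, 1, 1, 3, 7), 4, 2,
                  dimnames = list(paste0("g", 1:4), c("A", "B")))
  D <- mahalanobis_d2(means)                  # identity covariance
  expect_equal(unname(D["g1", "g2"]), 0)      # identical rows
  expect_equal(unname(D["g1", "g3"]), (2 - 1)^2 + (3 - 1)^2)
  expect_equal(diag(D), setNames(rep(0, 4), rownames(means)))
  expect_equal(D, t(D))
})

test_that("D2 matches brute-force matrix arithmetic on a toy problem", {
  means <- matrix(c(2, 4, 1, 7, 3, 5, 8, 2), 4, 2,
                  dimnames = list(paste0("g", 1:4), c("A", "B")))
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2)        # hand-invertible
  D <- mahalanobis_d2(means, S)
  expect_equal(unclass(D), o_d2(means, S), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("D2 is invariant under nonsingular linear trait transforms", {
  set.seed(15)
  means <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("g", 1:5),
                                                      c("A", "B", "C")))
  S <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  D0 <- mahalanobis_d2(means, S)
  for (i in 1:3) {
    A <- matrix(rnorm(9), 3, 3)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(9), 3, 3)
    D1 <- mahalanobis_d2(means %*% A, t(A) %*% S %*% A)
    expect_equal(unclass(D1), unclass(D0), tolerance = 1e-6)
  }
})

test_that("singular covariance needs explicit pseudo-inverse permission", {
  means <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("g", 1:4),
                                                  c("A", "B")))
  S <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(mahalanobis_d2(means, S), "singular")
  expect_warning(D <- mahalanobis_d2(means, S, pseudo_inverse = TRUE),
                 "pseudo-inverse")
  expect_true(all(is.finite(D)))
})

test_that("pooled within covariance matches per-slice residual products", {
  sim <- simulate_met(sim_config(
    data.frame(trait = c("A", "B"), grand_mean = c(10, 20),
               sigma2_g = c(4, 4), sigma2_e = c(2, 3)),
    n_genotypes = 8, n_environments = 2, n_replicates = 3,
    error_correlation = 0.5, seed = 44))
  S <- pooled_within_covariance(sim$table)
  expect_equal(attr(S, "df"), 2 * (8 - 1) * (3 - 1))
  expect_equal(S, t(S), ignore_attr = TRUE)
  # diagonal equals the per-trait pooled error MS
  ms <- mean(sapply(c("E1", "E2"), function(e) {
    an <- fit_rcbd_anova(sim$table, "A", e)
    an$MS[an$source == "Error"]
  }))
  expect_equal(unname(S["A", "A"]), ms, tolerance = 1e-10)
})

test_that("Tocher separates well-separated groups and is deterministic", {
  # two equilateral triangles (all within-group D2 equal) far apart, so
  # the admission threshold equals the within-group distance exactly
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  means <- rbind(tri, sweep(tri, 2, c(100, 0), `+`))
  rownames(means) <- sprintf("g%02d", 1:6)
  D <- mahalanobis_d2(means)
  sol <- cluster_genotypes(D, method = "tocher")
  expect_equal(sol$n_clusters, 2)
  expect_equal(length(unique(sol$assignments[1:3])), 1L)
  expect_equal(length(unique(sol$assignments[4:6])), 1L)
  sol2 <- cluster_genotypes(D, method = "tocher")
  expect_identical(sol$assignments, sol2$assignments)
})

test_that("hierarchical methods recover well-separated Gaussian blobs", {
  set.seed(9)
  blob1 <- matrix(rnorm(10 * 2, 0, 0.5), 10, 2)
  blob2 <- matrix(rnorm(8 * 2, 20, 0.5), 8, 2)
  means <- rbind(blob1, blob2)
  rownames(means) <- sprintf("g%02d", 1:18)
  D <- mahalanobis_d2(means)
  for (method in c("ward", "average")) {
    sol <- cluster_genotypes(D, method = method, k = 2)
    expect_equal(length(unique(sol$assignments[1:10])), 1L)
    expect_equal(length(unique(sol$assignments[11:18])), 1L)
  }
})

test_that("degenerate k choices behave as documented", {
  set.seed(2)
  means <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6), NULL))
  D <- mahalanobis_d2(means)
  all_single <- cluster_genotypes(D, method = "average", k = 6)
  expect_equal(all_single$n_clusters, 6)
  s <- cluster_summary(all_single, D)
  expect_true(all(diag(s$distance) == 0))

  one <- cluster_genotypes(D, method = "ward", k = 1)
  s1 <- cluster_summary(one, D)
  expect_equal(dim(s1$distance), c(1L, 1L))
  expect_error(cluster_genotypes(D, method = "ward", k = 7), "exceed")
  expect_error(cluster_genotypes(D, method = "ward"), "k is required")
})

test_that("cluster summaries match pair-enumeration oracles", {
  set.seed(21)
  means <- matrix(rnorm(10, 0, 3), 5, 2,
                  dimnames = list(paste0("g", 1:5), c("A", "B")))
  D <- mahalanobis_d2(means)
  sol <- structure(list(assignments = setNames(c(1L, 1L, 1L, 2L, 2L),
                                               rownames(means)),
                        n_clusters = 2L, method = "manual", hclust = NULL),
                   class = "cluster_solution")
  s <- cluster_summary(sol, D, means)
  expect_equal(s$distance["C1", "C1"], o_intra(D, 1:3), tolerance = 1e-10)
  expect_equal(s$distance["C2", "C2"], o_intra(D, 4:5), tolerance = 1e-10)
  expect_equal(s$distance["C1", "C2"], o_inter(D, 1:3, 4:5),
               tolerance = 1e-10)
  expect_equal(s$distance["C1", "C2"], s$distance["C2", "C1"])
  expect_true(all(s$distance >= 0))
  expect_equal(sum(s$membership$percent), 100)
  expect_equal(unname(s$cluster_means["C1", "A"]), mean(means[1:3, "A"]))
  # sqrt scale reports D, not D2
  s_sqrt <- cluster_summary(sol, D, scale = "sqrt")
  expect_equal(s_sqrt$distance["C1", "C2"],
               mean(sqrt(D[1:3, 4:5])), tolerance = 1e-10)
})

test_that("membership percentages mirror a 25-of-53 cluster", {
  asg <- setNames(rep(c(1L, 2L), c(25L, 28L)), sprintf("g%02d", 1:53))
  D <- matrix(1, 53, 53, dimnames = list(names(asg), names(asg)))
  diag(D) <- 0
  sol <- structure(list(assignments = asg, n_clusters = 2L,
                        method = "manual", hclust = NULL),
                   class = "cluster_solution")
  s <- cluster_summary(sol, D)
  expect_equal(s$membership$percent[1], 100 * 25 / 53, tolerance = 1e-10)
  expect_equal(round(s$membership$percent[1], 2), 47.17)
})

test_that("hierarchical solutions export valid Newick", {
  set.seed(5)
  means <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("g", 1:8), NULL))
  D <- mahalanobis_d2(means)
  sol <- cluster_genotypes(D, method = "average", k = 3)
  nwk <- hclust_newick(sol$hclust, digits = 12)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("\\(", nwk))),
               lengths(regmatches(nwk, gregexpr("\\)", nwk))))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, paste0("g", 1:8))
  # leaf depths equal the root height (ultrametric dendrogram)
  depths <- ape::node.depth.edgelength(tree)[seq_len(8)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-6)
})
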