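test_that("noiseless contrast and constant data give the textbook SS", {
  m <- matrix(c(1, 3, 1, 3), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  an <- fit_rcbd_anova(matrix_table(m), "PH", "e1")
  expect_equal(an$SS[an$source == "Genotype"], 4)
  expect_equal(an$SS[an$source == "Error"], 0)
  expect_equal(an$SS[an$source == "Replication"], 0)

  const <- matrix(5, 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  an2 <- fit_rcbd_anova(matrix_table(const), "PH", "e1")
  expect_true(all(an2$SS == 0))
})

test_that("RCBD decomposition matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(18, 20, 4), 6, 3,
                dimnames = list(paste0("g", 1:6), NULL))
    an <- fit_rcbd_anova(matrix_table(m), "PH", "e1")
    o <- o_rcbd_ss(m)
    expect_equal(an$SS, c(o$rep, o$gen, o$err), tolerance = 1e-10)
    # additivity invariants
    expect_equal(sum(an$SS), attr(an, "total_SS"), tolerance = 1e-12)
    expect_equal(sum(an$df), attr(an, "total_df"))
    expect_equal(an$MS, an$SS / an$df)
  }
})

test_that("degenerate designs are rejected", {
  tt <- toy_table(G = 3, R = 2, seed = 1)
  expect_error(fit_rcbd_anova(tt, "PH", "nope"), "no records")
  one_rep <- toy_table(G = 3, R = 1, seed = 1)
  expect_error(fit_rcbd_anova(one_rep, "PH", "e1"), ">= 2 replicates")
})

test_that("moment estimators invert the expected mean squares", {
  an <- data.frame(source = c("Genotype", "Error"), df = c(52, 52),
                   SS = c(622.85 * 52, 72.67 * 52),
                   MS = c(622.85, 72.67), F = NA, p = NA)
  vc <- variance_components(an, r = 2, grand_mean = 86.94)
  expect_equal(vc$sigma2_g, 275.09)
  expect_equal(vc$sigma2_p, vc$sigma2_g + vc$sigma2_e)
  expect_false(vc$truncated)

  an$MS[1] <- 72.67   # MS_gen == MS_err
  vc0 <- variance_components(an, r = 2, grand_mean = 86.94)
  expect_equal(vc0$sigma2_g, 0)

  an$MS[1] <- 10      # negative moment estimate
  vcn <- variance_components(an, r = 2, grand_mean = 86.94)
  expect_equal(vcn$sigma2_g, 0)
  expect_true(vcn$truncated)
  expect_error(variance_components(an, r = 1, grand_mean = 86.94),
               "r must be >= 2")
})

test_that("precision statistics reproduce the reference season rows", {
  vc <- structure(list(sigma2_e = 72.67, sigma2_g = 275.09,
                       sigma2_p = 347.76, r = 2, df_error = 52,
                       grand_mean = 86.94, truncated = FALSE),
                  class = "variance_components")
  ps <- precision_stats(vc)
  expect_equal(ps$SE, 6.03, tolerance = 0.005 / 6.03)
  expect_equal(ps$CV_percent, 9.81, tolerance = 0.005 / 9.81)
  expect_equal(unname(ps$CD[1]), 17.11, tolerance = 0.005 / 17.11)
  expect_equal(unname(ps$CD[2]), 22.79, tolerance = 0.005 / 22.79)

  vc2 <- structure(list(sigma2_e = 28.14, sigma2_g = 39.15,
                        sigma2_p = 67.29, r = 2, df_error = 52,
                        grand_mean = 100.24, truncated = FALSE),
                   class = "variance_components")
  expect_equal(precision_stats(vc2)$CV_percent, 5.29,
               tolerance = 0.005 / 5.29)

  vc0 <- structure(list(sigma2_e = 0, sigma2_g = 10, sigma2_p = 10, r = 2,
                        df_error = 52, grand_mean = 5, truncated = FALSE),
                   class = "variance_components")
  ps0 <- precision_stats(vc0)
  expect_equal(ps0$SE, 0)
  expect_equal(ps0$CV_percent, 0)
  expect_true(all(ps0$CD == 0))
  vc0$grand_mean <- 0
  expect_error(precision_stats(vc0), "grand mean")
})

test_that("CD(1%) strictly exceeds CD(5%) whenever error variance > 0", {
  set.seed(3)
  for (i in 1:10) {
    vc <- structure(list(sigma2_e = runif(1, 0.1, 100), sigma2_g = 1,
                         sigma2_p = 1, r = sample(2:4, 1),
                         df_error = sample(5:60, 1), grand_mean = 10,
                         truncated = FALSE),
                    class = "variance_components")
    cd <- precision_stats(vc)$CD
    expect_gt(cd[2], cd[1])
  }
})

test_that("combined G x Y decomposition matches the oracle", {
  set.seed(19)
  a <- array(rnorm(4 * 2 * 2, 10, 3), c(4, 2, 2))
  df <- expand.grid(g = 1:4, r = 1:2, e = 1:2, KEEP.OUT.ATTRS = FALSE)
  tt <- trait_table(data.frame(genotype = paste0("g", df$g),
                               environment = paste0("e", df$e),
                               replicate = df$r, trait = "FY",
                               value = a[cbind(df$g, df$r, df$e)]))
  an <- combined_gxy_anova(tt, "FY")
  o <- o_combined_ss(a)
  expect_equal(an$SS, c(o$rep, o$gen, o$year, o$gy, o$res),
               tolerance = 1e-10)
  expect_equal(sum(an$SS), attr(an, "total_SS"), tolerance = 1e-12)
  expect_equal(sum(an$df), attr(an, "total_df"))
  expect_equal(an$pct_total_SS, 100 * an$SS / sum(an$SS))
  expect_error(combined_gxy_anova(toy_table(G = 3, Y = 1, R = 2, seed = 2),
                                  "PH"), ">= 2 environments")
})

test_that("combined ANOVA df layout nests replication within year", {
  sim <- simulate_met(sim_config(
    data.frame(trait = "FY", grand_mean = 20, sigma2_g = 50,
               sigma2_e = 2, sigma2_y = 30, sigma2_gy = 40),
    n_genotypes = 53, n_environments = 3, n_replicates = 2, seed = 8))
  an <- combined_gxy_anova(sim$table, "FY")
  expect_equal(an$df, c(3, 52, 2, 104, 156))
  expect_equal(attr(an, "total_df"), 317)
})

test_that("null year and interaction give F near 1 on average", {
  set.seed(55)
  fs <- replicate(60, {
    sim <- simulate_met(sim_config(
      data.frame(trait = "A", grand_mean = 10, sigma2_g = 4,
                 sigma2_e = 1, sigma2_y = 0, sigma2_gy = 0),
      n_genotypes = 12, n_environments = 3, n_replicates = 2,
      seed = sample.int(1e6, 1)))
    an <- combined_gxy_anova(sim$table, "A")
    c(an$F[an$source == "Year"], an$F[an$source == "Genotype x Year"])
  })
  # E[F] = df2/(df2-2) ~= 1.03; loose MC band
  expect_lt(abs(mean(fs[1, ]) - 1), 0.35)
  expect_lt(abs(mean(fs[2, ]) - 1), 0.15)
})

test_that("genotype denominator is switchable to the interaction MS", {
  sim <- simulate_met(sim_config(
    data.frame(trait = "A", grand_mean = 10, sigma2_g = 4, sigma2_e = 1,
               sigma2_y = 1, sigma2_gy = 2),
    n_genotypes = 10, n_environments = 3, n_replicates = 2, seed = 14))
  res <- combined_gxy_anova(sim$table, "A")
  int <- combined_gxy_anova(sim$table, "A",
                            genotype_denominator = "interaction")
  ms <- res$MS
  expect_equal(res$F[2], ms[2] / ms[5])
  expect_equal(int$F[2], ms[2] / ms[4])
})
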