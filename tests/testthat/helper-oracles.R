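# Brute-force definitional oracles, kept independent of the package's
# computational paths: plain loops over the textbook sums.

# RCBD sums of squares from a genotype x replicate matrix
o_rcbd_ss <- function(m) {
  G <- nrow(m); R <- ncol(m)
  grand <- mean(m)
  ss_gen <- 0
  for (i in seq_len(G)) ss_gen <- ss_gen + R * (mean(m[i, ]) - grand)^2
  ss_rep <- 0
  for (k in seq_len(R)) ss_rep <- ss_rep + G * (mean(m[, k]) - grand)^2
  ss_err <- 0
  for (i in seq_len(G)) for (k in seq_len(R)) {
    ss_err <- ss_err + (m[i, k] - mean(m[i, ]) - mean(m[, k]) + grand)^2
  }
  list(rep = as.numeric(ss_rep), gen = as.numeric(ss_gen),
       err = as.numeric(ss_err), total = sum((m - grand)^2))
}

# combined G x Y ANOVA sums of squares from a genotype x rep x year array
o_combined_ss <- function(a) {
  G <- dim(a)[1L]; R <- dim(a)[2L]; Y <- dim(a)[3L]
  grand <- mean(a)
  ss_gen <- ss_year <- ss_rep <- ss_gy <- 0
  for (i in seq_len(G)) ss_gen <- ss_gen + Y * R * (mean(a[i, , ]) - grand)^2
  for (j in seq_len(Y)) ss_year <- ss_year + G * R * (mean(a[, , j]) - grand)^2
  for (j in seq_len(Y)) for (k in seq_len(R)) {
    ss_rep <- ss_rep + G * (mean(a[, k, j]) - mean(a[, , j]))^2
  }
  for (i in seq_len(G)) for (j in seq_len(Y)) {
    ss_gy <- ss_gy + R * (mean(a[i, , j]) - mean(a[i, , ]) -
                            mean(a[, , j]) + grand)^2
  }
  total <- sum((a - grand)^2)
  list(rep = ss_rep, gen = ss_gen, year = ss_year, gy = ss_gy,
       res = total - ss_rep - ss_gen - ss_year - ss_gy, total = total)
}

# Mahalanobis D2 by explicit per-pair matrix arithmetic
o_d2 <- function(means, S) {
  n <- nrow(means)
  Si <- solve(S)
  D <- matrix(0, n, n, dimnames = list(rownames(means), rownames(means)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- means[i, ] - means[j, ]
    D[i, j] <- drop(t(d) %*% Si %*% d)
  }
  D
}

# OLS via normal equations; returns coefficients and R2 (percent)
o_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  b <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  e <- y - Xd %*% b
  r2 <- 100 * (1 - sum(e^2) / sum((y - mean(y))^2))
  list(b = drop(b), r2 = r2)
}

# descending average-tie ranks by explicit position counting
o_rank_desc <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    higher <- sum(x > x[i])
    ties <- sum(x == x[i])
    out[i] <- mean(seq(higher + 1L, higher + ties))
  }
  out
}

# intra/inter cluster mean distances by pair enumeration
o_intra <- function(D, members) {
  if (length(members) < 2L) return(0)
  tot <- 0; np <- 0L
  for (i in members) for (j in members) {
    if (i != j) { tot <- tot + D[i, j]; np <- np + 1L }
  }
  tot / np
}
o_inter <- function(D, m1, m2) {
  tot <- 0; np <- 0L
  for (i in m1) for (j in m2) { tot <- tot + D[i, j]; np <- np + 1L }
  tot / np
}
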