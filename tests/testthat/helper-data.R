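# Small balanced tables built in code for unit tests.

# fully crossed table with values supplied (or drawn) per record
toy_table <- function(G = 3, Y = 1, R = 2, trait_names = "PH",
                      values = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- expand.grid(genotype = sprintf("g%02d", seq_len(G)),
                    environment = sprintf("e%d", seq_len(Y)),
                    replicate = seq_len(R),
                    trait = trait_names,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$value <- if (is.null(values)) stats::rnorm(nrow(df), 10, 2) else values
  trait_table(df)
}

# table with prescribed genotype x replicate matrix for one trait/env
matrix_table <- function(m, trait = "PH", env = "e1") {
  df <- expand.grid(genotype = rownames(m), replicate = seq_len(ncol(m)),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$environment <- env
  df$trait <- trait
  df$value <- m[cbind(match(df$genotype, rownames(m)), df$replicate)]
  trait_table(df[c("genotype", "environment", "replicate", "trait",
                   "value")])
}

# table whose genotype means per trait are exact (replicates identical)
means_table <- function(means, Y = 1, R = 2) {
  trait_names <- colnames(means)
  recs <- list()
  for (tr in trait_names) {
    df <- expand.grid(genotype = rownames(means),
                      environment = sprintf("e%d", seq_len(Y)),
                      replicate = seq_len(R),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    df$trait <- tr
    df$value <- means[df$genotype, tr]
    recs[[tr]] <- df
  }
  trait_table(do.call(rbind, recs)[c("genotype", "environment",
                                     "replicate", "trait", "value")])
}
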