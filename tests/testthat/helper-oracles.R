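# Independent oracles and small fixture builders shared across tests.

# Brute-force weighted running-sum enrichment score: explicit walk down the
# ranked list, independent of the package's vectorized implementation.
es_bruteforce <- function(scores, set, weight = 1) {
  ord <- order(-scores, names(scores), method = "radix")
  s <- scores[ord]
  inset <- names(s) %in% set
  nr <- sum(abs(s[inset])^weight)
  n_miss <- sum(!inset)
  run <- 0
  best <- 0
  best_i <- NA_integer_
  for (i in seq_along(s)) {
    run <- if (inset[i]) run + abs(s[i])^weight / nr else run - 1 / n_miss
    if (abs(run) > abs(best)) {
      best <- run
      best_i <- i
    }
  }
  list(ES = unname(best), cutoff = best_i)
}

# Closed-form saturated two-factor fit on the 2x2 log2 table via lm():
# species and environment indicators with treatment coding.
loglinear_fit <- function(hm, hr, dm, dr) {
  df <- data.frame(
    y = log2(c(hm, hr, dm, dr)),
    s = c(0, 1, 0, 1),  # rat genotype
    e = c(0, 1, 1, 0)   # rat-like environment
  )
  b <- coef(lm(y ~ s * e, data = df))
  list(I = unname(b["s"] + b["s:e"] / 2),
       E = unname(b["e"] + b["s:e"] / 2),
       N = unname(b["s:e"] / 2))
}

# Random positive quartet table
random_quartets <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("q%05d", seq_len(n)),
             HM = 2^rnorm(n, 4, 2), HR = 2^rnorm(n, 4, 2),
             DM = 2^rnorm(n, 4, 2), DR = 2^rnorm(n, 4, 2))
}

# Random pseudobulk table with given depth imbalance across combinations.
# Scales mimic filtered pseudobulk columns (hundreds of cells summed per
# combination); the standard <10-counts-in-all-combinations floor is
# applied as in the pipeline.
random_combo_table <- function(n_genes = 2000, depth_factors = c(1, 2, 5, 10),
                               mean_count = 150, size = 1, seed = 1) {
  set.seed(seed)
  base <- rgamma(n_genes, shape = 2, rate = 2 / mean_count)
  m <- vapply(depth_factors, function(f)
    rnbinom(n_genes, mu = base * f, size = size), numeric(n_genes))
  colnames(m) <- c("HM", "HR", "DM", "DR")
  rownames(m) <- sprintf("g%05d", seq_len(n_genes))
  combo_counts(m[apply(m >= 10, 1, any), , drop = FALSE])
}

expect_negated <- function(a, b, cols) {
  for (cl in cols) expect_equal(a[[cl]], -b[[cl]], tolerance = 1e-12)
}
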