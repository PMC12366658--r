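test_that("unweighted ES for a set equal to the top of the list peaks at k", {
  scores <- setNames(seq(10, 1), letters[1:10])
  res <- preranked_enrichment(scores, list(top = letters[1:3]),
                              n_perm = 50, min_size = 1, weight = 0)
  expect_equal(res$leading_edge_cutoff_rank, 3)
  expect_equal(res$ES, 1)   # all hits before any miss: peak 3/3 - 0/7
})

test_that("running-sum ES matches the brute-force oracle on small lists", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    scores <- setNames(rnorm(n, 0, 2), paste0("g", sample(100, n)))
    set <- sample(names(scores), sample(2:4, 1))
    for (w in c(0, 1)) {
      res <- preranked_enrichment(scores, list(s = set), n_perm = 10,
                                  min_size = 1, weight = w)
      oracle <- es_bruteforce(scores, set, weight = w)
      expect_equal(res$ES, oracle$ES)
      expect_equal(res$leading_edge_cutoff_rank, oracle$cutoff)
    }
  }
})

test_that("ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  scores <- setNames(sort(rnorm(50, 0, 2), decreasing = TRUE),
                     sprintf("g%02d", 1:50))
  for (k in c(5, 10, 20)) {
    set <- sample(names(scores), k)
    res <- preranked_enrichment(scores, list(s = set), n_perm = 10,
                                min_size = 1)
    ref <- fgsea::calcGseaStat(scores, which(names(scores) %in% set),
                               gseaParam = 1)
    expect_equal(res$ES, ref, tolerance = 1e-9)
  }
})

test_that("permutation p-values are uniform under the null", {
  set.seed(29)
  scores <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  p <- vapply(1:200, function(i) {
    set <- sample(names(scores), 20)
    preranked_enrichment(scores, list(s = set), n_perm = 200,
                         seed = i, min_size = 1)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted extrinsic gene set is detected at low FDR", {
  # decomposition-style scores: signed extrinsic proportion with a planted
  # positive-E subset
  set.seed(35)
  n <- 600
  genes <- sprintf("g%03d", 1:n)
  scores <- rnorm(n, 0, 0.2)
  planted <- genes[1:40]
  scores[1:40] <- scores[1:40] + 0.8
  names(scores) <- genes
  res <- preranked_enrichment(scores, list(planted = planted,
                                           random = genes[300:340]),
                              n_perm = 500)
  expect_lt(res$FDR[res$set_name == "planted"], 0.05)
  expect_gt(res$ES[res$set_name == "planted"], 0)
  expect_gt(res$p[res$set_name == "random"], 0.05)
})

test_that("symmetric rank transform mirrors ranks around the midpoint", {
  # the canonical 5,000-gene case
  vals <- setNames(seq(5000, 1) / 100, sprintf("g%04d", 1:5000))
  tr <- symmetric_rank_transform(vals)
  expect_equal(unname(tr[1]), 2500)
  expect_equal(unname(tr[2]), 2499)
  expect_equal(unname(tr[5000]), -2500)
  expect_equal(sum(tr), 0)
  # four distinct values: (2, 1, -1, -2), zero skipped
  tr4 <- symmetric_rank_transform(c(a = 4, b = 3, c = 2, d = 1))
  expect_equal(unname(tr4), c(2, 1, -1, -2))
  # odd length: lowest = -ceiling(n/2), value 0 never used
  tr5 <- symmetric_rank_transform(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  expect_equal(unname(tr5), c(3, 2, 1, -2, -3))
  # odd function of rank position around the midpoint (even lists mirror
  # exactly; odd lists share the +/- pivot at the center)
  expect_equal(unname(tr4 + rev(tr4)), rep(0, 4))
  expect_equal(unname(tr5 + rev(tr5))[-3], rep(0, 4))
  # deterministic lexicographic tie-break
  tied <- c(z = 1, a = 1, m = 1, b = 1)
  expect_equal(names(symmetric_rank_transform(tied)), c("a", "b", "m", "z"))
  expect_error(symmetric_rank_transform(c(a = -1, b = 2)), "nonnegative")
})

test_that("log2 fold-enrichment counts tail members with pseudocounts", {
  n <- 2000
  genes <- sprintf("g%04d", 1:n)
  ranked <- setNames(seq(n, 1), genes)
  # 15 members in the top 500, none in the bottom 500
  set <- genes[seq(10, 150, by = 10)]
  expect_equal(log2_fold_enrichment(ranked, set, 500), 4)
  # absent from both tails
  expect_equal(log2_fold_enrichment(ranked, genes[900:910], 500), 0)
  # symmetric counts cancel
  set2 <- c(genes[1:5], genes[(n - 4):n])
  expect_equal(log2_fold_enrichment(ranked, set2, 500), 0)
  # direction flip swaps the tails
  expect_equal(log2_fold_enrichment(ranked, set, 500, "negative"), -4)
  expect_error(log2_fold_enrichment(ranked, set, 0), "cutoff")
  expect_error(log2_fold_enrichment(ranked, set, 1500), "n/2")
})

test_that("TF-to-target propagation correlation matches cor.test", {
  set.seed(41)
  ct <- sprintf("celltype%02d", 1:10)
  tf <- setNames(rnorm(10), ct)
  expect_equal(tf_propagation_correlation(tf, tf)$rho, 1)
  expect_equal(tf_propagation_correlation(tf, setNames(-tf, ct))$rho, -1)
  target <- setNames(2 * tf + rnorm(10, 0, 0.5), ct)
  res <- tf_propagation_correlation(tf, target)
  ref <- cor.test(tf, target, method = "spearman")
  expect_equal(res$rho, unname(ref$estimate))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$n, 10)
  expect_error(tf_propagation_correlation(tf[1:2], tf[1:2]), "3")
})

test_that("imprinted-style interaction is detected in absolute mode", {
  # decomposition table with a 40-gene high-|N| set among nulls
  set.seed(47)
  n <- 800
  genes <- sprintf("g%03d", 1:n)
  N <- rnorm(n, 0, 0.1)
  N[1:40] <- N[1:40] + sample(c(-1.5, 1.5), 40, TRUE)
  d <- decompose_divergence(data.frame(
    gene_id = genes, HM = 2^(4 + N / 2), HR = 2^(4 + N / 2),
    DM = 2^4, DR = 2^4))
  expect_equal(d$N, N / 2, tolerance = 1e-9)
  res <- imprinted_interaction_test(d, genes[1:40], mode = "absolute",
                                    n_perm = 300)
  expect_lt(res$FDR, 0.05)
  expect_gt(res$ES, 0)
})

test_that("signed mode places mismatch-upregulated sets at the negative end", {
  # genes higher in species-mismatched combinations have negative N under
  # the estimator's matched-positive orientation
  set.seed(53)
  n <- 400
  genes <- sprintf("g%03d", 1:n)
  Nmis <- rnorm(n, 0, 0.2)
  Nmis[1:30] <- Nmis[1:30] + 2      # planted mismatch upregulation
  q <- data.frame(gene_id = genes,
                  HM = 2^4, HR = 2^4,
                  DM = 2^(4 + Nmis), DR = 2^(4 + Nmis))
  d <- decompose_divergence(q, min_abs_lfc = 0.1)
  res <- imprinted_interaction_test(d, genes[1:30], mode = "signed",
                                    n_perm = 300, min_size = 5)
  expect_lt(res$ES, 0)
  expect_lt(res$p, 0.05)
})

test_that("null interaction scores yield no enrichment", {
  set.seed(59)
  n <- 300
  genes <- sprintf("g%03d", 1:n)
  d <- decompose_divergence(data.frame(
    gene_id = genes, HM = 2^rnorm(n, 4, 1), HR = 2^4, DM = 2^4, DR = 2^4),
    min_abs_lfc = 0)
  # N has no planted structure w.r.t. the set
  res <- imprinted_interaction_test(d, sample(genes, 30), mode = "absolute",
                                    n_perm = 300)
  expect_gt(res$p, 0.05)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
  skip_if_not_installed("fgsea")
  expect_equal(fgsea::gmtPathways(path), sets)
})
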