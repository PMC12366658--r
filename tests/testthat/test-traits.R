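test_that("ratio traits decompose like expression quartets", {
  # equal ratios everywhere: no divergence
  d <- ratio_decompose(list(HM = c(200, 100), HR = c(100, 50),
                            DM = c(60, 30), DR = c(40, 20)))
  expect_equal(d$I, 0); expect_equal(d$E, 0); expect_equal(d$N, 0)

  # mouse cells more neuron-rich regardless of environment: pure intrinsic
  d <- ratio_decompose(list(HM = c(400, 100), HR = c(100, 100),
                            DM = c(200, 50), DR = c(30, 30)))
  expect_equal(d$Ip, 1)
  expect_equal(d$I, -2)   # rat-minus-mouse orientation

  # mixed quartet equals decompose on the hand-built ratio table
  counts <- list(HM = c(400, 100), HR = c(120, 100),
                 DM = c(90, 100), DR = c(410, 100))
  d <- ratio_decompose(counts)
  ref <- decompose_divergence(c(HM = 4, HR = 1.2, DM = 0.9, DR = 4.1))
  expect_equal(d$I, ref$I); expect_equal(d$E, ref$E); expect_equal(d$N, ref$N)

  # denominators cancel: proportions and counts give identical results
  prop <- lapply(counts, function(x) x / sum(x))
  expect_equal(ratio_decompose(prop)$I, d$I)

  expect_error(ratio_decompose(list(HM = c(1, 0), HR = c(1, 1),
                                    DM = c(1, 1), DR = c(1, 1))),
               "HM")
})

test_that("tau spans its canonical endpoints and formula", {
  expect_equal(tau(c(5, 0, 0, 0)), 1)
  expect_equal(tau(c(3, 3, 3)), 0)
  expect_equal(tau(c(1, 0.5, 0)), 0.75)
  # scale invariance
  set.seed(61)
  x <- rgamma(8, 2)
  expect_equal(tau(17 * x), tau(x))
  expect_error(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(5), "at least 2")
})

test_that("covariate correlations use Ip - Ep with configurable joins", {
  q <- random_quartets(200, seed = 67)
  d <- decompose_divergence(q, min_abs_lfc = 0.5)
  keep <- d$passed_divergence_filter
  diff <- (d$Ip - d$Ep)[keep]
  cov <- data.frame(gene_id = d$gene_id[keep],
                    self = diff,
                    noise = rnorm(sum(keep)),
                    const = 1)
  res <- predictor_correlations(d, cov)
  expect_equal(res$rho[res$covariate == "self"], 1)
  expect_true(is.na(res$rho[res$covariate == "const"]))
  expect_lt(abs(res$rho[res$covariate == "noise"]), 0.3)

  # per-covariate policy keeps genes missing in other covariates
  cov$noise[1:50] <- NA
  res_pc <- predictor_correlations(d, cov, policy = "per_covariate")
  res_cc <- predictor_correlations(d, cov, policy = "complete")
  expect_gt(res_pc$n[res_pc$covariate == "self"],
            res_cc$n[res_cc$covariate == "self"])
  expect_error(predictor_correlations(d, data.frame(gene_id = "zzz", x = 1)),
               "no genes")
})

test_that("covariates independent of the decomposition give uniform p", {
  set.seed(71)
  q <- random_quartets(150, seed = 73)
  d <- decompose_divergence(q, min_abs_lfc = 0)
  p <- vapply(1:100, function(i) {
    cov <- data.frame(gene_id = d$gene_id, x = rnorm(nrow(d)))
    predictor_correlations(d, cov)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("developmental dynamics classes follow the correlation products", {
  stages <- c(11.5, 13.5, 15.25)
  mouse <- rbind(inc = c(1, 2, 4), opp = c(1, 2, 4), shift = c(1, 2, 4),
                 flat = c(2, 2.1, 2))
  rat <- rbind(inc = c(2, 4, 8), opp = c(4, 2, 1), shift = c(1, 2, 4) * 2^0.1,
               flat = c(1, 2, 4))
  cls <- classify_dynamics(mouse, rat, stages)
  expect_equal(cls$class[cls$gene_id == "inc"], "similar")
  expect_equal(cls$direction[cls$gene_id == "inc"], "increasing")
  expect_equal(cls$class[cls$gene_id == "opp"], "opposite")
  expect_equal(cls$class[cls$gene_id == "shift"], "temporal_shift")
  expect_equal(cls$class[cls$gene_id == "flat"], "unclassified")
  # higher-in flags at |log2FC| > 0.5
  expect_equal(cls$higher_in[cls$gene_id == "inc"], "rat")
  expect_equal(cls$higher_in[cls$gene_id == "shift"], "neither")
  expect_error(classify_dynamics(mouse[, 1:2], rat[, 1:2], stages[1:2]),
               "3 developmental stages")
})

test_that("a mid-range correlation product stays unclassified", {
  stages <- 1:3
  # product of correlations ~0.5: inside (-0.25, 0.7]
  mouse <- matrix(c(1, 2, 4), 1)
  rat <- matrix(c(1, 4, 2), 1)   # r_rat = 0.5 vs stages, r_mouse ~ 0.98
  cls <- classify_dynamics(2^mouse, 2^rat, stages)
  prod <- cls$r_mouse * cls$r_rat
  expect_true(prod <= 0.7 && prod >= -0.25)
  expect_equal(cls$class, "unclassified")
})

test_that("imprinted bulk workflow floors, flags, and clusters", {
  set.seed(79)
  genes <- sprintf("ig%02d", 1:20)
  samples <- sprintf("s%02d", 1:9)
  conditions <- setNames(rep(c("mismatched", "matched", "wildtype"),
                             each = 3), samples)
  base <- matrix(rnorm(180, 6, 0.1), 20, 9,
                 dimnames = list(genes, samples))
  tpm <- 2^base
  # a shared imprinting signature in mismatched samples
  tpm[1:10, conditions == "mismatched"] <-
    tpm[1:10, conditions == "mismatched"] * 8
  # one gene below 5 TPM in every condition
  tpm["ig20", ] <- 2
  res <- imprinted_bulk_workflow(tpm, conditions, gene_set = genes)
  expect_false("ig20" %in% rownames(res$medians))
  expect_true(all(genes[1:10] %in% res$flagged))
  # mismatched samples form one flat cluster
  ord <- res$sample_order
  mism <- which(ord %in% names(conditions)[conditions == "mismatched"])
  expect_equal(max(mism) - min(mism), 2)
  # permutation invariance to input sample order
  perm <- sample(ncol(tpm))
  res2 <- imprinted_bulk_workflow(tpm[, perm], conditions, gene_set = genes)
  expect_equal(sort(res2$flagged), sort(res$flagged))
  expect_error(imprinted_bulk_workflow(tpm, setNames(rep("matched", 9),
                                                     samples)),
               "zero samples|condition")
})

test_that("median fold-change flag uses the stated arithmetic", {
  tpm <- matrix(c(rep(2.4, 2), rep(10, 2), rep(9, 2)), 1,
                dimnames = list("gX", sprintf("s%d", 1:6)))
  conditions <- setNames(rep(c("mismatched", "matched", "wildtype"),
                             each = 2), colnames(tpm))
  res <- imprinted_bulk_workflow(tpm, conditions)
  expect_equal(unname(res$medians["gX", "mismatched"]), 2.4)
  expect_equal(abs(log2(2.4 / 10)) > 1, TRUE)
  expect_equal(res$flagged, "gX")
})

test_that("marker gating and pseudo-TPM helpers follow strict thresholds", {
  tpm <- matrix(c(1, 1, 1,   2, 0, 0,  0, 0, 0), 3,
                dimnames = list(c("NANOG", "SOX2", "POU5F1"),
                                c("c1", "c2", "c3")))
  gate <- marker_gate(tpm, c("NANOG", "SOX2", "POU5F1"))
  expect_equal(unname(gate), c(FALSE, TRUE, FALSE))  # exactly 1 TPM fails
  expect_error(marker_gate(tpm, character(0)), "empty")
  expect_error(marker_gate(tpm, "OCT4"), "absent")

  x <- c(g1 = 3, g2 = 0.2, g3 = 0)
  y <- c(g1 = 1, g2 = 0.5, g3 = 0)
  lfc <- pseudo_tpm_lfc(x, y)
  expect_equal(unname(lfc["g1"]), log2(4 / 2))
  expect_false("g3" %in% names(lfc))  # below 1 TPM in all categories
})

test_that("cpm floors low-count genes and scales to a million", {
  counts <- matrix(c(10, 100, 19, 5), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm(counts, min_counts = 20)
  expect_equal(rownames(out), "g2")
  expect_equal(unname(out["g2", "s1"]), 100 / 110 * 1e6)
  # transcript collapse sums within genes
  tr <- matrix(c(1, 2, 3, 4), 2, 2,
               dimnames = list(c("t1", "t2"), c("s1", "s2")))
  g <- c(t1 = "gA", t2 = "gA")
  expect_equal(unname(collapse_transcripts(tr, g)[1, ]), c(3, 7))
})
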