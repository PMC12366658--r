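#' Build a deterministic ranked gene list
#'
#' Sorts scores in descending order with ties broken by gene id
#' (lexicographic, ascending), so identical inputs always yield the same
#' ordering. Duplicate gene ids are an error.
#'
#' @param scores named numeric vector (names = gene ids).
#' @return named numeric vector sorted for preranked enrichment.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by gene id")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in ranking")
  if (anyNA(scores)) stop("NA scores in ranking")
  scores[order(-scores, names(scores), method = "radix")]
}

# Weighted Kolmogorov-Smirnov running sum on an already-sorted list.
# Returns the enrichment score (value at the extremum of the running sum),
# the rank of the extremum, and optionally the full running sum.
running_sum_es <- function(scores_sorted, in_set, weight = 1,
                           keep_running = FALSE) {
  w <- abs(scores_sorted)^weight
  hit <- ifelse(in_set, w, 0)
  nr <- sum(hit)
  n_miss <- sum(!in_set)
  if (nr == 0 || n_miss == 0)
    return(list(ES = 0, cutoff = NA_integer_, running = NULL))
  run <- cumsum(hit / nr - (!in_set) / n_miss)
  i <- which.max(abs(run))
  list(ES = run[[i]], cutoff = i,
       running = if (keep_running) run else NULL)
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Self-contained preranked enrichment: the weighted Kolmogorov-Smirnov
#' running-sum statistic (enrichment score, ES, the signed extremum of the
#' running sum), a gene-permutation null (`n_perm` random same-size gene
#' sets on the fixed ranking), NES normalization by the mean same-sign null
#' ES, nominal p against the same-sign null, and FDR by the standard
#' positive/negative pooling of null and observed NES. Sets whose overlap
#' with the ranked list falls outside `[min_size, max_size]` are skipped.
#'
#' Defaults mirror the conventional preranked configuration
#' (1000 permutations, seed 6, set sizes 10-300, weight 1).
#'
#' @param ranked named numeric vector of ranking scores (sorted with
#'   [ranked_list()]; unsorted input is sorted automatically).
#' @param sets named list of character vectors (gene sets), e.g. from
#'   [read_gmt()], or a single character vector.
#' @param n_perm number of gene permutations.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked list.
#' @param seed integer seed for the permutation draw.
#' @param weight exponent on |score| in the running sum (0 = classic KS).
#' @return data frame with one row per tested set: `set_name`, `size`,
#'   `ES`, `NES`, `p`, `FDR`, `leading_edge_cutoff_rank`,
#'   `log2_fold_enrichment` (see [log2_fold_enrichment()], computed at
#'   `min(cutoff, floor(n/2))`).
#' @examples
#' sc <- ranked_list(stats::setNames(10:1, letters[1:10]))
#' preranked_enrichment(sc, list(top = c("a", "b", "c")),
#'                      n_perm = 100, min_size = 2)
#' @export
preranked_enrichment <- function(ranked, sets, n_perm = 1000,
                                 min_size = 10, max_size = 300,
                                 seed = 6, weight = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!length(ranked)) stop("empty ranked list")
  if (is.character(sets)) sets <- list(set = sets)
  if (is.null(names(sets))) names(sets) <- sprintf("set%d", seq_along(sets))
  ranked <- ranked_list(ranked)
  genes <- names(ranked)
  n <- length(genes)

  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set overlaps the ranked list within [min_size, max_size]")
  sets <- sets[keep]; sizes <- sizes[keep]

  obs <- lapply(sets, function(s)
    running_sum_es(ranked, genes %in% s, weight))
  es <- vapply(obs, `[[`, numeric(1), "ES")
  cutoff <- vapply(obs, function(o) as.integer(o$cutoff), integer(1))

  # null ES distributions depend only on set size; cache per size
  null_by_size <- new.env(parent = emptyenv())
  withr_seed(seed, {
    for (k in sort(unique(sizes))) {
      key <- as.character(k)
      null_es <- vapply(seq_len(n_perm), function(p) {
        idx <- sample.int(n, k)
        in_set <- logical(n); in_set[idx] <- TRUE
        running_sum_es(ranked, in_set, weight)$ES
      }, numeric(1))
      assign(key, null_es, envir = null_by_size)
    }
  })

  p <- numeric(length(es)); nes <- numeric(length(es))
  null_nes_all <- vector("list", length(es))
  for (i in seq_along(es)) {
    null_es <- get(as.character(sizes[[i]]), envir = null_by_size)
    pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (es[[i]] >= 0) {
      p[[i]] <- (sum(pos >= es[[i]]) + 1) / (length(pos) + 1)
      nes[[i]] <- if (is.na(mean_pos) || mean_pos == 0) 0 else es[[i]] / mean_pos
    } else {
      p[[i]] <- (sum(neg <= es[[i]]) + 1) / (length(neg) + 1)
      nes[[i]] <- if (is.na(mean_neg) || mean_neg == 0) 0 else abs(es[[i]]) / mean_neg * -1
    }
    null_nes <- ifelse(null_es >= 0,
                       if (is.na(mean_pos) || mean_pos == 0) 0 else null_es / mean_pos,
                       if (is.na(mean_neg) || mean_neg == 0) 0 else null_es / mean_neg)
    null_nes_all[[i]] <- null_nes
  }
  pooled_null <- unlist(null_nes_all)
  fdr <- vapply(seq_along(es), function(i) {
    if (nes[[i]] >= 0) {
      num_d <- sum(pooled_null >= 0)
      num <- if (num_d) sum(pooled_null >= nes[[i]]) / num_d else 1
      den_d <- sum(nes >= 0)
      den <- if (den_d) sum(nes >= nes[[i]] & nes >= 0) / den_d else 1
    } else {
      num_d <- sum(pooled_null < 0)
      num <- if (num_d) sum(pooled_null <= nes[[i]]) / num_d else 1
      den_d <- sum(nes < 0)
      den <- if (den_d) sum(nes <= nes[[i]] & nes < 0) / den_d else 1
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))

  lfe <- vapply(seq_along(es), function(i) {
    ct <- min(cutoff[[i]], floor(n / 2))
    if (is.na(ct) || ct < 1) return(NA_real_)
    log2_fold_enrichment(ranked, sets[[i]], ct,
                         direction = if (es[[i]] >= 0) "positive" else "negative")
  }, numeric(1))

  data.frame(set_name = names(sets), size = sizes, ES = es, NES = nes,
             p = p, FDR = fdr, leading_edge_cutoff_rank = cutoff,
             log2_fold_enrichment = lfe,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Symmetric rank transform for unsigned metrics
#'
#' The running-sum statistic was designed for signed metrics; ranking by an
#' absolute (nonnegative) metric can produce spuriously strong
#' enrichments. This transform maps the metric to mirrored ranks: with `n`
#' genes, the gene with the largest value gets `ceiling(n/2)`, the next
#' `ceiling(n/2) - 1`, ..., while the smallest gets `-ceiling(n/2)`, the
#' next smallest `-ceiling(n/2) + 1`, ...; for even `n` the value zero is
#' skipped. With 5,000 genes the top gene maps to 2,500 and the lowest to
#' -2,500. Ties are broken by gene id so the output is deterministic.
#'
#' @param values named nonnegative numeric vector (e.g. absolute
#'   interaction divergence per gene).
#' @return named numeric vector of mirrored ranks, sorted descending
#'   (ready for [preranked_enrichment()]).
#' @export
symmetric_rank_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 genes")
  if (any(values < 0)) stop("symmetric rank transform is for nonnegative metrics")
  sorted <- ranked_list(values)
  n <- length(sorted)
  half <- ceiling(n / 2)
  r <- seq_len(n)
  out <- ifelse(r <= half, half - r + 1, -(half - (n - r + 1) + 1))
  names(out) <- names(sorted)
  out
}

#' Log2 fold-enrichment of a gene set between the two tails of a ranking
#'
#' Counts set members among the top `cutoff_rank` genes (`k_top`) and among
#' the bottom `cutoff_rank` genes (`k_bottom`) and returns
#' `log2((k_top + 1) / (k_bottom + 1))` (reversed for `direction =
#' "negative"`). With 15 set members in the top 500 and 0 in the bottom
#' 500 the statistic is `log2(16/1) = 4`.
#'
#' @param ranked named ranking vector (descending).
#' @param set character vector of gene ids.
#' @param cutoff_rank tail size (must be >= 1 and <= half the list).
#' @param direction `"positive"` (enrichment at the top) or `"negative"`.
#' @return log2 fold-enrichment (a single number).
#' @export
log2_fold_enrichment <- function(ranked, set, cutoff_rank,
                                 direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  genes <- names(ranked_list(ranked))
  n <- length(genes)
  if (cutoff_rank < 1) stop("cutoff_rank must be >= 1")
  if (cutoff_rank > floor(n / 2)) stop("cutoff_rank must be <= n/2")
  k_top <- sum(genes[seq_len(cutoff_rank)] %in% set)
  k_bottom <- sum(genes[seq.int(n - cutoff_rank + 1, n)] %in% set)
  if (direction == "positive") log2((k_top + 1) / (k_bottom + 1))
  else log2((k_bottom + 1) / (k_top + 1))
}

#' Correlation between a regulator's divergence and its targets' enrichment
#'
#' Tests whether (say) extrinsic divergence of a transcription factor
#' propagates to its target genes: Spearman correlation, across cell
#' types, between the TF's signed component and the enrichment score of
#' its target set.
#'
#' @param tf_component named numeric vector (cell type -> TF signed
#'   component).
#' @param target_enrichment named numeric vector (cell type -> target-set
#'   enrichment score).
#' @return list with `rho`, `p` (two-sided) and `n` (shared cell types).
#' @export
tf_propagation_correlation <- function(tf_component, target_enrichment) {
  shared <- intersect(names(tf_component), names(target_enrichment))
  if (length(shared) < 3) stop("need at least 3 shared cell types")
  ct <- suppressWarnings(
    stats::cor.test(tf_component[shared], target_enrichment[shared],
                    method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Test a gene set (e.g. imprinted genes) for interaction divergence
#'
#' Absolute mode asks whether the set carries unusually large interaction
#' magnitudes: genes are ranked by |N| through the symmetric rank
#' transform (see [symmetric_rank_transform()]) and the set is tested with
#' [preranked_enrichment()]. Signed mode ranks by the signed interaction
#' proportion directly, so enrichment at the negative end means higher
#' expression in species-mismatched environments (the estimator orients
#' positive interaction toward matched combinations).
#'
#' @param decomp a `divergence_decomp` table.
#' @param gene_set character vector of gene ids (e.g. imprinted genes).
#' @param mode `"absolute"` or `"signed"`.
#' @param filter_passing_only restrict to traits passing the divergence
#'   filter (signed mode requires it since proportions are NA otherwise).
#' @param ... forwarded to [preranked_enrichment()].
#' @return one-row data frame as returned by [preranked_enrichment()].
#' @export
imprinted_interaction_test <- function(decomp, gene_set,
                                       mode = c("absolute", "signed"),
                                       filter_passing_only = (mode == "signed"),
                                       ...) {
  mode <- match.arg(mode)
  d <- as.data.frame(decomp)
  if (filter_passing_only[1]) d <- d[d$passed_divergence_filter, ]
  if (!length(intersect(d$gene_id, gene_set)))
    stop("gene set does not intersect the decomposition table")
  metric <- if (mode == "absolute") {
    symmetric_rank_transform(stats::setNames(abs(d$N), d$gene_id))
  } else {
    ranked_list(stats::setNames(d$signed_Np, d$gene_id)[!is.na(d$signed_Np)])
  }
  preranked_enrichment(metric, list(gene_set = gene_set), ...)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab
#' separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1))
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
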