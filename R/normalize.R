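#' Direct pseudocounted normalization of a pseudobulk table
#'
#' Each combination column is scaled to counts per `scale` (default 10,000)
#' after adding a pseudocount to every gene:
#' `(count + pseudocount) / column_total * scale`, where `column_total` is
#' the raw (un-pseudocounted) total of the combination.
#'
#' With totals of 1e6 for DM, HM and HR but only 1e5 for DR, a gene with 99
#' counts in DM and HM and 0 in HR and DR normalizes to (1, 1, 0.01, 0.1):
#' the fold-change DM/HR is 100 while DM/DR is 10, even though both rat
#' combinations saw zero counts. This depth artefact motivates the
#' resampled variant ([normalize_resampled()]), which equalizes depth before
#' normalizing.
#'
#' @param table a `combo_counts` object (see [pseudobulk()]) or a gene x
#'   combination matrix with columns `HM`, `HR`, `DM`, `DR`.
#' @param scale target library size after normalization.
#' @param pseudocount added to every count before division.
#' @param totals optional named column totals; defaults to the table's
#'   recorded totals (or column sums for a bare matrix).
#' @return a data frame with columns `gene_id`, `HM`, `HR`, `DM`, `DR` of
#'   normalized values (all strictly positive).
#' @export
normalize_direct <- function(table, scale = 10000, pseudocount = 1,
                             totals = NULL) {
  m <- combo_matrix(table)
  if (is.null(totals)) totals <- combo_totals(table)
  totals <- totals[colnames(m)]
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("all combination totals must be positive")
  norm <- sweep(m + pseudocount, 2, totals / scale, "/")
  data.frame(gene_id = rownames(m), as.data.frame(norm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Equal-depth resampled normalization
#'
#' Sequencing depth routinely differs several-fold between the four
#' species-environment combinations, which biases pseudocounted
#' fold-changes for lowly expressed genes (see [normalize_direct()]). This
#' variant first downsamples every combination's counts, without
#' replacement (multivariate hypergeometric), to the minimum column total,
#' repeats the downsampling `n_reps` times (default 100), averages the
#' resampled counts per gene, and only then applies the pseudocount and
#' per-10,000 scaling. The pseudocount is added after averaging so that the
#' identity case (already-equal totals) reproduces [normalize_direct()]
#' exactly.
#'
#' @inheritParams normalize_direct
#' @param n_reps number of resampling repetitions.
#' @param seed integer seed; the procedure is deterministic given the seed.
#' @return as [normalize_direct()]; additionally carries the resampling
#'   target total as attribute `target_total`.
#' @export
normalize_resampled <- function(table, n_reps = 100, scale = 10000,
                                pseudocount = 1, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- combo_matrix(table)
  totals <- combo_totals(table)[colnames(m)]
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("all combination totals must be positive")
  target <- min(totals)
  extra <- totals - colSums(m)   # counts held by genes dropped upstream
  if (any(extra < -1e-8)) stop("column totals smaller than column sums")

  withr_seed(seed, {
    means <- vapply(colnames(m), function(cmb) {
      # The column may represent only a subset of the library's counts
      # (genes filtered before normalization); the remainder competes in the
      # draw as a single pseudo-gene so expectations stay unbiased.
      counts <- c(m[, cmb], .other = round(extra[[cmb]]))
      draws <- downsample_counts(counts, target, n_reps)
      rowMeans(draws)[seq_len(nrow(m))]
    }, numeric(nrow(m)))
  })
  norm <- (means + pseudocount) / target * scale
  rownames(norm) <- rownames(m)
  out <- data.frame(gene_id = rownames(m), as.data.frame(norm),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "target_total") <- target
  out
}

#' Downsample a count vector to a fixed total without replacement
#'
#' Draws from the multivariate hypergeometric distribution: `target` reads
#' are drawn uniformly without replacement from the pool of reads implied
#' by `counts`. Each replicate column sums exactly to `target`; the
#' expectation of each entry is `counts * target / sum(counts)`.
#' Implemented as sequential conditional [stats::rhyper()] draws, vectorized
#' over replicates.
#'
#' @param counts nonnegative integer vector.
#' @param target total to draw (`<= sum(counts)`).
#' @param n_reps number of independent replicate draws.
#' @return integer matrix, `length(counts)` x `n_reps`.
#' @export
downsample_counts <- function(counts, target, n_reps = 1) {
  total <- sum(counts)
  if (target > total) stop("target exceeds available counts")
  out <- matrix(0L, length(counts), n_reps)
  remaining_target <- rep.int(as.numeric(target), n_reps)
  remaining_total <- total
  for (i in seq_along(counts)) {
    ci <- counts[[i]]
    remaining_total <- remaining_total - ci
    if (ci == 0) next
    x <- stats::rhyper(n_reps, m = ci, n = remaining_total,
                       k = remaining_target)
    out[i, ] <- x
    remaining_target <- remaining_target - x
    if (remaining_total == 0) break
  }
  out
}

#' Per-cell log-normalized counts (convenience)
#'
#' Counts per `scale` followed by `log1p`; the transform commonly used for
#' per-cell visualization. Not used by the decomposition itself.
#'
#' @param counts gene x cell count matrix.
#' @param scale target per-cell total.
#' @return matrix of `log1p`-transformed per-10,000 counts.
#' @export
lognorm_cp10k <- function(counts, scale = 10000) {
  log1p(sweep(as.matrix(counts), 2, colSums(counts) / scale, "/"))
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
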