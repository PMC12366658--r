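#' Decompose divergence in a cell-state ratio trait
#'
#' Applies the quartet decomposition to a count-derived ratio trait, e.g.
#' the ratio of post-mitotic neurons to progenitors, computed in each of
#' the four species-environment combinations. Because the per-combination
#' totals cancel in the ratio, raw cell counts and cell proportions give
#' identical results.
#'
#' @param cell_counts named list (or data frame with row names `HM`, `HR`,
#'   `DM`, `DR`) giving `numerator` and `denominator` counts per
#'   combination, e.g. `list(HM = c(400, 100), ...)` with
#'   (neurons, progenitors).
#' @param trait_name label for the resulting row.
#' @param min_abs_lfc divergence filter threshold.
#' @return a one-row `divergence_decomp` object.
#' @examples
#' ratio_decompose(list(HM = c(400, 100), HR = c(100, 100),
#'                      DM = c(300, 100), DR = c(120, 100)))
#' @export
ratio_decompose <- function(cell_counts, trait_name = "ratio",
                            min_abs_lfc = 0.5) {
  combos <- c("HM", "HR", "DM", "DR")
  if (is.data.frame(cell_counts) || is.matrix(cell_counts))
    cell_counts <- lapply(stats::setNames(combos, combos),
                          function(cmb) as.numeric(cell_counts[cmb, ]))
  if (!all(combos %in% names(cell_counts)))
    stop("cell_counts needs entries HM, HR, DM, DR")
  ratio <- vapply(combos, function(cmb) {
    x <- cell_counts[[cmb]]
    if (x[2] <= 0)
      stop("zero denominator count in combination ", cmb)
    if (x[1] <= 0)
      stop("zero numerator count in combination ", cmb)
    x[1] / x[2]
  }, numeric(1))
  q <- data.frame(gene_id = trait_name, HM = ratio[["HM"]],
                  HR = ratio[["HR"]], DM = ratio[["DM"]],
                  DR = ratio[["DR"]])
  decompose_divergence(q, min_abs_lfc = min_abs_lfc)
}

#' Tau cell-type specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 1 when a gene is expressed in
#' exactly one cell type, 0 when equally expressed in all. Scale
#' invariant.
#'
#' @param x nonnegative expression vector across cell types (length >= 2).
#' @return a number in \[0, 1\].
#' @examples
#' tau(c(5, 0, 0, 0))  # 1
#' tau(c(3, 3, 3))     # 0
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least 2 cell types")
  if (any(x < 0)) stop("tau is defined for nonnegative expression values")
  mx <- max(x)
  if (mx == 0) stop("all-zero expression vector")
  sum(1 - x / mx) / (length(x) - 1)
}

#' Correlate covariates with the intrinsic-minus-extrinsic proportion
#'
#' For each covariate column, the Spearman correlation (two-sided) between
#' the gene-level `Ip - Ep` difference and the covariate, after joining on
#' gene id. `policy = "complete"` keeps only genes with every covariate
#' present (one shared gene universe); `policy = "per_covariate"` drops
#' missing values covariate by covariate.
#'
#' @param decomp a `divergence_decomp` table (filter-passing rows are
#'   used).
#' @param covariates data frame with a `gene_id` column plus numeric
#'   covariate columns.
#' @param policy `"complete"` or `"per_covariate"`.
#' @param min_genes minimum joined genes per covariate.
#' @return data frame with `covariate`, `rho`, `p`, `n`.
#' @export
predictor_correlations <- function(decomp, covariates,
                                   policy = c("complete", "per_covariate"),
                                   min_genes = 10) {
  policy <- match.arg(policy)
  d <- as.data.frame(decomp)
  d <- d[d$passed_divergence_filter & !is.na(d$Ip), ]
  d$ip_minus_ep <- d$Ip - d$Ep
  merged <- merge(d[, c("gene_id", "ip_minus_ep")], covariates,
                  by = "gene_id")
  if (!nrow(merged)) stop("no genes shared between decomposition and covariates")
  cov_cols <- setdiff(colnames(covariates), "gene_id")
  if (policy == "complete")
    merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  out <- lapply(cov_cols, function(cv) {
    sub <- merged[!is.na(merged[[cv]]), c("ip_minus_ep", cv)]
    if (nrow(sub) < min_genes)
      stop("fewer than ", min_genes, " genes for covariate ", cv)
    if (stats::sd(sub[[cv]]) == 0)
      return(data.frame(covariate = cv, rho = NA_real_, p = NA_real_,
                        n = nrow(sub)))
    ct <- suppressWarnings(
      stats::cor.test(sub$ip_minus_ep, sub[[cv]], method = "spearman"))
    data.frame(covariate = cv, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify developmental expression dynamics of each gene
#'
#' Computes, per species, the Pearson correlation between expression and
#' developmental stage (Pearson because three timepoints make rank
#' correlations degenerate). A gene is `similar` if the product of the
#' mouse and rat correlations exceeds `similar_min` (default 0.7),
#' `opposite` if the product is below `opposite_max` (default -0.25), else
#' `unclassified`. `temporal_shift` genes are the subset of similar genes
#' whose absolute cross-species log2 fold-change is below `shift_lfc_max`
#' (default 0.25) at both of the two later stages — trajectories shared
#' between species but offset in developmental time. Direction is
#' `increasing`/`decreasing` when both correlations share that sign.
#' Genes are additionally flagged `higher_in_mouse` / `higher_in_rat` when
#' the mean cross-species log2 fold-change exceeds `higher_lfc_min` in
#' magnitude.
#'
#' @param mouse,rat gene x stage expression matrices (>= 3 stages, linear
#'   scale).
#' @param stages numeric developmental stages.
#' @param similar_min,opposite_max thresholds on the correlation product.
#' @param shift_lfc_max cross-species |log2FC| bound at the two later
#'   stages for a temporal shift.
#' @param higher_lfc_min |log2FC| threshold for the higher-in-species
#'   flags.
#' @return data frame with `gene_id`, `r_mouse`, `r_rat`, `class`,
#'   `temporal_shift`, `direction`, `higher_in`.
#' @export
classify_dynamics <- function(mouse, rat, stages,
                              similar_min = 0.7, opposite_max = -0.25,
                              shift_lfc_max = 0.25, higher_lfc_min = 0.5) {
  mouse <- as.matrix(mouse); rat <- as.matrix(rat)
  if (length(stages) < 3) stop("at least 3 developmental stages required")
  stopifnot(ncol(mouse) == length(stages), ncol(rat) == length(stages),
            nrow(mouse) == nrow(rat))
  lm2 <- log2(mouse); lr2 <- log2(rat)
  r_mouse <- apply(lm2, 1, function(v)
    if (stats::sd(v) == 0) 0 else stats::cor(v, stages))
  r_rat <- apply(lr2, 1, function(v)
    if (stats::sd(v) == 0) 0 else stats::cor(v, stages))
  prod_r <- r_mouse * r_rat
  cls <- ifelse(prod_r > similar_min, "similar",
                ifelse(prod_r < opposite_max, "opposite", "unclassified"))
  later <- utils::tail(seq_along(stages), 2)
  lfc_later <- lm2[, later, drop = FALSE] - lr2[, later, drop = FALSE]
  shift <- cls == "similar" & apply(abs(lfc_later) < shift_lfc_max, 1, all)
  cls[shift] <- "temporal_shift"
  direction <- ifelse(cls %in% c("similar", "temporal_shift") &
                        r_mouse > 0 & r_rat > 0, "increasing",
                      ifelse(cls %in% c("similar", "temporal_shift") &
                               r_mouse < 0 & r_rat < 0, "decreasing",
                             "none"))
  mean_lfc <- rowMeans(lm2 - lr2)
  higher_in <- ifelse(mean_lfc > higher_lfc_min, "mouse",
                      ifelse(mean_lfc < -higher_lfc_min, "rat", "neither"))
  gene_id <- rownames(mouse)
  if (is.null(gene_id)) gene_id <- sprintf("g%04d", seq_len(nrow(mouse)))
  data.frame(gene_id = gene_id, r_mouse = r_mouse, r_rat = r_rat,
             class = cls, temporal_shift = shift, direction = direction,
             higher_in = higher_in, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bulk imprinted-gene misexpression workflow
#'
#' For a bulk TPM table with samples in species-mismatched,
#' species-matched and wildtype conditions: per-condition median TPM per
#' gene, removal of genes below `min_median_tpm` in all conditions,
#' restriction to a gene set (e.g. imprinted genes), per-gene
#' standardization, hierarchical clustering of the samples (Euclidean
#' distance, `linkage` linkage), and flagging of genes with
#' `|log2(mismatched/matched)| > lfc_flag_min` on the raw condition
#' medians.
#'
#' @param tpm gene x sample TPM matrix.
#' @param conditions named vector mapping sample -> condition, levels
#'   `mismatched`, `matched`, `wildtype`.
#' @param gene_set optional restriction (e.g. imprinted genes); `NULL`
#'   keeps all genes passing the TPM floor.
#' @param min_median_tpm expression floor (gene dropped if below it in
#'   every condition).
#' @param lfc_flag_min |log2FC| threshold for flagging.
#' @param linkage hclust agglomeration method.
#' @return list with `medians` (gene x condition), `flagged` (gene ids),
#'   `sample_order` (clustering leaf order), `hclust`, and `scaled` (the
#'   standardized matrix used for clustering).
#' @export
imprinted_bulk_workflow <- function(tpm, conditions, gene_set = NULL,
                                    min_median_tpm = 5, lfc_flag_min = 1,
                                    linkage = "average") {
  tpm <- as.matrix(tpm)
  conditions <- conditions[colnames(tpm)]
  if (anyNA(conditions)) stop("every sample needs a condition")
  lev <- union(c("mismatched", "matched"), unique(conditions))
  cnt <- table(factor(conditions, levels = lev))
  if (any(cnt == 0))
    stop("condition with zero samples: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  medians <- vapply(lev, function(cd)
    apply(tpm[, conditions == cd, drop = FALSE], 1, stats::median),
    numeric(nrow(tpm)))
  medians <- matrix(medians, nrow = nrow(tpm),
                    dimnames = list(rownames(tpm), lev))
  keep <- apply(medians >= min_median_tpm, 1, any)
  tpm <- tpm[keep, , drop = FALSE]
  medians <- medians[keep, , drop = FALSE]
  if (!is.null(gene_set)) {
    sel <- rownames(tpm) %in% gene_set
    if (!any(sel)) stop("gene set does not intersect the expressed genes")
    tpm <- tpm[sel, , drop = FALSE]
    medians <- medians[sel, , drop = FALSE]
  }
  scaled <- t(scale(t(tpm)))
  scaled[!is.finite(scaled)] <- 0
  hc <- stats::hclust(stats::dist(t(scaled), method = "euclidean"),
                      method = linkage)
  lfc <- log2(medians[, "mismatched"] / medians[, "matched"])
  flag <- abs(lfc) > lfc_flag_min
  flag[is.na(flag)] <- FALSE
  list(medians = medians,
       flagged = rownames(medians)[flag],
       sample_order = colnames(tpm)[hc$order], hclust = hc,
       scaled = scaled)
}

#' Sum transcript-level TPM to gene level
#'
#' @param tpm transcript x sample matrix.
#' @param transcript_to_gene named vector transcript -> gene id.
#' @return gene x sample matrix of summed TPM.
#' @export
collapse_transcripts <- function(tpm, transcript_to_gene) {
  tpm <- as.matrix(tpm)
  g <- transcript_to_gene[rownames(tpm)]
  if (anyNA(g)) stop("transcripts without gene assignment")
  rowsum(tpm, group = g)
}

#' Marker-based cell gating on TPM
#'
#' TRUE for cells where any marker gene strictly exceeds `min_tpm`
#' (e.g. putative epiblast cells by NANOG/SOX2/POU5F1).
#'
#' @param tpm gene x cell TPM matrix.
#' @param markers marker gene ids (must be present in the table).
#' @param min_tpm gating threshold (strict).
#' @return logical vector per cell.
#' @export
marker_gate <- function(tpm, markers, min_tpm = 1) {
  if (!length(markers)) stop("empty marker list")
  missing <- setdiff(markers, rownames(tpm))
  if (length(missing))
    stop("markers absent from table: ", paste(missing, collapse = ", "))
  apply(tpm[markers, , drop = FALSE] > min_tpm, 2, any)
}

#' Pseudo-TPM log2 fold-changes between two categories
#'
#' Adds one pseudo-TPM to both sides, drops genes below `min_tpm` in all
#' categories, and returns per-gene log2 ratios.
#'
#' @param x,y named numeric vectors of per-gene mean TPM for the two
#'   categories (same genes).
#' @param min_tpm expression floor applied across both categories.
#' @return named vector of log2((x+1)/(y+1)) over retained genes.
#' @export
pseudo_tpm_lfc <- function(x, y, min_tpm = 1) {
  stopifnot(length(x) == length(y))
  keep <- x >= min_tpm | y >= min_tpm
  log2((x[keep] + 1) / (y[keep] + 1))
}

#' Counts per million with an all-sample count floor
#'
#' Removes genes below `min_counts` in every sample, then scales each
#' sample to one million.
#'
#' @param counts gene x sample count matrix.
#' @param min_counts floor applied across all samples.
#' @return CPM matrix over retained genes.
#' @export
cpm <- function(counts, min_counts = 20) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  keep <- apply(counts >= min_counts, 1, any)
  sweep(counts[keep, , drop = FALSE], 2, totals / 1e6, "/")
}
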