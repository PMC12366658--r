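#' Assign a species to each barcode from dual-genome alignment fractions
#'
#' Barnyard-style deconvolution: a barcode is called mouse if at least
#' `threshold` (default 70%) of its aligned reads map to the mouse genome,
#' rat if at least `threshold` map to the rat genome, and a doublet
#' otherwise (doublets are discarded downstream). The boundary is
#' inclusive: a mouse fraction of exactly 0.70 is called mouse.
#'
#' @param counts_mouse,counts_rat total aligned reads per barcode for each
#'   genome (vectors of equal length).
#' @param threshold inclusive fraction required for a species call.
#' @return character vector in `c("mouse", "rat", "doublet")`.
#' @export
assign_species <- function(counts_mouse, counts_rat, threshold = 0.70) {
  stopifnot(length(counts_mouse) == length(counts_rat))
  total <- counts_mouse + counts_rat
  if (any(total <= 0))
    stop("zero aligned reads for barcode(s): ",
         paste(utils::head(which(total <= 0), 5), collapse = ", "))
  frac_mouse <- counts_mouse / total
  ifelse(frac_mouse >= threshold, "mouse",
         ifelse(1 - frac_mouse >= threshold, "rat", "doublet"))
}

#' Quality-control filter on per-cell metrics
#'
#' Removes cells with a mitochondrial read fraction above `mito_max`
#' (default 15%) or with more than `genes_detected_max` genes detected
#' (default 7500, a doublet proxy). Both boundaries keep the cell:
#' rejection requires strictly exceeding the threshold.
#'
#' @param meta data frame with columns `mito_fraction` and
#'   `genes_detected` (and usually `barcode`).
#' @param mito_max maximum tolerated mitochondrial fraction.
#' @param genes_detected_max maximum tolerated number of detected genes.
#' @return list with `retained` (the surviving rows of `meta`), `keep`
#'   (logical index) and `log` (one row per rejected cell with a `reason`
#'   of `"mito"`, `"genes_detected"` or `"mito+genes_detected"`).
#' @export
qc_filter <- function(meta, mito_max = 0.15, genes_detected_max = 7500) {
  if (!all(c("mito_fraction", "genes_detected") %in% colnames(meta)))
    stop("meta needs mito_fraction and genes_detected columns")
  bad_mito <- meta$mito_fraction > mito_max
  bad_genes <- meta$genes_detected > genes_detected_max
  if (anyNA(bad_mito) || anyNA(bad_genes))
    stop("missing QC metrics")
  keep <- !(bad_mito | bad_genes)
  reason <- paste(ifelse(bad_mito, "mito", ""),
                  ifelse(bad_genes, "genes_detected", ""), sep = "+")
  reason <- gsub("^\\+|\\+$", "", reason)
  log <- data.frame(meta[!keep, , drop = FALSE],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  list(retained = meta[keep, , drop = FALSE], keep = keep, log = log)
}

#' Remove genes not robustly detected in any combination
#'
#' A gene is kept if it is expressed (count > 0) in at least `min_frac`
#' (default 20%, boundary inclusive) of the cells of at least one of the
#' four species-environment combinations.
#'
#' @param counts gene x cell count matrix (assigned-genome counts).
#' @param combo character vector per cell in `c("HM","HR","DM","DR")`.
#' @param min_frac detection fraction required in at least one combination.
#' @return character vector of retained gene ids.
#' @export
filter_genes_cellfrac <- function(counts, combo, min_frac = 0.20) {
  combo <- factor(combo, levels = c("HM", "HR", "DM", "DR"))
  n <- table(combo)
  if (any(n == 0))
    stop("combination(s) with zero cells: ",
         paste(names(n)[n == 0], collapse = ", "))
  detected <- counts > 0
  frac <- vapply(levels(combo), function(cmb)
    rowMeans(detected[, combo == cmb, drop = FALSE]), numeric(nrow(counts)))
  rownames(counts)[apply(frac >= min_frac, 1, any)]
}

#' Combination label from species and environment
#'
#' `HM` = mouse cell, mouse-like environment; `HR` = rat/rat-like;
#' `DM` = mouse/rat-like (donor mouse); `DR` = rat/mouse-like (donor rat).
#'
#' @param species `"mouse"` or `"rat"` per cell.
#' @param environment `"mouse_like"` or `"rat_like"` per cell.
#' @return character vector in `c("HM","HR","DM","DR")`.
#' @export
combo_label <- function(species, environment) {
  ok_s <- species %in% c("mouse", "rat")
  ok_e <- environment %in% c("mouse_like", "rat_like")
  if (any(!ok_s) || any(!ok_e))
    stop("unknown species/environment label: ",
         paste(unique(c(species[!ok_s], environment[!ok_e])), collapse = ", "))
  matched <- (species == "mouse") == (environment == "mouse_like")
  ifelse(matched, ifelse(species == "mouse", "HM", "HR"),
         ifelse(species == "mouse", "DM", "DR"))
}

#' Pseudobulk single cells into the four species-environment combinations
#'
#' Sums counts across the cells of each cell type for each of the four
#' combinations. Cell types with fewer than `min_cells` cells in any
#' combination are dropped (with a warning); genes with fewer than
#' `min_counts` summed counts in all four combinations are removed.
#'
#' @param counts gene x cell matrix of assigned-genome counts.
#' @param species,environment per-cell labels (see [combo_label()]).
#' @param cell_type per-cell cell-type label.
#' @param min_cells minimum cells per combination for a cell type to be kept.
#' @param min_counts a gene is dropped if its summed counts are below this
#'   in every combination.
#' @param gene_whitelist optional gene ids to restrict to before
#'   pseudobulking (e.g. autosomal one-to-one orthologs).
#' @return named list of `combo_counts` objects, one per retained cell
#'   type. Each holds `counts` (gene x 4 matrix), `n_cells`, `totals` (raw
#'   per-combination totals before gene removal) and `cell_type`.
#' @export
pseudobulk <- function(counts, species, environment, cell_type,
                       min_cells = 10, min_counts = 10,
                       gene_whitelist = NULL) {
  combo <- combo_label(species, environment)
  counts <- as.matrix(counts)
  if (!is.null(gene_whitelist))
    counts <- counts[rownames(counts) %in% gene_whitelist, , drop = FALSE]
  out <- list()
  for (ct in unique(cell_type)) {
    idx <- cell_type == ct
    n_cells <- table(factor(combo[idx], levels = c("HM", "HR", "DM", "DR")))
    if (any(n_cells < min_cells)) {
      warning(sprintf(
        "dropping cell type '%s': fewer than %d cells in %s", ct, min_cells,
        paste(names(n_cells)[n_cells < min_cells], collapse = ", ")))
      next
    }
    m <- vapply(c("HM", "HR", "DM", "DR"), function(cmb)
      rowSums(counts[, idx & combo == cmb, drop = FALSE]),
      numeric(nrow(counts)))
    totals <- colSums(m)
    keep <- apply(m >= min_counts, 1, any)
    out[[ct]] <- combo_counts(m[keep, , drop = FALSE], cell_type = ct,
                              n_cells = as.integer(n_cells),
                              totals = totals)
  }
  out
}

#' Construct a pseudobulked combination count table
#'
#' @param counts gene x 4 matrix with columns `HM`, `HR`, `DM`, `DR`.
#' @param cell_type label.
#' @param n_cells integer vector of cells per combination.
#' @param totals raw per-combination count totals (defaults to column sums;
#'   may exceed them when genes were removed after summing).
#' @return object of class `combo_counts`.
#' @export
combo_counts <- function(counts, cell_type = "all", n_cells = NULL,
                         totals = NULL) {
  counts <- as.matrix(counts)
  if (!all(c("HM", "HR", "DM", "DR") %in% colnames(counts)))
    stop("counts must have columns HM, HR, DM, DR")
  counts <- counts[, c("HM", "HR", "DM", "DR"), drop = FALSE]
  if (is.null(totals)) totals <- colSums(counts)
  totals <- stats::setNames(as.numeric(totals), colnames(counts))
  if (is.null(n_cells)) n_cells <- rep(NA_integer_, 4L)
  structure(list(cell_type = cell_type, counts = counts,
                 n_cells = stats::setNames(as.integer(n_cells),
                                           colnames(counts)),
                 totals = totals),
            class = "combo_counts")
}

#' @export
print.combo_counts <- function(x, ...) {
  cat(sprintf("Pseudobulk combination counts: cell type '%s', %d genes\n",
              x$cell_type, nrow(x$counts)))
  cat("  cells: ", paste(sprintf("%s=%s", names(x$n_cells), x$n_cells),
                         collapse = " "), "\n")
  cat("  totals:", paste(sprintf("%s=%.0f", names(x$totals), x$totals),
                         collapse = " "), "\n")
  invisible(x)
}

combo_matrix <- function(table) {
  if (inherits(table, "combo_counts")) return(table$counts)
  m <- as.matrix(table)
  if (!all(c("HM", "HR", "DM", "DR") %in% colnames(m)))
    stop("expected a combo_counts object or a matrix with columns HM, HR, DM, DR")
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene%04d", seq_len(nrow(m)))
  m[, c("HM", "HR", "DM", "DR"), drop = FALSE]
}

combo_totals <- function(table) {
  if (inherits(table, "combo_counts")) return(table$totals)
  colSums(combo_matrix(table))
}

#' Read a two-column one-to-one ortholog map
#'
#' @param path TSV with two columns (e.g. mouse id, rat id); a header line
#'   is detected and skipped if both fields are non-identifiers.
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  stats::setNames(df[, 1:2], c("id_a", "id_b"))
}
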