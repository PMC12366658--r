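#' Default pipeline configuration
#'
#' All thresholds default to the framework's standard parameterization:
#' species-assignment fraction 0.70, mitochondrial maximum 0.15, maximum
#' 7500 genes detected, 20% detection fraction, 10 minimum cells and 10
#' minimum counts, divergence evidence 0.5 log2 units, 100 resampling
#' repetitions at scale 10,000 with pseudocount 1, and 1000 enrichment
#' permutations with seed 6 and set sizes 10-300.
#'
#' @param ... named overrides of any default (unknown keys are rejected).
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    species_threshold = 0.70,
    mito_max = 0.15,
    genes_detected_max = 7500,
    gene_cell_frac = 0.20,
    min_cells = 10,
    min_counts = 10,
    divergence_lfc = 0.5,
    norm_reps = 100,
    norm_scale = 10000,
    norm_pseudocount = 1,
    enrich_n_perm = 1000,
    enrich_seed = 6,
    enrich_min_size = 10,
    enrich_max_size = 300,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are a subset of [default_config()]'s.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full decomposition pipeline on a dataset
#'
#' Orchestrates species assignment, QC, gene filtering, pseudobulking,
#' equal-depth resampled normalization and decomposition, writing per-cell
#' -type decomposition TSVs, a JSON manifest (seeds, thresholds, per-stage
#' record counts) and a JSON-lines log into `out_dir`. Deterministic given
#' the config seed.
#'
#' @param sim a `chimera_sim` dataset (or a list with the same fields read
#'   from disk via [read_chimera_dataset()]).
#' @param out_dir output directory (created if missing).
#' @param config a [default_config()] list.
#' @return invisibly, a list with `decomp` (named list of
#'   `divergence_decomp` tables per cell type) and `manifest`.
#' @export
run_pipeline <- function(sim, out_dir, config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  meta <- sim$cell_meta
  n0 <- nrow(meta)
  species <- stage("assign_species",
                   assign_species(meta$aligned_mouse, meta$aligned_rat,
                                  threshold = config$species_threshold))
  keep_singlet <- species != "doublet"
  log_line("assign_species", n_cells = n0,
           n_doublets_removed = sum(!keep_singlet))

  qc <- stage("qc_filter",
              qc_filter(meta[keep_singlet, ],
                        mito_max = config$mito_max,
                        genes_detected_max = config$genes_detected_max))
  meta2 <- qc$retained
  species2 <- species[keep_singlet][qc$keep]
  log_line("qc_filter", n_in = sum(keep_singlet), n_out = nrow(meta2),
           n_rejected = nrow(qc$log))

  genes <- rownames(sim$counts$mouse)
  counts <- matrix(0, length(genes), nrow(meta2),
                   dimnames = list(genes, meta2$barcode))
  is_m <- species2 == "mouse"
  counts[, is_m] <- sim$counts$mouse[, meta2$barcode[is_m], drop = FALSE]
  counts[, !is_m] <- sim$counts$rat[, meta2$barcode[!is_m], drop = FALSE]

  combo <- combo_label(species2, meta2$environment)
  pb <- stage("pseudobulk", suppressWarnings(
    pseudobulk(counts, species2, meta2$environment, meta2$cell_type,
               min_cells = config$min_cells,
               min_counts = config$min_counts)))
  if (!length(pb))
    stop("pipeline stage 'pseudobulk' failed: no cell type retained")
  log_line("pseudobulk", cell_types = names(pb))

  decomp <- list()
  for (ct in names(pb)) {
    tab <- pb[[ct]]
    idx <- meta2$cell_type == ct
    genes_keep <- stage("filter_genes", filter_genes_cellfrac(
      counts[rownames(tab$counts), idx, drop = FALSE], combo[idx],
      min_frac = config$gene_cell_frac))
    n_before <- nrow(tab$counts)
    tab$counts <- tab$counts[rownames(tab$counts) %in% genes_keep, ,
                             drop = FALSE]
    norm <- stage("normalize", normalize_resampled(
      tab, n_reps = config$norm_reps, scale = config$norm_scale,
      pseudocount = config$norm_pseudocount, seed = config$seed))
    dec <- stage("decompose", decompose_divergence(
      norm, min_abs_lfc = config$divergence_lfc, cell_type = ct))
    decomp[[ct]] <- dec
    write_decomposition(dec, file.path(out_dir,
                                       sprintf("decomposition_%s.tsv", ct)))
    log_line("decompose", cell_type = ct, n_genes_pseudobulk = n_before,
             n_genes_normalized = nrow(tab$counts),
             n_passed_filter = sum(dec$passed_divergence_filter))
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_cells_input = n0,
    n_doublets_removed = sum(!keep_singlet),
    n_cells_qc_rejected = nrow(qc$log),
    n_cells_retained = nrow(meta2),
    cell_types = names(pb),
    n_genes_decomposed = vapply(decomp, nrow, integer(1))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(decomp = decomp, manifest = manifest))
}

#' Summarize decomposition components across cell types
#'
#' Per cell type, the mean intrinsic/extrinsic/interaction proportions
#' over filter-passing genes (a triple summing to one); across cell
#' types, pairwise Spearman correlation matrices of the signed intrinsic
#' and extrinsic components over shared filter-passing genes, with a
#' hierarchical-clustering ordering of cell types.
#'
#' @param decomp_list named list of `divergence_decomp` tables (one per
#'   cell type).
#' @return list with `mean_proportions` (cell type x 3 matrix), `cor_I`,
#'   `cor_E` (cell type x cell type Spearman matrices, `NULL` for a
#'   single cell type) and `cell_type_order`.
#' @export
summarize_components <- function(decomp_list) {
  if (!length(decomp_list)) stop("no cell types supplied")
  if (is.null(names(decomp_list)))
    names(decomp_list) <- sprintf("cell_type%d", seq_along(decomp_list))
  means <- t(vapply(decomp_list, function(d) {
    keep <- d$passed_divergence_filter & !is.na(d$Ip)
    if (!any(keep)) stop("a cell type has no filter-passing genes")
    colMeans(d[keep, c("Ip", "Ep", "Np")])
  }, numeric(3)))

  cor_I <- cor_E <- NULL
  order_ct <- names(decomp_list)
  if (length(decomp_list) >= 2) {
    shared <- Reduce(intersect, lapply(decomp_list, function(d)
      d$gene_id[d$passed_divergence_filter]))
    if (length(shared) >= 3) {
      getm <- function(col) vapply(decomp_list, function(d)
        stats::setNames(d[[col]], d$gene_id)[shared],
        numeric(length(shared)))
      cor_I <- stats::cor(getm("I"), method = "spearman")
      cor_E <- stats::cor(getm("E"), method = "spearman")
      if (length(decomp_list) >= 3) {
        hc <- stats::hclust(stats::as.dist(1 - cor_I), method = "average")
        order_ct <- names(decomp_list)[hc$order]
      }
    }
  }
  list(mean_proportions = means, cor_I = cor_I, cor_E = cor_E,
       cell_type_order = order_ct)
}

#' Write a synthetic dual-genome dataset to disk
#'
#' Standard sparse exchange formats: one MTX (+ genes and barcodes TSV)
#' per genome, cell metadata TSV, and the ground-truth table TSV.
#'
#' @param sim a `chimera_sim` object.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_chimera_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (genome in names(sim$counts)) {
    m <- Matrix::Matrix(sim$counts[[genome]], sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, sprintf("counts_%s.mtx", genome)))
    writeLines(rownames(m), file.path(dir, sprintf("genes_%s.tsv", genome)))
  }
  writeLines(colnames(sim$counts[[1]]), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_chimera_dataset()]
#'
#' @param dir dataset directory.
#' @return a `chimera_sim`-shaped list.
#' @export
read_chimera_dataset <- function(dir) {
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- lapply(c(mouse = "mouse", rat = "rat"), function(genome) {
    m <- as.matrix(Matrix::readMM(
      file.path(dir, sprintf("counts_%s.mtx", genome))))
    rownames(m) <- readLines(file.path(dir, sprintf("genes_%s.tsv", genome)))
    colnames(m) <- barcodes
    m
  })
  meta <- utils::read.table(file.path(dir, "cell_meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.table(truth_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  structure(list(counts = counts, cell_meta = meta, truth = truth,
                 seed = NA_integer_, params = list()),
            class = "chimera_sim")
}
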