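#' Simulate reciprocal-chimera single-cell counts with known ground truth
#'
#' Generates a dual-genome single-cell dataset emulating a pair of
#' reciprocal mouse-rat chimeras: four species-environment combinations
#' (host mouse `HM`, host rat `HR`, donor mouse `DM`, donor rat `DR`) with
#' unequal cell numbers and sequencing depths, negative-binomial count
#' noise, log-normal per-cell library-size variation, mixed-species doublet
#' barcodes, and per-gene planted effects on a log2 scale.
#'
#' The latent model for the expected log2 expression of gene g in a cell of
#' species s in environment e is
#' `baseline_g + I_g * [s = rat] + E_g * [e = rat-like] + N_g * [s != e]`:
#' `I_g` is the intrinsic (genotype) effect (rat minus mouse), `E_g` the
#' extrinsic (environment) effect (rat-like minus mouse-like) and `N_g` a
#' mismatch term applied symmetrically to both donor combinations
#' (positive `N_g` = higher in species-mismatched environments, the
#' imprinted-gene phenotype). Note the estimator's interaction component
#' has the opposite orientation (positive = higher in matched
#' combinations), so the decomposition of the expected quartet recovers
#' `I_g`, `E_g` and `-N_g`; [truth_decomposition()] returns the planted
#' effects in the estimator's convention.
#'
#' The two genomes are disjoint namespaces over the same orthologous genes.
#' Singlet cells carry a small cross-genome misalignment fraction; doublet
#' barcodes mix a mouse and a rat cell with a mixing fraction uniform in
#' (0.3, 0.7), so they fail the 70% species-assignment rule.
#'
#' @param n_genes number of orthologous genes.
#' @param cells_per_combo named integer vector of singlet cells for `HM`,
#'   `HR`, `DM`, `DR` (all must be positive).
#' @param effect_spec list with `mean_I`, `mean_E`, `mean_N` and `sd_I`,
#'   `sd_E`, `sd_N` (normal parameters of the per-gene effect
#'   distributions, log2 units), and optionally `n_imprinted` genes given
#'   a fixed mismatch effect `imprinted_N` (log2 units) on top of the
#'   `sd_N` noise. Explicit per-gene vectors `I`, `E`, `N` override the
#'   draws. Because expression is compositional (normalized to library
#'   totals), only effects that vary across genes are identifiable; a
#'   shared shift is absorbed into the normalization.
#' @param depth_per_combo expected per-cell library size per combination
#'   (unequal by default, as in real chimera libraries).
#' @param dispersion negative-binomial size parameter (larger = less
#'   overdispersion).
#' @param baseline_log2_mean,baseline_log2_sd normal parameters of the
#'   per-gene baseline log2 expression.
#' @param libsize_sdlog sdlog of the log-normal per-cell library factor.
#' @param crossalign_range range of the per-cell cross-genome misalignment
#'   fraction for singlets.
#' @param doublet_fraction fraction of emitted barcodes that are doublets.
#' @param cell_type cell-type label stored in the metadata.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return object of class `chimera_sim`: list with `counts` (list of two
#'   gene x barcode matrices, `mouse` and `rat` genome), `cell_meta`
#'   (barcode, true_species, environment, combo, cell_type, is_doublet,
#'   mito_fraction, genes_detected, aligned_mouse, aligned_rat) and `truth`
#'   (gene_id, baseline, I, E, N plus the expected normalized quartet
#'   means `mu_HM`, `mu_HR`, `mu_DM`, `mu_DR`).
#' @examples
#' sim <- simulate_chimera_counts(n_genes = 50,
#'   cells_per_combo = c(HM = 30, HR = 30, DM = 30, DR = 30), seed = 1)
#' table(sim$cell_meta$combo)
#' @export
simulate_chimera_counts <- function(
    n_genes = 2000,
    cells_per_combo = c(HM = 250, HR = 250, DM = 150, DR = 100),
    effect_spec = list(sd_I = 1, sd_E = 0.5, sd_N = 0,
                       n_imprinted = 0, imprinted_N = 2),
    depth_per_combo = c(HM = 3000, HR = 2500, DM = 2000, DR = 1200),
    dispersion = 10,
    baseline_log2_mean = 4, baseline_log2_sd = 1.5,
    libsize_sdlog = 0.3,
    crossalign_range = c(0.01, 0.05),
    doublet_fraction = 0.02,
    cell_type = "typeA",
    seed = 1) {
  combos <- c("HM", "HR", "DM", "DR")
  cells_per_combo <- cells_per_combo[combos]
  if (anyNA(cells_per_combo) || any(cells_per_combo <= 0))
    stop("zero cells requested in combination(s): ",
         paste(combos[is.na(cells_per_combo) | cells_per_combo <= 0],
               collapse = ", "))
  depth_per_combo <- depth_per_combo[combos]
  if (anyNA(depth_per_combo) || any(depth_per_combo <= 0))
    stop("depths must be positive for all four combinations")
  spec <- utils::modifyList(
    list(mean_I = 0, mean_E = 0, mean_N = 0,
         sd_I = 1, sd_E = 0.5, sd_N = 0, n_imprinted = 0, imprinted_N = 2),
    effect_spec)
  if (dispersion <= 0) stop("dispersion must be positive")

  withr_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
    # explicit per-gene effect vectors override the normal draws
    I_g <- if (!is.null(spec$I)) rep_len(spec$I, n_genes) else
      stats::rnorm(n_genes, spec$mean_I, spec$sd_I)
    E_g <- if (!is.null(spec$E)) rep_len(spec$E, n_genes) else
      stats::rnorm(n_genes, spec$mean_E, spec$sd_E)
    N_g <- if (!is.null(spec$N)) rep_len(spec$N, n_genes) else
      stats::rnorm(n_genes, spec$mean_N, spec$sd_N)
    imprinted <- character(0)
    if (spec$n_imprinted > 0) {
      idx <- seq_len(min(spec$n_imprinted, n_genes))
      N_g[idx] <- N_g[idx] + spec$imprinted_N
      imprinted <- genes[idx]
    }

    # expected relative expression per combination (linear scale)
    mu <- cbind(HM = 2^baseline,
                HR = 2^(baseline + I_g + E_g),
                DM = 2^(baseline + E_g + N_g),
                DR = 2^(baseline + I_g + N_g))
    rownames(mu) <- genes

    species_of <- c(HM = "mouse", HR = "rat", DM = "mouse", DR = "rat")
    env_of <- c(HM = "mouse_like", HR = "rat_like",
                DM = "rat_like", DR = "mouse_like")

    draw_cell_counts <- function(cmb, n) {
      p <- mu[, cmb] / sum(mu[, cmb])
      lib <- stats::rlnorm(n, -libsize_sdlog^2 / 2, libsize_sdlog)
      m <- vapply(seq_len(n), function(j)
        stats::rnbinom(n_genes,
                       mu = p * depth_per_combo[[cmb]] * lib[j],
                       size = dispersion),
        numeric(n_genes))
      rownames(m) <- genes
      m
    }

    n_singlet <- sum(cells_per_combo)
    n_doublet <- round(n_singlet * doublet_fraction / (1 - doublet_fraction))

    own <- lapply(combos, function(cmb)
      draw_cell_counts(cmb, cells_per_combo[[cmb]]))
    names(own) <- combos

    meta <- data.frame(
      true_species = rep(species_of[combos], cells_per_combo),
      environment = rep(env_of[combos], cells_per_combo),
      combo = rep(combos, cells_per_combo),
      is_doublet = FALSE, stringsAsFactors = FALSE)
    own_counts <- do.call(cbind, own)

    # cross-genome misalignment for singlets: a small fraction of each
    # cell's reads scattered across the other genome
    n_cells <- nrow(meta)
    cross_rate <- stats::runif(n_cells, crossalign_range[1],
                               crossalign_range[2])
    own_tot <- colSums(own_counts)
    cross_tot <- round(own_tot * cross_rate / (1 - cross_rate))
    p_flat <- rep(1 / n_genes, n_genes)
    cross_counts <- vapply(seq_len(n_cells), function(j)
      if (cross_tot[j] > 0)
        as.numeric(stats::rmultinom(1, cross_tot[j], p_flat))
      else numeric(n_genes),
      numeric(n_genes))
    rownames(cross_counts) <- genes

    is_mouse <- meta$true_species == "mouse"
    counts_mouse <- own_counts
    counts_mouse[, !is_mouse] <- cross_counts[, !is_mouse]
    counts_rat <- own_counts
    counts_rat[, is_mouse] <- cross_counts[, is_mouse]

    # doublets: one mouse + one rat cell sharing an environment, mixed with
    # a fraction uniform in (0.3, 0.7) so neither genome reaches 70%
    if (n_doublet > 0) {
      env_d <- sample(c("mouse_like", "rat_like"), n_doublet, replace = TRUE)
      u <- stats::runif(n_doublet, 0.3, 0.7)
      dm_m <- matrix(0, n_genes, n_doublet, dimnames = list(genes, NULL))
      dm_r <- dm_m
      for (j in seq_len(n_doublet)) {
        cmb_m <- if (env_d[j] == "mouse_like") "HM" else "DM"
        cmb_r <- if (env_d[j] == "rat_like") "HR" else "DR"
        depth <- mean(depth_per_combo[c(cmb_m, cmb_r)])
        dm_m[, j] <- stats::rnbinom(
          n_genes, mu = mu[, cmb_m] / sum(mu[, cmb_m]) * depth * u[j],
          size = dispersion)
        dm_r[, j] <- stats::rnbinom(
          n_genes, mu = mu[, cmb_r] / sum(mu[, cmb_r]) * depth * (1 - u[j]),
          size = dispersion)
      }
      counts_mouse <- cbind(counts_mouse, dm_m)
      counts_rat <- cbind(counts_rat, dm_r)
      meta <- rbind(meta, data.frame(
        true_species = "doublet", environment = env_d, combo = NA_character_,
        is_doublet = TRUE, stringsAsFactors = FALSE))
    }

    n_all <- nrow(meta)
    barcodes <- sprintf("cell%05d", seq_len(n_all))
    colnames(counts_mouse) <- colnames(counts_rat) <- barcodes
    meta <- data.frame(
      barcode = barcodes, meta,
      cell_type = cell_type,
      mito_fraction = stats::rbeta(n_all, 2, 30),
      aligned_mouse = colSums(counts_mouse),
      aligned_rat = colSums(counts_rat),
      stringsAsFactors = FALSE)
    meta$genes_detected <- ifelse(
      meta$true_species == "rat",
      colSums(counts_rat > 0), colSums(counts_mouse > 0))

    truth <- data.frame(
      gene_id = genes, baseline = baseline, I = I_g, E = E_g, N = N_g,
      is_imprinted = genes %in% imprinted,
      mu_HM = mu[, "HM"], mu_HR = mu[, "HR"],
      mu_DM = mu[, "DM"], mu_DR = mu[, "DR"],
      stringsAsFactors = FALSE, row.names = NULL)

    structure(list(counts = list(mouse = counts_mouse, rat = counts_rat),
                   cell_meta = meta, truth = truth, seed = seed,
                   params = list(cells_per_combo = cells_per_combo,
                                 depth_per_combo = depth_per_combo,
                                 effect_spec = spec,
                                 dispersion = dispersion,
                                 doublet_fraction = doublet_fraction)),
              class = "chimera_sim")
  })
}

#' @export
print.chimera_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic reciprocal-chimera dataset: %d genes, %d barcodes (%d doublets), seed %d\n",
    nrow(x$truth), nrow(x$cell_meta), sum(x$cell_meta$is_doublet), x$seed))
  print(table(combo = x$cell_meta$combo, useNA = "ifany"))
  invisible(x)
}

#' Planted effects in the estimator's sign convention
#'
#' Decomposes each gene's expected (noise-free) quartet of means, giving
#' the component values the estimator should recover: `I` and `E` equal the
#' planted effects, and the interaction equals minus the planted mismatch
#' effect (the estimator orients positive interaction toward
#' species-matched combinations).
#'
#' @param truth the `truth` data frame of a [simulate_chimera_counts()]
#'   dataset (or the `chimera_sim` object itself).
#' @param min_abs_lfc forwarded to [decompose_divergence()].
#' @return a `divergence_decomp` object on the expected quartets.
#' @export
truth_decomposition <- function(truth, min_abs_lfc = 0.5) {
  if (inherits(truth, "chimera_sim")) truth <- truth$truth
  q <- data.frame(gene_id = truth$gene_id, HM = truth$mu_HM,
                  HR = truth$mu_HR, DM = truth$mu_DM, DR = truth$mu_DR)
  decompose_divergence(q, min_abs_lfc = min_abs_lfc)
}

#' Run the standard ingest + normalization + decomposition on a synthetic
#' dataset
#'
#' Convenience wrapper used throughout the tests and examples: assigns
#' species by the 70% rule, applies QC, pseudobulks per cell type,
#' resample-normalizes and decomposes.
#'
#' @param sim a `chimera_sim` object.
#' @param n_reps resampling repetitions (see [normalize_resampled()]).
#' @param seed seed for the resampling.
#' @param min_frac detection filter (see [filter_genes_cellfrac()]).
#' @param min_abs_lfc divergence filter threshold.
#' @return a `divergence_decomp` table for the first (usually only) cell
#'   type.
#' @export
decompose_simulation <- function(sim, n_reps = 100, seed = 1,
                                 min_frac = 0.20, min_abs_lfc = 0.5) {
  species <- assign_species(sim$cell_meta$aligned_mouse,
                            sim$cell_meta$aligned_rat)
  keep <- species != "doublet"
  qc <- qc_filter(sim$cell_meta[keep, ])
  meta <- qc$retained
  species <- species[keep][qc$keep]
  counts <- matrix(0, nrow(sim$truth), nrow(meta),
                   dimnames = list(sim$truth$gene_id, meta$barcode))
  is_m <- species == "mouse"
  counts[, is_m] <- sim$counts$mouse[, meta$barcode[is_m], drop = FALSE]
  counts[, !is_m] <- sim$counts$rat[, meta$barcode[!is_m], drop = FALSE]
  pb <- pseudobulk(counts, species, meta$environment, meta$cell_type)
  if (!length(pb)) stop("no cell type survived pseudobulking")
  tab <- pb[[1]]
  genes_keep <- filter_genes_cellfrac(
    counts[rownames(tab$counts), , drop = FALSE],
    combo_label(species, meta$environment), min_frac = min_frac)
  tab$counts <- tab$counts[rownames(tab$counts) %in% genes_keep, ,
                           drop = FALSE]
  norm <- normalize_resampled(tab, n_reps = n_reps, seed = seed)
  decompose_divergence(norm, min_abs_lfc = min_abs_lfc,
                       cell_type = tab$cell_type)
}

#' Simulate a two-species bulk developmental time course
#'
#' Emits per-gene expression at three developmental stages for mouse and
#' rat with planted dynamics classes: `similar` (same-sign monotone
#' trajectories in both species, species offset > 0.25 log2 at the two
#' later stages), `temporal_shift` (similar trajectories and |log2
#' fold-change| < 0.25 at both later stages), `opposite` (monotone in
#' opposite directions) and `unclassified` (flat/noisy in one species).
#'
#' @param n_genes number of genes.
#' @param class_props named proportions for `similar`, `opposite`,
#'   `temporal_shift` (must sum to <= 1; the remainder is unclassified).
#' @param stages numeric developmental stages (>= 3 values).
#' @param noise_sd log2-scale noise added to every value (0 = noise-free).
#' @param seed integer seed.
#' @return list with `mouse` and `rat` (gene x stage matrices), `stages`
#'   and `truth` (gene_id, class).
#' @export
simulate_timecourse <- function(n_genes = 300,
                                class_props = c(similar = 0.4,
                                                opposite = 0.2,
                                                temporal_shift = 0.2),
                                stages = c(11.5, 13.5, 15.25),
                                noise_sd = 0, seed = 1) {
  if (length(stages) < 3) stop("at least 3 timepoints are required")
  props <- class_props[c("similar", "opposite", "temporal_shift")]
  props[is.na(props)] <- 0
  if (sum(props) > 1 + 1e-8) stop("class proportions must sum to <= 1")
  n_cls <- c(round(props * n_genes),
             unclassified = n_genes - sum(round(props * n_genes)))
  withr_seed(seed, {
    cls <- rep(names(n_cls), n_cls)
    t_norm <- (stages - min(stages)) / diff(range(stages))  # 0..1
    mouse <- matrix(0, n_genes, length(stages))
    rat <- matrix(0, n_genes, length(stages))
    base <- stats::runif(n_genes, 3, 8)
    slope <- stats::runif(n_genes, 1.5, 3) *
      sample(c(-1, 1), n_genes, replace = TRUE)
    offset <- stats::runif(n_genes, 0.6, 1.5) *
      sample(c(-1, 1), n_genes, replace = TRUE)
    for (i in seq_len(n_genes)) {
      traj <- base[i] + slope[i] * t_norm
      mouse[i, ] <- traj
      rat[i, ] <- switch(
        cls[i],
        similar = traj + offset[i],
        temporal_shift = traj + stats::runif(1, -0.2, 0.2) * c(1, 0.5, 0.5),
        opposite = base[i] + slope[i] * (1 - t_norm) + offset[i] / 4,
        unclassified = {
          # flat in rat: correlation ~ 0 -> product outside both cutoffs
          rat_traj <- rep(base[i], length(stages))
          rat_traj[2] <- base[i] + 0.05
          rat_traj
        })
    }
    if (noise_sd > 0) {
      mouse <- mouse + stats::rnorm(length(mouse), 0, noise_sd)
      rat <- rat + stats::rnorm(length(rat), 0, noise_sd)
    }
    genes <- sprintf("tg%04d", seq_len(n_genes))
    dimnames(mouse) <- dimnames(rat) <-
      list(genes, sprintf("E%.2f", stages))
    list(mouse = 2^mouse, rat = 2^rat, stages = stages,
         truth = data.frame(gene_id = genes, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a multi-channel immunofluorescence image with known truth
#'
#' Builds a three-channel image (DAPI, TdTomato, target protein): donor
#' nuclei (TdTomato+) at given centers/radii with a stated target
#' intensity, host nuclei (TdTomato-) at `host_intensity`, a constant
#' background added to the target channel, and optional Gaussian noise.
#'
#' @param shape image height and width in pixels.
#' @param donor_blobs data frame with columns `x`, `y`, `r`,
#'   `intensity` (target-channel intensity inside the blob).
#' @param host_blobs data frame with columns `x`, `y`, `r`; if `NULL`,
#'   host nuclei are placed on a grid avoiding the donor blobs.
#' @param host_intensity target-channel intensity inside host nuclei.
#' @param background constant added to the whole target channel.
#' @param dapi_intensity,tdt_intensity channel levels inside nuclei.
#' @param noise_sd Gaussian noise sd added to every channel (0 = none).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `image` (h x w x 3 array, channels DAPI, TdTomato,
#'   target) and `truth` (donor/host pixel masks and intensities).
#' @export
simulate_if_image <- function(shape = c(128, 128),
                              donor_blobs = data.frame(
                                x = c(40, 90), y = c(40, 80), r = 10,
                                intensity = 10),
                              host_blobs = NULL,
                              host_intensity = 5,
                              background = 0,
                              dapi_intensity = 100, tdt_intensity = 100,
                              noise_sd = 0, seed = 1) {
  h <- shape[1]; w <- shape[2]
  disc <- function(x0, y0, r) {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    (xs - x0)^2 + (ys - y0)^2 <= r^2
  }
  donor_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(donor_blobs))) {
    b <- donor_blobs[i, ]
    if (b$x - b$r < 1 || b$x + b$r > w || b$y - b$r < 1 || b$y + b$r > h)
      stop("donor blob outside image bounds")
    donor_mask <- donor_mask | disc(b$x, b$y, b$r)
  }
  if (is.null(host_blobs)) {
    cand <- expand.grid(x = seq(15, w - 15, by = 26),
                        y = seq(15, h - 15, by = 26))
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      d <- sqrt((donor_blobs$x - cand$x[i])^2 + (donor_blobs$y - cand$y[i])^2)
      all(d > donor_blobs$r + 18)  # clear of donor blobs and blur halos
    }, logical(1))
    host_blobs <- data.frame(cand[keep, ], r = 7)
  }
  host_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(host_blobs))) {
    b <- host_blobs[i, ]
    host_mask <- host_mask | disc(b$x, b$y, b$r)
  }
  if (any(donor_mask & host_mask))
    stop("donor and host truth regions overlap")

  target <- matrix(background, h, w)
  donor_int <- matrix(0, h, w)
  for (i in seq_len(nrow(donor_blobs))) {
    b <- donor_blobs[i, ]
    donor_int[disc(b$x, b$y, b$r)] <- b$intensity
  }
  target[donor_mask] <- donor_int[donor_mask] + background
  target[host_mask] <- host_intensity + background
  dapi <- matrix(0, h, w)
  dapi[donor_mask | host_mask] <- dapi_intensity
  tdt <- matrix(0, h, w)
  tdt[donor_mask] <- tdt_intensity

  img <- array(c(dapi, tdt, target), dim = c(h, w, 3),
               dimnames = list(NULL, NULL, c("dapi", "tdt", "target")))
  if (noise_sd > 0) {
    withr_seed(seed, {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    })
    img[img < 0] <- 0
  }
  list(image = img,
       truth = list(donor_mask = donor_mask, host_mask = host_mask,
                    donor_intensity = donor_blobs$intensity,
                    host_intensity = host_intensity,
                    background = background))
}
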