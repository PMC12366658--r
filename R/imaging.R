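#' Separable Gaussian blur with reflected boundaries
#'
#' Used to smooth the DAPI and TdTomato channels before masking. The
#' kernel is truncated at 4 sigma; image edges are handled by reflection
#' so border nuclei are not attenuated.
#'
#' @param mat numeric matrix (one channel).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(m, r) {
    top <- m[rev(seq_len(r)), , drop = FALSE]
    bottom <- m[nrow(m) - seq_len(r) + 1, , drop = FALSE]
    rbind(top, m, bottom)
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * p[seq_len(nrow(m)) + (j - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

#' Masking parameters for immunofluorescence quantification
#'
#' @param sigma_dapi,sigma_tdt Gaussian blur sigmas (pixels) for the DAPI
#'   and TdTomato channels.
#' @param dapi_cutoff,tdt_cutoff intensity thresholds on the blurred
#'   channels; a pixel is positive if strictly above the cutoff.
#' @param roi optional region of interest `c(x0, x1, y0, y1)` in pixel
#'   coordinates, origin top-left, half-open (`x0 <= x < x1`); `NULL` uses
#'   the whole image.
#' @return list of class `mask_params`.
#' @export
mask_params <- function(sigma_dapi = 2, sigma_tdt = 2,
                        dapi_cutoff, tdt_cutoff, roi = NULL) {
  if (sigma_dapi <= 0 || sigma_tdt <= 0) stop("sigmas must be positive")
  structure(list(sigma_dapi = sigma_dapi, sigma_tdt = sigma_tdt,
                 dapi_cutoff = dapi_cutoff, tdt_cutoff = tdt_cutoff,
                 roi = roi),
            class = "mask_params")
}

roi_mask <- function(dim_hw, roi) {
  m <- matrix(TRUE, dim_hw[1], dim_hw[2])
  if (is.null(roi)) return(m)
  if (roi[1] < 0 || roi[2] > dim_hw[2] || roi[3] < 0 || roi[4] > dim_hw[1])
    stop("roi outside image bounds")
  m[] <- FALSE
  m[(roi[3] + 1):roi[4], (roi[1] + 1):roi[2]] <- TRUE
  m
}

#' Quantify donor vs host protein signal in a multi-channel IF image
#'
#' The blur-mask-measure procedure: the DAPI and TdTomato channels are
#' Gaussian blurred and thresholded into positive/negative masks (the
#' measured target channel is never blurred). Donor pixels are DAPI+ and
#' TdTomato+ (species-mismatched cells), host pixels DAPI+ and TdTomato-
#' (species-matched). Mean target intensity is computed in each mask,
#' restricted to pixels with non-zero raw target intensity. The
#' within-image comparison is `log2fc_within = log2(donor_mean /
#' host_mean)` on unsubtracted means; means with the average background
#' (from a nucleus-free rectangular region) subtracted are also returned
#' for between-image comparisons.
#'
#' @param image h x w x 3 array with channels DAPI, TdTomato, target (in
#'   that order, or named via `dimnames`), e.g. from
#'   [simulate_if_image()] or [read_if_tiff()].
#' @param params a [mask_params()] object.
#' @param background_roi rectangle `c(x0, x1, y0, y1)` (half-open, origin
#'   top-left) containing no DAPI+ pixels, used for the background
#'   estimate; `NULL` skips background subtraction (background 0).
#' @return list of class `if_measurement`: `donor_mean`, `host_mean`,
#'   `background_mean`, `donor_mean_sub`, `host_mean_sub`,
#'   `n_donor_pixels`, `n_host_pixels`, `log2fc_within`,
#'   `log2fc_within_sub`.
#' @export
quantify_if <- function(image, params, background_roi = NULL) {
  dapi <- image[, , 1]; tdt <- image[, , 2]; target <- image[, , 3]
  if (!all(dim(dapi) == dim(target)) || !all(dim(tdt) == dim(target)))
    stop("all three channels must share a shape")
  dapi_pos <- gaussian_blur(dapi, params$sigma_dapi) > params$dapi_cutoff
  tdt_pos <- gaussian_blur(tdt, params$sigma_tdt) > params$tdt_cutoff
  in_roi <- roi_mask(dim(dapi), params$roi)

  donor <- dapi_pos & tdt_pos & in_roi & target > 0
  host <- dapi_pos & !tdt_pos & in_roi & target > 0
  if (!any(donor)) stop("empty donor (DAPI+ TdTomato+) mask")
  if (!any(host)) stop("empty host (DAPI+ TdTomato-) mask")

  background_mean <- 0
  if (!is.null(background_roi)) {
    bg <- roi_mask(dim(dapi), background_roi)
    if (any(bg & dapi_pos))
      stop("background region overlaps DAPI+ pixels")
    background_mean <- mean(target[bg])
  }
  donor_mean <- mean(target[donor])
  host_mean <- mean(target[host])
  structure(list(
    donor_mean = donor_mean, host_mean = host_mean,
    background_mean = background_mean,
    donor_mean_sub = donor_mean - background_mean,
    host_mean_sub = host_mean - background_mean,
    n_donor_pixels = sum(donor), n_host_pixels = sum(host),
    log2fc_within = log2(donor_mean / host_mean),
    log2fc_within_sub = log2((donor_mean - background_mean) /
                               (host_mean - background_mean))),
    class = "if_measurement")
}

#' @export
print.if_measurement <- function(x, ...) {
  cat(sprintf(
    "IF measurement: donor %.3f (n=%d px), host %.3f (n=%d px), background %.3f\n",
    x$donor_mean, x$n_donor_pixels, x$host_mean, x$n_host_pixels,
    x$background_mean))
  cat(sprintf("  log2FC donor/host: %.4f (unsubtracted), %.4f (subtracted)\n",
              x$log2fc_within, x$log2fc_within_sub))
  invisible(x)
}

#' Decompose protein divergence from a pair of reciprocal chimera images
#'
#' Assembles the protein quartet from background-subtracted donor/host
#' means: in the rat-like chimera the host cells are rat (`HR`) and the
#' donor cells mouse (`DM`); in the mouse-like chimera the host cells are
#' mouse (`HM`) and the donor cells rat (`DR`). The quartet is then passed
#' to [decompose_divergence()].
#'
#' @param rat_like,mouse_like `if_measurement` objects for the two
#'   chimeras.
#' @param trait_name label (e.g. the protein).
#' @param min_abs_lfc divergence filter threshold.
#' @return a one-row `divergence_decomp` object.
#' @export
if_decompose <- function(rat_like, mouse_like, trait_name = "protein",
                         min_abs_lfc = 0.5) {
  vals <- c(HM = mouse_like$host_mean_sub, HR = rat_like$host_mean_sub,
            DM = rat_like$donor_mean_sub, DR = mouse_like$donor_mean_sub)
  if (any(vals <= 0))
    stop("nonpositive background-subtracted mean for ",
         paste(names(vals)[vals <= 0], collapse = ", "))
  decompose_divergence(
    data.frame(gene_id = trait_name, HM = vals[["HM"]], HR = vals[["HR"]],
               DM = vals[["DM"]], DR = vals[["DR"]]),
    min_abs_lfc = min_abs_lfc)
}

#' Robustness of the masking cutoffs: the 81-combination sweep
#'
#' Because masking cutoffs are hand-tuned, the measurement is recomputed
#' for every combination of three DAPI and three TdTomato cutoffs in each
#' of the two chimera images (3^4 = 81 combinations) and the standard
#' error of each log2 fold-change across combinations is reported.
#' Combinations that empty a mask are excluded and counted.
#'
#' @param rat_like_image,mouse_like_image h x w x 3 channel arrays.
#' @param rat_like_params,mouse_like_params [mask_params()] for each image
#'   (their cutoffs define the center of each grid unless grids are given
#'   explicitly).
#' @param dapi_cutoffs,tdt_cutoffs lists with elements `rat_like` and
#'   `mouse_like`, each a numeric vector of 3 cutoffs.
#' @param background_rois list with elements `rat_like`, `mouse_like`
#'   (or `NULL`).
#' @return list with `results` (one row per combination: the four quartet
#'   values and derived log2 fold-changes), `se` (named standard errors),
#'   `sd`, `n_valid`, `n_failed`.
#' @export
mask_robustness_sweep <- function(rat_like_image, mouse_like_image,
                                  rat_like_params, mouse_like_params,
                                  dapi_cutoffs, tdt_cutoffs,
                                  background_rois = NULL) {
  stopifnot(length(dapi_cutoffs$rat_like) == 3,
            length(dapi_cutoffs$mouse_like) == 3,
            length(tdt_cutoffs$rat_like) == 3,
            length(tdt_cutoffs$mouse_like) == 3)
  grid <- expand.grid(dapi_r = dapi_cutoffs$rat_like,
                      tdt_r = tdt_cutoffs$rat_like,
                      dapi_m = dapi_cutoffs$mouse_like,
                      tdt_m = tdt_cutoffs$mouse_like)
  stopifnot(nrow(grid) == 81)
  bg_r <- background_rois$rat_like
  bg_m <- background_rois$mouse_like
  rows <- vector("list", nrow(grid))
  n_failed <- 0L
  for (i in seq_len(nrow(grid))) {
    pr <- rat_like_params; pm <- mouse_like_params
    pr$dapi_cutoff <- grid$dapi_r[i]; pr$tdt_cutoff <- grid$tdt_r[i]
    pm$dapi_cutoff <- grid$dapi_m[i]; pm$tdt_cutoff <- grid$tdt_m[i]
    meas <- tryCatch(list(r = quantify_if(rat_like_image, pr, bg_r),
                          m = quantify_if(mouse_like_image, pm, bg_m)),
                     error = function(e) NULL)
    if (is.null(meas)) { n_failed <- n_failed + 1L; next }
    r <- meas$r; m <- meas$m
    rows[[i]] <- data.frame(
      lfc_within_rat_like = r$log2fc_within,
      lfc_within_mouse_like = m$log2fc_within,
      lfc_host_rat_vs_mouse = log2(r$host_mean_sub / m$host_mean_sub),
      lfc_donor_mouse_vs_rat = log2(r$donor_mean_sub / m$donor_mean_sub))
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("every cutoff combination emptied a mask")
  n_valid <- nrow(res)
  sds <- vapply(res, stats::sd, numeric(1))
  list(results = res, sd = sds, se = sds / sqrt(n_valid),
       n_valid = n_valid, n_failed = n_failed)
}

#' Read a multi-page TIFF as an IF channel array
#'
#' @param path TIFF file with three pages (DAPI, TdTomato, target).
#' @return h x w x 3 numeric array.
#' @export
read_if_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < 3) stop("expected a 3-page TIFF (DAPI, TdTomato, target)")
  arr <- simplify2array(pages[1:3])
  dimnames(arr) <- list(NULL, NULL, c("dapi", "tdt", "target"))
  arr
}

#' Write an IF channel array as a multi-page TIFF
#'
#' Intensities are stored as 16-bit after scaling by `max_value`.
#'
#' @param image h x w x 3 array.
#' @param path output file.
#' @param max_value intensity mapped to the maximum representable value.
#' @return invisibly, `path`.
#' @export
write_if_tiff <- function(image, path, max_value = max(image)) {
  pages <- lapply(seq_len(dim(image)[3]),
                  function(i) image[, , i] / max_value)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
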