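# Mask cutoffs used throughout: a high DAPI cutoff keeps only nucleus
# interiors (where the blurred channel is at full intensity) and a low
# TdTomato cutoff captures the whole blurred donor halo, so masks stay
# inside the true regions and the noiseless examples are exact.
interior_params <- function(roi = NULL)
  mask_params(sigma_dapi = 2, sigma_tdt = 2,
              dapi_cutoff = 90, tdt_cutoff = 1, roi = roi)

test_that("noiseless donor/host contrast is measured exactly", {
  img <- simulate_if_image(noise_sd = 0)   # donor 10, host 5, background 0
  m <- quantify_if(img$image, interior_params())
  expect_equal(m$donor_mean, 10)
  expect_equal(m$host_mean, 5)
  expect_equal(m$log2fc_within, 1)
})

test_that("background subtraction restores the planted ratio", {
  img <- simulate_if_image(donor_blobs = data.frame(x = c(40, 90),
                                                    y = c(40, 80), r = 10,
                                                    intensity = 12),
                           host_intensity = 7, background = 2, noise_sd = 0)
  # nucleus-free rectangle: image corner (half-open pixel coords)
  bg_roi <- c(110, 126, 108, 126)
  m <- quantify_if(img$image, interior_params(), background_roi = bg_roi)
  expect_equal(m$background_mean, 2)
  expect_equal(m$donor_mean, 14)  # 12 planted + 2 background
  expect_equal(m$host_mean, 9)
  expect_equal(m$donor_mean_sub, 12)
  expect_equal(m$log2fc_within_sub, log2(12 / 7))
  # within-chimera value on unsubtracted means is also reported
  expect_equal(m$log2fc_within, log2(14 / 9))
  # a background region touching nuclei is rejected
  expect_error(quantify_if(img$image, interior_params(),
                           background_roi = c(30, 60, 30, 60)),
               "overlaps DAPI")
})

test_that("masked means match truth-mask arithmetic under noise at SNR 10", {
  img <- simulate_if_image(noise_sd = 1, seed = 91)  # signal 10 vs sd 1
  m <- quantify_if(img$image, interior_params())
  truth <- img$truth
  target <- img$image[, , "target"]
  oracle_lfc <- log2(mean(target[truth$donor_mask]) /
                       mean(target[truth$host_mask]))
  expect_lt(abs(m$log2fc_within - oracle_lfc), 0.05)
  expect_lt(abs(m$log2fc_within - 1), 0.1)
})

test_that("masks are monotone in their cutoffs", {
  img <- simulate_if_image(noise_sd = 1, seed = 97)
  p_lo <- interior_params(); p_hi <- interior_params()
  p_hi$dapi_cutoff <- 95; p_hi$tdt_cutoff <- 50
  m_lo <- quantify_if(img$image, p_lo)
  m_hi <- quantify_if(img$image, p_hi)
  expect_lte(m_hi$n_donor_pixels, m_lo$n_donor_pixels)
  # affine rescaling of mask channels with rescaled cutoffs is a no-op
  img2 <- img$image
  img2[, , 1] <- img2[, , 1] * 3
  img2[, , 2] <- img2[, , 2] * 3
  p3 <- interior_params()
  p3$dapi_cutoff <- p3$dapi_cutoff * 3
  p3$tdt_cutoff <- p3$tdt_cutoff * 3
  m3 <- quantify_if(img2, p3)
  expect_equal(m3$log2fc_within, m_lo$log2fc_within)
  expect_equal(m3$n_donor_pixels, m_lo$n_donor_pixels)
})

test_that("empty masks are errors", {
  img <- simulate_if_image(noise_sd = 0)
  p <- interior_params()
  p$tdt_cutoff <- 1e6
  expect_error(quantify_if(img$image, p), "empty donor")
  p$dapi_cutoff <- 1e6
  expect_error(quantify_if(img$image, p), "empty")
})

test_that("protein quartets decompose with correct chimera orientation", {
  # pure extrinsic plant: donor matches host in both chimeras
  rat_like <- simulate_if_image(donor_blobs = data.frame(
    x = c(40, 90), y = c(40, 80), r = 10, intensity = 8),
    host_intensity = 8, noise_sd = 0)
  mouse_like <- simulate_if_image(donor_blobs = data.frame(
    x = c(40, 90), y = c(40, 80), r = 10, intensity = 2),
    host_intensity = 2, noise_sd = 0)
  mr <- quantify_if(rat_like$image, interior_params())
  mm <- quantify_if(mouse_like$image, interior_params())
  d <- if_decompose(mr, mm)
  expect_equal(d$E, 2)          # rat-like environment 4x higher
  expect_equal(d$I, 0)
  expect_equal(d$N, 0)
  expect_equal(d$Ep, 1)

  # relabeling the chimera orientation negates I and E, preserves N
  d_swap <- if_decompose(mm, mr)
  expect_equal(d_swap$I, -d$I)
  expect_equal(d_swap$E, -d$E)
  expect_equal(d_swap$N, d$N)
})

test_that("the 81-combination cutoff sweep has zero SE on clean images", {
  rat_like <- simulate_if_image(noise_sd = 0)         # donor 10, host 5
  mouse_like <- simulate_if_image(donor_blobs = data.frame(
    x = c(40, 90), y = c(40, 80), r = 10, intensity = 6),
    host_intensity = 4, noise_sd = 0)
  # well-separated cutoffs: all 81 combinations give identical masks
  sweep <- mask_robustness_sweep(
    rat_like$image, mouse_like$image,
    interior_params(), interior_params(),
    dapi_cutoffs = list(rat_like = c(85, 90, 95),
                        mouse_like = c(85, 90, 95)),
    tdt_cutoffs = list(rat_like = c(0.5, 1, 2),
                       mouse_like = c(0.5, 1, 2)))
  expect_equal(sweep$n_valid, 81)
  expect_equal(unname(sweep$se), rep(0, 4))
  expect_equal(sweep$results$lfc_within_rat_like[1], 1)

  # identical cutoffs trivially give identical results
  sweep2 <- mask_robustness_sweep(
    rat_like$image, mouse_like$image,
    interior_params(), interior_params(),
    dapi_cutoffs = list(rat_like = rep(90, 3), mouse_like = rep(90, 3)),
    tdt_cutoffs = list(rat_like = rep(1, 3), mouse_like = rep(1, 3)))
  expect_equal(unname(sweep2$sd), rep(0, 4))
})

test_that("moderate noise keeps the sweep SE small", {
  rat_like <- simulate_if_image(noise_sd = 1, seed = 101)
  mouse_like <- simulate_if_image(donor_blobs = data.frame(
    x = c(40, 90), y = c(40, 80), r = 10, intensity = 6),
    host_intensity = 4, noise_sd = 0.5, seed = 103)
  sweep <- mask_robustness_sweep(
    rat_like$image, mouse_like$image,
    interior_params(), interior_params(),
    dapi_cutoffs = list(rat_like = c(80, 90, 95),
                        mouse_like = c(80, 90, 95)),
    tdt_cutoffs = list(rat_like = c(0.5, 1, 2),
                       mouse_like = c(0.5, 1, 2)))
  expect_true(all(sweep$se < 0.05))
})

test_that("gaussian blur preserves flat regions and total mass", {
  m <- matrix(5, 30, 30)
  expect_equal(gaussian_blur(m, 2), m)
  set.seed(107)
  m2 <- matrix(runif(900), 30, 30)
  b <- gaussian_blur(m2, 1.5)
  # reflection padding conserves the overall mean approximately
  expect_equal(mean(b), mean(m2), tolerance = 0.01)
  expect_error(gaussian_blur(m, 0), "sigma")
})

test_that("channel arrays round-trip through multi-page TIFF", {
  img <- simulate_if_image(noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".tif")
  write_if_tiff(img$image, path)
  back <- read_if_tiff(path)
  rescaled <- back / max(back) * max(img$image)
  expect_equal(rescaled, img$image, tolerance = 0.01,
               ignore_attr = TRUE)
})
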