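test_that("empty plots render as soil and canopy grows with green matter", {
  rp <- render_params(patch_px = 32)
  empty <- render_plot_image(0, rp, seed = 1)
  expect_equal(dim(empty), c(32, 32, 3))
  expect_lt(green_fraction(empty), 0.05)
  expect_true(all(empty >= 0 & empty <= 1))

  rp0 <- render_params(patch_px = 32, hue_noise_sd = 0, texture_noise_sd = 0)
  g <- c(0.5, 1.5, 3, 6)
  fr <- sapply(seq_along(g), function(i) {
    green_fraction(render_plot_image(g[i], rp0, seed = 10 + i))
  })
  expect_true(all(diff(fr) > 0))
})

test_that("canopy fraction tracks green matter across a simulated trial", {
  lay <- make_layout(seed = 1)
  truth <- simulate_trial(lay, genetic_params(), seed = 2)
  imgs <- render_trial_images(truth, render_params(), seed = 3)
  fr <- vapply(imgs$image, green_fraction, numeric(1))
  rho <- cor(fr, truth$true_green_matter, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("mosaic dimensions follow the placement arithmetic", {
  lay <- small_layout(seed = 1)
  truth <- simulate_trial(lay, genetic_params(), seed = 2)
  rp <- render_params(patch_px = 32, mosaic_gap_px = 8)
  imgs <- render_trial_images(truth, rp, seed = 3)
  mosaic <- render_orthomosaic(lay, imgs, rp)
  n_rows <- attr(lay, "n_rows")
  n_cols <- attr(lay, "n_cols")
  expect_equal(dim(mosaic$raster)[1], n_rows * 32 + (n_rows + 1) * 8)
  expect_equal(dim(mosaic$raster)[2], n_cols * 32 + (n_cols + 1) * 8)

  expect_error(render_orthomosaic(lay, imgs[-1, ], rp), "Missing image")
})

test_that("extraction windows are disjoint, in-bounds and numbered both ways", {
  grid <- grid_config(origin_px = c(4, 4), patch_w_px = 10, patch_h_px = 10,
                      gap_x_px = 2, gap_y_px = 2, n_rows = 3, n_cols = 4,
                      numbering = "serpentine")
  raster <- array(runif(60 * 60 * 3), c(60, 60, 3))
  patches <- extract_plots(raster, grid)
  expect_equal(nrow(patches), 12)
  # pairwise disjoint windows
  for (i in 1:11) {
    for (j in (i + 1):12) {
      overlap_x <- max(0, min(patches$x1[i], patches$x1[j]) -
                          max(patches$x0[i], patches$x0[j]))
      overlap_y <- max(0, min(patches$y1[i], patches$y1[j]) -
                          max(patches$y0[i], patches$y0[j]))
      expect_equal(overlap_x * overlap_y, 0)
    }
  }
  # serpentine: plot 5 starts row 2 from the right-hand column
  expect_equal(patches$x0[5], 4 + 3 * 12)

  bad <- grid_config(origin_px = c(55, 0), patch_w_px = 10, patch_h_px = 10,
                     n_rows = 1, n_cols = 1)
  expect_error(extract_plots(raster, bad), "outside")
  expect_error(extract_plots(array(0, c(10, 10, 1)), grid), "3-band")
})

test_that("orthomosaic extraction is pixel-identical and PNG round-trips", {
  lay <- small_layout(seed = 2)
  truth <- simulate_trial(lay, genetic_params(), seed = 3)
  rp <- render_params(patch_px = 32, mosaic_gap_px = 4)
  imgs <- render_trial_images(truth, rp, seed = 4)
  mosaic <- render_orthomosaic(lay, imgs, rp)
  patches <- extract_plots(mosaic)
  expect_equal(nrow(patches), nrow(lay))
  img_of <- setNames(imgs$image, imgs$plot_id)
  for (id in lay$plot_id) {
    expect_identical(patches$image[[which(patches$plot_id == id)]],
                     img_of[[as.character(id)]])
  }

  # file round trip: 8-bit PNG quantization only
  path <- tempfile(fileext = ".png")
  write_mosaic(mosaic, path)
  back <- read_mosaic(path)
  expect_lt(max(abs(back$raster - mosaic$raster)), 1 / 255)
  p2 <- extract_plots(back)
  expect_equal(p2$plot_id, patches$plot_id)
})
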