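#' Rendering parameters for synthetic plot imagery
#'
#' Controls the synthetic canopy renderer: patch size, plant arrangement
#' (two rows of five plants per plot by default), the saturating mapping
#' from plot green matter to canopy cover, per-pixel colour noise, and the
#' background gap used when assembling an orthomosaic. The rendered signal
#' is deliberately simple — canopy cover is a noisy monotone function of
#' green matter — so an image regressor has a learnable but imperfect
#' yield signal.
#'
#' @param patch_px Side length of the square plot patch in pixels (>= 32).
#' @param plants_per_plot Number of plant canopies per plot (arranged in two
#'   rows).
#' @param canopy_gain Green-matter scale (kg) of the saturating cover curve
#'   `cover = cover_max * (1 - exp(-green_matter / canopy_gain))`.
#' @param cover_max Asymptotic canopy cover fraction.
#' @param hue_noise_sd,texture_noise_sd Per-pixel, per-channel Gaussian
#'   noise on canopy and soil colours (>= 0).
#' @param green_color,soil_color RGB triples in `[0, 1]`.
#' @param mosaic_gap_px Background gap between plots in the assembled
#'   mosaic.
#' @return A list of class `render_params`.
#' @export
render_params <- function(patch_px = 64,
                          plants_per_plot = 10,
                          canopy_gain = 3,
                          cover_max = 0.9,
                          hue_noise_sd = 0.05,
                          texture_noise_sd = 0.03,
                          green_color = c(0.20, 0.55, 0.15),
                          soil_color = c(0.45, 0.35, 0.25),
                          mosaic_gap_px = 8) {
  check_scalar(patch_px, "patch_px", lower = 32)
  check_scalar(hue_noise_sd, "hue_noise_sd", lower = 0)
  check_scalar(texture_noise_sd, "texture_noise_sd", lower = 0)
  check_scalar(canopy_gain, "canopy_gain", lower = 0, strict = TRUE)
  check_scalar(cover_max, "cover_max", lower = 0, upper = 1)
  check_scalar(mosaic_gap_px, "mosaic_gap_px", lower = 0)
  stopifnot(length(green_color) == 3L, length(soil_color) == 3L)
  structure(
    list(
      patch_px = as.integer(patch_px), plants_per_plot = plants_per_plot,
      canopy_gain = canopy_gain, cover_max = cover_max,
      hue_noise_sd = hue_noise_sd, texture_noise_sd = texture_noise_sd,
      green_color = green_color, soil_color = soil_color,
      mosaic_gap_px = as.integer(mosaic_gap_px)
    ),
    class = "render_params"
  )
}

# canopy cover fraction from green matter (kg): saturating, 0 at 0
canopy_cover <- function(green_matter, rp) {
  rp$cover_max * (1 - exp(-green_matter / rp$canopy_gain))
}

#' Render one synthetic plot patch
#'
#' Draws a square RGB patch: plant canopies (two jittered rows of plant
#' centres) over a soil background. Exactly `round(cover * patch_px^2)`
#' pixels — those nearest the plant centres — are canopy, where the cover
#' fraction is the saturating function of green matter defined by the
#' [render_params()]; the green-pixel count is therefore a strictly
#' increasing (up to single-pixel discreteness) function of green matter,
#' before colour noise.
#'
#' @param green_matter Plot green (fresh) matter in kg, or a one-row tibble
#'   from [simulate_trial()] (its `true_green_matter` is used).
#' @param rp A [render_params()] object.
#' @param seed Integer seed (placement jitter and colour noise).
#' @return An `patch_px x patch_px x 3` numeric array in `[0, 1]`.
#' @examples
#' img <- render_plot_image(3, render_params(), seed = 1)
#' dim(img)
#' @export
render_plot_image <- function(green_matter, rp = render_params(), seed = 1L) {
  stopifnot(inherits(rp, "render_params"))
  if (is.data.frame(green_matter)) {
    stopifnot(nrow(green_matter) == 1L, "true_green_matter" %in% names(green_matter))
    green_matter <- green_matter$true_green_matter
  }
  check_scalar(green_matter, "green_matter", lower = 0)
  set.seed(seed)
  px <- rp$patch_px
  npix <- px * px

  n_per_row <- ceiling(rp$plants_per_plot / 2)
  cx <- rep(px * (seq_len(n_per_row) - 0.5) / n_per_row, 2)[seq_len(rp$plants_per_plot)]
  cy <- rep(px * c(0.32, 0.68), each = n_per_row)[seq_len(rp$plants_per_plot)]
  cx <- cx + rnorm(rp$plants_per_plot, 0, px * 0.03)
  cy <- cy + rnorm(rp$plants_per_plot, 0, px * 0.03)

  xs <- matrix(rep(seq_len(px) - 0.5, each = px), px, px) # columns
  ys <- matrix(rep(seq_len(px) - 0.5, times = px), px, px) # rows
  d2 <- matrix(Inf, px, px)
  for (k in seq_len(rp$plants_per_plot)) {
    d2 <- pmin(d2, (xs - cx[k])^2 + (ys - cy[k])^2)
  }

  cover <- canopy_cover(green_matter, rp)
  n_green <- round(cover * npix)
  mask <- matrix(FALSE, px, px)
  if (n_green >= 1L) {
    ord <- order(as.vector(d2))[seq_len(min(n_green, npix))]
    mask[ord] <- TRUE
  }

  img <- array(0, dim = c(px, px, 3))
  for (ch in 1:3) {
    base <- ifelse(mask, rp$green_color[ch], rp$soil_color[ch])
    noise_sd <- ifelse(mask, rp$hue_noise_sd, rp$texture_noise_sd)
    img[, , ch] <- pmin(pmax(base + rnorm(npix, 0, 1) * noise_sd, 0), 1)
  }
  img
}

#' Render patches for every plot in a simulated trial
#'
#' @param truth A tibble from [simulate_trial()].
#' @param rp A [render_params()] object.
#' @param seed Base seed; plot `k` uses `seed + k` so patches are
#'   independently reproducible.
#' @return A tibble with `plot_id` and a list-column `image`.
#' @export
render_trial_images <- function(truth, rp = render_params(), seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("plot_id", "true_green_matter") %in% names(truth)))
  imgs <- purrr::map2(
    truth$true_green_matter, truth$plot_id,
    function(g, id) render_plot_image(g, rp, seed = seed + id)
  )
  tibble(plot_id = truth$plot_id, image = imgs)
}

#' Fraction of canopy (green) pixels in a patch
#'
#' Classifies pixels by the excess-green index `2G - R - B` against a fixed
#' threshold midway between the soil and canopy base colours. Used to
#' verify that rendered canopy cover tracks green matter.
#'
#' @param img An `H x W x 3` array in `[0, 1]`.
#' @param threshold Excess-green classification threshold.
#' @return Proportion of pixels classified as canopy.
#' @export
green_fraction <- function(img, threshold = 0.3) {
  exg <- 2 * img[, , 2] - img[, , 1] - img[, , 3]
  mean(exg > threshold)
}

#' Assemble plot patches into an orthomosaic raster
#'
#' Places one patch per plot on the layout's field grid, separated by a
#' uniform background gap, and records the grid metadata needed to slice
#' the raster back into pixel-identical patches.
#'
#' @param layout A [make_layout()] layout.
#' @param images A tibble with `plot_id` and list-column `image` (as from
#'   [render_trial_images()]), one patch per plot, all the same size.
#' @param rp A [render_params()] object (`mosaic_gap_px` and `soil_color`
#'   are used).
#' @return A list of class `htp_mosaic`: `raster` (H x W x 3 array) and
#'   `meta` (origin, patch size, gap, grid shape, numbering).
#' @export
render_orthomosaic <- function(layout, images, rp = render_params()) {
  stopifnot(inherits(layout, "htp_layout"), is.data.frame(images))
  if (nrow(layout) == 0L) abort("Empty layout.")
  if (!all(layout$plot_id %in% images$plot_id)) {
    missing_ids <- setdiff(layout$plot_id, images$plot_id)
    abort(paste0("Missing image for plot(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  sizes <- vapply(images$image, function(im) dim(im)[1:2], integer(2))
  if (any(sizes != sizes[1])) abort("All patches must have the same size.")
  ph <- sizes[1, 1]
  pw <- sizes[2, 1]
  gap <- rp$mosaic_gap_px
  n_rows <- attr(layout, "n_rows")
  n_cols <- attr(layout, "n_cols")
  H <- n_rows * ph + (n_rows + 1L) * gap
  W <- n_cols * pw + (n_cols + 1L) * gap

  raster <- array(rep(rp$soil_color, each = H * W), dim = c(H, W, 3))
  img_of <- stats::setNames(images$image, images$plot_id)
  for (k in seq_len(nrow(layout))) {
    r <- layout$field_row[k]
    cc <- layout$field_col[k]
    y0 <- gap + (r - 1L) * (ph + gap)
    x0 <- gap + (cc - 1L) * (pw + gap)
    raster[(y0 + 1L):(y0 + ph), (x0 + 1L):(x0 + pw), ] <-
      img_of[[as.character(layout$plot_id[k])]]
  }
  structure(
    list(
      raster = raster,
      meta = list(
        origin_px = c(x = gap, y = gap),
        patch_w_px = pw, patch_h_px = ph,
        gap_x_px = gap, gap_y_px = gap,
        n_rows = n_rows, n_cols = n_cols,
        numbering = attr(layout, "numbering"),
        expected_plots = nrow(layout)
      )
    ),
    class = "htp_mosaic"
  )
}

#' Write / read an orthomosaic as PNG plus a JSON grid sidecar
#'
#' The raster is stored as an 8-bit PNG and the grid metadata (origin,
#' patch size, gaps, grid shape, numbering) as a JSON sidecar so the
#' mosaic round-trips through [extract_plots()].
#'
#' @param mosaic An `htp_mosaic`.
#' @param path PNG path; the sidecar is `paste0(path, ".json")`.
#' @return `write_mosaic()` returns `path` invisibly; `read_mosaic()`
#'   returns an `htp_mosaic`.
#' @export
write_mosaic <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "htp_mosaic"))
  png::writePNG(mosaic$raster, path)
  jsonlite::write_json(mosaic$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  raster <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(raster = raster, meta = meta), class = "htp_mosaic")
}

#' @export
print.htp_mosaic <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf(
    "<htp_mosaic> %d x %d px, %d x %d plots of %d x %d px, gap %d px (%s)\n",
    d[1], d[2], x$meta$n_rows, x$meta$n_cols,
    x$meta$patch_h_px, x$meta$patch_w_px, x$meta$gap_x_px, x$meta$numbering
  ))
  invisible(x)
}
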