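#' Grid configuration for slicing an orthomosaic into plot patches
#'
#' Describes a uniform rectangular plot grid in pixel coordinates: the
#' top-left corner of the first plot, the plot footprint, inter-plot gaps,
#' the grid shape and the plot numbering rule. Pixel coordinates are
#' 0-based and windows are half-open `[x0, x1) x [y0, y1)`.
#'
#' @param origin_px Length-2 `(x, y)` of the first plot's top-left corner.
#' @param patch_w_px,patch_h_px Plot footprint in pixels.
#' @param gap_x_px,gap_y_px Gaps between adjacent plots (>= 0).
#' @param n_rows,n_cols Plot grid shape.
#' @param numbering `"row_major"` or `"serpentine"`.
#' @param expected_plots Number of plots to extract (defaults to
#'   `n_rows * n_cols`).
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(origin_px, patch_w_px, patch_h_px,
                        gap_x_px = 0, gap_y_px = 0,
                        n_rows, n_cols,
                        numbering = c("row_major", "serpentine"),
                        expected_plots = n_rows * n_cols) {
  numbering <- match.arg(numbering)
  stopifnot(
    length(origin_px) == 2L, all(origin_px >= 0),
    patch_w_px >= 1, patch_h_px >= 1, gap_x_px >= 0, gap_y_px >= 0,
    n_rows >= 1, n_cols >= 1
  )
  if (n_rows * n_cols < expected_plots) {
    abort("Grid too small for `expected_plots`.")
  }
  structure(
    list(
      origin_px = c(x = origin_px[[1]], y = origin_px[[2]]),
      patch_w_px = as.integer(patch_w_px), patch_h_px = as.integer(patch_h_px),
      gap_x_px = as.integer(gap_x_px), gap_y_px = as.integer(gap_y_px),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      numbering = numbering, expected_plots = as.integer(expected_plots)
    ),
    class = "grid_config"
  )
}

#' Grid configuration matching an assembled mosaic
#'
#' @param mosaic An `htp_mosaic` from [render_orthomosaic()] or
#'   [read_mosaic()].
#' @return The [grid_config()] that slices the mosaic back into its
#'   original patches.
#' @export
grid_config_from_mosaic <- function(mosaic) {
  m <- mosaic$meta
  origin <- if (!is.null(names(m$origin_px)) &&
                all(c("x", "y") %in% names(m$origin_px))) {
    c(m$origin_px[["x"]], m$origin_px[["y"]])
  } else {
    c(m$origin_px[[1]], m$origin_px[[2]]) # JSON sidecars drop names
  }
  grid_config(
    origin_px = origin,
    patch_w_px = m$patch_w_px, patch_h_px = m$patch_h_px,
    gap_x_px = m$gap_x_px, gap_y_px = m$gap_y_px,
    n_rows = m$n_rows, n_cols = m$n_cols,
    numbering = m$numbering, expected_plots = m$expected_plots
  )
}

#' Slice an orthomosaic into numbered plot patches
#'
#' Copies each plot's pixel window out of the raster (no resampling). Plot
#' `k` sits at grid position `(row, col)` given by the numbering rule; its
#' window starts at `origin + ((col-1) * (w + gap_x), (row-1) * (h + gap_y))`.
#'
#' @param mosaic An `htp_mosaic`, or a raw `H x W x 3` array.
#' @param grid A [grid_config()]; defaults to the mosaic's own metadata.
#' @return A tibble with `plot_id`, list-column `image`, and the 0-based
#'   half-open window coordinates `x0`, `y0`, `x1`, `y1`.
#' @export
extract_plots <- function(mosaic, grid = NULL) {
  if (inherits(mosaic, "htp_mosaic")) {
    raster <- mosaic$raster
    if (is.null(grid)) grid <- grid_config_from_mosaic(mosaic)
  } else {
    raster <- mosaic
    if (is.null(grid)) abort("`grid` is required when `mosaic` is a raw array.")
  }
  if (length(dim(raster)) != 3L || dim(raster)[3] != 3L) {
    abort("Raster must be a 3-band (RGB) array.")
  }
  stopifnot(inherits(grid, "grid_config"))
  H <- dim(raster)[1]
  W <- dim(raster)[2]

  out <- purrr::map_dfr(seq_len(grid$expected_plots), function(id) {
    row <- (id - 1L) %/% grid$n_cols + 1L
    col <- (id - 1L) %% grid$n_cols + 1L
    if (grid$numbering == "serpentine" && row %% 2L == 0L) {
      col <- grid$n_cols + 1L - col
    }
    x0 <- grid$origin_px[["x"]] + (col - 1L) * (grid$patch_w_px + grid$gap_x_px)
    y0 <- grid$origin_px[["y"]] + (row - 1L) * (grid$patch_h_px + grid$gap_y_px)
    x1 <- x0 + grid$patch_w_px
    y1 <- y0 + grid$patch_h_px
    if (x0 < 0 || y0 < 0 || x1 > W || y1 > H) {
      abort(sprintf(
        "Window for plot %d ([%d,%d) x [%d,%d)) lies outside the %d x %d raster.",
        id, x0, x1, y0, y1, W, H
      ))
    }
    tibble(
      plot_id = id,
      image = list(raster[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]),
      x0 = x0, y0 = y0, x1 = x1, y1 = y1
    )
  })
  out
}

#' Write extracted patches as PNG files with a manifest
#'
#' Saves each patch as `plot_%04d.png` under `dir` and writes
#' `manifest.csv` with the plot ids and window coordinates.
#'
#' @param patches A tibble from [extract_plots()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("plot_%04d.png", patches$plot_id))
  purrr::walk2(patches$image, paths, function(im, p) png::writePNG(im, p))
  manifest <- dplyr::select(patches, "plot_id", "x0", "y0", "x1", "y1") |>
    dplyr::mutate(path = basename(paths))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
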