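#' Generate an alpha-lattice-style trial layout
#'
#' Builds the design backbone of a forage breeding trial: one plot record per
#' replication x entry, with entries partitioned into randomized
#' incomplete blocks within each replication and laid out on a rectangular
#' field grid. The default mirrors a guineagrass progeny trial: 86 full-sib
#' families plus 10 sexual genitors, 10 apomictic genitors and 4 commercial
#' check cultivars (110 entries), 3 replications of 11 blocks x 10 plots,
#' 330 plots of 4.5 m2 on a 22-row x 15-column grid.
#'
#' The incomplete-block generator is deliberately simple: within each
#' replication the entries are shuffled and cut into `blocks_per_rep` equal
#' blocks whose order is also shuffled. The downstream mixed model only
#' consumes the rep/block/genotype labels, not the lattice's concurrence
#' structure.
#'
#' @param n_families Number of full-sib families (random genetic entries).
#' @param n_genitors_sexual,n_genitors_apomictic,n_checks Numbers of fixed
#'   (check-type) entries: sexual genitors, apomictic genitors, cultivar checks.
#' @param n_reps Number of complete replications.
#' @param blocks_per_rep Number of incomplete blocks within each replication;
#'   must divide the entry count.
#' @param n_rows,n_cols Field grid dimensions (plots). `n_rows * n_cols` must
#'   be at least `n_reps *` entries.
#' @param plot_area_m2 Net plot area in m2 (default 4.5).
#' @param numbering Plot numbering scheme on the grid: `"row_major"` or
#'   `"serpentine"` (alternate rows reversed).
#' @param seed Integer seed; the layout is deterministic given the seed.
#'
#' @return A tibble of class `htp_layout` with one row per plot and columns
#'   `plot_id`, `field_row`, `field_col`, `rep`, `block`, `genotype_id`,
#'   `genotype_class` (factor: `family`, `genitor_sexual`,
#'   `genitor_apomictic`, `cultivar_check`). Design constants are stored as
#'   attributes (`n_rows`, `n_cols`, `n_reps`, `blocks_per_rep`,
#'   `plot_area_m2`, `numbering`).
#' @examples
#' lay <- make_layout(seed = 1)
#' nrow(lay) # 330
#' @export
make_layout <- function(n_families = 86,
                        n_genitors_sexual = 10,
                        n_genitors_apomictic = 10,
                        n_checks = 4,
                        n_reps = 3,
                        blocks_per_rep = 11,
                        n_rows = 22,
                        n_cols = 15,
                        plot_area_m2 = 4.5,
                        numbering = c("row_major", "serpentine"),
                        seed = 1L) {
  numbering <- match.arg(numbering)
  check_scalar(plot_area_m2, "plot_area_m2", lower = 0, strict = TRUE)
  n_entries <- n_families + n_genitors_sexual + n_genitors_apomictic + n_checks
  if (n_entries < 1L || n_reps < 1L) {
    abort("Need at least one entry and one replication.")
  }
  if (n_entries %% blocks_per_rep != 0L) {
    abort(sprintf(
      "Block size must divide the entry count: %d entries cannot form %d equal blocks.",
      n_entries, blocks_per_rep
    ))
  }
  n_plots <- n_entries * n_reps
  if (n_rows * n_cols < n_plots) {
    abort(sprintf(
      "Field grid %d x %d holds %d plots but the design needs %d.",
      n_rows, n_cols, n_rows * n_cols, n_plots
    ))
  }

  pad_id <- function(prefix, n) {
    if (n == 0L) return(character(0))
    sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))
  }
  registry <- tibble(
    genotype_id = c(
      pad_id("F", n_families),
      pad_id("GS", n_genitors_sexual),
      pad_id("GA", n_genitors_apomictic),
      pad_id("CHK", n_checks)
    ),
    genotype_class = factor(
      rep(
        c("family", "genitor_sexual", "genitor_apomictic", "cultivar_check"),
        times = c(n_families, n_genitors_sexual, n_genitors_apomictic, n_checks)
      ),
      levels = c("family", "genitor_sexual", "genitor_apomictic", "cultivar_check")
    )
  )

  block_size <- n_entries %/% blocks_per_rep
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  per_rep <- withr_seed({
    purrr::map(seq_len(n_reps), function(r) {
      entry_order <- sample.int(n_entries)
      block_of <- rep(sample.int(blocks_per_rep), each = block_size)
      tibble(
        rep = r,
        block = block_of,
        genotype_id = registry$genotype_id[entry_order]
      ) |>
        dplyr::arrange(.data$block)
    })
  })
  plots <- dplyr::bind_rows(per_rep)
  plots$plot_id <- seq_len(n_plots)

  coords <- grid_coords(seq_len(n_plots), n_rows, n_cols, numbering)
  plots$field_row <- coords$row
  plots$field_col <- coords$col
  plots <- dplyr::left_join(plots, registry, by = "genotype_id") |>
    dplyr::select(
      "plot_id", "field_row", "field_col", "rep", "block",
      "genotype_id", "genotype_class"
    )

  out <- as_tibble(plots)
  attr(out, "n_rows") <- as.integer(n_rows)
  attr(out, "n_cols") <- as.integer(n_cols)
  attr(out, "n_reps") <- as.integer(n_reps)
  attr(out, "blocks_per_rep") <- as.integer(blocks_per_rep)
  attr(out, "plot_area_m2") <- plot_area_m2
  attr(out, "numbering") <- numbering
  attr(out, "registry") <- registry
  class(out) <- c("htp_layout", class(out))
  out
}

# plot_id -> (row, col) on the field grid for both numbering rules
grid_coords <- function(id, n_rows, n_cols, numbering) {
  id <- as.integer(id)
  row <- (id - 1L) %/% n_cols + 1L
  col <- (id - 1L) %% n_cols + 1L
  if (numbering == "serpentine") {
    rev_rows <- row %% 2L == 0L
    col[rev_rows] <- n_cols + 1L - col[rev_rows]
  }
  list(row = row, col = col)
}

# (row, col) -> plot_id; inverse of grid_coords
grid_plot_id <- function(row, col, n_cols, numbering) {
  col_eff <- col
  if (numbering == "serpentine") {
    rev_rows <- row %% 2L == 0L
    col_eff[rev_rows] <- n_cols + 1L - col[rev_rows]
  }
  (row - 1L) * n_cols + col_eff
}

#' @export
print.htp_layout <- function(x, ...) {
  cat(sprintf(
    "<htp_layout> %d plots, %d reps x %d blocks, grid %d x %d, plot %.2f m2\n",
    nrow(x), attr(x, "n_reps"), attr(x, "blocks_per_rep"),
    attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "plot_area_m2")
  ))
  NextMethod()
}
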