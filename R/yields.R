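#' Per-plot dry matter yields from field and laboratory weights
#'
#' Converts harvest records into plot-level dry matter yields by scaling the
#' sample component dry weights up to the whole plot:
#' `LDMY = TGMW * LDMW / SGW`, and likewise for the sheath+stem and
#' dead-material components; `TDMY` is their sum. All sample weights must be
#' in the same unit (grams here); the results inherit the unit of `tgmw_kg`
#' (kg per plot).
#'
#' @param samples A data frame with columns `plot_id`, `tgmw_kg` (total green
#'   matter weight per plot, kg), `sgw_g` (sample green weight, g) and the
#'   sample component dry weights `ldmw_g`, `ssdmw_g`, `dmdmw_g` (g).
#'
#' @return A tibble with `plot_id` and plot-scale yields `ldmy_kg`,
#'   `ssdmy_kg`, `dmdmy_kg`, `tdmy_kg`.
#' @examples
#' component_yields(data.frame(
#'   plot_id = 1, tgmw_kg = 10, sgw_g = 500,
#'   ldmw_g = 250, ssdmw_g = 200, dmdmw_g = 50
#' ))
#' @export
component_yields <- function(samples) {
  need <- c("plot_id", "tgmw_kg", "sgw_g", "ldmw_g", "ssdmw_g", "dmdmw_g")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    abort(paste0("`samples` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  num <- samples[setdiff(need, "plot_id")]
  if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
    abort("Weights must be non-negative.")
  }
  if (any(samples$tgmw_kg > 0 & samples$sgw_g == 0)) {
    abort("Sample green weight is zero on a plot with harvested green matter; the component ratios are undefined.")
  }
  comp_sum <- samples$ldmw_g + samples$ssdmw_g + samples$dmdmw_g
  if (any(comp_sum > samples$sgw_g * (1 + 1e-9))) {
    abort("Component dry weights exceed the sample green weight.")
  }
  ratio <- ifelse(samples$sgw_g > 0, samples$tgmw_kg / samples$sgw_g, 0)
  tibble(
    plot_id = samples$plot_id,
    ldmy_kg = ratio * samples$ldmw_g,
    ssdmy_kg = ratio * samples$ssdmw_g,
    dmdmy_kg = ratio * samples$dmdmw_g
  ) |>
    dplyr::mutate(tdmy_kg = .data$ldmy_kg + .data$ssdmy_kg + .data$dmdmy_kg)
}

#' Convert plot-scale yields to kg per hectare
#'
#' @param yields A data frame from [component_yields()] (columns ending in
#'   `_kg`).
#' @param plot_area_m2 Net plot area in m2 (> 0); default 4.5.
#'
#' @return The input tibble with an additional `_ha` column for every `_kg`
#'   column (`value_ha = value_kg * 10000 / plot_area_m2`).
#' @examples
#' y <- component_yields(data.frame(
#'   plot_id = 1, tgmw_kg = 10, sgw_g = 500,
#'   ldmw_g = 250, ssdmw_g = 200, dmdmw_g = 50
#' ))
#' yields_to_kg_ha(y, plot_area_m2 = 4.5)
#' @export
yields_to_kg_ha <- function(yields, plot_area_m2 = 4.5) {
  check_scalar(plot_area_m2, "plot_area_m2", lower = 0, strict = TRUE)
  kg_cols <- grep("_kg$", names(yields), value = TRUE)
  if (!length(kg_cols)) abort("No `_kg` yield columns found.")
  out <- as_tibble(yields)
  for (cl in kg_cols) {
    out[[sub("_kg$", "_ha", cl)]] <- out[[cl]] * 10000 / plot_area_m2
  }
  out
}
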