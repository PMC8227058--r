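#' Standardized selection intensity for truncation selection
#'
#' For a selected proportion `p` under a standard normal trait distribution,
#' the intensity is `i = phi(z) / p` with `z` the upper `p` truncation point
#' (`z = qnorm(1 - p)`) and `phi` the standard normal density. Full
#' precision is kept internally; round only for presentation (2 decimals
#' gives the conventional 1.76, 2.06, 2.67 for p = 10%, 5%, 1%).
#'
#' @param p Selected proportion(s) in (0, 1).
#' @return Selection intensity (standard-deviation units), vectorized over
#'   `p`.
#' @examples
#' round(selection_intensity(c(0.10, 0.05, 0.01)), 2)
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must be in (0, 1).")
  }
  dnorm(qnorm(1 - p)) / p
}

#' Selection intensity at presentation precision
#'
#' Quantitative-genetics practice quotes intensities from the standard
#' three-decimal tables (1.755, 2.063, 2.665 for 10%, 5%, 1%) and presents
#' them half-up rounded to two decimals (1.76, 2.06, 2.67). This helper
#' reproduces that convention: the exact intensity is first taken to three
#' decimals, then half-up rounded to `digits`.
#'
#' @param p Selected proportion(s) in (0, 1).
#' @param digits Presentation decimals (default 2).
#' @return Rounded intensity values.
#' @examples
#' printed_intensity(c(0.10, 0.05, 0.01)) # 1.76 2.06 2.67
#' @export
printed_intensity <- function(p, digits = 2) {
  half_up <- function(x, d) floor(x * 10^d + 0.5 + 1e-9) / 10^d
  half_up(half_up(selection_intensity(p), 3), digits)
}

#' Direct response to selection
#'
#' `DR = i * sqrt(H) * sqrt(Vg)` on the trait scale: the expected gain from
#' selecting directly on the measured trait with heritability `H` and
#' genetic variance `Vg` at selection intensity `i`.
#'
#' @param i Selection intensity (> 0).
#' @param H Broad-sense heritability of the selected trait, in `[0, 1]`.
#' @param Vg Genetic variance of the trait (>= 0).
#' @return Response in trait units (e.g. kg/ha).
#' @examples
#' direct_response(i = 1.76, H = 0.41, Vg = 44258) # ~237
#' @export
direct_response <- function(i, H, Vg) {
  if (any(!is.finite(H)) || any(H < 0) || any(H > 1)) {
    abort("`H` must be in [0, 1]; a negative heritability has no square root.")
  }
  if (any(Vg < 0)) abort("`Vg` must be non-negative.")
  i * sqrt(H) * sqrt(Vg)
}

#' Correlated response to indirect selection
#'
#' `CR = i * sqrt(H_htp) * r * sqrt(Vg_real)`: the expected gain in the real
#' trait when selection acts on a secondary (HTP) trait with heritability
#' `H_htp` and genetic correlation `r` to the real trait.
#'
#' @param i Selection intensity applied to the secondary trait.
#' @param H_htp Heritability of the secondary trait, in `[0, 1]`.
#' @param r Genetic correlation between secondary and real trait, `[-1, 1]`.
#' @param Vg_real Genetic variance of the real trait.
#' @return Response in real-trait units.
#' @examples
#' correlated_response(i = 1.76, H_htp = 0.45, r = 0.84, Vg_real = 44258) # ~209
#' @export
correlated_response <- function(i, H_htp, r, Vg_real) {
  if (any(!is.finite(H_htp)) || any(H_htp < 0) || any(H_htp > 1)) {
    abort("`H_htp` must be in [0, 1]; a negative heritability has no square root.")
  }
  if (any(abs(r) > 1)) abort("`r` must lie in [-1, 1].")
  if (any(Vg_real < 0)) abort("`Vg_real` must be non-negative.")
  i * sqrt(H_htp) * r * sqrt(Vg_real)
}

#' Default selection scenarios
#'
#' Three truncation-selection scenarios keeping the number of selected
#' families constant while the evaluated population grows: 10% selection in
#' the base trial, 5% in a doubled trial, and 1% in a ten-fold trial. Plot
#' and family counts are metadata; the genetic parameters are assumed
#' unchanged across scenario sizes.
#'
#' @param base_plots,base_families Size of the base trial.
#' @return A tibble with `label`, `p`, `n_plots`, `n_families`.
#' @export
selection_scenarios <- function(base_plots = 330, base_families = 86) {
  tibble(
    label = c("base 10%", "doubled 5%", "tenfold 1%"),
    p = c(0.10, 0.05, 0.01),
    n_plots = base_plots * c(1, 2, 10),
    n_families = base_families * c(1, 2, 10)
  )
}

#' Direct and correlated selection-response table
#'
#' Combines the genetic summaries of a real trait and its HTP counterpart
#' into a scenario table: the direct response `DR` is computed once at the
#' baseline (first) scenario from the real-trait parameters; the correlated
#' response `CR` is computed for every scenario from the HTP heritability,
#' the genetic correlation and the real genetic variance; `CR/DR` measures
#' the efficiency of indirect selection.
#'
#' Selection intensities are taken at presentation precision via
#' [printed_intensity()] (default 2 decimals: 1.76, 2.06, 2.67) before the
#' responses are computed; set `intensity_digits = NULL` to use full
#' precision instead.
#'
#' @param real A list or one-row data frame with `H` and `Vg` for the real
#'   trait.
#' @param htp A list or one-row data frame with `H` and `r` for the HTP
#'   trait (its correlation to the real trait).
#' @param scenarios A tibble as from [selection_scenarios()]; the first row
#'   is the baseline used for `DR`.
#' @param intensity_digits Decimals to which intensities are rounded before
#'   computing responses (`NULL` = no rounding).
#' @return A tibble of class `htp_selection` with one row per scenario:
#'   `label`, `p`, `i`, `n_plots`, `n_families`, `DR` (baseline value on
#'   every row), `CR`, `CR_DR`.
#' @examples
#' scenario_table(
#'   real = list(H = 0.41, Vg = 44258),
#'   htp = list(H = 0.45, r = 0.84)
#' )
#' @export
scenario_table <- function(real, htp, scenarios = selection_scenarios(),
                           intensity_digits = 2) {
  real <- as.list(real)
  htp <- as.list(htp)
  for (nm in c("H", "Vg")) {
    if (is.null(real[[nm]]) || !is.finite(real[[nm]])) {
      abort(sprintf("`real$%s` is missing.", nm))
    }
  }
  for (nm in c("H", "r")) {
    if (is.null(htp[[nm]]) || !is.finite(htp[[nm]])) {
      abort(sprintf("`htp$%s` is missing.", nm))
    }
  }
  if (nrow(scenarios) < 1L) abort("Need at least one scenario.")

  i_vals <- if (is.null(intensity_digits)) {
    selection_intensity(scenarios$p)
  } else {
    printed_intensity(scenarios$p, intensity_digits)
  }

  DR <- direct_response(i_vals[1], real$H, real$Vg)
  CR <- correlated_response(i_vals, htp$H, htp$r, real$Vg)

  out <- dplyr::mutate(
    as_tibble(scenarios),
    i = i_vals,
    DR = DR,
    CR = CR,
    CR_DR = CR / DR
  )
  class(out) <- c("htp_selection", class(out))
  out
}

#' @export
print.htp_selection <- function(x, digits = 2, ...) {
  cat("<htp_selection> responses to selection (baseline DR from first scenario)\n")
  fmt <- dplyr::mutate(
    as_tibble(x),
    DR = round(.data$DR), CR = round(.data$CR),
    CR_DR = round(.data$CR_DR, digits)
  )
  print(fmt, ...)
  invisible(x)
}
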