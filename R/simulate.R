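#' Genetic and sampling parameters for trial simulation
#'
#' Bundles the variance components of the plot-level mixed model
#' (`y = mu + rep + check/family + block + spatially correlated residual`),
#' the fixed check and replication deviations, and the sampling distributions
#' used to decompose total dry matter into leaf / sheath+stem / dead
#' components and back-calculate fresh (green) matter via a moisture
#' fraction.
#'
#' Defaults are calibrated to a guineagrass progeny trial on the
#' kg/ha scale of total dry matter yield: population mean 2000 kg/ha,
#' family variance 44258, block variance 20000, residual variance 100000
#' with AR1 correlations 0.3 along field rows and columns, field samples of
#' 300-500 g of green matter, and fresh-matter moisture between 0.65
#' and 0.80.
#'
#' @param mu Population mean total dry matter yield (kg/ha).
#' @param Vg Genetic variance among full-sib families ((kg/ha)^2).
#' @param Vb Variance of blocks within replications.
#' @param Ve Residual variance.
#' @param rho_row,rho_col AR1 residual correlations along field rows and
#'   columns, each in (-1, 1).
#' @param check_effects Fixed deviations (kg/ha) for check-class genotypes.
#'   Either a single number recycled to all checks, or a named vector keyed
#'   by genotype id. Default 0.
#' @param rep_effects Fixed deviations per replication (kg/ha), recycled as
#'   needed. Default `c(0, -100, 100)`.
#' @param leaf_frac_mean,leaf_frac_sd Mean/sd of the leaf share of plot dry
#'   matter.
#' @param dead_frac_mean,dead_frac_sd Mean/sd of the dead-material share.
#' @param moisture_range Interval for the water fraction of fresh matter,
#'   inside (0, 1).
#' @param sample_green_weight_range Interval (g) for the lab sample green
#'   weight, default `c(300, 500)`.
#'
#' @return A list of class `genetic_params`.
#' @examples
#' gp <- genetic_params(Vg = 30000)
#' @export
genetic_params <- function(mu = 2000,
                           Vg = 44258,
                           Vb = 20000,
                           Ve = 100000,
                           rho_row = 0.3,
                           rho_col = 0.3,
                           check_effects = 0,
                           rep_effects = c(0, -100, 100),
                           leaf_frac_mean = 0.55, leaf_frac_sd = 0.05,
                           dead_frac_mean = 0.10, dead_frac_sd = 0.03,
                           moisture_range = c(0.65, 0.80),
                           sample_green_weight_range = c(300, 500)) {
  check_scalar(Vg, "Vg", lower = 0)
  check_scalar(Vb, "Vb", lower = 0)
  check_scalar(Ve, "Ve", lower = 0)
  check_scalar(rho_row, "rho_row", lower = -1, upper = 1, strict = TRUE)
  check_scalar(rho_col, "rho_col", lower = -1, upper = 1, strict = TRUE)
  stopifnot(
    length(moisture_range) == 2L, all(moisture_range > 0), all(moisture_range < 1),
    moisture_range[1] <= moisture_range[2],
    length(sample_green_weight_range) == 2L, all(sample_green_weight_range > 0),
    leaf_frac_mean >= 0, leaf_frac_mean <= 1, leaf_frac_sd >= 0,
    dead_frac_mean >= 0, dead_frac_mean <= 1, dead_frac_sd >= 0
  )
  structure(
    list(
      mu = mu, Vg = Vg, Vb = Vb, Ve = Ve,
      rho_row = rho_row, rho_col = rho_col,
      check_effects = check_effects, rep_effects = rep_effects,
      leaf_frac_mean = leaf_frac_mean, leaf_frac_sd = leaf_frac_sd,
      dead_frac_mean = dead_frac_mean, dead_frac_sd = dead_frac_sd,
      moisture_range = moisture_range,
      sample_green_weight_range = sample_green_weight_range
    ),
    class = "genetic_params"
  )
}

#' Simulate per-plot true yields for a trial layout
#'
#' Draws one genetic effect per family (shared across its replicated plots)
#' from `N(0, Vg)`, block-within-rep effects from `N(0, Vb)`, and a residual
#' field from `N(0, Ve * R)` where `R` is the separable AR1(row) x AR1(col)
#' correlation over the occupied plot coordinates (sampled exactly via the
#' Cholesky factor of `R`). Check-class genotypes receive their fixed
#' deviations instead of family draws. Total dry matter yield is assembled
#' additively on the kg/ha scale and truncated at zero, then split into
#' leaf / sheath+stem / dead components by per-plot sampled fractions.
#' A per-plot moisture fraction converts plot dry matter (kg) into total
#' green (fresh) matter (kg).
#'
#' @param layout A layout from [make_layout()].
#' @param params A [genetic_params()] object.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#'
#' @return A tibble of class `htp_truth`: the layout columns plus
#'   `family_effect`, `block_effect`, `residual`, `moisture`,
#'   `true_tdmy`, `true_ldmy`, `true_ssdmy`, `true_dmdmy` (kg/ha) and
#'   `true_green_matter` (kg fresh matter per plot). The zero-truncation
#'   rate is stored in attribute `truncation_rate`.
#' @examples
#' lay <- make_layout(seed = 1)
#' truth <- simulate_trial(lay, genetic_params(), seed = 2)
#' @export
simulate_trial <- function(layout, params = genetic_params(), seed = 1L) {
  stopifnot(inherits(layout, "htp_layout"), inherits(params, "genetic_params"))
  n <- nrow(layout)
  area <- attr(layout, "plot_area_m2")
  set.seed(seed)

  is_family <- layout$genotype_class == "family"
  fam_ids <- sort(unique(layout$genotype_id[is_family]))
  fam_draw <- stats::setNames(rnorm(length(fam_ids), 0, sqrt(params$Vg)), fam_ids)

  check_ids <- sort(unique(layout$genotype_id[!is_family]))
  ce <- params$check_effects
  if (is.null(names(ce))) {
    ce <- stats::setNames(rep_len(ce, length(check_ids)), check_ids)
  } else if (!all(check_ids %in% names(ce))) {
    abort("Named `check_effects` must cover every check-class genotype.")
  }

  rep_eff <- rep_len(params$rep_effects, attr(layout, "n_reps"))

  block_key <- paste(layout$rep, layout$block, sep = ":")
  blocks <- unique(block_key)
  block_draw <- stats::setNames(rnorm(length(blocks), 0, sqrt(params$Vb)), blocks)

  R <- ar1_kron_ar1(params$rho_row, params$rho_col,
                    layout$field_row, layout$field_col)
  L <- chol(R)
  residual <- sqrt(params$Ve) * drop(crossprod(L, rnorm(n)))

  gen_eff <- unname(ifelse(is_family,
                           fam_draw[layout$genotype_id],
                           ce[layout$genotype_id]))
  tdmy_raw <- unname(params$mu + rep_eff[layout$rep] + gen_eff +
                       block_draw[block_key] + residual)
  tdmy <- pmax(tdmy_raw, 0)
  trunc_rate <- mean(tdmy_raw < 0)
  if (trunc_rate > 0) {
    warn(sprintf("%.1f%% of simulated plot yields truncated at 0.", 100 * trunc_rate))
  }

  leaf <- pmin(pmax(rnorm(n, params$leaf_frac_mean, params$leaf_frac_sd), 0), 1)
  dead <- pmin(pmax(rnorm(n, params$dead_frac_mean, params$dead_frac_sd), 0), 1)
  over <- leaf + dead > 1
  tot <- leaf + dead
  leaf[over] <- leaf[over] / tot[over]
  dead[over] <- dead[over] / tot[over]
  stem <- 1 - leaf - dead

  moisture <- runif(n, params$moisture_range[1], params$moisture_range[2])
  dry_kg <- tdmy * area / 10000
  green_kg <- dry_kg / (1 - moisture)

  out <- dplyr::mutate(
    as_tibble(layout),
    family_effect = ifelse(is_family, gen_eff, 0),
    block_effect = unname(block_draw[block_key]),
    residual = residual,
    moisture = moisture,
    true_ldmy = leaf * tdmy,
    true_ssdmy = stem * tdmy,
    true_dmdmy = dead * tdmy,
    true_tdmy = .data$true_ldmy + .data$true_ssdmy + .data$true_dmdmy,
    true_green_matter = green_kg
  )
  for (a in c("n_rows", "n_cols", "n_reps", "blocks_per_rep",
              "plot_area_m2", "numbering")) {
    attr(out, a) <- attr(layout, a)
  }
  attr(out, "truncation_rate") <- trunc_rate
  class(out) <- c("htp_truth", class(out))
  out
}

#' Derive field and laboratory sample weights from simulated truth
#'
#' Inverts the yield-component arithmetic: given each plot's true component
#' yields and green matter, emits the records a field crew and lab would
#' produce — total green matter weight per plot (TGMW, kg), sample green
#' weight (SGW, g) and sample component dry weights (g) — such that feeding
#' them back through [component_yields()] recovers the true yields exactly
#' (to floating-point round-off).
#'
#' @param truth A tibble from [simulate_trial()].
#' @param params The [genetic_params()] used (for the sample-weight range).
#' @param seed Integer seed for the sample green weight draws.
#'
#' @return A tibble with columns `plot_id`, `tgmw_kg`, `sgw_g`, `ldmw_g`,
#'   `ssdmw_g`, `dmdmw_g`.
#' @examples
#' lay <- make_layout(seed = 1)
#' truth <- simulate_trial(lay, genetic_params(), seed = 2)
#' fs <- derive_field_samples(truth, genetic_params(), seed = 3)
#' @export
derive_field_samples <- function(truth, params = genetic_params(), seed = 1L) {
  stopifnot(inherits(truth, "htp_truth"))
  area <- attr(truth, "plot_area_m2")
  n <- nrow(truth)
  set.seed(seed)

  tgmw <- truth$true_green_matter
  sgw <- runif(n, params$sample_green_weight_range[1],
               params$sample_green_weight_range[2])
  # a lab sample cannot exceed the harvested plot mass
  sgw <- pmin(sgw, tgmw * 1000)

  dry_kg <- function(ha) ha * area / 10000
  ratio <- ifelse(tgmw > 0, sgw / (tgmw * 1000), 0) # sample share of plot mass
  tibble(
    plot_id = truth$plot_id,
    tgmw_kg = tgmw,
    sgw_g = sgw,
    ldmw_g = dry_kg(truth$true_ldmy) * 1000 * ratio,
    ssdmw_g = dry_kg(truth$true_ssdmy) * 1000 * ratio,
    dmdmw_g = dry_kg(truth$true_dmdmy) * 1000 * ratio
  )
}
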