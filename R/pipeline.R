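#' Default run configuration
#'
#' The full pipeline — simulate, render, extract, train, metrics, genetics,
#' selection — at demonstration scale: 64-px patches, the compact
#' four-block CNN, 10 folds. Every block maps onto the corresponding
#' constructor's arguments and can be overridden from YAML.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(
    list(
      seed = 1L,
      out_dir = "htp-run",
      stages = c("simulate", "render", "extract", "train", "metrics",
                 "genetics", "selection"),
      layout = list(),
      genetic_params = list(),
      render = list(),
      arch = list(name = "macnn"),
      train = list(epochs = 100L, batch_size = 64L, early_stop_interval = 20L),
      cv = list(k = 10L, target = "tdmy_ha"),
      n_bins = 20L,
      selection = list()
    ),
    class = "run_config"
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected so typos fail before any stage runs; known
#' blocks are merged over [default_run_config()].
#'
#' @param path YAML file path, or a named list.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(unclass(base), user)
  known_stages <- c("simulate", "render", "extract", "train", "metrics",
                    "genetics", "selection")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad)) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Run the phenotyping-validation pipeline
#'
#' Executes the enabled stages in order on one simulated trial: generate
#' the design and true yields, derive field samples and recompute yields,
#' render plot images and the orthomosaic, extract patches, train the CNN
#' with k-fold out-of-fold prediction, evaluate prediction metrics, fit
#' the spatial mixed model to the real and HTP traits, and build the
#' selection-response table. Per-stage CSV/JSON artifacts are written under
#' `out_dir`, along with the fully-resolved configuration for provenance.
#'
#' The `selection` stage uses the fitted genetic parameters when the
#' `genetics` stage ran; alternatively supply them directly as
#' `config$selection$real` (list with `H`, `Vg`) and `config$selection$htp`
#' (list with `H`, `r`).
#'
#' @param config A `run_config`, a YAML path, or a named list of overrides.
#' @return Invisibly, a named list with the artifacts of each stage.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  seed <- config$seed
  res <- list()
  on_stage <- function(s) s %in% config$stages
  msg <- function(...) message(sprintf(...))

  if (on_stage("simulate")) {
    msg("stage simulate")
    layout <- do.call(make_layout, c(config$layout, list(seed = seed)))
    gp <- do.call(genetic_params, config$genetic_params)
    truth <- simulate_trial(layout, gp, seed = seed + 1L)
    samples <- derive_field_samples(truth, gp, seed = seed + 2L)
    yields <- yields_to_kg_ha(component_yields(samples),
                              plot_area_m2 = attr(layout, "plot_area_m2"))
    plot_table <- dplyr::left_join(as_tibble(truth), yields, by = "plot_id")
    write.csv(plot_table, file.path(config$out_dir, "plots.csv"),
              row.names = FALSE)
    res$layout <- layout
    res$truth <- truth
    res$samples <- samples
    res$yields <- yields
    res$plot_table <- plot_table
  }

  if (on_stage("render")) {
    stopifnot(!is.null(res$truth))
    msg("stage render")
    rp <- do.call(render_params, config$render)
    images <- render_trial_images(res$truth, rp, seed = seed + 3L)
    mosaic <- render_orthomosaic(res$layout, images, rp)
    write_mosaic(mosaic, file.path(config$out_dir, "orthomosaic.png"))
    res$render_params <- rp
    res$images <- images
    res$mosaic <- mosaic
  }

  if (on_stage("extract")) {
    stopifnot(!is.null(res$mosaic))
    msg("stage extract")
    patches <- extract_plots(res$mosaic)
    write_patches(patches, file.path(config$out_dir, "patches"))
    res$patches <- patches
  }

  if (on_stage("train")) {
    stopifnot(!is.null(res$patches), !is.null(res$yields))
    msg("stage train")
    target <- config$cv$target
    dat <- dplyr::inner_join(
      dplyr::select(res$patches, "plot_id", "image"),
      dplyr::select(res$yields, "plot_id", dplyr::all_of(target)),
      by = "plot_id"
    )
    spec <- do.call(arch_spec, config$arch)
    tcfg <- do.call(train_config, c(config$train, list(seed = seed + 4L)))
    cv <- crossval_predict(dat, target, spec, tcfg,
                           k = config$cv$k, seed = seed + 5L)
    write.csv(cv$predictions,
              file.path(config$out_dir, "htp_predictions.csv"),
              row.names = FALSE)
    res$cv <- cv
  }

  if (on_stage("metrics")) {
    stopifnot(!is.null(res$cv))
    msg("stage metrics")
    metr <- list(
      overall = regression_metrics(res$cv$predictions$y, res$cv$predictions$yhat),
      folds = res$cv$summary,
      histogram_intersection = histogram_intersection(
        res$cv$predictions$y, res$cv$predictions$yhat, n_bins = config$n_bins
      )
    )
    jsonlite::write_json(metr, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    res$metrics <- metr
  }

  if (on_stage("genetics")) {
    stopifnot(!is.null(res$plot_table))
    msg("stage genetics")
    target <- config$cv$target
    fit_real <- reml_fit(res$plot_table, trait = target)
    res$fit_real <- fit_real
    genetics <- glance(fit_real)
    if (!is.null(res$cv)) {
      htp_table <- dplyr::left_join(
        dplyr::select(as_tibble(res$plot_table), -dplyr::any_of("yhat")),
        dplyr::select(res$cv$predictions, "plot_id", "yhat"),
        by = "plot_id"
      )
      fit_htp <- reml_fit(htp_table, trait = "yhat")
      res$fit_htp <- fit_htp
      genetics <- dplyr::bind_rows(
        dplyr::mutate(genetics, origin = "real",
                      r = 1),
        dplyr::mutate(glance(fit_htp), origin = "htp",
                      r = genetic_correlation(fit_real, fit_htp))
      )
    }
    write.csv(genetics, file.path(config$out_dir, "genetics.csv"),
              row.names = FALSE)
    res$genetics <- genetics
  }

  if (on_stage("selection")) {
    msg("stage selection")
    sel_cfg <- config$selection
    real <- sel_cfg$real
    htp <- sel_cfg$htp
    if (is.null(real) || is.null(htp)) {
      if (is.null(res$fit_real) || is.null(res$fit_htp)) {
        abort("Selection stage needs either fitted genetics or explicit `selection$real`/`selection$htp` parameters.")
      }
      real <- real %||% list(H = res$fit_real$H, Vg = res$fit_real$theta$Vg)
      htp <- htp %||% list(
        H = res$fit_htp$H,
        r = genetic_correlation(res$fit_real, res$fit_htp)
      )
    }
    scen <- if (!is.null(sel_cfg$scenarios)) {
      dplyr::bind_rows(lapply(sel_cfg$scenarios, as_tibble))
    } else {
      selection_scenarios()
    }
    sel <- scenario_table(real, htp, scen)
    write.csv(sel, file.path(config$out_dir, "selection.csv"),
              row.names = FALSE)
    res$selection <- sel
  }

  invisible(res)
}
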