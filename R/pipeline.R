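#' Pipeline configuration
#'
#' Collects paths and tuning parameters for [run_pipeline()]. Defaults mirror
#' the standard analysis: kernel scale 1 /km (mean dispersal distance 1 km),
#' 1000 bootstrap draws, 100 simulation replicates, 15 cover classes, all
#' four candidate precipitation months.
#'
#' @param patches,occupancy,precipitation input CSV paths (see [read_patches()],
#'   [read_occupancy()], [read_precipitation()]); ignored when `synth` is set.
#' @param out output directory.
#' @param synth optional synthetic profile name (`"tiny"`, `"default"`,
#'   `"power"`); when set, inputs are generated into `out/inputs` instead of
#'   read from disk.
#' @param alpha dispersal-kernel scale (1/km).
#' @param draws parametric-bootstrap draws B.
#' @param replicates simulation replicates R.
#' @param classes cover classes k for the gradient summaries.
#' @param months precipitation months entering model selection.
#' @param seed master seed for every stochastic stage.
#' @param use_ranef propagate random-effect point predictions into forecasts.
#' @param sim_years number of years to simulate (default: the observed
#'   transition years).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(patches = NULL, occupancy = NULL,
                            precipitation = NULL, out = "metaspom-out",
                            synth = NULL, alpha = 1, draws = 1000,
                            replicates = 100, classes = 15, months = MONTHS,
                            seed = 1, use_ranef = TRUE, sim_years = NULL) {
  if (draws < 1 || replicates < 1) stop("draws and replicates must be >= 1")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(patches = patches, occupancy = occupancy,
                 precipitation = precipitation, out = out, synth = synth,
                 alpha = alpha, draws = draws, replicates = replicates,
                 classes = classes, months = months, seed = seed,
                 use_ranef = use_ranef, sim_years = sim_years),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override the defaults.
#' @param ... further overrides applied on top of the file.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading (or synthetic generation), turnover-event
#' assignment, per-species colonization/extinction model fitting with
#' weather-covariate selection, patch-state effect screens, parametric
#' bootstrap forecasting (per-year and per-cover-class summaries), and the
#' closed-loop metacommunity simulation. Every stage logs its parameters;
#' any failure aborts with the failing stage named. Outputs are plain CSV/JSON
#' files under `config$out`; a rerun with the identical config reproduces
#' them byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[metaspom] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  inputs <- stage("inputs", {
    if (!is.null(config$synth)) {
      fx <- make_fixture(config$synth, seed = config$seed,
                         dir = file.path(config$out, "inputs"))
      list(patches = fx$patches, history = fx$history, precip = fx$precip)
    } else {
      list(patches = read_patches(config$patches),
           history = read_occupancy(config$occupancy),
           precip = read_precipitation(config$precipitation))
    }
  })
  patches <- inputs$patches
  history <- inputs$history
  precip <- inputs$precip

  events <- stage("events", {
    ev <- lapply(SPECIES, function(sp) assign_turnover_events(history, sp))
    names(ev) <- SPECIES
    ev
  })

  fits <- stage("fit", {
    out <- list()
    for (sp in SPECIES) {
      out[[sp]] <- list()
      for (resp in c("colonization", "extinction")) {
        tab <- build_transition_table(history, patches, precip, sp, resp,
                                      alpha = config$alpha)
        sel <- tryCatch(select_weather_model(tab, covariate_terms(sp),
                                             months = config$months),
                        error = function(e) {
                          warning(sp, " ", resp, " model degenerate (",
                                  conditionMessage(e),
                                  "); using the empirical event rate")
                          keep <- complete.cases(tab[, c("outcome", covariate_terms(sp))])
                          fit <- degenerate_fit(tab[keep, , drop = FALSE],
                                                covariate_terms(sp))
                          list(best = fit, table = NULL)
                        })
        out[[sp]][[substr(resp, 1, 3)]] <- sel$best
        out[[sp]][[paste0(substr(resp, 1, 3), "_table")]] <- tab
        out[[sp]][[paste0(substr(resp, 1, 3), "_selection")]] <- sel$table %||% NULL
        say("  ", sp, " ", resp, ": AIC ", round(sel$best$aic, 1),
            ", terms [", paste(sel$best$terms, collapse = ", "), "]")
      }
    }
    out
  })

  screens <- stage("state-models", {
    out <- list()
    for (sp in SPECIES) for (resp in c("col", "ext")) {
      tab <- fits[[sp]][[paste0(resp, "_table")]]
      scr <- tryCatch(state_effect_screen(tab, fits[[sp]][[resp]]$terms),
                      error = function(e) {
                        warning("state screen ", sp, " ", resp, " skipped: ",
                                conditionMessage(e))
                        NULL
                      })
      out[[paste(sp, resp, sep = "_")]] <- scr
    }
    out
  })

  fc <- stage("forecast", {
    mods <- lapply(fits, function(f) list(col = f$col, ext = f$ext))
    ens <- bootstrap_predictions(mods, history, patches, precip,
                                 B = config$draws, seed = config$seed,
                                 alpha = config$alpha,
                                 use_ranef = config$use_ranef)
    list(ensemble = ens,
         by_year = summarize_forecast(ens, "year", "species"),
         by_year_state = summarize_forecast(ens, "year", "state"),
         by_cover = summarize_forecast(ens, "cover_class", "species",
                                       k = config$classes))
  })

  sim <- stage("simulate", {
    years <- history_years(history)
    sim_years <- if (is.null(config$sim_years)) years[-1] else
      (years[1] + 1L):(years[1] + config$sim_years)
    init <- history[, 1, SPECIES]
    init[is.na(init)] <- 0
    mods <- lapply(fits, function(f) list(col = f$col, ext = f$ext))
    simulate_ensemble(init, mods, patches, precip, sim_years,
                      R = config$replicates, alpha = config$alpha,
                      seed = config$seed)
  })

  paths <- stage("write", {
    p <- list()
    p$events <- file.path(config$out, "events.json")
    jsonlite::write_json(lapply(events, function(e) list(
      colonizations = nrow(e$colonizations),
      extinctions = nrow(e$extinctions),
      n_possible_col = e$n_possible_col, n_possible_ext = e$n_possible_ext,
      col_rate_pct = 100 * nrow(e$colonizations) / max(e$n_possible_col, 1),
      ext_rate_pct = 100 * nrow(e$extinctions) / max(e$n_possible_ext, 1),
      joint_col = e$n_joint_col, joint_ext = e$n_joint_ext)),
      p$events, auto_unbox = TRUE, digits = NA)

    p$fits <- file.path(config$out, "fits.json")
    jsonlite::write_json(lapply(fits, function(f) lapply(f[c("col", "ext")],
      function(ft) list(beta = as.list(ft$beta),
                        se = as.list(sqrt(diag(ft$vcov))),
                        sigma2_patch = ft$sigma2_patch,
                        sigma2_year = ft$sigma2_year,
                        loglik = ft$loglik, aic = ft$aic, n = ft$n,
                        r2 = suppressWarnings(r2_nakagawa(ft)),
                        var_share_pct = tryCatch(
                          as.list(fixed_effect_variance_share(ft)),
                          error = function(e) NULL)))),
      p$fits, auto_unbox = TRUE, digits = NA)

    p$state_rates <- file.path(config$out, "state_rates.csv")
    sr <- do.call(rbind, lapply(names(screens), function(nm) {
      scr <- screens[[nm]]
      if (is.null(scr)) return(NULL)
      cbind(model = nm, scr$rates, delta_aic = scr$delta_aic)
    }))
    write.csv(sr, p$state_rates, row.names = FALSE, quote = FALSE)

    p$forecast_year <- file.path(config$out, "forecast_year.csv")
    write.csv(fc$by_year, p$forecast_year, row.names = FALSE, quote = FALSE)
    p$forecast_states <- file.path(config$out, "forecast_states.csv")
    write.csv(fc$by_year_state, p$forecast_states, row.names = FALSE, quote = FALSE)
    p$forecast_cover <- file.path(config$out, "forecast_cover.csv")
    write.csv(fc$by_cover, p$forecast_cover, row.names = FALSE, quote = FALSE)

    p$sim_species <- file.path(config$out, "simulation_species.csv")
    write.csv(sim$summary_species, p$sim_species, row.names = FALSE, quote = FALSE)
    p$sim_states <- file.path(config$out, "simulation_states.csv")
    write.csv(sim$summary_states, p$sim_states, row.names = FALSE, quote = FALSE)

    p$report <- file.path(config$out, "report.json")
    obs_states <- state_distribution(history)
    jsonlite::write_json(list(
      seed = config$seed, alpha = config$alpha, draws = config$draws,
      replicates = config$replicates,
      n_patches = nrow(patches), years = history_years(history),
      observed_state_distribution = cbind(
        data.frame(year = as.integer(rownames(obs_states))),
        as.data.frame(obs_states)),
      delta_aic = lapply(screens, function(s) if (!is.null(s)) s$delta_aic)),
      p$report, auto_unbox = TRUE, digits = NA)
    p
  })
  say("done: ", length(paths), " artifact(s) in ", config$out)
  invisible(list(config = config, events = events, fits = fits,
                 screens = screens, forecast = fc, simulation = sim,
                 paths = paths))
}
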