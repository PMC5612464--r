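#' Default pipeline configuration
#'
#' A nested list describing a full analysis run: anchor overrides, the
#' (D0, p) configurations to fit, detection-curve candidates, scenario
#' settings, sensitivity settings, economics presets, the RNG seed and the
#' grid resolution. Unknown keys are rejected by [run_pipeline()].
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    anchors = list(),
    models = expand.grid(D0 = c(0.01, 0.05), p = c(2, 5, 15, 50, 125),
                         KEEP.OUT.ATTRS = FALSE),
    curves = list(families = c("linear", "parabola_up", "parabola_down",
                               "sigmoid"),
                  D_end_sets = list(`0.05` = c(0.075, 0.10, 0.15),
                                    `0.01` = c(0.02, 0.05, 0.10))),
    grid = 100L,
    scenarios = list(q_values = c(0.30, 0.23, 0.185),
                     overdiagnosis_alphas = c(0.01, 0.03, 0.10),
                     projections = TRUE),
    sensitivity = list(n = 2000L, sd_frac = 0.10,
                       params = c("I0", "D0", "r", "q", "d",
                                  "t4", "t5", "t6", "t7")),
    economics = list(nnt = 10, consultations_per_excision = c(1, 25),
                     cost_excision_event = 300, cost_consultation = 50,
                     excisions_per_life = c(50, 120)),
    seed = 1L
  )
}

# nested sections merge key-wise; everything else (notably the `models`
# data frame) is replaced wholesale
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (nm %in% c("scenarios", "sensitivity", "economics", "curves") &&
        is.list(user[[nm]]) && !is.data.frame(user[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(config) {
  known <- names(default_config())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  sections <- list(
    curves = c("families", "D_end_sets"),
    scenarios = c("q_values", "overdiagnosis_alphas", "projections"),
    sensitivity = c("n", "sd_frac", "params"),
    economics = c("nnt", "consultations_per_excision", "cost_excision_event",
                  "cost_consultation", "excisions_per_life"))
  for (sec in names(sections)) {
    bad <- setdiff(names(config[[sec]]), sections[[sec]])
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  ba <- setdiff(names(config$anchors), names(formals(anchor_set)))
  if (length(ba))
    stop("unknown anchor override(s): ", paste(ba, collapse = ", "))
  invisible(config)
}

# rolling polynomial hash of the deparsed config, used to stamp output
# files (pure double arithmetic, so no 32-bit integer overflow)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow: build the emulated registry series,
#' calibrate and fit every requested (D0, p) configuration, run the
#' retrospective secondary-prevention comparison (fitted versus
#' frozen-at-1982 detection), the tertiary-prevention (q) reductions, the
#' over-diagnosis overlays, the 2014-2028 projections (maintain / revert /
#' double policies), the one-at-a-time sensitivity analysis on the best
#' model, and the economics presets. Optionally writes JSON/CSV results
#' (stamped with a hash of the configuration) and diagnostic figures.
#'
#' @param config a configuration list (see [default_config()]).
#' @param outdir optional output directory; created if missing.
#' @param figures also write PNG figures (requires a working png device).
#' @param quiet suppress progress messages.
#' @return A list with all stage results (invisibly returns the same list
#'   after writing files when `outdir` is given).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         figures = FALSE, quiet = TRUE) {
  config <- merge_config(default_config(), config)
  validate_config(config)
  say <- function(...) if (!quiet) message(...)
  set.seed(as.integer(config$seed))

  say("stage 1/6: emulated registry series")
  anchors <- do.call(anchor_set, config$anchors)
  observed <- build_observed_series(anchors)
  projection <- build_projection_series(anchors, observed)

  say("stage 2/6: calibration and curve fitting")
  fits <- select_best_model(configs = config$models, anchors = anchors,
                            observed = observed,
                            families = config$curves$families,
                            D_end_sets = config$curves$D_end_sets,
                            n_grid = config$grid, quiet = quiet)

  say("stage 3/6: retrospective secondary-prevention comparison")
  retro <- lapply(fits$models, function(m) {
    fitted <- run_scenario(m, scenario_spec(c(1982L, 2013L), "fitted"))
    frozen <- run_scenario(m, scenario_spec(c(1982L, 2013L), "frozen"))
    cmp <- compare_scenarios(fitted, frozen)
    data.frame(D0 = m$config$D0, p = m$config$p, error = m$fit$error,
               TE = fitted$TE, TM = fitted$TM,
               EE = cmp$delta_excisions, RM = -cmp$delta_mortality,
               ratio = cmp$ratio)
  })
  retro <- do.call(rbind, retro)

  say("stage 4/6: tertiary prevention and over-diagnosis")
  best <- fits$models[[which.min(fits$summary$error)]]
  q_red <- do.call(rbind, lapply(config$scenarios$q_values, function(qv)
    data.frame(q = qv,
               reduction_1982_2013 = q_mortality_reduction(best, qv,
                                                           c(1982L, 2013L)),
               reduction_2014_2028 = q_mortality_reduction(best, qv,
                                                           c(2014L, 2028L)))))
  overd <- do.call(rbind, lapply(config$scenarios$overdiagnosis_alphas,
    function(al) data.frame(alpha = al,
                            excess_diagnoses = overdiagnosis_excess(best, al))))

  proj <- NULL
  if (isTRUE(config$scenarios$projections)) {
    say("stage 5/6: 2014-2028 projections")
    proj <- do.call(rbind, lapply(fits$models, function(m) {
      maintain <- project_2028(m, "maintain")
      frozen82 <- run_scenario(m, scenario_spec(c(2013L, 2028L), "frozen"))
      revert <- project_2028(m, "revert")
      cmp3 <- compare_scenarios(maintain, frozen82)
      cmp4 <- compare_scenarios(revert, maintain)
      data.frame(D0 = m$config$D0, p = m$config$p,
                 TE_maintain = maintain$TE, TM_maintain = maintain$TM,
                 EE_vs_frozen = cmp3$delta_excisions,
                 RM_vs_frozen = -cmp3$delta_mortality,
                 ratio_vs_frozen = cmp3$ratio,
                 TE_revert = revert$TE, TM_revert = revert$TM,
                 RE_vs_maintain = -cmp4$delta_excisions,
                 EM_vs_maintain = cmp4$delta_mortality,
                 ratio_revert = cmp4$ratio)
    }))
  }

  say("stage 6/6: sensitivity and economics")
  sens <- lapply(config$sensitivity$params, function(id)
    perturb_parameter(best, id, n = config$sensitivity$n,
                      sd_frac = config$sensitivity$sd_frac,
                      seed = config$seed))
  names(sens) <- config$sensitivity$params
  sens_summary <- do.call(rbind, lapply(sens, function(s)
    data.frame(param = s$param,
               sd_incidence = stats::sd(s$deviations[, 1]),
               sd_mortality = stats::sd(s$deviations[, 2]),
               sd_prevalence = stats::sd(s$deviations[, 3]))))

  eco <- config$economics
  economics <- do.call(rbind, lapply(eco$consultations_per_excision,
    function(cpe) data.frame(
      consultations_per_excision = cpe,
      nns = nns(cpe, eco$nnt, max(eco$excisions_per_life)),
      cost_per_excision = cost_per_excision(cpe, eco$cost_excision_event,
                                            eco$cost_consultation),
      cost_per_life_low = cost_per_life_saved(cpe, eco$nnt,
                                              eco$excisions_per_life,
                                              eco$cost_excision_event,
                                              eco$cost_consultation)[1],
      cost_per_life_high = cost_per_life_saved(cpe, eco$nnt,
                                               eco$excisions_per_life,
                                               eco$cost_excision_event,
                                               eco$cost_consultation)[2])))

  result <- list(config = config, config_hash = config_hash(config),
                 anchors = anchors, observed = observed,
                 projection = projection, models = fits$models,
                 model_summary = fits$summary, table_retrospective = retro,
                 q_reduction = q_red, overdiagnosis = overd,
                 table_projection = proj,
                 sensitivity = sens, sensitivity_summary = sens_summary,
                 economics = economics, seed = config$seed)

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir, figures, say)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir, figures, say) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- result$config_hash
  stamp <- function(x) c(list(config_hash = hash), x)

  json <- list(model_summary = result$model_summary,
               table_retrospective = result$table_retrospective,
               q_reduction = result$q_reduction,
               overdiagnosis = result$overdiagnosis,
               table_projection = result$table_projection,
               sensitivity_summary = result$sensitivity_summary,
               economics = result$economics, seed = result$seed)
  jsonlite::write_json(stamp(json), file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_series_csv(result$observed$incidence,
                   file.path(outdir, "observed_incidence.csv"))
  write_series_csv(result$observed$mortality,
                   file.path(outdir, "observed_mortality.csv"))
  utils::write.csv(result$table_retrospective,
                   file.path(outdir, "table_retrospective.csv"),
                   row.names = FALSE)
  if (!is.null(result$table_projection))
    utils::write.csv(result$table_projection,
                     file.path(outdir, "table_projection.csv"),
                     row.names = FALSE)
  log_lines <- c(sprintf("melmark %s", as.character(utils::packageVersion("melmark"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %d", result$seed),
                 sprintf("config_hash %s", hash),
                 sprintf("run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(log_lines, file.path(outdir, "run.log"))

  if (figures) {
    ok <- try({
      best <- result$models[[which.min(result$model_summary$error)]]
      grDevices::png(file.path(outdir, "fit.png"), 900, 600)
      plot_fit(best)
      grDevices::dev.off()
    }, silent = TRUE)
    if (inherits(ok, "try-error"))
      say("figure device unavailable; skipped figures")
  }
  say("outputs written to ", outdir)
  invisible(result)
}

#' Plot a fitted model against the emulated series
#'
#' Two-panel base-graphics plot of diagnostic incidence and melanoma
#' mortality: emulated observed series (lines) and model output (points).
#'
#' @param model a [fit_model()] result.
#' @return The model, invisibly.
#' @export
plot_fit <- function(model) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  obs <- model$observed
  graphics::plot(obs$incidence$year, obs$incidence$rate_per_100k,
                 type = "l", xlab = "year",
                 ylab = "diagnoses per 100,000/yr",
                 main = "diagnostic incidence")
  graphics::points(model$fit$model_incidence$year,
                   model$fit$model_incidence$rate_per_100k, pch = 20,
                   col = "steelblue")
  graphics::plot(obs$mortality$year, obs$mortality$rate_per_100k,
                 type = "l", xlab = "year",
                 ylab = "deaths per 100,000/yr", main = "melanoma mortality")
  graphics::points(model$fit$model_mortality$year,
                   model$fit$model_mortality$rate_per_100k, pch = 20,
                   col = "steelblue")
  invisible(model)
}
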