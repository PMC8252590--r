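#' Forest-plot data layout for a pooled estimate
#'
#' Lays out a pooled estimate and its inputs in the row order of a forest
#' plot: one row per cluster (normal-approximation CI from the input SE),
#' then the summary row (Hartung-Knapp CI), then the prediction-interval
#' row. Weight percentages are the random-effects weights.
#'
#' @param pooled a [pool()] result.
#' @return data.frame with columns `label`, `estimate`, `lower`, `upper`,
#'   `weight_pct`, `is_summary`, `is_pi`.
#' @seealso [write_forest_tsv()]
#' @export
render_forest_table <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  z <- stats::qnorm(1 - (1 - pooled$level) / 2)
  wpct <- 100 * pooled$weights / sum(pooled$weights)
  rows <- data.frame(
    label = pooled$labels,
    estimate = pooled$values,
    lower = pooled$values - z * pooled$ses,
    upper = pooled$values + z * pooled$ses,
    weight_pct = wpct,
    is_summary = FALSE, is_pi = FALSE,
    stringsAsFactors = FALSE
  )
  rows <- rbind(
    rows,
    data.frame(label = "Summary", estimate = pooled$value,
               lower = pooled$ci[1], upper = pooled$ci[2],
               weight_pct = 100, is_summary = TRUE, is_pi = FALSE),
    data.frame(label = "Prediction interval", estimate = pooled$value,
               lower = pooled$pi[1], upper = pooled$pi[2],
               weight_pct = NA_real_, is_summary = FALSE, is_pi = TRUE)
  )
  rownames(rows) <- NULL
  rows
}

#' @rdname render_forest_table
#' @param path output file path for a tab-separated rendering.
#' @export
write_forest_tsv <- function(pooled, path) {
  utils::write.table(render_forest_table(pooled), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a run configuration
#'
#' Type-checks a run configuration (parsed from YAML or JSON), rejects
#' unknown keys, fills defaults and returns the completed configuration.
#' Recognized keys: `cluster_col`, `outcome_col`, `terms` (candidate term
#' descriptors, see [spec_from_list()]), `forced_terms`, `direction`
#' (`forward`/`backward`), `loss`, `lambda`, `tau_estimator`,
#' `require_main_effects`, `c_stat_transform`, `alpha`.
#'
#' @param config a named list (e.g. `yaml::read_yaml(path)`).
#' @return The validated configuration with defaults filled, plus a
#'   `control` element holding the matching [siecv_control()]. Errors are
#'   classed `siecv_config_error` and name every offending key.
#' @export
run_config_validate <- function(config) {
  if (!is.list(config)) stop_config("configuration must be a named list")
  known <- c("cluster_col", "outcome_col", "terms", "forced_terms",
             "direction", "loss", "lambda", "tau_estimator",
             "require_main_effects", "c_stat_transform", "alpha",
             "min_improvement", "holdout_intercept")
  errors <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in c("cluster_col", "outcome_col")) {
    if (is.null(config[[key]]) || !is.character(config[[key]])) {
      errors <- c(errors, paste0("'", key, "' is required and must be a string"))
    }
  }
  defaults <- list(direction = "forward", loss = "re", lambda = 0.5,
                   tau_estimator = "REML", require_main_effects = FALSE,
                   c_stat_transform = "identity", alpha = 0.05,
                   min_improvement = 0, holdout_intercept = "pooled",
                   forced_terms = character())
  for (key in names(defaults)) {
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  }
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(config$direction %in% c("forward", "backward"),
      "'direction' must be forward or backward")
  chk(config$loss %in% c("mean", "re", "sd", "gini"),
      "'loss' must be one of mean, re, sd, gini")
  chk(is.numeric(config$lambda) && length(config$lambda) == 1 &&
        config$lambda >= 0 && config$lambda <= 1,
      "'lambda' must be a number in [0, 1]")
  chk(config$tau_estimator %in% c("REML", "DL", "PM"),
      "'tau_estimator' must be one of REML, DL, PM")
  chk(is.logical(config$require_main_effects) ||
        config$require_main_effects %in% c(0, 1),
      "'require_main_effects' must be logical")
  chk(config$c_stat_transform %in% c("identity", "logit"),
      "'c_stat_transform' must be identity or logit")
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "'alpha' must be in (0, 1)")
  chk(config$holdout_intercept %in% c("pooled", "reestimated"),
      "'holdout_intercept' must be pooled or reestimated")
  if (length(errors)) {
    stop_config("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  config$control <- siecv_control(
    loss = config$loss, lambda = config$lambda,
    tau_estimator = config$tau_estimator, alpha = config$alpha,
    require_main_effects = isTRUE(as.logical(config$require_main_effects)),
    c_stat_transform = config$c_stat_transform,
    min_improvement = config$min_improvement,
    holdout_intercept = config$holdout_intercept
  )
  config
}

# Serializable view of a trace: every number traces to a stored
# intermediate, nothing is recomputed at render time.
trace_to_list <- function(trace) {
  stopifnot(inherits(trace, "siecv_trace"))
  cyc <- lapply(trace$cycles, function(x) {
    list(cycle = x$cycle, direction = x$direction,
         candidates = x$candidates,
         selected = x$selected, loss = x$loss)
  })
  summaries <- lapply(trace$final_iecv$summaries, function(s) {
    list(value = s$value, se = s$se, tau = s$tau, tau2 = s$tau2,
         ci = s$ci, pi = s$pi, method = s$method, Q = s$Q)
  })
  list(
    schema = "siecv-trace/1",
    direction = trace$direction,
    stopping_reason = trace$stopping_reason,
    final_terms = I(term_names(trace$final_spec$included)),
    forced_terms = I(trace$final_spec$forced),
    control = unclass(trace$control),
    cycles = cyc,
    final_performance = summaries
  )
}

#' Write a stepwise-selection trace as JSON
#'
#' Serializes a [siecv()] trace (cycles, candidate losses, selected terms,
#' stopping reason, final-model pooled performance) to a versioned JSON
#' document. The algorithm is deterministic, so two runs on identical data
#' and configuration produce byte-identical files.
#'
#' @param trace a `siecv_trace`.
#' @param path output file path.
#' @export
write_trace_json <- function(trace, path) {
  json <- jsonlite::toJSON(trace_to_list(trace), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null",
                           dataframe = "rows")
  writeLines(json, path)
  invisible(path)
}

#' Plain-text run report
#'
#' Renders a stepwise run (trace plus optional global model) as a compact
#' human-readable report: configuration echo, per-cycle selections, final
#' coefficient table, and pooled performance with CIs and prediction
#' intervals. Rendering only reads stored results; it is idempotent and
#' side-effect-free.
#'
#' @param trace a `siecv_trace`.
#' @param global optional [fit_global()] result for the final model.
#' @return character vector of report lines (invisibly printed with
#'   `cat` when interactive use is wanted).
#' @export
render_run_report <- function(trace, global = NULL) {
  lines <- c(
    sprintf("Stepwise IECV run (%s), stopping reason: %s",
            trace$direction, trace$stopping_reason),
    sprintf("  loss: %s (lambda %g), tau estimator: %s",
            trace$control$loss, trace$control$lambda,
            trace$control$tau_estimator),
    "Cycles:"
  )
  for (cyc in trace$cycles) {
    lines <- c(lines, sprintf("  %d: %s (loss %.6f)", cyc$cycle,
                              if (is.na(cyc$selected)) "<stop>" else cyc$selected,
                              cyc$loss))
  }
  lines <- c(lines, paste("Final terms: intercept",
                          paste(term_names(trace$final_spec$included),
                                collapse = " + ")))
  if (!is.null(global)) {
    lines <- c(lines, "Global model (unshrunken | shrunken):")
    for (nm in names(global$coef)) {
      lines <- c(lines, sprintf("  %-20s %8.4f | %8.4f", nm,
                                global$coef[[nm]], global$coef_shrunken[[nm]]))
    }
    lines <- c(lines, sprintf("  shrinkage slope %.4f, intercept correction %.4f",
                              global$shrinkage$slope, global$shrinkage$cil))
  }
  for (m in names(trace$final_iecv$summaries)) {
    s <- trace$final_iecv$summaries[[m]]
    lines <- c(lines, sprintf(
      "  %-13s %6.3f  %d%% CI %6.3f:%6.3f  PI %6.3f:%6.3f",
      m, s$value, round(100 * s$level), s$ci[1], s$ci[2], s$pi[1], s$pi[2]))
  }
  lines
}
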