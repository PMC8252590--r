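#' Control parameters for IECV and stepwise selection
#'
#' @param loss aggregated loss family used to score candidate models:
#'   `"re"` (meta-analytic trade-off, the default), `"mean"`, `"sd"` or
#'   `"gini"`; see [aggregate_loss()].
#' @param lambda trade-off weight in \[0, 1\] for the `"re"` loss
#'   (1 = average performance only, 0 = heterogeneity only; default 0.5,
#'   equal weighting).
#' @param tau_estimator between-cluster variance estimator for all pooling:
#'   `"REML"` (default, with automatic DerSimonian-Laird fallback), `"DL"`
#'   or `"PM"`.
#' @param alpha 1 - confidence level for CIs and prediction intervals.
#' @param firth use Firth's penalization for per-cluster fits (default
#'   `TRUE`; disable only when all clusters are large).
#' @param require_main_effects if `TRUE`, an interaction term is eligible
#'   for inclusion only once all its constituent terms are in the model,
#'   and those constituents become unremovable while the interaction is
#'   present.
#' @param c_stat_transform pool c-statistics on the `"identity"` (default)
#'   or `"logit"` scale.
#' @param min_improvement minimum decrease in the aggregated loss required
#'   to continue another cycle (default 0: stop as soon as the best
#'   candidate does not improve on the previous cycle).
#' @param holdout_intercept intercept used when predicting in the hold-out
#'   cluster: `"pooled"` (default, the meta-analytic mean) or
#'   `"reestimated"` (re-estimated on the hold-out cluster's own data,
#'   emulating a local intercept update before validation).
#' @return A list of class `siecv_control`.
#' @export
siecv_control <- function(loss = c("re", "mean", "sd", "gini"),
                          lambda = 0.5,
                          tau_estimator = c("REML", "DL", "PM"),
                          alpha = 0.05,
                          firth = TRUE,
                          require_main_effects = FALSE,
                          c_stat_transform = c("identity", "logit"),
                          min_improvement = 0,
                          holdout_intercept = c("pooled", "reestimated")) {
  loss <- match.arg(loss)
  tau_estimator <- match.arg(tau_estimator)
  c_stat_transform <- match.arg(c_stat_transform)
  holdout_intercept <- match.arg(holdout_intercept)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop_config("lambda must be a single number in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must be in (0, 1)")
  }
  structure(
    list(loss = loss, lambda = lambda, tau_estimator = tau_estimator,
         alpha = alpha, firth = firth,
         require_main_effects = require_main_effects,
         c_stat_transform = c_stat_transform,
         min_improvement = min_improvement,
         holdout_intercept = holdout_intercept),
    class = "siecv_control"
  )
}

# Stage 1 of the two-stage approach: fit each cluster once, with Firth
# penalization and post-hoc intercept re-estimation. Clusters where the
# fit fails (single-class outcome, collinearity) are flagged unusable for
# development but remain available as hold-out validation clusters.
stage1_fits <- function(data, spec, control) {
  X <- build_design(data, spec)
  cl <- cluster_labels(data)
  y <- outcome(data)
  fits <- list()
  unusable <- character()
  for (k in data$clusters) {
    rows <- cl == k
    fit <- tryCatch({
      f <- fit_firth(X[rows, , drop = FALSE], y[rows], cluster = k,
                     firth = control$firth)
      reestimate_intercept(f, X[rows, , drop = FALSE], y[rows])
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning("cluster '", k, "' unusable for development: ",
              conditionMessage(fit), call. = FALSE)
      unusable <- c(unusable, k)
    } else {
      fits[[k]] <- fit
    }
  }
  list(X = X, fits = fits, unusable = unusable)
}

# Term-wise univariate random-effects pooling of a list of cluster fits.
pool_coefficients <- function(fits, method, level = 0.95) {
  terms <- names(fits[[1]]$coef)
  labels <- vapply(fits, `[[`, character(1), "cluster")
  pooled <- lapply(terms, function(tm) {
    pool(vapply(fits, function(f) f$coef[[tm]], numeric(1)),
         vapply(fits, function(f) f$se[[tm]], numeric(1)),
         method = method, level = level, labels = labels)
  })
  names(pooled) <- terms
  pooled
}

#' Internal-external cross-validation of a fixed model
#'
#' Runs the two-stage IECV loop for one model specification: every cluster
#' is fit once ([fit_firth()] + [reestimate_intercept()]); then each
#' cluster h in turn is held out, the remaining clusters' coefficients are
#' pooled term-wise by univariate random-effects meta-analysis, the pooled
#' model predicts cluster h, and hold-out performance is computed. Finally
#' each performance metric is pooled across the K hold-out clusters with a
#' Hartung-Knapp CI and an approximate prediction interval.
#'
#' A cluster whose stage-1 fit fails is excluded from development pooling
#' with a warning but still validated against; if fewer than 3 clusters
#' remain usable for development the procedure stops with an error.
#'
#' @param data a [clustered_dataset()].
#' @param spec a [model_spec()] (its `included` terms define the model) or
#'   a plain list of terms.
#' @param control a [siecv_control()].
#' @param metrics which hold-out metrics to compute (default all four).
#' @return An object of class `iecv_result`: `fits` (per-cluster stage-1
#'   fits), `unusable` (clusters excluded from development),
#'   `holdout` (per cluster: pooled development `coef`, `pred` with
#'   `lp`/`prob`, and `perf`), `summaries` (a [pool()] result per metric),
#'   `clusters`, `spec`, `control`.
#' @export
iecv <- function(data, spec, control = siecv_control(),
                 metrics = c("mse", "cal_slope", "cal_in_large", "c_statistic")) {
  stopifnot(inherits(data, "clustered_dataset"))
  if (!inherits(spec, "model_spec")) spec <- model_spec(included = spec)
  s1 <- stage1_fits(data, spec, control)
  usable <- setdiff(data$clusters, s1$unusable)
  if (length(usable) < 3) {
    stop_estimation("fewer than 3 clusters usable for development; ",
                    "IECV is unreliable and prediction intervals are undefined")
  }
  cl <- cluster_labels(data)
  y <- outcome(data)
  level <- 1 - control$alpha

  holdout <- list()
  for (h in data$clusters) {
    dev <- s1$fits[setdiff(usable, h)]
    pooled <- pool_coefficients(dev, control$tau_estimator, level)
    coef <- vapply(pooled, `[[`, numeric(1), "value")
    rows <- cl == h
    Xh <- s1$X[rows, , drop = FALSE]
    yh <- y[rows]
    if (control$holdout_intercept == "reestimated" &&
        sum(yh) >= 1 && sum(1 - yh) >= 1) {
      off <- if (ncol(Xh) > 1) drop(Xh[, -1, drop = FALSE] %*% coef[-1]) else rep(0, length(yh))
      one <- matrix(1, length(yh), 1, dimnames = list(NULL, "(Intercept)"))
      loc <- fit_firth(one, yh, cluster = h, firth = FALSE, offset = off)
      coef[1] <- loc$coef[1]
    }
    pred <- predict_risk(coef, Xh)
    perf <- holdout_performance(yh, pred, cluster = h, metrics = metrics)
    holdout[[h]] <- list(coef = coef, pooled = pooled, pred = pred,
                         perf = perf)
  }

  out <- structure(
    list(fits = s1$fits, unusable = s1$unusable, holdout = holdout,
         summaries = list(), clusters = data$clusters,
         spec = spec, control = control),
    class = "iecv_result"
  )
  out$summaries <- summarize_performance(out, metrics)
  out
}

# Pool each metric across the hold-out clusters (flagged NA estimates are
# dropped); c-statistics may be pooled on the logit scale.
summarize_performance <- function(result, metrics) {
  control <- result$control
  level <- 1 - control$alpha
  summaries <- list()
  for (m in metrics) {
    ests <- lapply(result$holdout, function(hh) hh$perf[[m]])
    keep <- !vapply(ests, function(e) is.na(e$value), logical(1))
    ests <- ests[keep]
    if (length(ests) < 2) next
    v <- vapply(ests, `[[`, numeric(1), "value")
    s <- vapply(ests, `[[`, numeric(1), "se")
    lab <- vapply(ests, `[[`, character(1), "cluster")
    summaries[[m]] <- if (m == "c_statistic") {
      pool_transformed(v, s, transform = control$c_stat_transform,
                       method = control$tau_estimator, level = level,
                       labels = lab)
    } else {
      pool(v, s, method = control$tau_estimator, level = level, labels = lab)
    }
  }
  summaries
}

# Recompute the remaining metrics for a result whose hold-out predictions
# were already produced (candidate scans only compute the MSE; the
# selected model per cycle gets the full set without refitting stage 1).
augment_metrics <- function(result, data,
                            metrics = c("mse", "cal_slope", "cal_in_large",
                                        "c_statistic")) {
  cl <- cluster_labels(data)
  y <- outcome(data)
  for (h in names(result$holdout)) {
    yh <- y[cl == h]
    result$holdout[[h]]$perf <-
      holdout_performance(yh, result$holdout[[h]]$pred, cluster = h,
                          metrics = metrics)
  }
  result$summaries <- summarize_performance(result, metrics)
  result
}

#' @export
print.iecv_result <- function(x, ...) {
  cat("IECV over", length(x$clusters), "clusters",
      if (length(x$unusable)) paste0("(", length(x$unusable),
                                     " excluded from development)"), "\n")
  for (m in names(x$summaries)) {
    s <- x$summaries[[m]]
    cat(sprintf("  %-13s %6.3f  CI %6.3f to %6.3f  PI %6.3f to %6.3f  tau %.3f\n",
                m, s$value, s$ci[1], s$ci[2], s$pi[1], s$pi[2], s$tau))
  }
  invisible(x)
}

#' Interaction eligibility under the main-effects constraint
#'
#' When `require_main_effects` is on, an interaction term may enter the
#' model only if every one of its constituent terms is already included,
#' and while an interaction is included its constituents may not be
#' removed. With the option off every candidate is always eligible.
#'
#' @param spec a [model_spec()] (its `included` list is consulted).
#' @param candidate the candidate term.
#' @param require_main_effects the option flag (see [siecv_control()]).
#' @return `TRUE` if the candidate may enter the model.
#' @export
interaction_guard <- function(spec, candidate, require_main_effects = TRUE) {
  if (!require_main_effects) return(TRUE)
  if (candidate$kind != "interaction") return(TRUE)
  all(candidate$source %in% term_names(spec$included))
}

# Terms locked against backward removal: forced terms plus, under the
# main-effects constraint, constituents of included interactions.
locked_terms <- function(spec, require_main_effects) {
  locked <- spec$forced
  if (require_main_effects) {
    for (t in spec$included) {
      if (t$kind == "interaction") locked <- union(locked, t$source)
    }
  }
  locked
}

evaluate_candidate <- function(data, terms, control) {
  res <- iecv(data, model_spec(included = terms), control, metrics = "mse")
  perf <- lapply(res$holdout, function(hh) hh$perf$mse)
  loss <- aggregate_loss(perf, family = control$loss,
                         lambda = control$lambda,
                         method = control$tau_estimator)
  list(result = res, loss = loss)
}

#' Stepwise internal-external cross-validation
#'
#' Greedy predictor selection driven by out-of-cluster generalizability.
#' Cycle 0 evaluates the base model (the intercept plus any forced terms)
#' by [iecv()] and scores its hold-out MSEs with the configured aggregated
#' loss. Each subsequent cycle extends the current model with every
#' remaining eligible candidate in turn, scores each extension the same
#' way, and keeps the candidate with the smallest loss (ties broken by
#' candidate order). The algorithm stops when the best extension no longer
#' improves on the previous cycle (`no_improvement`; the previous model is
#' returned) or when all candidates have been included
#' (`candidates_exhausted`). The procedure is fully deterministic: a fixed
#' dataset and configuration reproduce the trace bit for bit.
#'
#' Candidate models are scored on the hold-out mean squared error; the
#' full set of performance metrics (calibration slope,
#' calibration-in-the-large, c-statistic) is computed for each cycle's
#' selected model only.
#'
#' @param data a [clustered_dataset()].
#' @param spec a [model_spec()]: `included` (with `forced`) is the base
#'   model, `candidates` the terms considered for inclusion.
#' @param control a [siecv_control()].
#' @return An object of class `siecv_trace`: `cycles` (per cycle: the
#'   candidate losses, the selected term and its loss, and the selected
#'   model's full `iecv_result`), `stopping_reason`, `final_spec`,
#'   `final_iecv` (full-metric IECV of the final model), `direction`,
#'   `control`.
#' @seealso [siecv_backward()], [fit_global()]
#' @export
siecv <- function(data, spec, control = siecv_control()) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$candidates) == 0) stop_config("no candidate terms to select from")
  current <- spec$included
  remaining <- spec$candidates
  base <- evaluate_candidate(data, current, control)
  base$result <- augment_metrics(base$result, data)
  cycles <- list(list(
    cycle = 0, direction = "forward",
    candidates = data.frame(term = "(none)", loss = base$loss$value,
                            evaluated = TRUE, stringsAsFactors = FALSE),
    selected = "(none)", loss = base$loss$value
  ))
  best_prev <- base$loss$value
  selected_result <- base$result
  reason <- "candidates_exhausted"

  while (length(remaining) > 0) {
    cand_names <- term_names(remaining)
    losses <- rep(NA_real_, length(remaining))
    evaluated <- rep(FALSE, length(remaining))
    results <- vector("list", length(remaining))
    cur_spec <- model_spec(included = current,
                           forced = intersect(spec$forced, term_names(current)))
    for (j in seq_along(remaining)) {
      if (!interaction_guard(cur_spec, remaining[[j]],
                             control$require_main_effects)) next
      ev <- tryCatch(
        evaluate_candidate(data, c(current, remaining[j]), control),
        error = function(e) e
      )
      if (inherits(ev, "error")) {
        warning("candidate '", cand_names[j], "' skipped this cycle: ",
                conditionMessage(ev), call. = FALSE)
        next
      }
      losses[j] <- ev$loss$value
      evaluated[j] <- TRUE
      results[[j]] <- ev$result
    }
    if (!any(evaluated)) {
      reason <- "candidates_exhausted"
      break
    }
    best_j <- which(losses == min(losses, na.rm = TRUE))[1]
    cyc <- list(
      cycle = length(cycles), direction = "forward",
      candidates = data.frame(term = cand_names, loss = losses,
                              evaluated = evaluated, stringsAsFactors = FALSE),
      selected = cand_names[best_j], loss = losses[best_j]
    )
    if (losses[best_j] >= best_prev - control$min_improvement) {
      cyc$selected <- NA_character_
      cycles[[length(cycles) + 1]] <- cyc
      reason <- "no_improvement"
      break
    }
    cycles[[length(cycles) + 1]] <- cyc
    current <- c(current, remaining[best_j])
    remaining <- remaining[-best_j]
    best_prev <- losses[best_j]
    selected_result <- augment_metrics(results[[best_j]], data)
    cycles[[length(cycles)]]$iecv <- selected_result
  }

  final_spec <- model_spec(included = current,
                           forced = intersect(spec$forced, term_names(current)))
  structure(
    list(cycles = cycles, stopping_reason = reason,
         final_spec = final_spec, final_iecv = selected_result,
         direction = "forward", control = control),
    class = "siecv_trace"
  )
}

#' Backward stepwise internal-external cross-validation
#'
#' Mirror of [siecv()]: starts from the full model (all candidates
#' included) and each cycle evaluates the removal of every removable term,
#' removing the one whose absence minimizes the aggregated loss; stops
#' when no removal improves on the current model. Forced terms — and,
#' under the main-effects constraint, constituents of included
#' interactions — are never removal candidates.
#'
#' @inheritParams siecv
#' @param spec a [model_spec()] whose `included` terms form the full
#'   starting model; `forced` marks unremovable terms.
#' @return A `siecv_trace` (see [siecv()]) with `direction = "backward"`.
#' @export
siecv_backward <- function(data, spec, control = siecv_control()) {
  stopifnot(inherits(spec, "model_spec"))
  current <- spec$included
  base <- evaluate_candidate(data, current, control)
  base$result <- augment_metrics(base$result, data)
  cycles <- list(list(
    cycle = 0, direction = "backward",
    candidates = data.frame(term = "(none)", loss = base$loss$value,
                            evaluated = TRUE, stringsAsFactors = FALSE),
    selected = "(none)", loss = base$loss$value
  ))
  best_prev <- base$loss$value
  selected_result <- base$result
  reason <- "candidates_exhausted"

  repeat {
    cur_spec <- model_spec(included = current,
                           forced = intersect(spec$forced, term_names(current)))
    locked <- locked_terms(cur_spec, control$require_main_effects)
    removable <- which(!term_names(current) %in% locked)
    if (length(removable) == 0) {
      reason <- "candidates_exhausted"
      break
    }
    cand_names <- term_names(current)[removable]
    losses <- rep(NA_real_, length(removable))
    evaluated <- rep(FALSE, length(removable))
    results <- vector("list", length(removable))
    for (jj in seq_along(removable)) {
      ev <- tryCatch(
        evaluate_candidate(data, current[-removable[jj]], control),
        error = function(e) e
      )
      if (inherits(ev, "error")) {
        warning("removal of '", cand_names[jj], "' skipped this cycle: ",
                conditionMessage(ev), call. = FALSE)
        next
      }
      losses[jj] <- ev$loss$value
      evaluated[jj] <- TRUE
      results[[jj]] <- ev$result
    }
    if (!any(evaluated)) {
      reason <- "candidates_exhausted"
      break
    }
    best_j <- which(losses == min(losses, na.rm = TRUE))[1]
    cyc <- list(
      cycle = length(cycles), direction = "backward",
      candidates = data.frame(term = cand_names, loss = losses,
                              evaluated = evaluated, stringsAsFactors = FALSE),
      selected = cand_names[best_j], loss = losses[best_j]
    )
    if (losses[best_j] >= best_prev - control$min_improvement) {
      cyc$selected <- NA_character_
      cycles[[length(cycles) + 1]] <- cyc
      reason <- "no_improvement"
      break
    }
    cycles[[length(cycles) + 1]] <- cyc
    current <- current[-removable[best_j]]
    best_prev <- losses[best_j]
    selected_result <- augment_metrics(results[[best_j]], data)
    cycles[[length(cycles)]]$iecv <- selected_result
    if (length(current) == 0) {
      reason <- "candidates_exhausted"
      break
    }
  }

  final_spec <- model_spec(included = current,
                           forced = intersect(spec$forced, term_names(current)))
  structure(
    list(cycles = cycles, stopping_reason = reason,
         final_spec = final_spec, final_iecv = selected_result,
         direction = "backward", control = control),
    class = "siecv_trace"
  )
}

#' @export
print.siecv_trace <- function(x, ...) {
  cat("Stepwise IECV (", x$direction, "), ", length(x$cycles), " cycles, stopped: ",
      x$stopping_reason, "\n", sep = "")
  for (cyc in x$cycles) {
    cat(sprintf("  cycle %d: selected %s (loss %.6f)\n", cyc$cycle,
                if (is.na(cyc$selected)) "<none>" else cyc$selected, cyc$loss))
  }
  cat("Final model:\n")
  print(x$final_spec)
  invisible(x)
}

#' Global model with shrinkage from the final IECV cycle
#'
#' Fits the final model on all K clusters (no hold-out) by pooling all
#' per-cluster fits term-wise, then attaches shrinkage factors taken from
#' the final cycle's IECV summaries: the slope coefficients are multiplied
#' by the summary calibration slope, and the summary
#' calibration-in-the-large is added to the intercept. With a summary
#' slope of 1 and a summary CIL of 0 the shrunken and unshrunken
#' coefficients coincide.
#'
#' @param data a [clustered_dataset()].
#' @param spec the final [model_spec()] (or list of terms).
#' @param final_iecv the `iecv_result` of the final model (e.g.
#'   `trace$final_iecv`); its `cal_slope` and `cal_in_large` summaries
#'   supply the shrinkage. May be `NULL`, in which case no shrinkage is
#'   applied (slope 1, intercept correction 0).
#' @param control a [siecv_control()].
#' @return An object of class `global_model`: `coef` (pooled, unshrunken),
#'   `coef_shrunken`, `pooled` (per-term [pool()] results with CIs and
#'   prediction intervals), `shrinkage` (`slope`, `cil`), `fits`
#'   (per-cluster), `spec`, `provenance`.
#' @export
fit_global <- function(data, spec, final_iecv = NULL,
                       control = siecv_control()) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(included = spec)
  s1 <- stage1_fits(data, spec, control)
  if (length(s1$fits) < 2) {
    stop_estimation("fewer than 2 clusters usable; cannot pool a global model")
  }
  pooled <- pool_coefficients(s1$fits, control$tau_estimator,
                              level = 1 - control$alpha)
  coef <- vapply(pooled, `[[`, numeric(1), "value")
  s <- 1
  a <- 0
  if (!is.null(final_iecv)) {
    if (!is.null(final_iecv$summaries$cal_slope)) {
      s <- final_iecv$summaries$cal_slope$value
    }
    if (!is.null(final_iecv$summaries$cal_in_large)) {
      a <- final_iecv$summaries$cal_in_large$value
    }
  }
  shrunken <- coef
  if (length(coef) > 1) shrunken[-1] <- coef[-1] * s
  shrunken[1] <- coef[1] + a
  structure(
    list(coef = coef, coef_shrunken = shrunken, pooled = pooled,
         shrinkage = list(slope = s, cil = a), fits = s1$fits,
         unusable = s1$unusable, spec = spec,
         provenance = list(loss = control$loss, lambda = control$lambda,
                           tau_estimator = control$tau_estimator)),
    class = "global_model"
  )
}

#' @export
print.global_model <- function(x, ...) {
  cat("Global model pooled over", length(x$fits), "clusters\n")
  print(data.frame(term = names(x$coef),
                   unshrunken = round(unname(x$coef), 4),
                   shrunken = round(unname(x$coef_shrunken), 4),
                   row.names = NULL))
  cat(sprintf("  shrinkage: slope %.4f, intercept correction %.4f\n",
              x$shrinkage$slope, x$shrinkage$cil))
  invisible(x)
}
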