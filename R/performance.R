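#' Predicted probabilities from pooled coefficients
#'
#' Applies a coefficient vector to a design matrix on the logit scale.
#' Coefficient names must match the design columns exactly (same terms,
#' any order).
#'
#' @param coef named coefficient vector including `(Intercept)`.
#' @param X design matrix from [build_design()].
#' @return list with `lp` (linear predictor) and `prob`
#'   (`plogis(lp)`, all strictly in (0, 1)).
#' @export
predict_risk <- function(coef, X) {
  X <- as.matrix(X)
  if (is.null(names(coef)) || is.null(colnames(X)) ||
      !setequal(names(coef), colnames(X))) {
    stop_validation("coefficient names do not match design columns")
  }
  lp <- drop(X %*% coef[colnames(X)])
  list(lp = lp, prob = stats::plogis(lp))
}

new_perf <- function(metric, value, se, n, events, cluster = NA_character_,
                     flag = NA_character_) {
  structure(
    list(metric = metric, value = value, se = se, n = n, events = events,
         cluster = cluster, flag = flag),
    class = "performance_estimate"
  )
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("%s%s: %.4f (SE %.4f), n = %d, events = %d%s\n",
              x$metric,
              if (!is.na(x$cluster)) paste0(" [", x$cluster, "]") else "",
              x$value, x$se, x$n, x$events,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Hold-out performance statistics
#'
#' Performance of probability predictions for a binary outcome in a
#' hold-out cluster, each returned with a standard error so the K
#' per-cluster estimates can be pooled by random-effects meta-analysis.
#'
#' * `perf_mse()` — mean squared error of the predicted probabilities
#'   (the Brier score); SE is the sample SD of the squared errors over
#'   \eqn{\sqrt{n}}.
#' * `perf_cal_slope()` — calibration slope: the slope from a
#'   Firth-penalized logistic regression of the outcome on the linear
#'   predictor. 1 means the linear predictor is correctly scaled; < 1
#'   means predictions are too extreme (overfitting).
#' * `perf_cal_in_large()` — calibration-in-the-large: the intercept of an
#'   unpenalized logistic model with the linear predictor as a fixed
#'   offset (the standard recalibration framework). 0 means predicted and
#'   observed overall risk agree; positive means observed risk exceeds
#'   predicted. If the unpenalized offset model fails to converge
#'   (separation), the Firth fit is used and the result flagged.
#' * `perf_c_statistic()` — concordance probability
#'   \eqn{P(\hat y_{case} > \hat y_{control}) + \frac{1}{2} P(tie)},
#'   computed exactly via midranks; SE by the Hanley-McNeil closed form.
#'
#' A metric that requires model fitting (slope, CIL) is returned as a
#' flagged `NA` result when the cluster has fewer than 2 events or 2
#' non-events; the c-statistic is flagged when a class is absent.
#'
#' @param y binary 0/1 outcomes of the hold-out cluster.
#' @param prob predicted probabilities.
#' @param lp linear predictor (logit of the predicted probability).
#' @param cluster optional label carried into the result.
#' @return A `performance_estimate` (metric, value, SE, n, events,
#'   cluster, flag).
#' @name performance
NULL

#' @rdname performance
#' @export
perf_mse <- function(y, prob, cluster = NA_character_) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(prob), length(y) >= 2)
  sq <- (y - prob)^2
  new_perf("mse", mean(sq), stats::sd(sq) / sqrt(length(y)),
           length(y), sum(y), cluster)
}

#' @rdname performance
#' @export
perf_cal_slope <- function(y, lp, cluster = NA_character_) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(lp))
  if (sum(y) < 2 || sum(1 - y) < 2) {
    return(new_perf("cal_slope", NA_real_, NA_real_, length(y), sum(y),
                    cluster, flag = "too_few_events"))
  }
  if (stats::var(lp) == 0) {
    stop_estimation("calibration slope unidentifiable: constant linear predictor")
  }
  X <- cbind(`(Intercept)` = 1, lp = lp)
  fit <- fit_firth(X, y, cluster = cluster)
  new_perf("cal_slope", unname(fit$coef["lp"]), unname(fit$se["lp"]),
           length(y), sum(y), cluster)
}

#' @rdname performance
#' @export
perf_cal_in_large <- function(y, lp, cluster = NA_character_) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(lp))
  if (sum(y) < 2 || sum(1 - y) < 2) {
    return(new_perf("cal_in_large", NA_real_, NA_real_, length(y), sum(y),
                    cluster, flag = "too_few_events"))
  }
  one <- matrix(1, nrow = length(y), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  flag <- NA_character_
  fit <- tryCatch(fit_firth(one, y, cluster = cluster, firth = FALSE, offset = lp),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    fit <- fit_firth(one, y, cluster = cluster, firth = TRUE, offset = lp)
    flag <- "firth_fallback"
  }
  new_perf("cal_in_large", unname(fit$coef[1]), unname(fit$se[1]),
           length(y), sum(y), cluster, flag = flag)
}

#' @rdname performance
#' @export
perf_c_statistic <- function(y, prob, cluster = NA_character_) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(prob))
  n1 <- sum(y)
  n0 <- sum(1 - y)
  if (n1 == 0 || n0 == 0) {
    return(new_perf("c_statistic", NA_real_, NA_real_, length(y), n1,
                    cluster, flag = "one_class_absent"))
  }
  # midrank formulation: exact over all case-control pairs, ties count 1/2
  r <- rank(prob, ties.method = "average")
  cstat <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  se <- hanley_mcneil_se(cstat, n1, n0)
  new_perf("c_statistic", cstat, se, length(y), n1, cluster)
}

hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

# All four hold-out metrics for one cluster; `metrics` restricts the set
# (the stepwise engine scores candidates on the MSE alone).
holdout_performance <- function(y, pred, cluster = NA_character_,
                                metrics = c("mse", "cal_slope", "cal_in_large",
                                            "c_statistic")) {
  out <- list()
  if ("mse" %in% metrics) out$mse <- perf_mse(y, pred$prob, cluster)
  if ("cal_slope" %in% metrics) {
    # a constant linear predictor (e.g. an intercept-only model) leaves
    # the slope unidentifiable; report a flagged result, not a failure
    out$cal_slope <- tryCatch(perf_cal_slope(y, pred$lp, cluster),
      siecv_estimation_error = function(e) {
        new_perf("cal_slope", NA_real_, NA_real_, length(y), sum(y),
                 cluster, flag = "constant_lp")
      })
  }
  if ("cal_in_large" %in% metrics) {
    out$cal_in_large <- perf_cal_in_large(y, pred$lp, cluster)
  }
  if ("c_statistic" %in% metrics) {
    out$c_statistic <- perf_c_statistic(y, pred$prob, cluster)
  }
  out
}

#' Tidy per-cluster performance table
#'
#' @param perf list (per cluster) of lists of `performance_estimate`s, as
#'   stored in an [iecv()] result.
#' @return data.frame with one row per cluster-metric pair: `cluster`,
#'   `metric`, `value`, `se`, `n`, `events`, `flag`.
#' @export
performance_table <- function(perf) {
  rows <- lapply(unlist(perf, recursive = FALSE), function(p) {
    data.frame(cluster = p$cluster, metric = p$metric, value = p$value,
               se = p$se, n = p$n, events = p$events, flag = p$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
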