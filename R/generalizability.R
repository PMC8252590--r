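#' Aggregated loss functions over hold-out clusters
#'
#' Collapse the K per-cluster hold-out performance estimates of one metric
#' into a single number quantifying the model's generalizability. The
#' stepwise engine minimizes one of these; they differ in how much weight
#' they put on average performance versus its between-cluster
#' heterogeneity.
#'
#' * `loss_mean()` — unweighted mean of the K values (SEs deliberately
#'   ignored); reasonable only when clustering effects are negligible.
#' * `loss_re()` — \eqn{\lambda \hat Z^{RE} + (1-\lambda)\hat\tau}: a
#'   convex combination of the random-effects pooled mean of performance
#'   and its between-cluster SD \eqn{\hat\tau} (the SD, not the
#'   variance). \eqn{\lambda = 1} optimizes average performance in an
#'   "average" cluster, \eqn{\lambda = 0} purely minimizes heterogeneity,
#'   \eqn{\lambda = 1/2} weighs them equally.
#' * `loss_sd()` — sample SD (denominator K-1) of the K values, treating
#'   all clusters as equally important regardless of size.
#' * `loss_gini()` — Gini mean difference
#'   \eqn{\frac{2}{K(K-1)}\sum_{h<v} |Z_v - Z_h|}, a nonparametric
#'   dispersion measure free of distributional assumptions.
#'
#' All four are defined for any performance metric, but the stepwise
#' engine applies them to the hold-out MSE, for which smaller is better in
#' every component.
#'
#' @param perf list of `performance_estimate`s, one per hold-out cluster
#'   (all of the same metric).
#' @param lambda trade-off weight in \[0, 1\] for `loss_re`.
#' @param method \eqn{\tau^2} estimator passed to [pool()].
#' @return An object of class `aggregated_loss`: list with `family`,
#'   `value`, `lambda` (for `loss_re`), `components` (for `loss_re`:
#'   `z_re` and `tau`), and the consumed values.
#' @name aggregated_loss
NULL

perf_values <- function(perf) {
  v <- vapply(perf, `[[`, numeric(1), "value")
  if (length(v) < 2) stop_estimation("aggregated loss needs K >= 2 performance estimates")
  if (anyNA(v)) stop_estimation("aggregated loss over flagged (NA) performance estimates")
  v
}

new_loss <- function(family, value, values, lambda = NA_real_,
                     components = NULL) {
  structure(
    list(family = family, value = value, lambda = lambda,
         components = components, values = values),
    class = "aggregated_loss"
  )
}

#' @rdname aggregated_loss
#' @export
loss_mean <- function(perf) {
  v <- perf_values(perf)
  new_loss("A_M", mean(v), v)
}

#' @rdname aggregated_loss
#' @export
loss_re <- function(perf, lambda = 0.5, method = "REML") {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop_config("lambda must be a single number in [0, 1]")
  }
  v <- perf_values(perf)
  s <- vapply(perf, `[[`, numeric(1), "se")
  if (any(!is.finite(s) | s <= 0)) {
    stop_estimation("loss_re requires positive finite SEs for all estimates")
  }
  pooled <- pool(v, s, method = method)
  new_loss("A_RE", lambda * pooled$value + (1 - lambda) * pooled$tau, v,
           lambda = lambda,
           components = list(z_re = pooled$value, tau = pooled$tau,
                             pooled = pooled))
}

#' @rdname aggregated_loss
#' @export
loss_sd <- function(perf) {
  v <- perf_values(perf)
  new_loss("A_SD", stats::sd(v), v)
}

#' @rdname aggregated_loss
#' @export
loss_gini <- function(perf) {
  v <- perf_values(perf)
  K <- length(v)
  # sum over unordered pairs; the h = v diagonal contributes zero
  gmd <- 2 / (K * (K - 1)) * sum(abs(outer(v, v, `-`))) / 2
  new_loss("A_Gini", gmd, v)
}

#' @rdname aggregated_loss
#' @param family one of `"mean"`, `"re"`, `"sd"`, `"gini"`; dispatches to
#'   the matching loss (used by the stepwise engine from run
#'   configuration).
#' @export
aggregate_loss <- function(perf, family = c("re", "mean", "sd", "gini"),
                           lambda = 0.5, method = "REML") {
  family <- match.arg(family)
  switch(family,
    mean = loss_mean(perf),
    re = loss_re(perf, lambda, method),
    sd = loss_sd(perf),
    gini = loss_gini(perf)
  )
}

#' @export
print.aggregated_loss <- function(x, ...) {
  cat(sprintf("%s%s = %.6f over K = %d clusters\n", x$family,
              if (!is.na(x$lambda)) sprintf(" (lambda = %g)", x$lambda) else "",
              x$value, length(x$values)))
  if (!is.null(x$components)) {
    cat(sprintf("  pooled mean = %.6f, tau = %.6f\n",
                x$components$z_re, x$components$tau))
  }
  invisible(x)
}
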