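#' Univariate random-effects meta-analysis of one quantity
#'
#' Pools a set of per-cluster estimates of a single quantity (a regression
#' coefficient, or a hold-out performance statistic) under the standard
#' two-level normal model: each estimate is normal around its
#' cluster-specific true value, and the true values are normal around a
#' common mean with between-cluster variance \eqn{\tau^2}. Weights are
#' \eqn{w_k = 1/(se_k^2 + \hat\tau^2)}, the pooled value is
#' \eqn{\sum w_k \hat\beta_k / \sum w_k}, and the confidence interval uses
#' the Hartung-Knapp variance
#' \eqn{[\sum w_k(\hat\beta_k - \hat\beta)^2/(Q-1)] / \sum w_k}
#' with a \eqn{t_{Q-1}} quantile, which has better small-Q coverage than
#' the conventional normal interval.
#'
#' @param values numeric vector of estimates (at least 2).
#' @param ses their standard errors (all > 0).
#' @param method \eqn{\tau^2} estimator: `"REML"` (restricted maximum
#'   likelihood, the default; falls back to `"DL"` with a warning if the
#'   restricted likelihood cannot be maximized), `"DL"`
#'   (DerSimonian-Laird moment estimator), `"PM"` (Paule-Mandel fixed
#'   point) or `"FE"` (common-effect, \eqn{\tau^2 \equiv 0}).
#' @param level confidence level (default 0.95).
#' @param labels optional labels for the inputs (used by forest-table
#'   export).
#' @return An object of class `pooled_estimate` with elements `value`,
#'   `se` (Hartung-Knapp), `var_conventional` (\eqn{1/\sum w}), `tau2`,
#'   `tau`, `weights`, `Q` (number of estimates pooled), `ci`
#'   `c(lower, upper)`, `pi` (approximate prediction interval, `NA` when
#'   fewer than 3 estimates), `method` (the estimator actually used),
#'   `fallback` flag, `level`, and the inputs (`values`, `ses`, `labels`).
#' @seealso [prediction_interval()], [pool_transformed()]
#' @export
pool <- function(values, ses, method = c("REML", "DL", "PM", "FE"),
                 level = 0.95, labels = NULL) {
  method <- match.arg(method)
  values <- as.numeric(values)
  ses <- as.numeric(ses)
  if (length(values) < 2) stop_estimation("need at least 2 estimates to pool")
  if (length(ses) != length(values)) stop_estimation("values and ses differ in length")
  if (any(!is.finite(values)) || any(!is.finite(ses)) || any(ses <= 0)) {
    stop_estimation("all estimates must be finite with positive SEs")
  }
  Q <- length(values)
  if (is.null(labels)) labels <- as.character(seq_len(Q))

  fallback <- FALSE
  used <- method
  tau2 <- switch(method,
    FE = 0,
    DL = tau2_dl(values, ses),
    PM = tau2_pm(values, ses),
    REML = {
      t2 <- tryCatch(tau2_reml(values, ses), error = function(e) NA_real_)
      if (is.na(t2)) {
        warning("REML estimation of tau^2 failed; falling back to DerSimonian-Laird")
        fallback <- TRUE
        used <- "DL"
        tau2_dl(values, ses)
      } else t2
    }
  )

  w <- 1 / (ses^2 + tau2)
  mu <- sum(w * values) / sum(w)
  var_conv <- 1 / sum(w)
  # Hartung-Knapp variance; exactly zero dispersion gives a zero-width CI
  var_hk <- sum(w * (values - mu)^2) / (Q - 1) / sum(w)
  tq <- stats::qt(1 - (1 - level) / 2, df = Q - 1)
  ci <- mu + c(-1, 1) * tq * sqrt(var_hk)

  out <- structure(
    list(value = mu, se = sqrt(var_hk), var_conventional = var_conv,
         tau2 = tau2, tau = sqrt(tau2), weights = w, Q = Q,
         ci = ci, pi = c(NA_real_, NA_real_), method = used,
         fallback = fallback, level = level,
         values = values, ses = ses, labels = labels),
    class = "pooled_estimate"
  )
  out$pi <- prediction_interval(out, level)
  out
}

# DerSimonian-Laird moment estimator from Cochran's Q.
tau2_dl <- function(values, ses) {
  w <- 1 / ses^2
  mu_fe <- sum(w * values) / sum(w)
  q_cochran <- sum(w * (values - mu_fe)^2)
  c_const <- sum(w) - sum(w^2) / sum(w)
  max(0, (q_cochran - (length(values) - 1)) / c_const)
}

# Paule-Mandel: tau^2 solving sum w(tau^2) (y - mu(tau^2))^2 = Q - 1.
tau2_pm <- function(values, ses, tol = 1e-8, maxit = 100) {
  gen_q <- function(t2) {
    w <- 1 / (ses^2 + t2)
    mu <- sum(w * values) / sum(w)
    sum(w * (values - mu)^2)
  }
  df <- length(values) - 1
  if (gen_q(0) <= df) return(0)
  lo <- 0
  hi <- max(stats::var(values) * 10, 1)
  while (gen_q(hi) > df) hi <- hi * 2
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (gen_q(mid) > df) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Restricted log-likelihood maximized on a bounded tau^2 interval.
tau2_reml <- function(values, ses) {
  upper <- max(10 * stats::var(values), 1e-6)
  restricted_ll <- function(t2) {
    w <- 1 / (ses^2 + t2)
    mu <- sum(w * values) / sum(w)
    -0.5 * sum(log(ses^2 + t2)) - 0.5 * log(sum(w)) -
      0.5 * sum(w * (values - mu)^2)
  }
  opt <- stats::optimize(restricted_ll, interval = c(0, upper), maximum = TRUE,
                         tol = 1e-10)
  # the optimum may sit at the boundary tau^2 = 0; compare explicitly
  if (restricted_ll(0) >= opt$objective) 0 else opt$maximum
}

#' Approximate prediction interval for a pooled estimate
#'
#' Interval of likely values of the pooled quantity in a *new* cluster:
#' \eqn{\hat\mu \pm t_{Q-2,1-\alpha/2}\sqrt{\hat\tau^2 +
#' \mathrm{var}(\hat\mu)}}, using the conventional variance
#' \eqn{1/\sum w}. Requires at least 3 pooled estimates (so the t
#' distribution has at least 1 degree of freedom); with fewer the interval
#' is returned as `NA` rather than an error, flagging that heterogeneity
#' cannot be meaningfully projected.
#'
#' @param pooled a `pooled_estimate`.
#' @param level interval level (defaults to the pooling level).
#' @return numeric `c(lower, upper)`.
#' @export
prediction_interval <- function(pooled, level = pooled$level) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  if (pooled$Q < 3) return(c(NA_real_, NA_real_))
  tq <- stats::qt(1 - (1 - level) / 2, df = pooled$Q - 2)
  pooled$value + c(-1, 1) * tq * sqrt(pooled$tau2 + pooled$var_conventional)
}

#' Pool on a transformed scale
#'
#' Some statistics are better pooled after transformation; in particular
#' the c-statistic is bounded in (0, 1) and may be pooled on the logit
#' scale, with delta-method standard errors
#' \eqn{se_{logit} = se / (v(1-v))}. The pooled value, CI and PI are
#' back-transformed; `tau2` is reported on the transformed scale.
#'
#' @inheritParams pool
#' @param transform `"identity"` (equivalent to [pool()]) or `"logit"`
#'   (values must lie strictly in (0, 1)).
#' @return A `pooled_estimate`; the element `transform` records the scale.
#' @export
pool_transformed <- function(values, ses, transform = c("identity", "logit"),
                             method = c("REML", "DL", "PM", "FE"),
                             level = 0.95, labels = NULL) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (transform == "identity") {
    out <- pool(values, ses, method, level, labels)
    out$transform <- "identity"
    return(out)
  }
  values <- as.numeric(values)
  ses <- as.numeric(ses)
  if (any(values <= 0 | values >= 1)) {
    stop_validation("logit pooling requires values strictly in (0, 1)")
  }
  tv <- stats::qlogis(values)
  tse <- ses / (values * (1 - values))
  out <- pool(tv, tse, method, level, labels)
  out$transform <- "logit"
  out$value_transformed <- out$value
  out$value <- stats::plogis(out$value_transformed)
  out$ci <- stats::plogis(out$ci)
  out$pi <- stats::plogis(out$pi)
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (%s%s, Q = %d): %.4f\n",
              x$method, if (isTRUE(x$fallback)) " after REML fallback" else "",
              x$Q, x$value))
  cat(sprintf("  tau = %.4f (tau^2 = %.4f)\n", x$tau, x$tau2))
  cat(sprintf("  %d%% CI (Hartung-Knapp): %.4f to %.4f\n",
              round(100 * x$level), x$ci[1], x$ci[2]))
  if (!anyNA(x$pi)) {
    cat(sprintf("  approximate %d%% PI: %.4f to %.4f\n",
                round(100 * x$level), x$pi[1], x$pi[2]))
  }
  invisible(x)
}
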