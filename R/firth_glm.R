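#' Firth-penalized logistic regression for one cluster
#'
#' Fits a binary logistic model by maximizing the Firth-penalized
#' log-likelihood \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)}, the
#' Jeffreys-prior penalty that removes the first-order small-sample bias of
#' maximum likelihood and keeps estimates and standard errors finite even
#' under complete separation. This is the stage-1 estimator of the
#' two-stage approach: each cluster is fit once, and coefficient vectors
#' are later combined by meta-analysis.
#'
#' The optimizer is Newton-Raphson on the modified score
#' \eqn{U^*(\beta) = X'(y - p + h(1/2 - p))}, where \eqn{h} are the hat
#' values of the weighted design, with step-halving; convergence requires
#' both the maximum absolute modified score and the parameter change to
#' fall below `tol`. Standard errors come from the inverse penalized
#' information at the optimum.
#'
#' @param X numeric design matrix including an intercept column (see
#'   [build_design()]).
#' @param y binary 0/1 outcome vector.
#' @param cluster optional cluster label carried into the result.
#' @param firth if `FALSE`, fits plain (unpenalized) maximum likelihood
#'   with the same Newton iteration; intended for large clusters where the
#'   penalty is immaterial.
#' @param offset optional fixed offset added to the linear predictor.
#' @param tol convergence tolerance on score and step.
#' @param maxit iteration cap.
#' @return An object of class `cluster_fit`: list with `coef`, `se`,
#'   `vcov`, `converged`, `n`, `events`, `cluster`, `firth`, and
#'   `intercept_se_source` (`"penalized"` until
#'   [reestimate_intercept()] replaces it).
#' @references Firth D (1993) Bias reduction of maximum likelihood
#'   estimates. Biometrika 80:27-38.
#' @export
fit_firth <- function(X, y, cluster = NA_character_, firth = TRUE,
                      offset = NULL, tol = 1e-6, maxit = 100) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (!all(y %in% c(0, 1))) stop_validation("outcome must be binary 0/1")
  if (all(y == 1) || all(y == 0)) {
    stop_estimation("cannot fit: outcome is all ", y[1],
                    if (!is.na(cluster)) paste0(" in cluster '", cluster, "'"))
  }
  if (is.null(offset)) offset <- rep(0, length(y))

  # drop constant non-intercept columns, then require full rank
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) > 1) {
    for (j in 2:ncol(X)) {
      if (stats::var(X[, j]) == 0) keep[j] <- FALSE
    }
  }
  if (any(!keep)) {
    stop_estimation("constant column(s) in design: ",
                    paste(colnames(X)[!keep], collapse = ", "))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_estimation("design matrix is rank deficient; collinear column(s): ",
                    paste(dep, collapse = ", "))
  }

  p_dim <- ncol(X)
  b <- rep(0, p_dim)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(offset + X %*% b)
    prob <- stats::plogis(eta)
    w <- prob * (1 - prob)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- tryCatch(solve(info), error = function(e) {
      stop_estimation("information matrix singular during iteration")
    })
    if (firth) {
      h <- rowSums((X %*% info_inv) * XW)
      score <- drop(crossprod(X, y - prob + h * (0.5 - prob)))
    } else {
      score <- drop(crossprod(X, y - prob))
    }
    delta <- drop(info_inv %*% score)
    # step-halving: keep the penalized objective finite / improving
    step <- 1
    obj_old <- firth_objective(X, y, offset, b, firth)
    repeat {
      b_new <- b + step * delta
      obj_new <- firth_objective(X, y, offset, b_new, firth)
      if (is.finite(obj_new) && (obj_new >= obj_old - 1e-10 || step < 1e-8)) break
      step <- step / 2
    }
    moved <- max(abs(step * delta))
    b <- b_new
    if (max(abs(score)) < tol && moved < tol) {
      converged <- TRUE
      break
    }
  }

  eta <- drop(offset + X %*% b)
  prob <- stats::plogis(eta)
  info <- crossprod(X, X * (prob * (1 - prob)))
  vc <- solve(info)
  se <- sqrt(diag(vc))
  names(b) <- names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coef = b, se = se, vcov = vc, converged = converged,
         n = length(y), events = sum(y), cluster = cluster, firth = firth,
         intercept_se_source = "penalized"),
    class = "cluster_fit"
  )
}

# Penalized (or plain) log-likelihood; the penalty is half the log
# determinant of the Fisher information.
firth_objective <- function(X, y, offset, b, firth) {
  eta <- drop(offset + X %*% b)
  ll <- sum(y * eta - log1p(exp(eta)))
  if (!firth) return(ll)
  prob <- stats::plogis(eta)
  info <- crossprod(X, X * (prob * (1 - prob)))
  ld <- determinant(info, logarithm = TRUE)
  ll + 0.5 * as.numeric(ld$modulus)
}

#' Post-hoc unpenalized re-estimation of the intercept
#'
#' The Jeffreys penalty shrinks the intercept as well as the slopes, which
#' biases the average predicted risk. This correction holds the slope
#' coefficients fixed at their Firth values and re-solves the
#' one-dimensional unpenalized maximum-likelihood problem for the
#' intercept: an intercept-only logistic model with the fixed linear
#' predictor (minus its intercept) as offset. After the correction the mean
#' fitted probability equals the observed event rate on the fitting data
#' (the intercept score equation).
#'
#' @param fit a converged `cluster_fit`.
#' @param X,y the design matrix and outcome the fit was estimated on.
#' @return The updated `cluster_fit`; only the intercept and its SE change
#'   (`intercept_se_source` becomes `"offset_model"`: the SE of the
#'   one-parameter offset model, matching the estimation actually
#'   performed).
#' @export
reestimate_intercept <- function(fit, X, y) {
  stopifnot(inherits(fit, "cluster_fit"))
  if (!fit$converged) stop_estimation("cannot re-estimate intercept: fit did not converge")
  X <- as.matrix(X)
  y <- as.numeric(y)
  off <- if (ncol(X) > 1) drop(X[, -1, drop = FALSE] %*% fit$coef[-1]) else rep(0, length(y))
  one <- matrix(1, nrow = length(y), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  sub <- fit_firth(one, y, cluster = fit$cluster, firth = FALSE, offset = off)
  if (!sub$converged) stop_estimation("intercept re-estimation did not converge")
  fit$coef[1] <- sub$coef[1]
  fit$se[1] <- sub$se[1]
  fit$vcov[1, 1] <- sub$se[1]^2
  fit$intercept_se_source <- "offset_model"
  fit
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat("Cluster fit",
      if (!is.na(x$cluster)) paste0("'", x$cluster, "'"),
      sprintf("(n = %d, events = %d, %s%s)\n", x$n, x$events,
              if (x$firth) "Firth" else "ML",
              if (x$converged) "" else ", NOT converged"))
  print(data.frame(estimate = round(x$coef, 4), se = round(x$se, 4)))
  invisible(x)
}

#' Tidy table of per-cluster coefficient estimates
#'
#' @param fits list of `cluster_fit` objects.
#' @return data.frame with columns `cluster`, `term`, `estimate`, `se` —
#'   the long layout of a per-cluster coefficient table.
#' @export
cluster_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(cluster = f$cluster, term = names(f$coef),
               estimate = unname(f$coef), se = unname(f$se),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
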