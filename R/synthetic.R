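#' Configuration for the clustered binary-outcome generator
#'
#' Describes a data-generating process of the same form the two-stage
#' model assumes: cluster k has intercept
#' \eqn{\alpha_k \sim N(\mu_\alpha, \sigma_\alpha^2)} and, for each
#' predictor p, a cluster-specific log-odds coefficient
#' \eqn{\beta_{p,k} \sim N(\mu_{\beta,p}, \tau_p^2)}; outcomes are
#' Bernoulli at \eqn{\mathrm{expit}(\alpha_k + \sum_p \beta_{p,k} x)}.
#' Covariate distributions may themselves shift between clusters: binary
#' covariates draw a cluster-level prevalence from a logit-normal, and
#' continuous covariates draw a cluster-level mean shift from a normal.
#'
#' @param K number of clusters (>= 2).
#' @param n_k either a length-K integer vector of cluster sizes or a
#'   single number, the mean of a Poisson draw per cluster (minimum size 2
#'   enforced).
#' @param mu_alpha,sigma_alpha mean and between-cluster SD of the
#'   cluster intercepts (log-odds scale).
#' @param covariates named list; each element is a list with `type`
#'   (`"binary"` or `"continuous"`) and parameters: binary —
#'   `prevalence` (overall) and `prevalence_logit_sd` (between-cluster SD
#'   of the logit prevalence); continuous — `mean`, `sd` (within-cluster)
#'   and `shift_sd` (between-cluster SD of the cluster mean).
#' @param effects named numeric vector `mu` of common log-odds effects and
#'   named numeric vector `tau` of between-cluster effect SDs; names must
#'   match `covariates`.
#' @param seed integer seed; the generator is fully reproducible from the
#'   configuration alone.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(K, n_k, mu_alpha, sigma_alpha,
                             covariates, effects_mu, effects_tau, seed = 1L) {
  stopifnot(K >= 2, sigma_alpha >= 0, all(effects_tau >= 0))
  if (length(n_k) != 1 && length(n_k) != K) {
    stop_config("n_k must be a single mean or a length-K vector")
  }
  if (length(n_k) == K && any(n_k < 2)) stop_config("all cluster sizes must be >= 2")
  nm <- names(covariates)
  if (is.null(nm) || !setequal(nm, names(effects_mu)) ||
      !setequal(nm, names(effects_tau))) {
    stop_config("covariates, effects_mu and effects_tau must share the same names")
  }
  structure(
    list(K = K, n_k = n_k, mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
         covariates = covariates, effects_mu = effects_mu[nm],
         effects_tau = effects_tau[nm], seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a clustered binary-outcome dataset with known truth
#'
#' Draws a dataset from the process described by a [generator_config()]
#' and returns it together with every drawn parameter, so that
#' recovery of the common effects and of the between-cluster heterogeneity
#' can be tested against the truth.
#'
#' @param config a [generator_config()].
#' @return list with `data` (a [clustered_dataset()]; cluster column
#'   `cluster`, outcome column `y`) and `truth` (list: `alpha_k`, `beta`
#'   — a K x P matrix of cluster-specific coefficients — and the
#'   cluster-level covariate parameters).
#' @export
generate_clustered <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  K <- config$K
  sizes <- if (length(config$n_k) == 1) {
    pmax(2L, stats::rpois(K, config$n_k))
  } else as.integer(config$n_k)
  p_names <- names(config$covariates)
  P <- length(p_names)

  for (p in p_names) {
    cv <- config$covariates[[p]]
    if (identical(cv$type, "continuous") && cv$sd == 0 &&
        config$effects_mu[[p]] != 0) {
      warning("covariate '", p, "' is degenerate (zero variance) but has ",
              "a nonzero effect", call. = FALSE)
    }
  }

  alpha_k <- stats::rnorm(K, config$mu_alpha, config$sigma_alpha)
  beta <- matrix(NA_real_, K, P, dimnames = list(NULL, p_names))
  for (p in seq_len(P)) {
    beta[, p] <- stats::rnorm(K, config$effects_mu[p], config$effects_tau[p])
  }

  cov_params <- list()
  frames <- vector("list", K)
  for (k in seq_len(K)) {
    n <- sizes[k]
    xmat <- matrix(NA_real_, n, P, dimnames = list(NULL, p_names))
    for (p in p_names) {
      cv <- config$covariates[[p]]
      if (cv$type == "binary") {
        sdl <- if (is.null(cv$prevalence_logit_sd)) 0 else cv$prevalence_logit_sd
        prev_k <- stats::plogis(stats::rnorm(1, stats::qlogis(cv$prevalence), sdl))
        cov_params[[p]] <- c(cov_params[[p]], prev_k)
        xmat[, p] <- stats::rbinom(n, 1, prev_k)
      } else if (cv$type == "continuous") {
        shift_sd <- if (is.null(cv$shift_sd)) 0 else cv$shift_sd
        mean_k <- stats::rnorm(1, cv$mean, shift_sd)
        cov_params[[p]] <- c(cov_params[[p]], mean_k)
        xmat[, p] <- stats::rnorm(n, mean_k, cv$sd)
      } else {
        stop_config("unknown covariate type '", cv$type, "'")
      }
    }
    lp <- alpha_k[k] + drop(xmat %*% beta[k, ])
    y <- stats::rbinom(n, 1, stats::plogis(lp))
    frames[[k]] <- data.frame(cluster = paste0("c", k), y = y, xmat,
                              stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, frames)
  list(
    data = clustered_dataset(df, "cluster", "y"),
    truth = list(alpha_k = alpha_k, beta = beta, sizes = sizes,
                 cluster_covariate_params = cov_params, config = config)
  )
}

#' Generator preset shaped like a multi-study diagnostic IPD set
#'
#' Eleven clusters of unequal size (about 10 000 participants in total),
#' three binary predictors with prevalences, common log-odds effects and
#' between-cluster effect SDs on the scale seen in multi-study deep-vein
#' thrombosis data, and an intercept distribution chosen so that the
#' overall event rate is close to 0.19. Intended as a realistic default
#' scenario for exercising the full pipeline; it emulates scale and
#' heterogeneity structure, not any particular study.
#'
#' @param seed integer seed stored in the configuration.
#' @return A [generator_config()].
#' @export
dvt_like_preset <- function(seed = 1L) {
  generator_config(
    K = 11,
    n_k = 910,
    mu_alpha = -2.18,
    sigma_alpha = 0.5,
    covariates = list(
      malignancy = list(type = "binary", prevalence = 0.083,
                        prevalence_logit_sd = 0.3),
      calf_difference = list(type = "binary", prevalence = 0.301,
                             prevalence_logit_sd = 0.3),
      surgery = list(type = "binary", prevalence = 0.111,
                     prevalence_logit_sd = 0.3)
    ),
    effects_mu = c(malignancy = 0.98, calf_difference = 1.27, surgery = 0.55),
    effects_tau = c(malignancy = 0.35, calf_difference = 0.15, surgery = 0.12),
    seed = seed
  )
}
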