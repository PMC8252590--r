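# Small programmatic fixtures shared across test files.

# Deterministic 3-cluster, 2-predictor table (30 rows).
toy_frame <- function() {
  set.seed(421)
  data.frame(
    study = rep(c("a", "b", "c"), each = 10),
    dvt = rep(c(0, 1), 15),
    age = round(stats::runif(30, 20, 90)),
    sex = rep(c(0, 1), each = 15)
  )
}

toy_dataset <- function() clustered_dataset(toy_frame(), "study", "dvt")

# Clustered binary data from a known logistic truth; balanced enough that
# every cluster is usable for model fitting.
sim_dataset <- function(seed = 1, K = 5, n = 120, beta = c(x1 = 0.8, x2 = 0),
                        tau = c(x1 = 0, x2 = 0), sigma_alpha = 0.3) {
  cfg <- generator_config(
    K = K, n_k = n, mu_alpha = -0.7, sigma_alpha = sigma_alpha,
    covariates = list(
      x1 = list(type = "continuous", mean = 0, sd = 1, shift_sd = 0.2),
      x2 = list(type = "continuous", mean = 0, sd = 1, shift_sd = 0.2)
    ),
    effects_mu = beta, effects_tau = tau, seed = seed
  )
  generate_clustered(cfg)
}

# A list of performance_estimate-shaped objects from bare values/SEs,
# for exercising the aggregated losses directly.
perf_list <- function(values, ses = rep(0.1, length(values))) {
  mapply(function(v, s, k) {
    structure(list(metric = "mse", value = v, se = s, n = 100L,
                   events = 20L, cluster = paste0("c", k), flag = NA_character_),
              class = "performance_estimate")
  }, values, ses, seq_along(values), SIMPLIFY = FALSE)
}
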