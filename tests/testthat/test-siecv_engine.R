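ctrl_dl <- siecv_control(tau_estimator = "DL")

test_that("iecv has the right structure and never leaks the hold-out cluster", {
  sim <- sim_dataset(seed = 3, K = 3, n = 150)
  spec <- model_spec(included = list(term_main("x1")))
  res <- iecv(sim$data, spec, ctrl_dl)

  expect_length(res$holdout, 3)
  for (h in names(res$holdout)) {
    # development pooling uses exactly the K-1 other clusters
    pooled <- res$holdout[[h]]$pooled[["x1"]]
    expect_equal(pooled$Q, 2)
    expect_false(h %in% pooled$labels)
  }

  # perturbing hold-out outcomes must not move the coefficients used there
  df2 <- sim$data$data
  h <- sim$data$clusters[1]
  rows <- which(df2$cluster == h)
  df2$y[rows[1:20]] <- 1 - df2$y[rows[1:20]]
  res2 <- iecv(clustered_dataset(df2, "cluster", "y"), spec, ctrl_dl)
  expect_identical(res2$holdout[[h]]$coef, res$holdout[[h]]$coef)
})

test_that("intercept-only models predict a constant pooled risk per hold-out", {
  sim <- sim_dataset(seed = 4, K = 4, n = 100)
  res <- iecv(sim$data, model_spec(), ctrl_dl, metrics = "mse")
  for (h in names(res$holdout)) {
    coef <- res$holdout[[h]]$coef
    expect_length(coef, 1)
    expect_equal(unique(res$holdout[[h]]$pred$prob), unname(plogis(coef)))
  }
})

test_that("pooled performance in a homogeneous population is well calibrated", {
  sim <- sim_dataset(seed = 9, K = 6, n = 800, sigma_alpha = 0,
                     beta = c(x1 = 0.8, x2 = 0.5))
  res <- iecv(sim$data, model_spec(included = list(term_main("x1"), term_main("x2"))),
              ctrl_dl)
  slope <- res$summaries$cal_slope
  expect_gte(1, slope$ci[1])
  expect_lte(1, slope$ci[2])
  expect_lt(slope$tau, 0.25)
})

test_that("forward selection follows the greedy argmin and records its trace", {
  sim <- sim_dataset(seed = 2, K = 5, n = 120)
  spec <- model_spec(candidates = list(term_main("x1"), term_main("x2")))
  tr <- suppressWarnings(siecv(sim$data, spec, ctrl_dl))

  expect_s3_class(tr, "siecv_trace")
  expect_identical(tr$cycles[[1]]$selected, "(none)")
  # independent brute-force pass over every evaluated cycle: the recorded
  # selection must be the argmin of freshly recomputed candidate losses
  current <- list()
  all_terms <- list(x1 = term_main("x1"), x2 = term_main("x2"))
  for (cyc in tr$cycles[-1]) {
    fresh <- vapply(cyc$candidates$term, function(nm) {
      terms <- c(current, all_terms[nm])
      r <- iecv(sim$data, model_spec(included = terms), ctrl_dl, metrics = "mse")
      aggregate_loss(lapply(r$holdout, function(x) x$perf$mse),
                     family = "re", lambda = 0.5, method = "DL")$value
    }, numeric(1))
    expect_equal(unname(fresh), cyc$candidates$loss, tolerance = 1e-12)
    if (!is.na(cyc$selected)) {
      expect_identical(cyc$selected,
                       cyc$candidates$term[which.min(cyc$candidates$loss)])
      current <- c(current, all_terms[cyc$selected])
    }
  }
  # termination: at most P + 1 evaluated cycles plus a stop record
  expect_lte(length(tr$cycles), 2 + 2)
})

test_that("stopping rules fire as specified", {
  # a pure-noise candidate does not improve on the base model: stop with
  # no_improvement after exactly one post-baseline cycle, base returned
  sim <- sim_dataset(seed = 1, K = 5, n = 120)
  tr <- suppressWarnings(siecv(
    sim$data,
    model_spec(included = list(term_main("x1")), forced = "x1",
               candidates = list(term_main("x2"))),
    ctrl_dl
  ))
  expect_identical(tr$stopping_reason, "no_improvement")
  expect_length(tr$cycles, 2)
  expect_identical(siecv:::term_names(tr$final_spec$included), "x1")

  # both candidates genuinely predictive: all included, candidates_exhausted
  sim2 <- sim_dataset(seed = 6, K = 5, n = 200, beta = c(x1 = 0.9, x2 = 0.7))
  tr2 <- suppressWarnings(siecv(
    sim2$data, model_spec(candidates = list(term_main("x1"), term_main("x2"))),
    ctrl_dl
  ))
  expect_identical(tr2$stopping_reason, "candidates_exhausted")
  expect_setequal(siecv:::term_names(tr2$final_spec$included), c("x1", "x2"))
})

test_that("backward elimination drops noise and protects forced terms", {
  sim <- sim_dataset(seed = 5, K = 6, n = 200)
  spec <- model_spec(included = list(term_main("x1"), term_main("x2")),
                     forced = "x1")
  tr <- suppressWarnings(siecv_backward(sim$data, spec, ctrl_dl))
  expect_identical(tr$direction, "backward")
  # forced terms never appear among removal candidates
  for (cyc in tr$cycles[-1]) {
    expect_false("x1" %in% cyc$candidates$term)
  }
  expect_true("x1" %in% siecv:::term_names(tr$final_spec$included))
})

test_that("forward and backward agree when the signal is clear", {
  sim <- sim_dataset(seed = 8, K = 8, n = 250)
  cands <- list(term_main("x1"), term_main("x2"))
  tf <- suppressWarnings(siecv(sim$data, model_spec(candidates = cands), ctrl_dl))
  tb <- suppressWarnings(siecv_backward(sim$data, model_spec(included = cands), ctrl_dl))
  expect_setequal(siecv:::term_names(tf$final_spec$included),
                  siecv:::term_names(tb$final_spec$included))
  expect_true("x1" %in% siecv:::term_names(tf$final_spec$included))
})

test_that("interaction eligibility and locking follow the main-effects rule", {
  ab <- term_interaction("ab", c("a", "b"))
  only_a <- model_spec(included = list(term_main("a")))
  both <- model_spec(included = list(term_main("a"), term_main("b")))
  expect_false(interaction_guard(only_a, ab, require_main_effects = TRUE))
  expect_true(interaction_guard(both, ab, require_main_effects = TRUE))
  expect_true(interaction_guard(only_a, ab, require_main_effects = FALSE))

  with_int <- model_spec(included = list(term_main("a"), term_main("b"), ab))
  expect_setequal(siecv:::locked_terms(with_int, TRUE), c("a", "b"))
  expect_length(siecv:::locked_terms(with_int, FALSE), 0)
})

test_that("the global model pools all clusters and applies shrinkage", {
  sim <- sim_dataset(seed = 10, K = 5, n = 200, beta = c(x1 = 2, x2 = 0))
  spec <- model_spec(included = list(term_main("x1")))

  g0 <- fit_global(sim$data, spec, final_iecv = NULL, ctrl_dl)
  expect_identical(g0$coef, g0$coef_shrunken)       # s = 1, a = 0
  expect_equal(g0$pooled[["x1"]]$Q, 5)              # no cluster left out

  res <- iecv(sim$data, spec, ctrl_dl)
  doctored <- res
  doctored$summaries$cal_slope$value <- 0.5
  doctored$summaries$cal_in_large$value <- 0.2
  g1 <- fit_global(sim$data, spec, doctored, ctrl_dl)
  expect_equal(unname(g1$coef_shrunken["x1"]), unname(g1$coef["x1"]) * 0.5)
  expect_equal(unname(g1$coef_shrunken["(Intercept)"]),
               unname(g1$coef["(Intercept)"]) + 0.2)
})

test_that("identical data and configuration give byte-identical traces", {
  sim <- sim_dataset(seed = 2, K = 5, n = 120)
  spec <- model_spec(candidates = list(term_main("x1"), term_main("x2")))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_trace_json(suppressWarnings(siecv(sim$data, spec, ctrl_dl)), f1)
  write_trace_json(suppressWarnings(siecv(sim$data, spec, ctrl_dl)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
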