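# Independent oracle: maximize the Jeffreys-penalized log-likelihood with a
# generic numeric optimizer, with no reference to the Newton-Raphson path.
firth_oracle <- function(X, y, offset = rep(0, nrow(X))) {
  obj <- function(b) {
    eta <- drop(offset + X %*% b)
    prob <- plogis(eta)
    info <- crossprod(X, X * (prob * (1 - prob)))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
  }
  optim(rep(0, ncol(X)), obj, method = "BFGS",
        control = list(fnscale = -1, reltol = 1e-14, maxit = 5000))$par
}

test_that("Firth fit matches closed forms and the numeric-optimizer oracle", {
  # complete separation: penalty is equivalent to adding 1/2 to each 2x2 cell
  X <- cbind(`(Intercept)` = 1, x = c(0, 0, 1, 1))
  y <- c(0, 0, 1, 1)
  fit <- fit_firth(X, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef["x"]), log(25), tolerance = 1e-6)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  expect_equal(unname(fit$coef), firth_oracle(X, y), tolerance = 1e-4)

  # intercept-only: Jeffreys posterior mode adds 1/2 to events, 1 to n
  one <- cbind(`(Intercept)` = rep(1, 10))
  y2 <- c(rep(1, 3), rep(0, 7))
  fit2 <- fit_firth(one, y2)
  expect_equal(unname(fit2$coef), qlogis(3.5 / 11), tolerance = 1e-6)
  expect_equal(unname(fit2$coef), firth_oracle(one, y2), tolerance = 1e-5)
})

test_that("Firth estimates approach unpenalized ML in large balanced samples", {
  set.seed(7)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.7 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_firth(X, y)
  ml <- glm(y ~ x, family = binomial)
  expect_equal(unname(fit$coef), unname(coef(ml)), tolerance = 1e-2)
  expect_equal(unname(fit$se), unname(summary(ml)$coefficients[, 2]),
               tolerance = 1e-2)
})

test_that("penalized likelihood at the optimum dominates the null vector", {
  set.seed(11)
  for (i in 1:5) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * x))
    X <- cbind(`(Intercept)` = 1, x = x)
    fit <- fit_firth(X, y)
    at_opt <- siecv:::firth_objective(X, y, rep(0, n), fit$coef, TRUE)
    at_zero <- siecv:::firth_objective(X, y, rep(0, n), c(0, 0), TRUE)
    expect_gte(at_opt, at_zero)
  }
})

test_that("estimates are invariant to design column reordering", {
  set.seed(5)
  n <- 80
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * X[, "a"] - 0.8 * X[, "b"]))
  f1 <- fit_firth(X, y)
  f2 <- fit_firth(X[, c("(Intercept)", "b", "a")], y)
  expect_equal(f1$coef[c("(Intercept)", "b", "a")], f2$coef, tolerance = 1e-8)
})

test_that("Jeffreys penalty shrinks slopes toward zero in small samples", {
  set.seed(23)
  shrunk <- 0L
  total <- 0L
  for (i in 1:30) {
    n <- 30
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.2 * x))
    if (sum(y) < 3 || sum(1 - y) < 3) next
    ml <- suppressWarnings(glm(y ~ x, family = binomial))
    if (!ml$converged || abs(coef(ml)[2]) > 10) next
    fit <- fit_firth(cbind(`(Intercept)` = 1, x = x), y)
    total <- total + 1L
    if (abs(fit$coef["x"]) <= abs(coef(ml)[2]) + 1e-10) shrunk <- shrunk + 1L
  }
  expect_gte(total, 20)
  expect_equal(shrunk, total)
})

test_that("fit_firth rejects degenerate designs and one-class outcomes", {
  X <- cbind(`(Intercept)` = 1, x = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8))
  expect_error(fit_firth(X, c(0, 1, 0, 1)), regexp = "collinear",
               class = "siecv_estimation_error")
  expect_error(fit_firth(X[, 1:2], c(1, 1, 1, 1)), class = "siecv_estimation_error")
  expect_error(
    fit_firth(cbind(`(Intercept)` = 1, z = rep(2, 4)), c(0, 1, 0, 1)),
    regexp = "constant", class = "siecv_estimation_error"
  )
})

test_that("intercept re-estimation restores the event rate and keeps slopes", {
  set.seed(31)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_firth(X, y)
  fit2 <- reestimate_intercept(fit, X, y)
  expect_identical(fit2$coef[-1], fit$coef[-1])
  # score equation of the unpenalized intercept: mean fitted prob = rate
  prob <- plogis(drop(X %*% fit2$coef))
  expect_equal(mean(prob), mean(y), tolerance = 1e-8)
  expect_identical(fit2$intercept_se_source, "offset_model")

  # intercept-only model: the corrected intercept is the empirical logit
  one <- cbind(`(Intercept)` = rep(1, n))
  f0 <- reestimate_intercept(fit_firth(one, y), one, y)
  expect_equal(unname(f0$coef), qlogis(mean(y)), tolerance = 1e-8)

  # separated 2x2 example: slopes untouched by the correction
  Xs <- cbind(`(Intercept)` = 1, x = c(0, 0, 1, 1))
  ys <- c(0, 0, 1, 1)
  fs <- reestimate_intercept(fit_firth(Xs, ys), Xs, ys)
  expect_equal(unname(fs$coef["x"]), log(25), tolerance = 1e-6)
})
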