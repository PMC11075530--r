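test_that("perfectly correlated predictor gives coefficient 1 and R2 1", {
  set.seed(1)
  x <- rnorm(50)
  d <- data.frame(y = 2 * x, x = x)
  fit <- suppressWarnings(fit_standardized_ols(d, "y", "x"))  # perfect fit
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_equal(est, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("coefficients solve the normal equations on an orthogonal design", {
  set.seed(2)
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  y <- rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- fit_standardized_ols(d, "y", c("x1", "x2"))
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, z(x1), z(x2))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% z(y))
  expect_equal(fit$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-10)
})

test_that("null effects stay within three standard errors at n = 1000", {
  set.seed(3)
  d <- data.frame(y = rnorm(1000), x1 = rnorm(1000), x2 = rnorm(1000))
  fit <- fit_standardized_ols(d, "y", c("x1", "x2"))
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_true(all(abs(cf$estimate) <= 3 * cf$std_error))
})

test_that("regression invariants hold: adjusted R2, t ratio, residual orthogonality", {
  set.seed(4)
  n <- 120
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                  g = sample(c("u", "v", "w"), n, replace = TRUE))
  fit <- fit_standardized_ols(d, "y", c("a", "b"), fixed_effects = "g")
  p <- fit$n_params
  expect_equal(fit$adj_r_squared,
               1 - (1 - fit$r_squared) * (fit$n - 1) / (fit$n - p - 1),
               tolerance = 1e-12)
  cf <- fit$coefficients
  expect_equal(abs(cf$statistic), abs(cf$estimate) / cf$std_error,
               tolerance = 1e-10)
  expect_equal(cf$p_value,
               2 * pt(abs(cf$statistic), fit$n - p - 1, lower.tail = FALSE),
               tolerance = 1e-12)
  X <- model.matrix(fit$fit)
  r <- residuals(fit$fit)
  expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-8)
  # reference level is the first in sorted order
  expect_true(all(c("gv", "gw") %in% cf$term) && !("gu" %in% cf$term))
})

test_that("aliased columns are reported, not silently dropped", {
  set.seed(5)
  x <- rnorm(40)
  d <- data.frame(y = rnorm(40), x1 = x, x2 = x)
  expect_error(fit_standardized_ols(d, "y", c("x1", "x2")), "aliased")
  d2 <- data.frame(y = rnorm(40), x1 = x, x2 = rep(1, 40))
  expect_error(fit_standardized_ols(d2, "y", c("x1", "x2")), "constant")
})

test_that("ridge at zero penalty reproduces OLS and shrinks to zero at infinity", {
  set.seed(6)
  n <- 80
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  ols <- fit_standardized_ols(d, "y", c("a", "b", "c"))
  r0 <- fit_ridge(d, "y", c("a", "b", "c"), lambda_grid = 0)
  expect_equal(r0$coefficients$estimate,
               ols$coefficients$estimate[ols$coefficients$term != "(Intercept)"],
               tolerance = 1e-8)
  rinf <- fit_ridge(d, "y", c("a", "b", "c"), lambda_grid = 1e12)
  expect_lt(max(abs(rinf$coefficients$estimate)), 1e-6)
})

test_that("ridge matches the normal-equations closed form and splits duplicates", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X %*% c(1, -0.5, 0.2) + rnorm(n)
  d <- data.frame(y = as.numeric(y), x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  lam <- 17
  fit <- fit_ridge(d, "y", c("x1", "x2", "x3"), lambda_grid = lam)
  z <- function(v) (v - mean(v)) / sd(v)
  Z <- cbind(z(X[, 1]), z(X[, 2]), z(X[, 3]))
  beta_oracle <- solve(crossprod(Z) + lam * diag(3), crossprod(Z, z(y)))
  expect_equal(fit$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-8)

  # exchangeable duplicated pair: weight split equally, at the closed form
  dd <- data.frame(y = as.numeric(y), x1 = X[, 1], x2 = X[, 1])
  fd <- fit_ridge(dd, "y", c("x1", "x2"), lambda_grid = lam)
  zx <- z(X[, 1]); zy <- z(y)
  b_expect <- sum(zx * zy) / (2 * sum(zx^2) + lam)
  expect_equal(fd$coefficients$estimate, rep(b_expect, 2), tolerance = 1e-8)
})

test_that("cross-validated penalty selection is deterministic and sensible", {
  set.seed(8)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X %*% c(0.5, 0.5, 0, 0) + rnorm(n, sd = 2)
  d <- data.frame(y = as.numeric(y), x1 = X[, 1], x2 = X[, 2],
                  x3 = X[, 3], x4 = X[, 4])
  f1 <- fit_ridge(d, "y", paste0("x", 1:4), seed = 11)
  f2 <- fit_ridge(d, "y", paste0("x", 1:4), seed = 11)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coefficients$estimate, f2$coefficients$estimate)
  expect_true(f1$lambda >= 0)
})

test_that("speed decomposition separates selection from ordering", {
  set.seed(9)
  n <- 600
  z <- function(v) (v - mean(v)) / sd(v)
  log_min <- rnorm(n, sd = 0.3)
  log_circ <- abs(rnorm(n, sd = 0.2))
  log_speed <- log_min + log_circ
  log_vol <- rnorm(n, sd = 0.4)
  tab <- data.frame(z_log_norm_volume = z(log_vol),
                    z_log_speed = z(log_speed),
                    z_log_min_required_speed = z(log_min),
                    z_log_circuitousness = z(log_circ))

  # outcome driven only by minimum required speed
  tab$y1 <- -0.3 * tab$z_log_min_required_speed + rnorm(n, sd = 0.5)
  dec1 <- decompose_speed_effect(tab, "y1")
  cf <- dec1$model_components$coefficients
  circ_est <- cf[cf$term == "z_log_circuitousness", ]
  expect_lt(abs(circ_est$estimate), 3 * circ_est$std_error)
  min_est <- cf[cf$term == "z_log_min_required_speed", ]
  expect_lt(min_est$estimate, 0)

  # outcome driven only by circuitousness
  tab$y2 <- 0.3 * tab$z_log_circuitousness + rnorm(n, sd = 0.5)
  dec2 <- decompose_speed_effect(tab, "y2")
  cf2 <- dec2$model_components$coefficients
  min2 <- cf2[cf2$term == "z_log_min_required_speed", ]
  expect_lt(abs(min2$estimate), 3 * min2$std_error)

  # both models expose the volume term
  expect_true("z_log_norm_volume" %in% dec1$model_speed$coefficients$term)
})
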