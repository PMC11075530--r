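#' Standardized ordinary least squares with covariates and fixed effects
#'
#' Fits `outcome ~ predictors (+ fixed effects)` with the outcome and every
#' continuous predictor z-scored (sample standard deviation, denominator
#' n - 1), so coefficients are standardized and comparable across
#' predictors. Fixed-effect columns are expanded to indicator contrasts with
#' the first level in sorted order as the reference (this choice moves the
#' intercept, never the focal coefficients). The solve is the QR
#' decomposition used by [stats::lm()]; exactly collinear columns are
#' detected and reported as an error listing the aliased terms rather than
#' silently dropped. Rows with missing values in any used column are dropped
#' with a count.
#'
#' @param data data.frame (typically a per-author feature table).
#' @param outcome name of the outcome column.
#' @param predictors character vector of continuous predictor columns.
#' @param fixed_effects character vector of categorical columns (optional).
#' @return object of class `topo_regression`: `coefficients` (term,
#'   estimate, std_error, statistic, p_value), `r_squared`,
#'   `adj_r_squared`, `n`, `n_params` (estimated coefficients excluding the
#'   intercept), `dropped_rows`, and the underlying `lm` fit. P values are
#'   two-sided from the t distribution with `n - n_params - 1` degrees of
#'   freedom.
#' @export
fit_standardized_ols <- function(data, outcome, predictors,
                                 fixed_effects = NULL) {
  dd <- build_design(data, outcome, predictors, fixed_effects)
  fit <- lm(.outcome ~ ., data = dd$frame)
  if (anyNA(coef(fit))) {
    stop(sprintf("rank-deficient design; aliased column(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      std_error = ct[, 2], statistic = ct[, 3],
                      p_value = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = nrow(dd$frame),
                 n_params = fit$rank - 1L,
                 dropped_rows = dd$dropped,
                 method = "ols", fit = fit),
            class = "topo_regression")
}

# Assemble the standardized model frame shared by the OLS and ridge fits.
build_design <- function(data, outcome, predictors, fixed_effects) {
  used <- c(outcome, predictors, fixed_effects)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not in data: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  sub <- data[used]
  keep <- stats::complete.cases(sub)
  dropped <- sum(!keep)
  sub <- sub[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n < length(predictors) + 2L) {
    stop("too few complete rows for the requested model", call. = FALSE)
  }
  zscore <- function(x, what) {
    s <- sd(x)
    if (is.na(s) || s == 0) stop(sprintf("column '%s' is constant", what),
                                 call. = FALSE)
    (x - mean(x)) / s
  }
  frame <- data.frame(.outcome = zscore(sub[[outcome]], outcome))
  for (p in predictors) frame[[p]] <- zscore(sub[[p]], p)
  for (f in fixed_effects) {
    frame[[f]] <- factor(as.character(sub[[f]]))  # levels sorted; first = reference
  }
  list(frame = frame, dropped = dropped)
}

#' @export
print.topo_regression <- function(x, ...) {
  cat(sprintf("Standardized %s regression (n = %d, %d parameters)\n",
              toupper(x$method), x$n, x$n_params))
  cf <- x$coefficients
  cf$estimate <- sprintf("% .4f", cf$estimate)
  if ("std_error" %in% names(cf) && !all(is.na(x$coefficients$std_error))) {
    cf$std_error <- sprintf("%.4f", as.numeric(cf$std_error))
    cf$statistic <- sprintf("% .2f", as.numeric(cf$statistic))
    cf$p_value <- format.pval(as.numeric(cf$p_value), digits = 3)
  }
  print(cf, row.names = FALSE)
  if (!is.na(x$r_squared)) {
    cat(sprintf("R-squared %.4f, adjusted %.4f\n", x$r_squared, x$adj_r_squared))
  }
  if (!is.null(x$lambda)) cat(sprintf("ridge penalty %.6g (10-fold CV)\n", x$lambda))
  invisible(x)
}

# Closed-form ridge solve via SVD: minimizes ||y - Xb||^2 + lambda ||b||^2.
# At lambda = 0 this is the minimum-norm least-squares solution, i.e. exact
# OLS on a full-rank design.
ridge_solve <- function(X, y, lambda) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d[1] * 1e-12, 0)
  dvec <- sv$d[keep]
  shrink <- dvec / (dvec^2 + lambda)
  sv$v[, keep, drop = FALSE] %*% (shrink * crossprod(sv$u[, keep, drop = FALSE], y))
}

#' Ridge regression with cross-validated penalty
#'
#' Same standardized design as [fit_standardized_ols()] (fixed-effect
#' indicators included unpenalized intercept aside: all columns and the
#' outcome are centered within each training set, which absorbs the
#' intercept). The penalty is chosen from `lambda_grid` by k-fold
#' cross-validation with a fixed fold seed, then the model is refit on the
#' full data at the selected penalty. The solution is the exact closed form
#' via the singular value decomposition, so `lambda = 0` reproduces OLS to
#' machine precision and very large penalties shrink every coefficient
#' toward zero.
#'
#' @inheritParams fit_standardized_ols
#' @param lambda_grid nonnegative penalties to evaluate (default 0 together
#'   with a log-spaced grid from 1e-4 to 1e4).
#' @param nfolds folds for cross-validation (default 10).
#' @param seed fold-assignment seed.
#' @return a `topo_regression` with `method = "ridge"`, the selected
#'   `lambda`, and the grid of cross-validated mean squared errors in
#'   `cv_mse`. Standard errors and p values are not reported for penalized
#'   fits.
#' @export
fit_ridge <- function(data, outcome, predictors, fixed_effects = NULL,
                      lambda_grid = c(0, 10^seq(-4, 4, length.out = 41)),
                      nfolds = 10L, seed = 42L) {
  dd <- build_design(data, outcome, predictors, fixed_effects)
  mm <- model.matrix(.outcome ~ ., data = dd$frame)[, -1L, drop = FALSE]
  y <- dd$frame$.outcome
  n <- nrow(mm)
  lambda_grid <- sort(unique(lambda_grid))
  folds <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  cv_mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(nfolds), function(f) {
      tr <- folds != f
      xm <- colMeans(mm[tr, , drop = FALSE])
      ym <- mean(y[tr])
      Xtr <- sweep(mm[tr, , drop = FALSE], 2L, xm)
      b <- ridge_solve(Xtr, y[tr] - ym, lam)
      pred <- ym + sweep(mm[!tr, , drop = FALSE], 2L, xm) %*% b
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv_mse)]
  xm <- colMeans(mm)
  beta <- ridge_solve(sweep(mm, 2L, xm), y - mean(y), lambda)
  fitted <- mean(y) + sweep(mm, 2L, xm) %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  p <- ncol(mm)
  coefs <- data.frame(term = colnames(mm), estimate = as.numeric(beta),
                      std_error = NA_real_, statistic = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 n = n, n_params = p, dropped_rows = dd$dropped,
                 method = "ridge", lambda = lambda,
                 cv_mse = data.frame(lambda = lambda_grid, mse = cv_mse)),
            class = "topo_regression")
}

#' Decompose the association of speed into selection and ordering
#'
#' Speed factorizes as `speed = min_required_speed * circuitousness`: the
#' first factor reflects which concepts were selected (how short a path can
#' connect them), the second how optimally they were ordered. On the log
#' scale the decomposition is additive, so replacing log speed by its two
#' components in an otherwise identical model splits the speed coefficient
#' into a selection part and an ordering part. Fits the two models side by
#' side: volume + speed, and volume + min required speed + circuitousness.
#'
#' @param table feature table with an outcome and the standardized log
#'   feature columns from [process_corpus()]/[aggregate_by_author()].
#' @param outcome name of the outcome column.
#' @param covariates extra continuous controls added to both models.
#' @param fixed_effects categorical controls added to both models.
#' @return object of class `speed_decomposition`: list with `model_speed`
#'   and `model_components`, both `topo_regression`.
#' @export
decompose_speed_effect <- function(table, outcome, covariates = NULL,
                                   fixed_effects = NULL) {
  m1 <- fit_standardized_ols(table, outcome,
                             c("z_log_norm_volume", "z_log_speed", covariates),
                             fixed_effects)
  m2 <- fit_standardized_ols(table, outcome,
                             c("z_log_norm_volume", "z_log_min_required_speed",
                               "z_log_circuitousness", covariates),
                             fixed_effects)
  structure(list(model_speed = m1, model_components = m2),
            class = "speed_decomposition")
}

#' @export
print.speed_decomposition <- function(x, ...) {
  cat("== Model 1: volume + speed ==\n")
  print(x$model_speed)
  cat("\n== Model 2: volume + min required speed + circuitousness ==\n")
  print(x$model_components)
  invisible(x)
}
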