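#' Stepping-strategy regression
#'
#' Ordinary least squares of the foot-placement deviation on the nine
#' midstance CoM-state deviations (position, velocity and acceleration in
#' the AP/ML/VT stride-frame axes). All variables are mean-centred within
#' the fitted stride set and no intercept is used, so each gain is the
#' change in stepping location per unit change of one CoM-state component,
#' and the coefficient of determination measures adherence to the stepping
#' strategy.
#'
#' @param features A per-stride feature tibble from [gait_features()] (or
#'   any data frame with the `pos_x` ... `acc_z` state columns and
#'   `fp_ap` / `fp_ml`).
#' @param direction `"ap"` or `"ml"`: which foot-placement coordinate to
#'   regress.
#' @param min_strides Minimum number of complete strides (default 30).
#' @return A `stepping_fit` object: gains, their standard errors, R^2,
#'   residuals, and the stride ids fitted. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_stepping <- function(features, direction = c("ap", "ml"),
                         min_strides = 30L) {
  direction <- match.arg(direction)
  fp_col <- paste0("fp_", direction)
  cols <- c(state_names(), fp_col)
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L) {
    abort(paste0("features are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ok <- complete.cases(features[cols])
  d <- features[ok, ]
  if (nrow(d) < min_strides) {
    abort(sprintf("only %d complete strides; need at least %d",
                  nrow(d), min_strides))
  }
  X <- scale(as.matrix(d[state_names()]), center = TRUE, scale = FALSE)
  y <- d[[fp_col]] - mean(d[[fp_col]])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0("midstance-state predictors are rank deficient; ",
                 "collinear column(s): ", paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum(y^2)
  df_res <- nrow(X) - ncol(X)
  sigma2 <- rss / df_res
  ord <- order(qrX$pivot)
  xtx_inv <- chol2inv(qr.R(qrX))[ord, ord, drop = FALSE]
  se <- sqrt(diag(xtx_inv) * sigma2)
  structure(
    list(direction = direction,
         gains = setNames(as.numeric(beta), state_names()),
         se = setNames(se, state_names()),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         residuals = as.numeric(res),
         sigma = sqrt(sigma2),
         n_strides = nrow(X),
         df_residual = df_res,
         stride_ids = d$stride %||% seq_len(nrow(X))),
    class = "stepping_fit")
}

#' @export
print.stepping_fit <- function(x, ...) {
  cat(sprintf("<stepping regression (%s): n = %d, R^2 = %.4f>\n",
              toupper(x$direction), x$n_strides, x$r_squared))
  print(round(x$gains, 4))
  invisible(x)
}

#' Per-stride foot-placement error
#'
#' The error of the stepping regression, defined as predicted minus actual
#' foot-placement deviation. Over the fitted stride set this is the
#' negative OLS residual, so its mean is zero.
#'
#' @param fit A `stepping_fit` from [fit_stepping()].
#' @param features Optional feature tibble; must contain exactly the
#'   strides the regression was fitted on.
#' @return A tibble with `stride` and `fp_error` (m).
#' @export
compute_fp_error <- function(fit, features = NULL) {
  if (!inherits(fit, "stepping_fit")) abort("fit must be a stepping_fit")
  if (!is.null(features)) {
    ids <- features$stride %||% seq_len(nrow(features))
    if (!all(fit$stride_ids %in% ids)) {
      abort("features do not contain the strides the regression was fitted on")
    }
  }
  tibble::tibble(stride = fit$stride_ids, fp_error = -fit$residuals)
}

#' Ankle/trunk compensation regression
#'
#' Relates the ML foot-placement error to the deviation of the stance-mean
#' ML centre of pressure (ankle strategy) and of the stride-mean ML trunk
#' angular velocity (trunk strategy): a two-predictor OLS with mean-centred
#' variables and no intercept. Each gain is tested against zero with a
#' t-test.
#'
#' @param error Per-stride foot-placement error (m); e.g.
#'   `compute_fp_error(fit)$fp_error`.
#' @param cop_bar Per-stride stance-mean ML CoP (m).
#' @param trunk_bar Per-stride stride-mean ML trunk angular velocity
#'   (deg/s).
#' @param min_strides Minimum number of complete strides (default 30).
#' @return A `compensation_fit` with `ankle_gain` (dimensionless),
#'   `trunk_gain` (m per deg/s), their SEs, t statistics and p values, and
#'   R^2. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_compensation <- function(error, cop_bar, trunk_bar, min_strides = 30L) {
  ok <- complete.cases(cbind(error, cop_bar, trunk_bar))
  e <- error[ok]; cb <- cop_bar[ok]; tb <- trunk_bar[ok]
  if (length(e) < min_strides) {
    abort(sprintf("only %d complete strides; need at least %d",
                  length(e), min_strides))
  }
  X <- cbind(ankle = cb - mean(cb), trunk = tb - mean(tb))
  if (any(apply(X, 2, function(x) max(abs(x)) < 1e-12))) {
    abort("a compensation predictor is constant; cannot fit")
  }
  y <- e - mean(e)
  qrX <- qr(X)
  if (qrX$rank < 2L) abort("compensation predictors are collinear")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum(y^2)
  df_res <- length(y) - 2L
  sigma2 <- rss / df_res
  se <- sqrt(diag(chol2inv(qr.R(qrX))) * sigma2)
  tval <- as.numeric(beta) / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  structure(
    list(ankle_gain = unname(beta["ankle"]),
         trunk_gain = unname(beta["trunk"]),
         se = setNames(se, c("ankle", "trunk")),
         t_value = setNames(tval, c("ankle", "trunk")),
         p_value = setNames(pval, c("ankle", "trunk")),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         residuals = as.numeric(res),
         n_strides = length(y),
         df_residual = df_res),
    class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<compensation regression: n = %d, R^2 = %.4f\n",
           "  ankle gain %.4f (p = %.3g), trunk gain %.4g (p = %.3g)>\n"),
    x$n_strides, x$r_squared, x$ankle_gain, x$p_value["ankle"],
    x$trunk_gain, x$p_value["trunk"]))
  invisible(x)
}

#' Extract the midstance CoM state of one stride
#'
#' Convenience accessor returning the nine-component midstance state
#' (already computed by [gait_features()]) of one stride as a named
#' vector, in stride-frame coordinates.
#'
#' @param features A feature tibble from [gait_features()].
#' @param stride Stride number.
#' @return Named numeric vector of length 9 (`pos_x` ... `acc_z`).
#' @export
extract_midstance_state <- function(features, stride) {
  row <- features[features$stride == stride, state_names()]
  if (nrow(row) != 1L) abort(sprintf("stride %s not found", stride))
  unlist(row[1, ])
}
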