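#' Nondimensionalization scales from leg length and gravity
#'
#' Lengths are divided by L, velocities by `sqrt(g L)`, accelerations by g
#' and times by `sqrt(L / g)`, so that `velocity_scale^2 = g * L` and
#' `time_scale * velocity_scale = L`.
#'
#' @param L Leg length in m.
#' @param g Gravitational acceleration in m/s^2.
#' @return A `nondim_scales` list with `length_scale`, `velocity_scale`,
#'   `accel_scale` and `time_scale`.
#' @export
#' @examples
#' nondim_scales(0.91, 9.806)$time_scale # ~0.30 s
nondim_scales <- function(L, g = 9.806) {
  if (!is.numeric(L) || L <= 0) abort("leg length L must be positive")
  if (!is.numeric(g) || g <= 0) abort("gravity g must be positive")
  structure(list(L = L, g = g,
                 length_scale = L,
                 velocity_scale = sqrt(g * L),
                 accel_scale = g,
                 time_scale = sqrt(L / g)),
            class = "nondim_scales")
}

#' Nondimensionalize a value
#'
#' @param value Numeric value(s).
#' @param kind One of `"length"`, `"velocity"`, `"acceleration"`, `"time"`.
#' @param scales A [nondim_scales()].
#' @return Dimensionless value(s).
#' @export
nondimensionalize <- function(value, kind, scales) {
  sc <- switch(kind,
               length = scales$length_scale,
               velocity = scales$velocity_scale,
               acceleration = scales$accel_scale,
               time = scales$time_scale,
               abort(paste0("unknown kind: ", kind)))
  value / sc
}

# column -> scale kind for the feature tibble
feature_kinds <- function() {
  c(stride_time = "time", stance_time = "time", speed = "velocity",
    stride_length = "length", step_width = "length",
    fw_mos = "length", bw_mos = "length", bos_extent = "length",
    ml_mos = "length",
    pos_x = "length", pos_y = "length", pos_z = "length",
    vel_x = "velocity", vel_y = "velocity", vel_z = "velocity",
    acc_x = "acceleration", acc_y = "acceleration", acc_z = "acceleration",
    fp_ap = "length", fp_ml = "length", cop_bar = "length")
}

#' Nondimensionalize a per-stride feature tibble
#'
#' Applies the matching scale to every dimensioned feature column; columns
#' without an assigned kind (identifiers, trunk angular velocity in deg/s)
#' are left unchanged.
#'
#' @param features A tibble from [gait_features()].
#' @param scales A [nondim_scales()]; defaults to scales built from the
#'   mean measured leg length.
#' @return The tibble with scaled columns.
#' @export
nondimensionalize_features <- function(features, scales = NULL) {
  scales <- scales %||%
    nondim_scales(mean(features$leg_length, na.rm = TRUE))
  kinds <- feature_kinds()
  for (col in intersect(names(kinds), names(features))) {
    features[[col]] <- nondimensionalize(features[[col]], kinds[[col]],
                                         scales)
  }
  features
}

#' Unpaired two-sample comparison
#'
#' Two-sided t-test between two groups. Both-constant groups with equal
#' means return p = 1 by convention (with a warning).
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param var_equal Pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return A tibble: `test`, `statistic`, `df`, `p`, `eta_squared` (the
#'   two-group effect size `t^2 / (t^2 + df)`).
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 finite observations")
  }
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
    if (abs(mean(a) - mean(b)) < 1e-12) {
      warn("both groups constant and equal; p = 1 by convention")
      return(tibble::tibble(test = "t", statistic = 0,
                            df = length(a) + length(b) - 2, p = 1,
                            eta_squared = 0))
    }
    warn("both groups constant but different; p = 0 by convention")
    return(tibble::tibble(test = "t", statistic = Inf,
                          df = length(a) + length(b) - 2, p = 0,
                          eta_squared = 1))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  tv <- unname(ht$statistic)
  df <- unname(ht$parameter)
  tibble::tibble(test = "t", statistic = tv, df = df,
                 p = unname(ht$p.value),
                 eta_squared = tv^2 / (tv^2 + df))
}

#' One-way analysis of variance with eta-squared
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length), or `values` may be a list of
#'   numeric vectors.
#' @return A tibble: `test`, `statistic` (F), `df1`, `df2`, `p`,
#'   `eta_squared` (= SS_between / SS_total).
#' @export
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) abort("need at least 2 groups")
  if (any(table(groups) < 2L)) abort("every group needs at least 2 values")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  ssb <- tab$`Sum Sq`[1]
  sst <- sum(tab$`Sum Sq`)
  tibble::tibble(test = "anova",
                 statistic = tab$`F value`[1],
                 df1 = tab$Df[1], df2 = tab$Df[2],
                 p = tab$`Pr(>F)`[1],
                 eta_squared = if (sst > 0) ssb / sst else 0)
}

#' Holm-Sidak step-down adjustment of p values
#'
#' Sorts the m p values ascending, adjusts the k-th as
#' `1 - (1 - p_(k))^(m - k + 1)`, enforces monotone non-decrease in sorted
#' order, caps at 1, and returns the adjusted values in the original
#' order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))
holm_sidak <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare a measure across conditions
#'
#' The study's comparison scheme: two groups are compared with an unpaired
#' t-test; three or more with a one-way ANOVA followed by post-hoc pairwise
#' t-tests carrying the Holm-Sidak correction. Effect sizes (eta-squared)
#' are always computed; a report layer may gate them on significance.
#'
#' @param data A data frame.
#' @param value Name of the measure column.
#' @param group Name of the grouping column.
#' @param var_equal Pooled-variance t-tests when `TRUE`.
#' @param alpha Significance level used for the `significant` flag.
#' @return A list with `omnibus` (one-row tibble) and `posthoc` (pairwise
#'   tibble with raw and adjusted p, `NULL` for two groups).
#' @export
compare_conditions <- function(data, value, group = "condition",
                               var_equal = TRUE, alpha = 0.05) {
  v <- data[[value]]
  gl <- factor(data[[group]])
  keep <- is.finite(v) & !is.na(gl)
  v <- v[keep]; gl <- droplevels(gl[keep])
  lv <- levels(gl)
  if (length(lv) < 2L) abort("need at least 2 groups to compare")
  if (length(lv) == 2L) {
    om <- unpaired_t(v[gl == lv[1]], v[gl == lv[2]], var_equal = var_equal)
    om$measure <- value
    om$significant <- om$p < alpha
    return(list(omnibus = om, posthoc = NULL))
  }
  om <- one_way_anova(v, gl)
  om$measure <- value
  om$significant <- om$p < alpha
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  ph <- purrr::map_dfr(pairs, function(pr) {
    tt <- unpaired_t(v[gl == pr[1]], v[gl == pr[2]], var_equal = var_equal)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = tt$statistic, df = tt$df, p = tt$p)
  })
  ph$p_adjusted <- holm_sidak(ph$p)
  ph$significant <- ph$p_adjusted < alpha
  list(omnibus = om, posthoc = ph)
}
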