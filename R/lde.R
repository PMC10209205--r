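#' Local divergence exponent of a stride-normalized series
#'
#' Rosenstein-type estimation: the scalar series (typically one component
#' of the stride-normalized CoM velocity, concatenated over many strides)
#' is delay-embedded; each embedded point's nearest neighbour is found
#' excluding temporal neighbours within one mean stride (a Theiler window);
#' the mean log Euclidean divergence is tracked over forward offsets; and
#' the LDE is the least-squares slope of that divergence curve over
#' `fit_range`, expressed per stride-normalized time unit.
#'
#' Distances of exactly zero (a perfectly periodic series) are floored at
#' `1e-12` before taking logs, which yields a flat divergence curve and an
#' LDE of zero in the noise-free limit.
#'
#' @param series Numeric vector: the concatenated stride-normalized signal.
#' @param dim Embedding dimension (default 5).
#' @param delay Embedding delay in samples (default 10).
#' @param stride_len Samples per stride in the normalized series (default
#'   100); sets the time unit, the Theiler window and the divergence
#'   horizon.
#' @param fit_range Fit interval of the divergence curve, in strides
#'   (default 0 to 0.5).
#' @param theiler Temporal exclusion window in samples (default one
#'   stride).
#' @param horizon Divergence-tracking horizon in strides (default 1).
#' @return An `lde_fit` list: `lde` (slope per stride), `curve` (tibble of
#'   `time_strides`, `mean_log_dist`), `n_points`, and the parameters used.
#' @export
compute_lde <- function(series, dim = 5L, delay = 10L, stride_len = 100L,
                        fit_range = c(0, 0.5), theiler = stride_len,
                        horizon = 1) {
  series <- as.numeric(series)
  n <- length(series)
  K <- round(horizon * stride_len)
  min_len <- (dim - 1L) * delay + K + 2L * theiler
  if (n < min_len) {
    abort(sprintf(
      "series too short for embedding: %d samples, need at least %d",
      n, min_len))
  }
  N <- n - (dim - 1L) * delay
  emb <- vapply(0:(dim - 1L), function(j) series[(1:N) + j * delay],
                numeric(N))
  n_ref <- N - K
  cand_norm2 <- rowSums(emb[1:n_ref, , drop = FALSE]^2)

  # nearest neighbour per reference point, Theiler-excluded, computed in
  # row blocks via the Gram-matrix expansion so BLAS does the heavy work
  nn <- integer(n_ref)
  block <- 1024L
  cand <- t(emb[1:n_ref, , drop = FALSE])
  for (b0 in seq(1L, n_ref, by = block)) {
    b1 <- min(b0 + block - 1L, n_ref)
    rows <- b0:b1
    # per-row argmin of |x_i - x_j|^2 = argmin_j (|x_j|^2 - 2 x_i.x_j)
    d2 <- emb[rows, , drop = FALSE] %*% cand
    d2 <- rep(cand_norm2, each = length(rows)) - 2 * d2
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      lo <- max(1L, i - theiler); hi <- min(n_ref, i + theiler)
      d2[ri, lo:hi] <- Inf
    }
    nn[rows] <- max.col(-d2, ties.method = "first")
  }

  ii <- 1:n_ref
  curve <- vapply(0:K, function(k) {
    d2 <- rowSums((emb[ii + k, , drop = FALSE] -
                     emb[nn + k, , drop = FALSE])^2)
    mean(log(pmax(sqrt(d2), 1e-12)))
  }, numeric(1))
  tcurve <- (0:K) / stride_len
  cdf <- tibble::tibble(time_strides = tcurve, mean_log_dist = curve)
  sel <- tcurve >= fit_range[1] & tcurve <= fit_range[2]
  fit <- lm(mean_log_dist ~ time_strides, data = cdf[sel, ])
  structure(
    list(lde = unname(coef(fit)[2]), curve = cdf,
         fit_range = fit_range, n_points = N,
         dim = dim, delay = delay, stride_len = stride_len),
    class = "lde_fit")
}

#' @export
print.lde_fit <- function(x, ...) {
  cat(sprintf(
    "<LDE fit: %.4f per stride (dim %d, delay %d, %d embedded points)>\n",
    x$lde, x$dim, x$delay, x$n_points))
  invisible(x)
}

#' Stride-normalized CoM velocity series for LDE input
#'
#' Resamples each stride's CoM velocity component to `stride_len` points
#' (cubic spline on the half-open stride, so concatenation does not repeat
#' boundary samples) and concatenates the requested number of strides.
#'
#' @param kin A [kin_recording()].
#' @param events A `gait_events` object.
#' @param component `"ap"`, `"ml"` or `"vt"` (stride-frame x/y/z; the
#'   global axes are used directly, consistent with straight-path walking;
#'   per-stride frames rotate only in the horizontal plane).
#' @param n_strides Number of strides to concatenate; defaults to all
#'   available.
#' @param stride_len Samples per normalized stride (default 100).
#' @return Numeric vector of length `n_strides * stride_len`.
#' @export
normalized_com_velocity <- function(kin, events,
                                    component = c("ap", "ml", "vt"),
                                    n_strides = NULL, stride_len = 100L) {
  component <- match.arg(component)
  col <- c(ap = "com_x", ml = "com_y", vt = "com_z")[[component]]
  fs <- rate_of(kin)
  vel <- central_diff(kin[[col]], 1 / fs)
  rhs <- events$rhs
  avail <- length(rhs) - 1L
  n_strides <- n_strides %||% avail
  if (n_strides > avail) {
    abort(sprintf("requested %d strides but only %d available",
                  n_strides, avail))
  }
  out <- numeric(n_strides * stride_len)
  for (k in seq_len(n_strides)) {
    i0 <- rhs[k]; i1 <- rhs[k + 1L]
    tq <- seq(kin$time[i0], kin$time[i1],
              length.out = stride_len + 1L)[1:stride_len]
    out[((k - 1L) * stride_len + 1L):(k * stride_len)] <-
      spline(kin$time[i0:i1], vel[i0:i1], xout = tq, method = "fmm")$y
  }
  out
}
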