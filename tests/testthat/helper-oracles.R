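# Independent brute-force oracle for the divergence curve: plain O(n^2)
# nearest-neighbour search and direct distance tracking, sharing only the
# definition (Theiler exclusion, first-index tie-break, 1e-12 log floor).
brute_divergence_curve <- function(series, dim, delay, theiler, K) {
  N <- length(series) - (dim - 1L) * delay
  emb <- sapply(0:(dim - 1L), function(j) series[(1:N) + j * delay])
  n_ref <- N - K
  nn <- integer(n_ref)
  for (i in 1:n_ref) {
    best <- Inf
    bj <- NA_integer_
    for (j in 1:n_ref) {
      if (abs(i - j) <= theiler) next
      d <- sum((emb[i, ] - emb[j, ])^2)
      if (d < best) {
        best <- d
        bj <- j
      }
    }
    nn[i] <- bj
  }
  sapply(0:K, function(k) {
    d <- sqrt(rowSums((emb[(1:n_ref) + k, , drop = FALSE] -
                         emb[nn + k, , drop = FALSE])^2))
    mean(log(pmax(d, 1e-12)))
  })
}

# a periodic stride-like waveform
periodic_series <- function(n_strides, stride_len = 100L) {
  s <- (0:(stride_len - 1L)) / stride_len
  rep(sin(2 * pi * s) + 0.4 * sin(4 * pi * s), n_strides)
}

# brute-force scan for upward force-threshold crossings
brute_crossings <- function(f, threshold) {
  which(f >= threshold & c(Inf, f[-length(f)]) < threshold)
}
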