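# Shared simulated trials, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# a noiseless walker: every regression target is exactly recoverable
noiseless_sim <- function() {
  cached("noiseless", simulate_walker(
    sim_config(n_strides = 40, fp_noise_sd = 0, compensation_noise_sd = 0,
               seed = 101)))
}

# default noise levels, known clock offset zero
noisy_sim <- function() {
  cached("noisy", simulate_walker(sim_config(n_strides = 60, seed = 102)))
}

# foot-placement noise but a fully explained compensation split
comp_exact_sim <- function() {
  cached("comp_exact", simulate_walker(
    sim_config(n_strides = 60, fp_noise_sd = 0.008,
               compensation_noise_sd = 0, seed = 103)))
}

noiseless_features <- function() {
  cached("noiseless_feats", {
    s <- noiseless_sim()
    gait_features(s$kin, s$insole, clock_offset = 0)
  })
}

noisy_features <- function() {
  cached("noisy_feats", {
    s <- noisy_sim()
    gait_features(s$kin, s$insole, clock_offset = 0)
  })
}

comp_exact_features <- function() {
  cached("comp_exact_feats", {
    s <- comp_exact_sim()
    gait_features(s$kin, s$insole, clock_offset = 0)
  })
}

# minimal flat-line kinematic recording (standing still)
standing_recording <- function(duration = 5, fs = 120) {
  t <- seq(0, duration, by = 1 / fs)
  df <- tibble::tibble(time = t)
  for (ch in gaitstab:::kin_channel_names()) df[[ch]] <- 0
  df$com_z <- 0.9
  kin_recording(df, fs)
}
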