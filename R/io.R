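#' Write and read recording fixtures
#'
#' Recordings are stored as plain CSV time series: one kinematic file
#' (`<name>_kin.csv`: time plus landmark/axis columns) and one insole file
#' per foot (`<name>_insole_left.csv`, `<name>_insole_right.csv`: time,
#' vgrf, cop_ml), plus a JSON sidecar (`<name>_truth.json`) holding the
#' simulation configuration and ground truth when the fixture was
#' generated.
#'
#' @param sim A `gait_sim` from [simulate_walker()].
#' @param dir Directory (created if needed).
#' @param name Fixture base name.
#' @return `write_gait_sim()` returns the file paths invisibly;
#'   `read_gait_recordings()` returns a list with `kin`, `insole` and
#'   (when the sidecar exists) `truth`.
#' @name fixture_io
NULL

#' @rdname fixture_io
#' @export
write_gait_sim <- function(sim, dir, name) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory ", dir))
  }
  paths <- c(
    kin = file.path(dir, paste0(name, "_kin.csv")),
    left = file.path(dir, paste0(name, "_insole_left.csv")),
    right = file.path(dir, paste0(name, "_insole_right.csv")),
    truth = file.path(dir, paste0(name, "_truth.json")))
  readr::write_csv(tibble::as_tibble(sim$kin), paths["kin"])
  ins <- sim$insole
  readr::write_csv(tibble::tibble(time = ins$time, vgrf = ins$vgrf_left,
                                  cop_ml = ins$cop_ml_left), paths["left"])
  readr::write_csv(tibble::tibble(time = ins$time, vgrf = ins$vgrf_right,
                                  cop_ml = ins$cop_ml_right), paths["right"])
  cfg <- sim$truth$config
  side <- list(
    config = cfg[setdiff(names(cfg), c("stepping_gains", "com_state_cov"))],
    stepping_gains = cfg$stepping_gains,
    com_state_cov = cfg$com_state_cov,
    sample_rate_kin = rate_of(sim$kin),
    sample_rate_insole = rate_of(sim$insole),
    walk_start = sim$truth$walk_start,
    clock_offset = sim$truth$clock_offset,
    rhs_times = sim$truth$rhs_times,
    lhs_times = sim$truth$lhs_times,
    rto_times = sim$truth$rto_times,
    lto_times = sim$truth$lto_times,
    mid_times = sim$truth$mid_times,
    ankle_gain = sim$truth$ankle_gain,
    trunk_gain = sim$truth$trunk_gain,
    strides = sim$truth$strides)
  jsonlite::write_json(side, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' @rdname fixture_io
#' @export
read_gait_recordings <- function(dir, name) {
  kin_path <- file.path(dir, paste0(name, "_kin.csv"))
  kin_df <- read_schema_csv(kin_path, c("time", kin_channel_names()))
  left <- read_schema_csv(file.path(dir, paste0(name, "_insole_left.csv")),
                          c("time", "vgrf", "cop_ml"))
  right <- read_schema_csv(file.path(dir, paste0(name, "_insole_right.csv")),
                           c("time", "vgrf", "cop_ml"))
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  truth <- NULL
  walk_start_kin <- 0
  walk_start_ins <- 0
  rate_kin <- infer_rate(kin_df$time)
  rate_ins <- infer_rate(left$time)
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    walk_start_kin <- truth$walk_start %||% 0
    walk_start_ins <- walk_start_kin + (truth$clock_offset %||% 0)
  }
  ins <- tibble::tibble(
    time = left$time,
    vgrf_right = right$vgrf, cop_ml_right = right$cop_ml,
    vgrf_left = left$vgrf, cop_ml_left = left$cop_ml)
  list(kin = kin_recording(kin_df, rate_kin, walk_start = walk_start_kin),
       insole = insole_recording(ins, rate_ins,
                                 walk_start = walk_start_ins),
       truth = truth)
}

read_schema_csv <- function(path, need) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(paste0(basename(path), " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

infer_rate <- function(time) {
  dt <- stats::median(diff(time))
  round(1 / dt)
}

#' Write the standard fixture library
#'
#' Generates and writes four named fixture pairs with their ground-truth
#' sidecars: `noiseless` (zero noise everywhere), `noisy` (default noise
#' levels), `zerogain` (no stepping control, zero noise) and
#' `offset_clock` (default noise, insole clock shifted by 0.37 s).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_strides Strides per fixture (default 40).
#' @param seed Base seed; fixture seeds are derived deterministically.
#' @return Invisibly, a named list of the path sets.
#' @export
make_fixture_suite <- function(out_dir, n_strides = 40L, seed = 1L) {
  zero_cfg <- function(...) {
    sim_config(n_strides = n_strides, fp_noise_sd = 0,
               compensation_noise_sd = 0, ...)
  }
  cfgs <- list(
    noiseless = zero_cfg(seed = seed),
    noisy = sim_config(n_strides = n_strides, seed = seed + 1L),
    zerogain = zero_cfg(stepping_gains = matrix(0, 2, 9), seed = seed + 2L),
    offset_clock = sim_config(n_strides = n_strides, clock_offset = 0.37,
                              seed = seed + 3L))
  paths <- lapply(names(cfgs), function(nm) {
    write_gait_sim(simulate_walker(cfgs[[nm]]), out_dir, nm)
  })
  names(paths) <- names(cfgs)
  invisible(paths)
}

#' Published reference values of the outdoor walking study
#'
#' Summary statistics reported by the outdoor summer/winter walking study
#' that this package's pipeline re-implements: study context (seasonal
#' mean temperatures, mean leg length, scale constants) and the
#' nondimensional group summaries of the stability and spatiotemporal
#' measures per condition (S: summer; W1: winter, cleared ground;
#' W2: winter, snow/ice-covered ground).
#'
#' @return A tibble with columns `section`, `measure`, `condition`,
#'   `mean`, `sd`.
#' @export
study_reference <- function() {
  path <- system.file("extdata", "study_reference.csv",
                      package = "gaitstab", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Simulates a trial, writes the fixture CSVs, runs the stride-level
#' analysis, the stepping and compensation regressions and the local
#' divergence exponents, and writes tidy result CSVs plus a JSON manifest
#' (configuration hash, seed, file list). Identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param lde_params List of LDE settings (`dim`, `delay`, `stride_len`,
#'   `fit_range`).
#' @param alpha Significance level recorded in the report.
#' @return Invisibly, a list with the computed objects (`features`,
#'   `stepping_ap`, `stepping_ml`, `compensation`, `lde`, `summary`) and
#'   the output paths.
#' @export
run_gait_pipeline <- function(config, out_dir,
                              lde_params = list(dim = 5L, delay = 10L,
                                                stride_len = 100L,
                                                fit_range = c(0, 0.5)),
                              alpha = 0.05) {
  sim <- simulate_walker(config)
  write_gait_sim(sim, out_dir, "trial")

  events <- detect_events_kinematic(sim$kin)
  offset <- synchronize_jumps(sim$kin, sim$insole,
                              gravity = config$gravity)
  feats <- gait_features(sim$kin, sim$insole, events = events,
                         clock_offset = offset,
                         condition = config$condition,
                         g = config$gravity)
  readr::write_csv(feats, file.path(out_dir, "stride_features.csv"))

  fits <- list(
    ap = fit_stepping(feats, "ap"),
    ml = fit_stepping(feats, "ml"))
  err <- compute_fp_error(fits$ml)
  comp <- fit_compensation(err$fp_error,
                           feats$cop_bar[feats$stride %in% err$stride],
                           feats$trunk_bar[feats$stride %in% err$stride])
  reg_tidy <- dplyr::bind_rows(
    dplyr::mutate(tidy(fits$ap), model = "stepping_ap"),
    dplyr::mutate(tidy(fits$ml), model = "stepping_ml"),
    dplyr::mutate(tidy(comp), model = "compensation"))
  readr::write_csv(reg_tidy, file.path(out_dir, "regressions.csv"))
  jsonlite::write_json(
    list(stepping_ap = glance(fits$ap), stepping_ml = glance(fits$ml),
         compensation = glance(comp)),
    file.path(out_dir, "regressions.json"), digits = NA, auto_unbox = TRUE)

  lde <- purrr::map_dfr(c("ap", "ml", "vt"), function(comp_dir) {
    series <- normalized_com_velocity(sim$kin, events, comp_dir,
                                      stride_len = lde_params$stride_len)
    fit <- compute_lde(series, dim = lde_params$dim,
                       delay = lde_params$delay,
                       stride_len = lde_params$stride_len,
                       fit_range = lde_params$fit_range)
    tibble::tibble(component = comp_dir, lde = fit$lde,
                   n_points = fit$n_points)
  })
  readr::write_csv(lde, file.path(out_dir, "lde.csv"))

  scales <- nondim_scales(mean(feats$leg_length), config$gravity)
  summ <- summarize_gait(nondimensionalize_features(feats, scales))
  readr::write_csv(summ, file.path(out_dir, "summary.csv"))

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    alpha = alpha,
    n_strides = config$n_strides,
    files = c("trial_kin.csv", "trial_insole_left.csv",
              "trial_insole_right.csv", "trial_truth.json",
              "stride_features.csv", "regressions.csv",
              "regressions.json", "lde.csv", "summary.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(features = feats, stepping_ap = fits$ap,
                 stepping_ml = fits$ml, compensation = comp, lde = lde,
                 summary = summ, out_dir = out_dir))
}
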