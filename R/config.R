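#' Pipeline configuration and detection thresholds
#'
#' Bundles every tunable of the pipeline. The error-rule thresholds default
#' to the operative values of the published validation set: 130 deg open
#' elbow, 120 deg open shoulder, 1 s supporting-hand grip time, 200 mm
#' knee-to-foot pass distance, 50 mm hip distance to the reference climber,
#' and 30 frames minimum valid movement.
#'
#' @param k_phi elbow-angle threshold, degrees.
#' @param k_theta shoulder-angle threshold, degrees.
#' @param k_t maximum supporting-hand motion time in the reaching phase,
#'   seconds.
#' @param k_dknee knee-past-foot distance threshold, mm.
#' @param k_dhip hip-to-reference distance threshold, mm.
#' @param k_mu minimum motion-interval length, frames.
#' @param eps_contact wall-contact tolerance for the feet, mm: a foot
#'   further than this from the wall plane counts as off the wall (the feet
#'   rest on protruding holds, so exact plane contact never happens).
#' @param min_event_frames minimum error-event length, frames (suppresses
#'   single-frame jitter flags).
#' @param min_phase_frames minimum phase-instance length, frames.
#' @param n_sigma sigma multiplier of the motion-segmentation envelope.
#' @param window rolling-window width of the envelope, frames.
#' @param rho envelope threshold fraction of the maximum.
#' @param smooth_window speed moving-average width, frames (odd).
#' @param fps frames per second of the recordings.
#' @param ransac_iterations,ransac_tol RANSAC settings for wall calibration.
#' @param seed integer seed for every random stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_phi = 130, k_theta = 120, k_t = 1,
                            k_dknee = 200, k_dhip = 50, k_mu = 30,
                            eps_contact = 150, min_event_frames = 5,
                            min_phase_frames = 5,
                            n_sigma = 2, window = 15, rho = 0.5,
                            smooth_window = 9, fps = 60,
                            ransac_iterations = 500, ransac_tol = 20,
                            seed = 1) {
  cfg <- list(k_phi = k_phi, k_theta = k_theta, k_t = k_t, k_dknee = k_dknee,
              k_dhip = k_dhip, k_mu = k_mu, eps_contact = eps_contact,
              min_event_frames = min_event_frames,
              min_phase_frames = min_phase_frames,
              n_sigma = n_sigma, window = window, rho = rho,
              smooth_window = smooth_window, fps = fps,
              ransac_iterations = ransac_iterations, ransac_tol = ransac_tol,
              seed = seed)
  num <- setdiff(names(cfg), "seed")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || !is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      ct_stop("config_error", "config field '%s' must be a positive number", k)
  }
  if (cfg$rho >= 1) ct_stop("config_error", "rho must be in (0, 1)")
  if (cfg$smooth_window %% 2 == 0)
    ct_stop("config_error", "smooth_window must be odd")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      ct_stop("config_error", "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    ct_stop("config_error", "unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
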