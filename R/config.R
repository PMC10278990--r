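#' Scenario configuration for synthetic recordings
#'
#' Bundles every parameter of the synthetic two-channel recording: the
#' acquisition geometry, the locomotion episode model, astrocytic and
#' neuronal calcium kinetics, and the camera noise model. The defaults
#' describe the emulated experiment: 10-minute 512 x 512 recordings at
#' 30 frames/s of cortical layer-1 cells in a head-fixed running mouse.
#' Tests and examples pass smaller `fov`/`duration_s` for speed; the
#' phenomena are scale-free.
#'
#' @param duration_s recording length in seconds.
#' @param fs_raw raw acquisition rate, Hz.
#' @param fov field of view in pixels, `c(H, W)` (a scalar is squared).
#' @param n_astro number of astrocytes in the scene.
#' @param n_neuro_units number of neuronal activity units in the scene.
#' @param mean_run_s,mean_quiet_s mean locomotion / quiescence episode
#'   lengths, seconds (exponential episode model).
#' @param paired_prob probability that a run is followed, after a short gap,
#'   by a second run forming a closely timed pair.
#' @param paired_gap_s quiescent gap inside a pair, seconds; must be < 30 so
#'   that the pair qualifies as closely timed.
#' @param run_speed_cms plateau running speed, cm/s.
#' @param astro_onset_lag_s lag from run onset to the astrocytic process
#'   calcium onset, seconds.
#' @param soma_delay_s centripetal delay: soma onset lags process onset by
#'   this many seconds (default 4.7 s, a typical soma-process latency).
#' @param soma_amp somatic amplification of the process peak (default 2.7,
#'   a typical soma/process peak dF/F ratio).
#' @param astro_peak_dff process peak response, dF/F fraction (1.7 = 170%).
#' @param astro_rise_s,astro_decay_s astrocytic transient time constants, s.
#' @param osc_freq_hz somatic oscillation frequency, Hz, within [0.1, 0.3].
#' @param osc_amp relative amplitude of the somatic oscillation (0 disables).
#' @param depletion_alpha paired-run depletion factor in (0, 1]: the second
#'   run of a pair evokes `alpha` times the first response.
#' @param neuro_lag_s lag from run onset to neuronal response, seconds.
#' @param neuro_peak_dff neuronal peak response, dF/F fraction.
#' @param neuro_rise_s,neuro_decay_s neuronal kernel time constants, s.
#' @param quiescent_frac fraction of neuronal units that are quiescent-active
#'   (high spontaneous activity outside runs).
#' @param q_event_rate_hz event rate of quiescent-active units during
#'   quiescence, Hz.
#' @param gain photon gain of the Poisson branch of the camera model
#'   (0 disables shot noise).
#' @param read_sd Gaussian read-noise SD in counts (0 disables).
#' @param max_shift_px per-frame cap on the rigid drift random walk, pixels.
#' @param psf_sigma_px Gaussian point-spread sigma applied to the emitted
#'   structure, pixels (diffraction-limited optics; 0 disables).
#' @param domain_radius_px,soma_radius_px astrocyte morphology radii, px.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(duration_s = 600, fs_raw = 30, fov = c(512L, 512L),
                            n_astro = 4L, n_neuro_units = 12L,
                            mean_run_s = 15, mean_quiet_s = 45,
                            paired_prob = 0.25, paired_gap_s = 15,
                            run_speed_cms = 10,
                            astro_onset_lag_s = 1, soma_delay_s = 4.7,
                            soma_amp = 2.7, astro_peak_dff = 1.7,
                            astro_rise_s = 2, astro_decay_s = 4,
                            osc_freq_hz = 0.2, osc_amp = 0.2,
                            depletion_alpha = 0.32,
                            neuro_lag_s = 0, neuro_peak_dff = 0.5,
                            neuro_rise_s = 0.05, neuro_decay_s = 0.3,
                            quiescent_frac = 0.5, q_event_rate_hz = 0.4,
                            gain = 1, read_sd = 1.5, max_shift_px = 2L,
                            psf_sigma_px = 0.8,
                            domain_radius_px = 20, soma_radius_px = 6,
                            seed = 1L) {
  if (length(fov) == 1L) fov <- c(fov, fov)
  cfg <- list(duration_s = duration_s, fs_raw = fs_raw,
              fov = as.integer(fov),
              n_astro = as.integer(n_astro),
              n_neuro_units = as.integer(n_neuro_units),
              mean_run_s = mean_run_s, mean_quiet_s = mean_quiet_s,
              paired_prob = paired_prob, paired_gap_s = paired_gap_s,
              run_speed_cms = run_speed_cms,
              astro_onset_lag_s = astro_onset_lag_s,
              soma_delay_s = soma_delay_s, soma_amp = soma_amp,
              astro_peak_dff = astro_peak_dff,
              astro_rise_s = astro_rise_s, astro_decay_s = astro_decay_s,
              osc_freq_hz = osc_freq_hz, osc_amp = osc_amp,
              depletion_alpha = depletion_alpha,
              neuro_lag_s = neuro_lag_s, neuro_peak_dff = neuro_peak_dff,
              neuro_rise_s = neuro_rise_s, neuro_decay_s = neuro_decay_s,
              quiescent_frac = quiescent_frac,
              q_event_rate_hz = q_event_rate_hz,
              gain = gain, read_sd = read_sd,
              max_shift_px = as.integer(max_shift_px),
              psf_sigma_px = psf_sigma_px,
              domain_radius_px = domain_radius_px,
              soma_radius_px = soma_radius_px,
              seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  stopifnot_cfg(cfg$duration_s > 0, "duration_s must be > 0")
  stopifnot_cfg(cfg$fs_raw > 0, "fs_raw must be > 0")
  stopifnot_cfg(all(cfg$fov >= 8L), "fov must be at least 8 px")
  stopifnot_cfg(cfg$n_astro >= 0L && cfg$n_neuro_units >= 0L,
                "cell counts must be >= 0")
  stopifnot_cfg(cfg$depletion_alpha > 0 && cfg$depletion_alpha <= 1,
                "depletion_alpha must lie in (0, 1]")
  stopifnot_cfg(cfg$osc_freq_hz >= 0.1 && cfg$osc_freq_hz <= 0.3,
                "osc_freq_hz must lie in [0.1, 0.3]")
  stopifnot_cfg(cfg$paired_gap_s > 0 && cfg$paired_gap_s < 30,
                "paired_gap_s must lie in (0, 30)")
  stopifnot_cfg(cfg$paired_prob >= 0 && cfg$paired_prob <= 1,
                "paired_prob must lie in [0, 1]")
  stopifnot_cfg(cfg$gain >= 0 && cfg$read_sd >= 0 && cfg$max_shift_px >= 0 &&
                  cfg$psf_sigma_px >= 0,
                "noise parameters must be >= 0")
  stopifnot_cfg(cfg$soma_radius_px < cfg$domain_radius_px,
                "soma radius must be smaller than domain radius")
  invisible(cfg)
}

stopifnot_cfg <- function(ok, msg) {
  if (!isTRUE(ok)) stop("configuration error: ", msg, call. = FALSE)
}
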