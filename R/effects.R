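#' Effect configuration for the session simulator
#'
#' Bundles every tunable group effect the simulator can inject into the raw
#' interaction streams. Disease (PD) effects act on tracing noise, tremor,
#' timing and false key presses; device effects act on response latency and
#' pointer noise; handedness acts as a noise penalty when the task hand is
#' not the dominant hand (the simulated pointing device is operated with the
#' right hand, so the penalty applies to left-dominant participants).
#'
#' A configuration with every multiplier equal to 1 and every additive term
#' equal to 0 (see [null_effects()]) produces group-exchangeable data: no
#' extracted feature depends on label, sex, race, device or hand.
#'
#' @param pd_deviation_scale Multiplier (>= 0) on the tracing-noise standard
#'   deviation for PD participants.
#' @param pd_tremor_amp Tremor amplitude in pixels, added for PD participants.
#' @param pd_tremor_freq Tremor frequency in Hz.
#' @param pd_time_scale Multiplier on task durations / response times for PD.
#' @param pd_false_press_scale Multiplier on the false key-press probability
#'   for PD participants.
#' @param pd_memory_penalty Additive reduction (in items) of working-memory
#'   capacity for PD participants.
#' @param device_latency_ms Named numeric vector of added response latency per
#'   device (`Windows`, `Mac`, `Linux`), milliseconds.
#' @param device_noise_scale Named numeric vector of pointer-noise multipliers
#'   per device.
#' @param device_pd_attenuation Named numeric vector of per-device multipliers
#'   on the PD effect magnitude (1 = full PD signal on that device; values
#'   below 1 shrink every PD effect towards the control behaviour for users
#'   of that device, which is how a device-linked masking bias is injected).
#' @param hand_nondominant_penalty Noise multiplier applied when the task hand
#'   differs from the dominant hand.
#' @param base_noise_sd Baseline tracing-noise standard deviation, pixels.
#' @param base_rt_ms Baseline key-press response time, milliseconds.
#' @param rt_noise_sd_ms Standard deviation of response-time noise, ms.
#' @param base_click_rt_ms Baseline click latency, milliseconds.
#' @param click_noise_sd_px Standard deviation of click placement error, px.
#' @param base_false_press_p Baseline false key-press probability.
#' @param between_subject_sd_time Log-scale s.d. of the per-participant
#'   speed multiplier (between-subject variability of task durations and
#'   response times; group-neutral).
#' @param between_subject_sd_noise Log-scale s.d. of the per-participant
#'   motor-noise multiplier (group-neutral).
#' @param between_subject_rt_sd_ms Between-subject s.d. of the response-time
#'   offset, ms (group-neutral).
#' @param sample_rate_hz Pointer sampling rate, Hz.
#' @param noise_ar Lag-1 autocorrelation of the tracing offset process.
#' @return An object of class `motorfair_effects` (a validated list).
#' @export
effect_config <- function(pd_deviation_scale = 1.6,
                          pd_tremor_amp = 4,
                          pd_tremor_freq = 5,
                          pd_time_scale = 1.25,
                          pd_false_press_scale = 2,
                          pd_memory_penalty = 0.5,
                          device_latency_ms = c(Windows = 20, Mac = 0, Linux = 10),
                          device_noise_scale = c(Windows = 1, Mac = 1, Linux = 1),
                          device_pd_attenuation = c(Windows = 1, Mac = 1, Linux = 1),
                          hand_nondominant_penalty = 1.15,
                          base_noise_sd = 6,
                          base_rt_ms = 600,
                          rt_noise_sd_ms = 80,
                          base_click_rt_ms = 900,
                          click_noise_sd_px = 8,
                          base_false_press_p = 0.03,
                          between_subject_sd_time = 0.18,
                          between_subject_sd_noise = 0.35,
                          between_subject_rt_sd_ms = 50,
                          sample_rate_hz = 60,
                          noise_ar = 0.9) {
  eff <- list(
    pd_deviation_scale = pd_deviation_scale,
    pd_tremor_amp = pd_tremor_amp,
    pd_tremor_freq = pd_tremor_freq,
    pd_time_scale = pd_time_scale,
    pd_false_press_scale = pd_false_press_scale,
    pd_memory_penalty = pd_memory_penalty,
    device_latency_ms = device_latency_ms,
    device_noise_scale = device_noise_scale,
    device_pd_attenuation = device_pd_attenuation,
    hand_nondominant_penalty = hand_nondominant_penalty,
    base_noise_sd = base_noise_sd,
    base_rt_ms = base_rt_ms,
    rt_noise_sd_ms = rt_noise_sd_ms,
    base_click_rt_ms = base_click_rt_ms,
    click_noise_sd_px = click_noise_sd_px,
    base_false_press_p = base_false_press_p,
    between_subject_sd_time = between_subject_sd_time,
    between_subject_sd_noise = between_subject_sd_noise,
    between_subject_rt_sd_ms = between_subject_rt_sd_ms,
    sample_rate_hz = sample_rate_hz,
    noise_ar = noise_ar
  )
  validate_effects(eff)
  structure(eff, class = "motorfair_effects")
}

#' Null effect configuration
#'
#' All group-linked multipliers 1 and additive group terms 0, so label,
#' device and hand have no influence on the generated streams; baseline
#' noise and timing terms are retained (the data are noisy but
#' group-exchangeable).
#'
#' @param ... Overrides forwarded to [effect_config()].
#' @return A `motorfair_effects` object.
#' @export
null_effects <- function(...) {
  args <- list(
    pd_deviation_scale = 1, pd_tremor_amp = 0, pd_time_scale = 1,
    pd_false_press_scale = 1, pd_memory_penalty = 0,
    device_latency_ms = c(Windows = 0, Mac = 0, Linux = 0),
    device_noise_scale = c(Windows = 1, Mac = 1, Linux = 1),
    device_pd_attenuation = c(Windows = 1, Mac = 1, Linux = 1),
    hand_nondominant_penalty = 1
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(effect_config, args)
}

validate_effects <- function(eff) {
  mults <- c(eff$pd_deviation_scale, eff$pd_time_scale,
             eff$pd_false_press_scale, eff$device_noise_scale,
             eff$device_pd_attenuation, eff$hand_nondominant_penalty)
  if (any(!is.finite(mults)) || any(mults < 0))
    stop("effect multipliers must be finite and >= 0", call. = FALSE)
  if (eff$pd_tremor_amp < 0 || eff$base_noise_sd < 0 || eff$rt_noise_sd_ms < 0)
    stop("noise amplitudes must be >= 0", call. = FALSE)
  if (eff$between_subject_sd_time < 0 || eff$between_subject_sd_noise < 0 ||
      eff$between_subject_rt_sd_ms < 0)
    stop("between-subject variability terms must be >= 0", call. = FALSE)
  for (nm in c("device_latency_ms", "device_noise_scale", "device_pd_attenuation")) {
    if (!all(c("Windows", "Mac", "Linux") %in% names(eff[[nm]])))
      stop(sprintf("%s must name Windows, Mac and Linux", nm), call. = FALSE)
  }
  if (eff$noise_ar < 0 || eff$noise_ar >= 1)
    stop("noise_ar must lie in [0, 1)", call. = FALSE)
  if (eff$base_false_press_p < 0 || eff$base_false_press_p > 1)
    stop("base_false_press_p must be a probability", call. = FALSE)
  invisible(eff)
}

## Per-participant effective effect terms after applying the device
## attenuation of the PD signal. Returns the multipliers/amplitudes that the
## simulators actually use.
participant_effects <- function(participant, eff) {
  is_pd <- participant$label == "PD"
  att <- unname(eff$device_pd_attenuation[[participant$device]])
  dev_scale <- if (is_pd) 1 + (eff$pd_deviation_scale - 1) * att else 1
  time_scale <- if (is_pd) 1 + (eff$pd_time_scale - 1) * att else 1
  fp_scale <- if (is_pd) 1 + (eff$pd_false_press_scale - 1) * att else 1
  tremor_amp <- if (is_pd) eff$pd_tremor_amp * att else 0
  hand_pen <- if (participant$hand == "left") eff$hand_nondominant_penalty else 1
  noise_mult <- dev_scale *
    unname(eff$device_noise_scale[[participant$device]]) * hand_pen
  list(
    noise_mult = noise_mult,
    noise_sd = eff$base_noise_sd * noise_mult,
    tremor_amp = tremor_amp,
    tremor_freq = eff$pd_tremor_freq,
    time_scale = time_scale,
    latency_ms = unname(eff$device_latency_ms[[participant$device]]),
    false_press_p = min(1, eff$base_false_press_p * fp_scale),
    memory_penalty = if (is_pd) eff$pd_memory_penalty * att else 0
  )
}

#' Draw per-participant latent traits
#'
#' Between-subject heterogeneity that is independent of every group
#' attribute: a lognormal speed multiplier, a lognormal motor-noise
#' multiplier, and a Gaussian response-time offset. Drawn once per session
#' so a participant is self-consistent across tasks.
#'
#' @param effects An [effect_config()].
#' @param seed Integer seed.
#' @return List with `time_mult`, `noise_mult`, `rt_shift_ms`.
#' @export
participant_traits <- function(effects, seed) {
  with_seed(seed, list(
    time_mult = exp(stats::rnorm(1, 0, effects$between_subject_sd_time)),
    noise_mult = exp(stats::rnorm(1, 0, effects$between_subject_sd_noise)),
    rt_shift_ms = stats::rnorm(1, 0, effects$between_subject_rt_sd_ms)
  ))
}

neutral_traits <- function() list(time_mult = 1, noise_mult = 1, rt_shift_ms = 0)
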