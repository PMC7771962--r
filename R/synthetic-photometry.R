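#' Photometry generator configuration
#'
#' Parameters of the two-channel synthetic photometry generator: sampling
#' rate, calcium-indicator kernel, and the artifact model (line noise, slow
#' baseline drift, and a motion process shared between the green GCaMP and
#' red tdTomato channels).
#'
#' @param fs Sampling rate (Hz).
#' @param kernel_rise,kernel_decay Rise and decay time constants (s) of the
#'   difference-of-exponentials calcium kernel (peak-normalised);
#'   GCaMP7f-like defaults.
#' @param noise_sd White measurement noise sd on the green channel (signal
#'   units).
#' @param line_noise_amp Amplitude of the 60 Hz line component.
#' @param drift_amp,drift_timescale Amplitude (signal units) and timescale
#'   (s) of the slow baseline wander.
#' @param motion_amp,motion_timescale Amplitude and timescale of the shared
#'   motion-artifact process.
#' @param motion_gain_red Coupling of the motion process into the red
#'   channel.
#' @param red_baseline,red_noise_sd Red-channel baseline level and
#'   independent noise sd.
#' @param seed Optional integer seed.
#' @return A `photometry_config` list.
#' @export
photometry_config <- function(fs = 1000,
                              kernel_rise = 0.05,
                              kernel_decay = 0.6,
                              noise_sd = 0.02,
                              line_noise_amp = 0.01,
                              drift_amp = 0.1,
                              drift_timescale = 50,
                              motion_amp = 0.05,
                              motion_timescale = 0.3,
                              motion_gain_red = 1,
                              red_baseline = 0,
                              red_noise_sd = 0.02,
                              seed = NULL) {
  if (fs <= 0) abort("`fs` must be positive.", class = "tdaxon_config_error")
  if (!(kernel_decay > kernel_rise && kernel_rise > 0)) {
    abort("Kernel must satisfy decay > rise > 0.", class = "tdaxon_config_error")
  }
  amps <- c(noise_sd, line_noise_amp, drift_amp, motion_amp, red_noise_sd)
  if (any(amps < 0)) abort("Amplitudes must be >= 0.", class = "tdaxon_config_error")
  out <- as.list(environment())
  out$amps <- NULL
  structure(out, class = "photometry_config")
}

#' Peak-normalised calcium kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)`, scaled to a
#' peak of 1, sampled at `fs`.
#'
#' @param cfg A [photometry_config()] (or any list with `fs`, `kernel_rise`,
#'   `kernel_decay`).
#' @param duration Kernel support length (s); defaults to eight decay
#'   constants.
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
calcium_kernel <- function(cfg, duration = 8 * cfg$kernel_decay) {
  t <- seq(0, duration, by = 1 / cfg$fs)
  k <- exp(-t / cfg$kernel_decay) - exp(-t / cfg$kernel_rise)
  k / max(k)
}

# band-limited unit-variance noise: white noise sampled at 1/timescale,
# linearly interpolated onto the fine grid
slow_process <- function(n, fs, timescale) {
  n_knots <- max(3, ceiling(n / fs / timescale) + 2)
  knots_t <- seq(0, (n - 1) / fs, length.out = n_knots)
  z <- rnorm(n_knots)
  approx(knots_t, z, xout = (seq_len(n) - 1) / fs)$y
}

#' Generate a two-channel photometry session
#'
#' Builds the green channel as the sum of TD-error impulses convolved with
#' the calcium kernel, plus slow drift, a 60 Hz line component, a shared
#' motion artifact, and white noise; the red channel as baseline plus the
#' coupled motion artifact and independent noise. Event markers from the
#' trial table are preserved at sample resolution.
#'
#' @param trials A trial table from [generate_session()].
#' @param impulses A tibble with columns `time`, `delta`, e.g. from
#'   [trial_td_impulses()]. Impulses closer together than one sample raise a
#'   sampling error.
#' @param cfg A [photometry_config()].
#' @return A `photometry_session`: list with `green`, `red`, `fs`, `time`
#'   origin 0, and `events` (named lists of timestamps including ITI
#'   bounds).
#' @examples
#' cfg <- session_config(n_trials_block1 = 4, n_trials_block2 = 4, seed = 1)
#' tr <- generate_session(cfg, task_model())
#' imp <- trial_td_impulses(tr, task_model())
#' ph <- generate_photometry(tr, imp, photometry_config(fs = 200, seed = 1))
#' @export
generate_photometry <- function(trials, impulses, cfg) {
  stopifnot(inherits(cfg, "photometry_config"))
  if (!all(c("time", "delta") %in% names(impulses))) {
    abort("`impulses` needs columns `time` and `delta`.",
          class = "tdaxon_input_error")
  }
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  fs <- cfg$fs
  duration <- max(trials$iti_end) + 2
  n <- ceiling(duration * fs) + 1
  idx <- round(impulses$time * fs) + 1
  if (anyDuplicated(idx[impulses$delta != 0])) {
    abort("Sampling rate too low: distinct impulses fall on the same sample.",
          class = "tdaxon_sampling_error")
  }
  train <- numeric(n)
  keep <- idx >= 1 & idx <= n
  train[idx[keep]] <- train[idx[keep]] + impulses$delta[keep]
  kern <- calcium_kernel(cfg)
  pad <- length(kern) - 1
  signal_clean <- stats::filter(c(rep(0, pad), train), kern,
                                method = "convolution", sides = 1)
  signal_clean <- as.numeric(signal_clean)[pad + seq_len(n)]
  tt <- (seq_len(n) - 1) / fs
  drift <- cfg$drift_amp * slow_process(n, fs, cfg$drift_timescale)
  line <- cfg$line_noise_amp * sin(2 * pi * 60 * tt)
  motion <- cfg$motion_amp * slow_process(n, fs, cfg$motion_timescale)
  green <- signal_clean + drift + line + motion + rnorm(n, 0, cfg$noise_sd)
  red <- cfg$red_baseline + cfg$motion_gain_red * motion +
    rnorm(n, 0, cfg$red_noise_sd)
  events <- list(
    odor_on = trials$odor_on,
    odor_out = trials$odor_out,
    port_in = trials$port_in,
    outcome = trials$outcome,
    water_on = trials$water_on[!is.na(trials$water_on)],
    iti_start = trials$iti_start,
    iti_end = trials$iti_end)
  structure(list(green = green, red = red, fs = fs, events = events,
                 duration = (n - 1) / fs),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat("<photometry_session>\n")
  cat(sprintf("  %d samples per channel at %g Hz (%.1f s)\n",
              length(x$green), x$fs, x$duration))
  cat("  events:", paste(names(x$events), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.photometry_session <- function(x, ...) {
  tibble(time = (seq_along(x$green) - 1) / x$fs, green = x$green, red = x$red)
}

# sample index of a timestamp (1-based, clamped)
time_to_index <- function(session, time) {
  pmin(length(session$green), pmax(1, round(time * session$fs) + 1))
}
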