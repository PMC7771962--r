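#' Remove line noise and smooth both channels
#'
#' Applies a Hamming-window FIR bandstop filter (default 58-62 Hz) to both
#' channels, forward-backward so that event latencies are not shifted, then
#' a centred moving average (default 50 ms) with shrinking windows at the
#' edges.
#'
#' @param session A `photometry_session`.
#' @param stopband Stopband edges (Hz).
#' @param smooth_s Moving-average width (s).
#' @return The session with filtered `green` and `red`.
#' @export
clean_trace <- function(session, stopband = c(58, 62), smooth_s = 0.05) {
  fs <- session$fs
  if (fs <= 2 * stopband[2]) {
    abort(sprintf("Sampling rate %g Hz too low for a %g-%g Hz stopband.",
                  fs, stopband[1], stopband[2]),
          class = "tdaxon_sampling_error")
  }
  b <- bandstop_fir(fs, stopband)
  session$green <- smooth_ma(fir_zero_phase(b, session$green), fs, smooth_s)
  session$red <- smooth_ma(fir_zero_phase(b, session$red), fs, smooth_s)
  session
}

# Hamming-window FIR bandstop; the order scales with fs so the transition
# bands fit inside the notch and stopband attenuation exceeds 20 dB
bandstop_fir <- function(fs, stopband) {
  n_taps <- 2 * floor(0.8 * fs) + 1
  signal::fir1(n_taps - 1, stopband / (fs / 2), type = "stop")
}

# symmetric odd-length FIR applied centred (hence zero-phase), with
# reflection padding so edges and DC signals are preserved
fir_zero_phase <- function(b, x) {
  nb <- length(b)
  n <- length(x)
  pad <- min(n - 1, nb)
  xp <- c(2 * x[1] - x[pad + 1 - seq_len(pad) + 1],
          x,
          2 * x[n] - x[n - seq_len(pad)])
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y)[pad + seq_len(n)]
}

# centred moving average; edges use the available samples
smooth_ma <- function(x, fs, width_s) {
  k <- max(1, round(width_s * fs))
  if (k %% 2 == 0) k <- k + 1
  if (k == 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (k - 1) / 2
  lo <- pmax(0, seq_len(n) - h - 1)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Remove slow baseline drift
#'
#' Subtracts a running median (default 100 s) from each channel. When the
#' trace is shorter than the window the global median is used, with a
#' warning.
#'
#' @param session A `photometry_session`.
#' @param window_s Median window (s).
#' @return The detrended session.
#' @export
detrend_trace <- function(session, window_s = 100) {
  k <- round(window_s * session$fs)
  if (k %% 2 == 0) k <- k + 1
  short <- k >= length(session$green)
  if (short) {
    warn(sprintf("Trace (%.1f s) shorter than the %g s median window; subtracting the global median.",
                 session$duration, window_s))
  }
  for (ch in c("green", "red")) {
    x <- session[[ch]]
    session[[ch]] <- if (short) {
      x - median(x)
    } else {
      x - as.numeric(runmed(x, k, endrule = "median"))
    }
  }
  session
}

#' Regress out shared motion artifacts
#'
#' Ordinary least squares of the green on the red channel restricted to
#' inter-trial-interval samples. If the slope is significant (p < 0.05) the
#' fitted red signal is subtracted from the whole green trace; otherwise the
#' green channel is left untouched. The regression report is retained in
#' `session$motion_fit`.
#'
#' @param session A `photometry_session` with `iti_start`/`iti_end` events.
#' @param p_threshold Significance level for applying the subtraction.
#' @return The session, with `motion_fit` (slope, intercept, p, applied).
#' @export
subtract_motion <- function(session, p_threshold = 0.05) {
  ev <- session$events
  if (is.null(ev$iti_start) || length(ev$iti_start) == 0) {
    abort("No ITI intervals defined.", class = "tdaxon_input_error")
  }
  n <- length(session$green)
  mask <- rep(FALSE, n)
  for (i in seq_along(ev$iti_start)) {
    i0 <- time_to_index(session, ev$iti_start[i])
    i1 <- time_to_index(session, ev$iti_end[i])
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  g <- session$green[mask]
  r <- session$red[mask]
  if (sd(r) < 1e-12) {
    warn("Red channel has no variance during ITI; skipping motion subtraction.")
    session$motion_fit <- list(applied = FALSE, slope = NA_real_,
                               intercept = NA_real_, p = NA_real_)
    return(session)
  }
  fit <- lm(g ~ r)
  # summary.lm warns on an essentially perfect fit; the p-value is still 0
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- sm["r", "Pr(>|t|)"]
  applied <- is.finite(p) && p < p_threshold
  if (applied) {
    session$green <- session$green -
      (coef(fit)[[1]] + coef(fit)[[2]] * session$red)
  }
  session$motion_fit <- list(applied = applied,
                             slope = unname(coef(fit)[[2]]),
                             intercept = unname(coef(fit)[[1]]),
                             p = unname(p),
                             n_iti_samples = sum(mask))
  session
}

default_windows <- function() {
  list(
    odor_pre_exit = list(event = "odor_out", window = c(-1, 0)),
    post_choice   = list(event = "port_in", window = c(0, 1)),
    outcome       = list(event = "water_on", window = c(0.3, 1.3)),
    outcome_early = list(event = "water_on", window = c(0, 1)))
}

window_mean <- function(session, times, win) {
  vapply(times, function(t0) {
    if (is.na(t0)) return(NA_real_)
    i0 <- round((t0 + win[1]) * session$fs) + 1
    i1 <- round((t0 + win[2]) * session$fs) + 1
    if (i0 < 1 || i1 > length(session$green)) return(NA_real_)
    mean(session$green[i0:i1])
  }, numeric(1))
}

#' Per-trial event-window responses
#'
#' Baseline-subtracted mean green-channel activity in named windows around
#' trial events. Defaults follow the analysis conventions: pre-choice
#' (1-0 s before odor port out), post-choice (0-1 s after water port in),
#' and the outcome window 0.3-1.3 s after water onset (the 0-1 s variant is
#' provided as `outcome_early`). The baseline is 1-0.2 s before odor onset;
#' pass `baseline_event = "water_on"`, `baseline_window = c(-1, -0.2)` for
#' the pre-reward-subtracted variant. Windows that extend beyond the trace
#' or reference a missing event yield `NA`.
#'
#' @param session A preprocessed `photometry_session`.
#' @param trials The matching trial table.
#' @param windows Named list of `list(event =, window =)` specs; events are
#'   trial-table time columns.
#' @param baseline_event,baseline_window Baseline reference event and
#'   window (s, relative).
#' @return The trial table augmented with one response column per window
#'   and a `baseline` column; the window spec is stored in attribute
#'   `windows`.
#' @export
event_responses <- function(session, trials, windows = default_windows(),
                            baseline_event = "odor_on",
                            baseline_window = c(-1, -0.2)) {
  for (w in windows) {
    if (!w$event %in% names(trials)) {
      abort(sprintf("Event column `%s` not present in the trial table.",
                    w$event), class = "tdaxon_input_error")
    }
  }
  baseline <- window_mean(session, trials[[baseline_event]], baseline_window)
  out <- trials
  out$baseline <- baseline
  for (nm in names(windows)) {
    w <- windows[[nm]]
    out[[nm]] <- window_mean(session, trials[[w$event]], w$window) - baseline
  }
  attr(out, "windows") <- windows
  attr(out, "baseline") <- list(event = baseline_event,
                                window = baseline_window)
  out
}

#' Normalize a session's green channel
#'
#' `method = "peak"` divides the green trace by the average peak response in
#' the first second after odor onset over all successful (correct) trials;
#' `method = "zscore"` z-scores using the mean and sd of the green samples
#' in all choice-trial windows (2 s before to 6 s after odor onset). The
#' scalars are recorded in `session$normalization`.
#'
#' @param session A `photometry_session`.
#' @param trials The matching trial table.
#' @param method `"peak"` or `"zscore"`.
#' @return The rescaled session.
#' @export
normalize_session <- function(session, trials, method = c("peak", "zscore")) {
  method <- match.arg(method)
  if (method == "peak") {
    ok <- trials$correct
    if (!any(ok)) abort("No successful trials to normalize by.",
                        class = "tdaxon_input_error")
    peaks <- vapply(trials$odor_on[ok], function(t0) {
      i0 <- time_to_index(session, t0)
      i1 <- time_to_index(session, t0 + 1)
      max(session$green[i0:i1])
    }, numeric(1))
    scale <- mean(peaks)
    if (!is.finite(scale) || scale == 0) {
      abort("Average odor-onset peak is zero; cannot peak-normalize.",
            class = "tdaxon_input_error")
    }
    session$green <- session$green / scale
    session$normalization <- list(method = "peak", scale = scale)
  } else {
    idx <- unlist(lapply(trials$odor_on, function(t0) {
      time_to_index(session, t0 - 2):time_to_index(session, t0 + 6)
    }))
    idx <- unique(idx)
    m <- mean(session$green[idx])
    s <- sd(session$green[idx])
    if (s == 0) abort("Zero variance in choice-trial signals.",
                      class = "tdaxon_input_error")
    session$green <- (session$green - m) / s
    session$normalization <- list(method = "zscore", mean = m, sd = s)
  }
  session
}

#' Time-warp trials onto median-duration segments
#'
#' Piecewise-linear resampling of each trial's green trace onto standard
#' windows: a fixed pre-odor segment, odor onset to odor port out stretched
#' to the median reaction time, odor port out to water port in stretched to
#' the median movement time, and a fixed post-choice segment, in 100 ms
#' bins. Intended for visualisation; statistics use unwarped responses.
#'
#' @param session A `photometry_session`.
#' @param trials The matching trial table.
#' @param bin_s Bin width (s).
#' @param pre_s,post_s Fixed segment lengths before odor onset and after
#'   water port entry.
#' @return A matrix (trials x bins) with bin centre times (relative,
#'   median-trial clock) in attribute `bin_time`; skipped trials (non-
#'   monotone anchors) are all-`NA` rows.
#' @export
time_warp <- function(session, trials, bin_s = 0.1, pre_s = 1, post_s = 2) {
  med_rt <- median(trials$odor_out - trials$odor_on)
  med_mt <- median(trials$port_in - trials$odor_out)
  n_pre <- round(pre_s / bin_s)
  n_rt <- max(1, round(med_rt / bin_s))
  n_mt <- max(1, round(med_mt / bin_s))
  n_post <- round(post_s / bin_s)
  n_bins <- n_pre + n_rt + n_mt + n_post
  bin_time <- (seq_len(n_bins) - 0.5) * bin_s - pre_s
  out <- matrix(NA_real_, nrow(trials), n_bins)
  seg_means <- function(t0, t1, k) {
    edges <- seq(t0, t1, length.out = k + 1)
    vapply(seq_len(k), function(i) {
      i0 <- time_to_index(session, edges[i])
      i1 <- time_to_index(session, edges[i + 1])
      mean(session$green[i0:i1])
    }, numeric(1))
  }
  for (i in seq_len(nrow(trials))) {
    a <- c(trials$odor_on[i], trials$odor_out[i], trials$port_in[i])
    if (any(diff(a) <= 0)) {
      warn(sprintf("Trial %d has non-monotone anchors; skipped.", trials$trial[i]))
      next
    }
    out[i, ] <- c(
      seg_means(a[1] - pre_s, a[1], n_pre),
      seg_means(a[1], a[2], n_rt),
      seg_means(a[2], a[3], n_mt),
      seg_means(a[3], a[3] + post_s, n_post))
  }
  attr(out, "bin_time") <- bin_time
  attr(out, "segments") <- c(pre = n_pre, reaction = n_rt, movement = n_mt,
                             post = n_post)
  out
}
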