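# bare session builder for filter tests
raw_session <- function(x, fs, red = NULL, iti = NULL) {
  if (is.null(red)) red <- x
  if (is.null(iti)) iti <- list(numeric(0), numeric(0))
  structure(list(green = x, red = red, fs = fs,
                 events = list(iti_start = iti[[1]], iti_end = iti[[2]]),
                 duration = (length(x) - 1) / fs),
            class = "photometry_session")
}

test_that("the bandstop filter removes 60 Hz and passes DC unshifted", {
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  sine <- sin(2 * pi * 60 * t)
  s <- clean_trace(raw_session(sine, fs))
  core <- seq(5 * fs, 55 * fs)  # avoid edges
  atten_db <- 20 * log10(sqrt(mean(sine[core]^2)) /
                           sqrt(mean(s$green[core]^2)))
  expect_gte(atten_db, 20)
  # DC is untouched
  dc <- clean_trace(raw_session(rep(2, 5 * fs), fs))
  expect_equal(dc$green, rep(2, 5 * fs), tolerance = 1e-3)
  # a step keeps its midpoint latency (zero-phase)
  step <- c(rep(0, 3 * fs), rep(1, 3 * fs))
  st <- clean_trace(raw_session(step, fs))
  mid_in <- min(which(step >= 0.5))
  mid_out <- min(which(st$green >= 0.5))
  expect_lt(abs(mid_out - mid_in), 0.05 * fs)
  expect_error(clean_trace(raw_session(rep(0, 100), fs = 100)),
               class = "tdaxon_sampling_error")
})

test_that("moving-median detrending removes drift but keeps impulses", {
  fs <- 100
  n <- 300 * fs
  drift <- seq(0, 5, length.out = n)
  x <- drift
  impulse_at <- seq(20 * fs, n - 20 * fs, by = 10 * fs)
  for (i in impulse_at) x[i:(i + fs / 2)] <- x[i:(i + fs / 2)] + 2
  s <- detrend_trace(raw_session(x, fs))
  # drift removed: baseline samples near zero
  baseline <- s$green[impulse_at - 2 * fs]
  expect_lt(max(abs(baseline)), 0.1)
  # impulse amplitude preserved within 5%
  peaks <- s$green[impulse_at + 10] - s$green[impulse_at - 2 * fs]
  expect_true(all(abs(peaks - 2) < 0.1))
  # constant trace -> zeros
  z <- detrend_trace(raw_session(rep(3, 200 * fs), fs))
  expect_equal(z$green, rep(0, 200 * fs))
  # short trace: global median with a warning
  expect_warning(sh <- detrend_trace(raw_session(1:100, fs = 1)), "shorter")
  expect_equal(sh$green, 1:100 - median(1:100))
})

test_that("motion subtraction recovers the coupling and nulls ITI correlation", {
  withr::local_seed(10)
  fs <- 100; n <- 200 * fs
  red <- as.numeric(stats::filter(rnorm(n), rep(1 / 20, 20),
                                  circular = TRUE))
  green <- 0.5 * red + rnorm(n, 0, 0.05)
  s <- raw_session(green, fs, red = red, iti = list(0, (n - 1) / fs))
  out <- subtract_motion(s)
  expect_true(out$motion_fit$applied)
  expect_equal(out$motion_fit$slope, 0.5, tolerance = 0.05)
  expect_lt(abs(cor(out$green, out$red)), 0.05)
  # independent channels: green untouched
  s2 <- raw_session(rnorm(n), fs, red = rnorm(n),
                    iti = list(0, (n - 1) / fs))
  out2 <- subtract_motion(s2)
  if (!out2$motion_fit$applied) expect_identical(out2$green, s2$green)
  expect_gte(out2$motion_fit$p, 0)
  # constant red: degenerate regression skipped with a warning
  s3 <- raw_session(rnorm(n), fs, red = rep(1, n),
                    iti = list(0, (n - 1) / fs))
  expect_warning(out3 <- subtract_motion(s3), "variance")
  expect_false(out3$motion_fit$applied)
  # no ITI -> error
  s4 <- raw_session(rnorm(100), fs, iti = list(numeric(0), numeric(0)))
  expect_error(subtract_motion(s4), class = "tdaxon_input_error")
})

test_that("an injected shared motion artifact is suppressed by >= 90%", {
  tr <- small_session(n1 = 0, n2 = 40, seed = 12)
  cfg <- photometry_config(fs = 250, motion_amp = 0.3, motion_gain_red = 1,
                           noise_sd = 0.01, red_noise_sd = 0.01,
                           drift_amp = 0, line_noise_amp = 0, seed = 13)
  imp <- tibble::tibble(time = numeric(0), delta = numeric(0))
  ph <- generate_photometry(tr, imp, cfg)
  var_before <- var(ph$green)
  out <- subtract_motion(ph)
  expect_true(out$motion_fit$applied)
  expect_lt(var(out$green), 0.1 * var_before)
})

test_that("event responses subtract baseline and handle edge windows", {
  fs <- 100
  tr <- small_session(n1 = 0, n2 = 5, seed = 14)
  n <- ceiling((max(tr$iti_end) + 2) * fs) + 1
  flat <- raw_session(rep(1, n), fs)
  er <- event_responses(flat, tr)
  expect_true(all(abs(er$post_choice) < 1e-12))
  expect_true(all(abs(er$outcome[tr$correct]) < 1e-12))
  # unit boxcar exactly in the outcome window -> response 1
  x <- rep(0, n)
  w0 <- tr$water_on[tr$correct][1]
  x[(round((w0 + 0.3) * fs) + 1):(round((w0 + 1.3) * fs) + 1)] <- 1
  er2 <- event_responses(raw_session(x, fs), tr)
  expect_equal(er2$outcome[tr$correct][1], 1, tolerance = 1e-12)
  # calcium kernel impulse at water onset: window mean equals the kernel's
  # integral over the window divided by its width
  cfgk <- quiet_photometry_config(fs = fs)
  kern <- calcium_kernel(cfgk)
  xk <- rep(0, n)
  i0 <- round(w0 * fs) + 1
  xk[i0:(i0 + length(kern) - 1)] <- kern
  er3 <- event_responses(raw_session(xk, fs), tr)
  idx <- (round(0.3 * fs) + 1):(round(1.3 * fs) + 1)
  expect_equal(er3$outcome[tr$correct][1], mean(kern[idx]), tolerance = 1e-9)
  # window beyond the trace end -> NA
  tr_edge <- tr
  tr_edge$water_on[tr_edge$trial == tr$trial[tr$correct][1]] <- (n - 1) / fs
  er4 <- event_responses(raw_session(x, fs), tr_edge)
  expect_true(is.na(er4$outcome[tr$correct][1]))
})

test_that("normalization scalars behave as defined", {
  fs <- 100
  tr <- small_session(n1 = 0, n2 = 8, seed = 15)
  cfg <- quiet_photometry_config(fs = fs)
  imp <- tibble::tibble(time = tr$odor_on, delta = 1)
  ph <- generate_photometry(tr, imp, cfg)
  pk <- normalize_session(ph, tr, method = "peak")
  # identical unit impulses at every odor onset: normalized peak is 1
  expect_equal(pk$normalization$scale, 1, tolerance = 1e-9)
  expect_equal(max(pk$green), 1, tolerance = 1e-9)
  # doubling the raw gain leaves normalized responses unchanged
  ph2 <- ph; ph2$green <- 2 * ph$green
  pk2 <- normalize_session(ph2, tr, method = "peak")
  er_a <- event_responses(pk, tr)
  er_b <- event_responses(pk2, tr)
  expect_equal(er_a$post_choice, er_b$post_choice, tolerance = 1e-10)
  # z-scoring: concatenated choice-trial samples have mean 0, sd 1
  withr::local_seed(16)
  ph3 <- ph; ph3$green <- ph$green + rnorm(length(ph$green))
  zs <- normalize_session(ph3, tr, method = "zscore")
  idx <- unique(unlist(lapply(tr$odor_on, function(t0) {
    (round((t0 - 2) * fs) + 1):(round((t0 + 6) * fs) + 1)
  })))
  expect_equal(mean(zs$green[idx]), 0, tolerance = 1e-10)
  expect_equal(sd(zs$green[idx]), 1, tolerance = 1e-10)
})

test_that("the cleaning pipeline is near-idempotent", {
  tr <- small_session(n1 = 0, n2 = 20, seed = 17)
  cfg <- photometry_config(fs = 250, seed = 18)
  ph <- generate_photometry(tr, trial_td_impulses(tr, softmax_spec()), cfg)
  once <- subtract_motion(detrend_trace(clean_trace(ph)))
  twice <- subtract_motion(detrend_trace(clean_trace(once)))
  core <- seq(5 * cfg$fs, length(once$green) - 5 * cfg$fs)
  expect_lt(sd(twice$green[core] - once$green[core]), 0.1 * sd(once$green[core]))
})

test_that("time warping preserves structure", {
  fs <- 100
  tr <- small_session(n1 = 0, n2 = 10, seed = 19)
  n <- ceiling((max(tr$iti_end) + 2) * fs) + 1
  # constant trace: constant output regardless of trial duration
  wm <- time_warp(raw_session(rep(4, n), fs), tr)
  expect_true(all(abs(wm - 4) < 1e-12, na.rm = TRUE))
  expect_false(anyNA(wm))
  # a trial already at the median durations reproduces direct binning
  tt <- (seq_len(n) - 1) / fs
  ramp <- raw_session(tt, fs)
  wr <- time_warp(ramp, tr)
  med_rt <- median(tr$odor_out - tr$odor_on)
  i_med <- which.min(abs((tr$odor_out - tr$odor_on) - med_rt))
  seg <- attr(wr, "segments")
  rt_bins <- wr[i_med, (seg[["pre"]] + 1):(seg[["pre"]] + seg[["reaction"]])]
  # a linear ramp stays linear with the trial's own slope over its segment
  expect_equal(diff(rt_bins),
               rep(diff(rt_bins)[1], length(rt_bins) - 1), tolerance = 0.05)
  # non-monotone anchors are skipped with a warning
  tr_bad <- tr
  tr_bad$odor_out[1] <- tr_bad$odor_on[1] - 0.1
  expect_warning(wb <- time_warp(ramp, tr_bad), "non-monotone")
  expect_true(all(is.na(wb[1, ])))
})
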