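# shared fixtures for the suite; everything is generated in code

softmax_spec <- function(...) task_model(sigma = 18, tau = 0.22, ...)
det_spec <- function(...) task_model(sigma = 21, policy = "deterministic", ...)

small_session <- function(n1 = 10, n2 = 20, seed = 1, ...) {
  generate_session(session_config(n_trials_block1 = n1, n_trials_block2 = n2,
                                  seed = seed, ...),
                   softmax_spec())
}

quiet_photometry_config <- function(fs = 250, seed = 1, ...) {
  photometry_config(fs = fs, noise_sd = 0, line_noise_amp = 0,
                    drift_amp = 0, motion_amp = 0, red_noise_sd = 0,
                    seed = seed, ...)
}

# reduced kernel set used for recovery studies (keeps the design small)
reduced_kernel_spec <- function() {
  ks <- kernel_spec()
  keep <- c("odor_base", "correct_big", "correct_small",
            "water_big", "water_small")
  ks$groups <- ks$groups[ks$groups$group %in% keep, ]
  ks
}

# draw smooth per-group kernel coefficients and the implied signal
simulate_kernel_data <- function(trials, session, ks, seed, snr = 1) {
  design <- build_design(trials, session, ks)
  withr::local_seed(seed)
  beta <- numeric(nrow(design$columns))
  for (g in unique(design$columns$group)) {
    idx <- which(design$columns$group == g)
    cen <- design$columns$center[idx]
    span <- max(cen) - min(cen) + 0.2
    beta[idx] <- sin(2 * pi * (cen - min(cen)) / span) * runif(1, 0.5, 1.5)
  }
  signal <- as.numeric(design$x %*% beta)
  noise_sd <- if (is.finite(snr)) sd(signal) / snr else 0
  design$y <- signal + rnorm(length(signal), 0, noise_sd)
  list(design = design, beta = beta, signal = signal)
}

# true kernel profile implied by coefficients, on the fitted profile's grid
true_profile <- function(columns, beta, spec, group, times) {
  idx <- which(columns$group == group)
  vapply(times, function(t0) {
    sum(beta[idx] *
          ifelse(abs(t0 - columns$center[idx]) <= spec$width / 2,
                 0.5 * (1 + cos(2 * pi * (t0 - columns$center[idx]) /
                                  spec$width)),
                 0))
  }, numeric(1))
}

# per-trial realized outcome utility for telescoping checks
realized_utility <- function(trials, spec) {
  ifelse(trials$reward_size > 0,
         ifelse(trials$block == 1, 1, trials$reward_size^spec$alpha_utility),
         0)
}
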