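test_that("session configs are validated", {
  expect_error(session_config(n_trials_block1 = -1),
               class = "tdaxon_config_error")
  expect_error(session_config(odor_set = numeric(0)),
               class = "tdaxon_config_error")
  expect_error(session_config(reward_multipliers = c(big = 1, medium = 2,
                                                     small = 0.2)),
               class = "tdaxon_config_error")
  expect_error(session_config(p_large_draw = 1.5),
               class = "tdaxon_config_error")
})

test_that("a noise-free deterministic agent is always correct", {
  agent <- task_model(sigma = 0.5, policy = "deterministic")
  tr <- generate_session(session_config(n_trials_block1 = 50,
                                        n_trials_block2 = 50, seed = 4),
                         agent)
  expect_true(all(tr$correct))
  expect_true(all(tr$reward_size > 0))
})

test_that("sessions are reproducible under a seed and respect task timing", {
  cfg <- session_config(seed = 9)
  a <- generate_session(cfg, softmax_spec())
  b <- generate_session(cfg, softmax_spec())
  expect_identical(a, b)
  expect_true(all(a$odor_out - a$odor_on >= 1))
  expect_equal(a$outcome - a$port_in, rep(1, nrow(a)), tolerance = 1e-12)
  expect_true(all(diff(a$odor_on) > 0))
  expect_true(all(a$odor_on < a$odor_out & a$odor_out < a$port_in &
                    a$port_in <= a$outcome))
  expect_true(all(a$reward_size[!a$correct] == 0))
})

test_that("the empirical psychometric matches the agent's analytic curve", {
  agent <- softmax_spec()
  tr <- generate_sessions(1, session_config(n_trials_block1 = 0,
                                            n_trials_block2 = 20000),
                          agent, seed = 21)
  emp <- dplyr::summarise(dplyr::group_by(tr, odor),
                          p = mean(choice == "big"), n = dplyr::n())
  th <- model_psychometric(agent, presented = emp$odor)
  se <- sqrt(th$p_big * (1 - th$p_big) / emp$n)
  expect_true(all(abs(emp$p - th$p_big) < 4 * se))
})

test_that("reward draws follow the schedule", {
  tr <- generate_sessions(20, session_config(n_trials_block1 = 0,
                                             n_trials_block2 = 600),
                          softmax_spec(), seed = 31)
  big_correct <- tr$correct & tr$choice == "big"
  small_correct <- tr$correct & tr$choice == "small"
  # expected reward per correct trial: BIG side 1.5x, SMALL side 0.5x
  m_big <- mean(tr$reward_size[big_correct])
  m_small <- mean(tr$reward_size[small_correct])
  expect_lt(abs(m_big - 1.5), 4 * 0.7 / sqrt(sum(big_correct)))
  expect_lt(abs(m_small - 0.5), 4 * 0.3 / sqrt(sum(small_correct)))
  # each size drawn with p = 0.5 within binomial error
  p_draw <- mean(tr$reward_class[big_correct] == "big")
  expect_lt(abs(p_draw - 0.5), 4 * 0.5 / sqrt(sum(big_correct)))
})

test_that("photometry reduces to the calcium kernel in the noiseless case", {
  tr <- small_session(n1 = 0, n2 = 3, seed = 2)
  cfg <- quiet_photometry_config(fs = 200)
  imp <- tibble::tibble(time = tr$odor_on[2], delta = 1)
  ph <- generate_photometry(tr, imp, cfg)
  kern <- calcium_kernel(cfg)
  i0 <- round(tr$odor_on[2] * cfg$fs) + 1
  expect_equal(ph$green[i0:(i0 + length(kern) - 1)], kern, tolerance = 1e-10)
  expect_equal(max(ph$green), 1, tolerance = 1e-10)
  expect_true(all(ph$green[1:(i0 - 1)] == 0))
})

test_that("impulses closer than one sample raise a sampling error", {
  tr <- small_session(n1 = 0, n2 = 2, seed = 2)
  imp <- tibble::tibble(time = c(5, 5.004), delta = c(1, 1))
  expect_error(generate_photometry(tr, imp, photometry_config(fs = 100)),
               class = "tdaxon_sampling_error")
})

test_that("shared motion artifacts couple the two channels during ITI", {
  tr <- small_session(n1 = 0, n2 = 30, seed = 5)
  cfg <- photometry_config(fs = 100, motion_amp = 0.3, motion_gain_red = 1,
                           noise_sd = 0.02, red_noise_sd = 0.02,
                           drift_amp = 0, line_noise_amp = 0, seed = 6)
  ph <- generate_photometry(tr, trial_td_impulses(tr, softmax_spec()), cfg)
  mask <- rep(FALSE, length(ph$green))
  for (i in seq_along(ph$events$iti_start)) {
    mask[round(ph$events$iti_start[i] * cfg$fs):
           round(ph$events$iti_end[i] * cfg$fs)] <- TRUE
  }
  r_obs <- cor(ph$green[mask], ph$red[mask])
  # permutation null: circularly shift the red channel
  withr::local_seed(7)
  null_r <- replicate(200, {
    k <- sample.int(sum(mask) - 1, 1)
    cor(ph$green[mask], ph$red[mask][c((k + 1):sum(mask), 1:k)])
  })
  expect_gt(r_obs, quantile(null_r, 0.99))
})

test_that("input-ratio presets flip the sign of medium-at-SMALL water responses", {
  spec <- softmax_spec()
  pv <- partial_learning_values(spec)
  tr <- small_session(n1 = 0, n2 = 200, seed = 8)
  sel <- which(tr$reward_class == "medium" & tr$choice == "small")
  expect_gt(length(sel), 5)
  # per-trial outcome-phase TD steps under partial learning: detection
  # (water noticed) then discrimination (amount 0.8 recognised)
  d_detect <- pv$v_water_small - pv$per_odor$v_small[tr$sub_odor_idx[sel]]
  d_discrim <- rep(reward_utility(spec, 0.8) - pv$v_water_small, length(sel))
  region_mean <- sapply(c("more_excitation", "balanced", "more_inhibition"),
                        function(r) {
    pars <- circuit_params(r)
    mean(postsynaptic_td(d_detect, pars) + postsynaptic_td(d_discrim, pars))
  })
  # an excitation-dominant region responds above the balanced one here
  # (net TD at this event is positive under partial learning)
  expect_gt(region_mean[["more_excitation"]], region_mean[["balanced"]])
  # the balanced region equals (1 + inh_gain) times the raw TD mean
  raw <- mean(d_detect + d_discrim)
  expect_equal(region_mean[["balanced"]], 1.1 * raw, tolerance = 1e-12)
  # and each region mean matches the piecewise transmission oracle exactly
  for (r in c("more_excitation", "more_inhibition")) {
    pars <- circuit_params(r)
    s_pos <- pars$w_exc + pars$inh_gain * pars$w_inh
    s_neg <- pars$inh_gain * pars$w_exc + pars$w_inh
    oracle <- mean(ifelse(d_detect >= 0, s_pos, s_neg) * d_detect +
                     ifelse(d_discrim >= 0, s_pos, s_neg) * d_discrim)
    expect_equal(unname(region_mean[[r]]), oracle, tolerance = 1e-12)
  }
})
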