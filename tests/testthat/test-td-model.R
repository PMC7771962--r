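test_that("subjective odor distributions are proper and symmetric", {
  spec <- softmax_spec()
  for (o in spec$odor_set) {
    p <- subjective_odor_distribution(spec, o)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  p50 <- subjective_odor_distribution(spec, 50)
  expect_equal(p50, rev(p50), tolerance = 1e-12)
  # sigma -> 0: unit mass on the nearest grid point
  tiny <- task_model(sigma = 1e-4)
  p <- subjective_odor_distribution(tiny, 65)
  expect_equal(max(p), 1, tolerance = 1e-9)
  expect_equal(tiny$subjective_grid[which.max(p)],
               tiny$subjective_grid[which.min(abs(tiny$subjective_grid - 65))])
  expect_error(task_model(sigma = -1), class = "tdaxon_parameter_error")
})

test_that("reward probability for BIG is symmetric, monotone, and saturates", {
  spec <- softmax_spec()
  fb <- reward_probability_big(spec)
  # symmetric grid + symmetric odor set: fB(g) + fB(100 - g) = 1
  expect_equal(fb + rev(fb), rep(1, length(fb)), tolerance = 1e-10)
  expect_true(all(diff(fb) >= -1e-12))
  fb5 <- reward_probability_big(task_model(sigma = 5))
  expect_gt(fb5[length(fb5)], 0.999)
})

test_that("choice probabilities follow each policy's formula", {
  for (pol in c("deterministic", "softmax", "matching", "epsilon_greedy")) {
    spec <- task_model(policy = pol, epsilon = 0.2)
    expect_equal(choice_probabilities(spec, 1, 1)$p_big, 0.5)
  }
  sm <- task_model(tau = 0.22)
  expect_equal(choice_probabilities(sm, 2, 1)$p_big,
               1 / (1 + exp(-(1 / 3) / 0.22)), tolerance = 1e-12)
  greedy_limit <- task_model(tau = 1e-8)
  expect_equal(choice_probabilities(greedy_limit, 2, 1)$p_big, 1)
  expect_equal(choice_probabilities(greedy_limit, 1, 2)$p_big, 0)
  mt <- task_model(policy = "matching")
  expect_equal(choice_probabilities(mt, 2, 1)$p_big, 2 / 3)
  mt_inv <- task_model(policy = "matching", matching_inverted = TRUE)
  expect_equal(choice_probabilities(mt_inv, 2, 1)$p_big, 1 / 3)
  eg <- task_model(policy = "epsilon_greedy", epsilon = 0.2)
  expect_equal(choice_probabilities(eg, 2, 1)$p_big, 0.9)
  expect_error(choice_probabilities(sm, 0, 0), class = "tdaxon_parameter_error")
})

test_that("exact state values match the closed-form water expectations", {
  spec <- softmax_spec()
  v <- solve_state_values(spec)
  expect_equal(v$v_water_big, (2.2^0.7 + 0.8^0.7) / 2, tolerance = 1e-12)
  expect_equal(v$v_water_small, (0.8^0.7 + 0.2^0.7) / 2, tolerance = 1e-12)
  expect_identical(v$v_iti, 0)
  expect_identical(v$v_nowater, 0)
  # fB ~ 1 at a grid point -> VB there ~ VWB
  tight <- task_model(sigma = 5, n_subjective = 4)
  vt <- solve_state_values(tight)
  expect_equal(vt$per_odor$v_big[4], vt$v_water_big, tolerance = 1e-3)
  # noise-free greedy on the pure BIG odor: VO' = VB = VWB
  nf <- task_model(sigma = 0.5, n_subjective = 4, policy = "deterministic")
  vn <- solve_state_values(nf)
  expect_equal(vn$per_odor$v_sub_odor[4], vn$v_water_big, tolerance = 1e-6)
  # equal multipliers: side values differ only through fB/fS
  eq <- task_model(reward_multipliers = c(big = 1, medium = 1, small = 1))
  ve <- solve_state_values(eq)
  expect_equal(ve$per_odor$v_big, ve$per_odor$f_big * ve$v_water_big)
  expect_equal(ve$per_odor$v_big + ve$per_odor$v_small,
               rep(ve$v_water_big, 60), tolerance = 1e-10)
})

test_that("partial-learning water values blend in the trained amount", {
  spec <- softmax_spec()
  pv <- partial_learning_values(spec)
  expect_equal(pv$v_water_big, (2.2^0.7 + 0.8^0.7 + 2 * 1^0.7) / 4,
               tolerance = 1e-12)
  expect_equal(pv$v_water_small, (0.8^0.7 + 0.2^0.7 + 2 * 1^0.7) / 4,
               tolerance = 1e-12)
  full <- solve_state_values(spec)
  # setting the trained value to the fully-learned mean recovers the full fit
  pv_full <- partial_learning_values(spec, v_trained = full$v_water_big)
  expect_equal(pv_full$v_water_big, full$v_water_big, tolerance = 1e-12)
  # concave utility: the trained standard amount undervalues the BIG port
  expect_lt(pv$v_water_big, full$v_water_big)
})

test_that("Monte-Carlo values agree with the exact solver and are seeded", {
  spec <- softmax_spec(n_subjective = 4)
  exact <- solve_state_values(spec)
  mc <- monte_carlo_state_values(spec, 30000, seed = 11)
  dev <- c(mc$v_odor_on - exact$v_odor_on,
           mc$v_water_big - exact$v_water_big,
           mc$v_water_small - exact$v_water_small,
           mc$per_odor$v_big - exact$per_odor$v_big,
           mc$per_odor$v_small - exact$per_odor$v_small,
           mc$per_odor$v_sub_odor - exact$per_odor$v_sub_odor)
  expect_lt(max(abs(dev)), 0.02)
  mc2 <- monte_carlo_state_values(spec, 30000, seed = 11)
  expect_identical(mc$per_odor, mc2$per_odor)
  # the N_S = 60 grid agrees too (looser: 15x fewer visits per cell)
  spec60 <- softmax_spec()
  mc60 <- monte_carlo_state_values(spec60, 60000, seed = 12)
  exact60 <- solve_state_values(spec60)
  mid <- mc60$per_odor$n_visit > 200
  expect_lt(max(abs(mc60$per_odor$v_big[mid] - exact60$per_odor$v_big[mid])),
            0.1)
})

test_that("a single Monte-Carlo trial assigns its realized return to visited states", {
  spec <- softmax_spec(n_subjective = 4)
  mc <- suppressMessages(monte_carlo_state_values(spec, 1, seed = 3))
  visited <- which(mc$per_odor$n_visit > 0)
  expect_length(visited, 1)
  r <- mc$per_odor$v_sub_odor[visited]
  expect_equal(mc$v_odor_on, r * mc$per_odor$p_marginal[visited])
  side_v <- if (mc$per_odor$n_big[visited] > 0) {
    mc$per_odor$v_big[visited]
  } else {
    mc$per_odor$v_small[visited]
  }
  expect_equal(side_v, r)
  # realized return is either 0 (error) or a delivered amount's utility
  utils_ok <- c(0, reward_utility(spec, spec$reward_multipliers))
  expect_true(any(abs(r - utils_ok) < 1e-12))
})

test_that("TD traces telescope to the realized outcome utility", {
  spec <- softmax_spec()
  v <- solve_state_values(spec)
  cases <- list(
    list(100, "big", "big"), list(100, "big", "medium"),
    list(65, "big", "medium"), list(35, "small", "medium"),
    list(0, "small", "small"), list(65, "small", "none"),
    list(0, "big", "none"))
  for (cs in cases) {
    tr <- td_trace(spec, v, cs[[1]], cs[[2]], cs[[3]])
    want <- if (cs[[3]] == "none") 0 else reward_utility(
      spec, spec$reward_multipliers[[cs[[3]]]])
    expect_equal(sum(tr$delta), want, tolerance = 1e-12)
    expect_equal(tr$value[1], 0)
  }
})

test_that("commitment deltas: zero for greedy, inhibitory dip for softmax", {
  det <- det_spec()
  vd <- solve_state_values(det)
  for (o in c(0, 35, 65, 100)) {
    for (ch in c("big", "small")) {
      tr <- tryCatch(
        td_trace(det, vd, o, ch, if ((ch == "big") == (o > 50)) "medium" else "none"),
        error = function(e) NULL)
      if (!is.null(tr)) {
        expect_equal(tr$delta[tr$state == "WaterPort1"], 0, tolerance = 1e-12)
      }
    }
  }
  sm <- softmax_spec()
  vs <- solve_state_values(sm)
  dip <- td_trace(sm, vs, 65, "small", "none")
  expect_lt(dip$delta[dip$state == "WaterPort1"], 0)
  strong_dip <- td_trace(sm, vs, 100, "small", "none")
  expect_lt(strong_dip$delta[strong_dip$state == "WaterPort1"],
            dip$delta[dip$state == "WaterPort1"])
})

test_that("zero-probability trial types are rejected by name", {
  # near-deterministic perception: choosing SMALL on the pure BIG odor
  # cannot happen under the greedy policy
  spec <- task_model(sigma = 0.5, n_subjective = 4, policy = "deterministic")
  v <- solve_state_values(spec)
  expect_error(td_trace(spec, v, 100, "small", "none"),
               class = "tdaxon_input_error")
  expect_error(td_trace(spec, v, 65, "big", "small"),
               class = "tdaxon_input_error")
  expect_error(td_trace(spec, v, 65, "big", "none"),
               class = "tdaxon_input_error")
})

test_that("invalid-trial transitions scale values without changing signs", {
  spec <- softmax_spec(include_invalid = TRUE)
  v <- solve_state_values(spec)
  v0 <- solve_state_values(softmax_spec())
  expect_equal(v$per_odor$v_big, 0.8 * v0$per_odor$v_big, tolerance = 1e-12)
  expect_lt(v$v_odor_on, v0$v_odor_on)
  dip <- td_trace(spec, v, 100, "small", "none")
  expect_lt(dip$delta[dip$state == "WaterPort1"], 0)
})

test_that("fitting the model to its own analytic curve recovers the parameters", {
  spec <- softmax_spec()
  target <- model_psychometric(spec)
  names(target)[2] <- "p_big"
  fit <- fit_task_model(target, spec,
                        sigma_grid = seq(12, 24, by = 2),
                        param_grid = seq(0.1, 0.4, by = 0.04))
  expect_equal(fit$sigma, 18)
  expect_equal(fit$param, 0.22)
  expect_lt(fit$mse, 1e-10)
})
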