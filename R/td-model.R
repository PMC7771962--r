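#' Specify the task model
#'
#' Builds the specification of the decision-task model: an agent that
#' perceives a noisy ("subjective") version of the presented odor mixture,
#' chooses the BIG- or SMALL-reward side under a configurable policy, and
#' receives water whose utility is a concave power function of amount.
#' State values over the within-trial state sequence
#' (ITI, OdorOn, SubOdor1/2, WaterPort1/2, Outcome1, Outcome2) are derived
#' from this specification by [solve_state_values()] or
#' [monte_carlo_state_values()].
#'
#' @param sigma Perceptual noise standard deviation, in % odor units.
#' @param n_subjective Number of subjective-odor grid points. When equal to
#'   `length(odor_set)` the grid is the presented odors themselves; otherwise
#'   a uniform grid on \[0, 100\].
#' @param policy Action-selection policy: `"softmax"` (Boltzmann on
#'   sum-normalised values with temperature `tau`), `"deterministic"`
#'   (argmax, ties split 0.5/0.5), `"matching"` (choice probability
#'   proportional to value), or `"epsilon_greedy"`.
#' @param tau Softmax temperature (on the value-ratio scale).
#' @param epsilon Exploration rate for the epsilon-greedy policy.
#' @param alpha_utility Exponent of the reward utility `u(R) = R^alpha`;
#'   0.7 makes utility concave in water amount.
#' @param reward_multipliers Named amounts (units of standard water) for the
#'   big, medium and small drops. The BIG side delivers big or medium, the
#'   SMALL side medium or small, each with probability 0.5 on correct trials.
#' @param odor_set Presented odor mixtures, coded as % odor instructing the
#'   BIG side.
#' @param include_invalid Include invalid-trial transitions (value 0) at the
#'   rates in `invalid_rates`.
#' @param invalid_rates Rates of the three failure modes: failing the water
#'   port stay, multiple odor pokes, and short odor pokes.
#' @param matching_inverted Use the anti-proportional matching orientation
#'   `PB = VS / (VB + VS)` instead of the value-proportional default.
#'
#' @return An object of class `task_model`.
#' @examples
#' spec <- task_model(sigma = 18, tau = 0.22)
#' solve_state_values(spec)
#' @export
task_model <- function(sigma = 18,
                       n_subjective = 60,
                       policy = c("softmax", "deterministic", "matching",
                                  "epsilon_greedy"),
                       tau = 0.22,
                       epsilon = 0.1,
                       alpha_utility = 0.7,
                       reward_multipliers = c(big = 2.2, medium = 0.8,
                                              small = 0.2),
                       odor_set = c(0, 35, 65, 100),
                       include_invalid = FALSE,
                       invalid_rates = c(water_stage = 0.20,
                                         multi_poke = 0.04,
                                         short_poke = 0.14),
                       matching_inverted = FALSE) {
  policy <- match.arg(policy)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.", class = "tdaxon_parameter_error")
  }
  if (n_subjective < 2) {
    abort("`n_subjective` must be at least 2.", class = "tdaxon_parameter_error")
  }
  if (policy == "softmax" && (!is.numeric(tau) || tau <= 0)) {
    abort("`tau` must be positive for the softmax policy.", class = "tdaxon_parameter_error")
  }
  if (policy == "epsilon_greedy" && (epsilon < 0 || epsilon > 1)) {
    abort("`epsilon` must lie in [0, 1].", class = "tdaxon_parameter_error")
  }
  if (any(odor_set < 0) || any(odor_set > 100)) {
    abort("`odor_set` values must lie in [0, 100].", class = "tdaxon_parameter_error")
  }
  stopifnot(all(reward_multipliers > 0), alpha_utility > 0)
  odor_set <- sort(unique(odor_set))
  grid <- if (n_subjective == length(odor_set)) {
    odor_set
  } else {
    seq(0, 100, length.out = n_subjective)
  }
  structure(
    list(sigma = sigma,
         n_subjective = n_subjective,
         subjective_grid = grid,
         policy = policy,
         tau = tau,
         epsilon = epsilon,
         alpha_utility = alpha_utility,
         reward_multipliers = reward_multipliers,
         odor_set = odor_set,
         include_invalid = include_invalid,
         invalid_rates = invalid_rates,
         matching_inverted = matching_inverted,
         gamma = 1),
    class = "task_model")
}

#' @export
print.task_model <- function(x, ...) {
  cat("<task_model>\n")
  cat("  policy:", x$policy,
      if (x$policy == "softmax") sprintf("(tau = %g)", x$tau)
      else if (x$policy == "epsilon_greedy") sprintf("(epsilon = %g)", x$epsilon)
      else "", "\n")
  cat("  sigma:", x$sigma, "%odor; subjective states:", x$n_subjective, "\n")
  cat("  utility exponent:", x$alpha_utility,
      "; amounts:", paste(x$reward_multipliers, collapse = "/"), "\n")
  invisible(x)
}

#' Reward utility of a water amount
#'
#' `u(R) = R^alpha`, the concave utility the model assigns to `R` units of
#' standard water.
#'
#' @param spec A [task_model()].
#' @param amount Water amount(s) in standard-water units.
#' @return Numeric utilities.
#' @export
reward_utility <- function(spec, amount) {
  amount^spec$alpha_utility
}

#' Distribution of subjective odors given a presented odor
#'
#' The probability that the agent's noisy internal estimate falls on each
#' subjective-odor grid point, given the presented mixture: a Gaussian with
#' standard deviation `spec$sigma` centred on the presented odor, evaluated
#' on the grid and renormalised to sum to one.
#'
#' @param spec A [task_model()].
#' @param presented Presented odor (% odor instructing BIG).
#' @return A probability vector over `spec$subjective_grid`.
#' @export
subjective_odor_distribution <- function(spec, presented) {
  d <- dnorm(spec$subjective_grid, mean = presented, sd = spec$sigma)
  if (sum(d) == 0) {
    # sigma so small that every grid point has underflowed density: put all
    # mass on the nearest grid point
    d[which.min(abs(spec$subjective_grid - presented))] <- 1
  }
  d / sum(d)
}

# likelihood matrix p(O' | O): rows = subjective grid, cols = presented odors
subjective_likelihood <- function(spec) {
  vapply(spec$odor_set,
         function(o) subjective_odor_distribution(spec, o),
         numeric(length(spec$subjective_grid)))
}

#' Probability that the BIG side is correct, per subjective odor
#'
#' For each subjective-odor grid point, the fraction of cases in which the
#' presented odor instructed the BIG side, under a uniform prior over the
#' presented odors. This is the reward probability for a BIG choice,
#' `fB(O')`; `fS = 1 - fB`. It does not depend on reward sizes.
#'
#' @param spec A [task_model()].
#' @return A numeric vector `fB` over the subjective grid.
#' @export
reward_probability_big <- function(spec) {
  lik <- subjective_likelihood(spec)
  tot <- rowSums(lik)
  big <- spec$odor_set > 50
  fb <- rowSums(lik[, big, drop = FALSE]) / tot
  if (any(!is.finite(fb))) {
    warn("Zero total density at some subjective-odor grid points; using nearest-odor limit.")
    bad <- !is.finite(fb)
    near_big <- vapply(spec$subjective_grid[bad], function(g) {
      spec$odor_set[which.min(abs(spec$odor_set - g))] > 50
    }, logical(1))
    fb[bad] <- as.numeric(near_big)
  }
  fb
}

#' Choice probabilities under the model's policy
#'
#' Maps the values of choosing the BIG and SMALL side into choice
#' probabilities. The softmax uses the Boltzmann distribution on
#' sum-normalised values, `PB = 1 / (1 + exp(-(VB - VS) / ((VB + VS) tau)))`;
#' matching is value-proportional by default; the deterministic policy picks
#' the larger value (ties 0.5/0.5); epsilon-greedy explores uniformly with
#' probability `epsilon`.
#'
#' @param spec A [task_model()].
#' @param v_big,v_small Values of choosing BIG and SMALL (vectorised).
#' @return A tibble with columns `p_big`, `p_small`.
#' @export
choice_probabilities <- function(spec, v_big, v_small) {
  stopifnot(length(v_big) == length(v_small))
  if (any(v_big < 0 | v_small < 0)) {
    abort("Choice values must be nonnegative.", class = "tdaxon_parameter_error")
  }
  both_zero <- v_big + v_small == 0
  if (spec$policy %in% c("softmax", "matching") && any(both_zero)) {
    abort("softmax/matching undefined when both values are 0.",
          class = "tdaxon_parameter_error")
  }
  pb <- switch(
    spec$policy,
    deterministic = as.numeric(v_big > v_small) + 0.5 * (v_big == v_small),
    softmax = {
      # PB = e^{x/tau} / (e^{x/tau} + e^{(1-x)/tau}), x = VB / (VB + VS)
      x <- v_big / (v_big + v_small)
      plogis((2 * x - 1) / spec$tau)
    },
    matching = if (spec$matching_inverted) {
      v_small / (v_big + v_small)
    } else {
      v_big / (v_big + v_small)
    },
    epsilon_greedy = {
      greedy <- as.numeric(v_big > v_small) + 0.5 * (v_big == v_small)
      (1 - spec$epsilon) * greedy + spec$epsilon / 2
    })
  tibble(p_big = pb, p_small = 1 - pb)
}

new_state_values <- function(per_odor, scalars, spec, method) {
  structure(c(list(per_odor = per_odor, spec = spec, method = method), scalars),
            class = "state_values")
}

#' Exact state values of the task model
#'
#' Backward computation of all state values: Outcome2 utilities
#' `u(2.2), u(0.8), u(0.2)`; Water states `VWB = (Vb + Vm)/2`,
#' `VWS = (Vm + Vs)/2`; No-water states 0; per-subjective-odor choice values
#' `VB = fB * VWB`, `VS = fS * VWS`; SubOdor values
#' `VO' = PB * VB + PS * VS` with policy probabilities; OdorOn the marginal
#' over subjective odors under a uniform prior on presented odors; ITI 0.
#' With `include_invalid`, the failure transitions (value 0) scale the
#' water-port and odor-period expectations by the stated rates.
#'
#' @param spec A [task_model()].
#' @return A `state_values` object: scalars (`v_iti`, `v_odor_on`,
#'   `v_water_big`, `v_water_small`, `v_nowater`, `utilities`) and a
#'   `per_odor` tibble over the subjective grid with `f_big`, `f_small`,
#'   `v_big`, `v_small`, `p_big`, `p_small`, `v_sub_odor` and the marginal
#'   visit probability `p_marginal`.
#' @examples
#' v <- solve_state_values(task_model(sigma = 18, tau = 0.22))
#' v$v_odor_on
#' @export
solve_state_values <- function(spec) {
  solve_values_internal(spec, water_values = learned_water_values(spec))
}

learned_water_values <- function(spec) {
  u <- reward_utility(spec, spec$reward_multipliers)
  c(big = unname((u[["big"]] + u[["medium"]]) / 2),
    small = unname((u[["medium"]] + u[["small"]]) / 2))
}

solve_values_internal <- function(spec, water_values) {
  fb <- reward_probability_big(spec)
  fs <- 1 - fb
  stay_ok <- if (spec$include_invalid) 1 - spec$invalid_rates[["water_stage"]] else 1
  odor_ok <- if (spec$include_invalid) {
    1 - spec$invalid_rates[["multi_poke"]] - spec$invalid_rates[["short_poke"]]
  } else 1
  v_big <- stay_ok * fb * water_values[["big"]]
  v_small <- stay_ok * fs * water_values[["small"]]
  p <- choice_probabilities(spec, v_big, v_small)
  v_sub <- p$p_big * v_big + p$p_small * v_small
  lik <- subjective_likelihood(spec)
  lik_norm <- sweep(lik, 2, colSums(lik), "/")
  p_marg <- rowMeans(lik_norm)
  per_odor <- tibble(
    sub_odor = spec$subjective_grid,
    p_marginal = p_marg,
    f_big = fb, f_small = fs,
    v_big = v_big, v_small = v_small,
    p_big = p$p_big, p_small = p$p_small,
    v_sub_odor = v_sub)
  u <- reward_utility(spec, spec$reward_multipliers)
  new_state_values(
    per_odor,
    list(v_iti = 0,
         v_odor_on = odor_ok * sum(p_marg * v_sub),
         v_water_big = unname(water_values[["big"]]),
         v_water_small = unname(water_values[["small"]]),
         v_nowater = 0,
         utilities = u),
    spec, method = "exact")
}

#' State values with partially learned water expectations
#'
#' Variant of [solve_state_values()] in which the expected value at the
#' water port blends the current schedule with the previously trained
#' standard amount: `VWB = (Vb + Vm + 2 Vtrained)/4` and
#' `VWS = (Vm + Vs + 2 Vtrained)/4` with `Vtrained = 1^alpha`. Used by the
#' mechanistic input-ratio circuit model to mimic water responses under
#' incomplete learning of the new amounts.
#'
#' @param spec A [task_model()].
#' @param v_trained Utility of the previously trained amount; defaults to
#'   the standard drop, `1^alpha`.
#' @return A `state_values` object (see [solve_state_values()]).
#' @export
partial_learning_values <- function(spec, v_trained = reward_utility(spec, 1)) {
  u <- reward_utility(spec, spec$reward_multipliers)
  wv <- c(big = unname((u[["big"]] + u[["medium"]] + 2 * v_trained) / 4),
          small = unname((u[["medium"]] + u[["small"]] + 2 * v_trained) / 4))
  out <- solve_values_internal(spec, water_values = wv)
  out$method <- "exact_partial_learning"
  out
}

#' @export
print.state_values <- function(x, ...) {
  cat("<state_values> (", x$method, ")\n", sep = "")
  cat(sprintf("  V(ITI) = 0, V(OdorOn) = %.4f\n", x$v_odor_on))
  cat(sprintf("  V(Water|BIG) = %.4f, V(Water|SMALL) = %.4f, V(NoWater) = 0\n",
              x$v_water_big, x$v_water_small))
  cat("  per-subjective-odor table: ", nrow(x$per_odor), " grid points\n", sep = "")
  invisible(x)
}

#' Monte-Carlo state values
#'
#' Estimates the state values by simulating `n_trials` trials of the agent
#' at steady state (choices drawn from the policy applied to the exact
#' values) and combining empirical transition frequencies with empirical
#' outcome averages: reward probabilities `fB`, `fS` and choice frequencies
#' per subjective odor, and water-state values from the realised outcome
#' utilities. Unvisited cells are flagged (`NA` estimates, `n = 0`).
#'
#' @param spec A [task_model()].
#' @param n_trials Number of simulated trials.
#' @param seed Optional integer seed for the simulation.
#' @return A `state_values` object with `method = "monte_carlo"`; per-odor
#'   columns carry visit counts `n_big`, `n_small`.
#' @examples
#' mc <- monte_carlo_state_values(task_model(n_subjective = 4), 5000, seed = 1)
#' @export
monte_carlo_state_values <- function(spec, n_trials, seed = NULL) {
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  exact <- solve_state_values(spec)
  lik <- subjective_likelihood(spec)
  lik_norm <- sweep(lik, 2, colSums(lik), "/")
  n_grid <- length(spec$subjective_grid)
  n_odor <- length(spec$odor_set)
  o_idx <- sample.int(n_odor, n_trials, replace = TRUE)
  s_idx <- integer(n_trials)
  for (o in seq_len(n_odor)) {
    sel <- o_idx == o
    if (any(sel)) {
      s_idx[sel] <- sample.int(n_grid, sum(sel), replace = TRUE,
                               prob = lik_norm[, o])
    }
  }
  choose_big <- runif(n_trials) < exact$per_odor$p_big[s_idx]
  big_instructed <- spec$odor_set[o_idx] > 50
  correct <- choose_big == big_instructed
  stay_ok <- if (spec$include_invalid) {
    runif(n_trials) >= spec$invalid_rates[["water_stage"]]
  } else rep(TRUE, n_trials)
  rewarded <- correct & stay_ok
  large_draw <- runif(n_trials) < 0.5
  mult <- spec$reward_multipliers
  amount <- numeric(n_trials)
  amount[rewarded & choose_big] <-
    ifelse(large_draw[rewarded & choose_big], mult[["big"]], mult[["medium"]])
  amount[rewarded & !choose_big] <-
    ifelse(large_draw[rewarded & !choose_big], mult[["medium"]], mult[["small"]])
  util <- ifelse(rewarded, reward_utility(spec, amount), 0)

  # outcome averages: empirical mean utility among rewarded trials per side
  vw_big <- if (any(rewarded & choose_big)) mean(util[rewarded & choose_big]) else NA_real_
  vw_small <- if (any(rewarded & !choose_big)) mean(util[rewarded & !choose_big]) else NA_real_

  n_big <- tabulate(s_idx[choose_big], nbins = n_grid)
  n_small <- tabulate(s_idx[!choose_big], nbins = n_grid)
  n_visit <- tabulate(s_idx, nbins = n_grid)
  f_big_hat <- vapply(seq_len(n_grid), function(j) {
    sel <- s_idx == j & choose_big
    if (any(sel)) mean(correct[sel]) else NA_real_
  }, numeric(1))
  f_small_hat <- vapply(seq_len(n_grid), function(j) {
    sel <- s_idx == j & !choose_big
    if (any(sel)) mean(correct[sel]) else NA_real_
  }, numeric(1))
  stay_rate <- if (spec$include_invalid) mean(stay_ok) else 1
  # zero empirical frequencies must not propagate NA outcome averages
  times_or_zero <- function(w, v) ifelse(!is.na(w) & w == 0, 0, w * v)
  v_big_hat <- stay_rate * times_or_zero(f_big_hat, vw_big)
  v_small_hat <- stay_rate * times_or_zero(f_small_hat, vw_small)
  p_big_hat <- ifelse(n_visit > 0, n_big / n_visit, NA_real_)
  v_sub_hat <- times_or_zero(p_big_hat, v_big_hat) +
    times_or_zero(1 - p_big_hat, v_small_hat)
  p_marg_hat <- n_visit / n_trials

  if (any(n_visit == 0)) {
    inform(sprintf("%d subjective-odor state(s) unvisited after %d trials.",
                   sum(n_visit == 0), n_trials))
  }
  per_odor <- tibble(
    sub_odor = spec$subjective_grid,
    p_marginal = p_marg_hat,
    f_big = f_big_hat, f_small = f_small_hat,
    v_big = v_big_hat, v_small = v_small_hat,
    p_big = p_big_hat, p_small = 1 - p_big_hat,
    v_sub_odor = v_sub_hat,
    n_visit = n_visit, n_big = n_big, n_small = n_small)
  new_state_values(
    per_odor,
    list(v_iti = 0,
         v_odor_on = sum(p_marg_hat * v_sub_hat, na.rm = TRUE),
         v_water_big = vw_big,
         v_water_small = vw_small,
         v_nowater = 0,
         utilities = reward_utility(spec, spec$reward_multipliers),
         n_trials = n_trials),
    spec, method = "monte_carlo")
}

trial_state_names <- c("ITI", "OdorOn", "SubOdor1", "SubOdor2",
                       "WaterPort1", "WaterPort2", "Outcome1", "Outcome2")

validate_trial_type <- function(spec, odor, choice, outcome) {
  if (!odor %in% spec$odor_set) {
    abort(sprintf("Odor %g is not in the model's odor set.", odor),
          class = "tdaxon_input_error")
  }
  choice <- match.arg(choice, c("big", "small"))
  outcome <- match.arg(outcome, c("big", "medium", "small", "none"))
  correct <- (choice == "big") == (odor > 50)
  if (odor == 50) {
    abort("Odor 50 has no correct side; trial type undefined.",
          class = "tdaxon_input_error")
  }
  if (correct && outcome == "none") {
    abort("A correct trial must have a delivered amount as outcome.",
          class = "tdaxon_input_error")
  }
  if (!correct && outcome != "none") {
    abort("An error trial has outcome \"none\".", class = "tdaxon_input_error")
  }
  if (correct) {
    allowed <- if (choice == "big") c("big", "medium") else c("medium", "small")
    if (!outcome %in% allowed) {
      abort(sprintf("Outcome \"%s\" cannot occur at the %s side.", outcome,
                    toupper(choice)), class = "tdaxon_input_error")
    }
  }
  list(choice = choice, outcome = outcome, correct = correct)
}

#' TD-error trace for a trial type
#'
#' The sequence of state values and TD errors (`delta = r + V(next) -
#' V(current)`, discount 1) across the trial state machine for a given
#' objective odor, choice, and outcome. Because the trial type conditions on
#' the objective odor and the realised choice, the pre-outcome values are
#' probability-weighted mixtures over subjective odors with Bayes weights
#' proportional to `p(O'|O) * P(choice|O')`. The delivered reward is folded
#' into the terminal transition so the trace ends at outcome recognition and
#' the deltas telescope to the realised outcome utility.
#'
#' @param spec A [task_model()].
#' @param values A `state_values` object from [solve_state_values()] (or
#'   [partial_learning_values()]).
#' @param odor Objective odor (% odor instructing BIG), one of
#'   `spec$odor_set`.
#' @param choice `"big"` or `"small"`.
#' @param outcome Delivered amount class (`"big"`, `"medium"`, `"small"`) on
#'   correct trials, `"none"` on error trials.
#' @return A `td_trace` tibble with columns `state`, `value`, `delta` plus
#'   the trial-type descriptors and probability (attribute
#'   `trial_type_probability`).
#' @examples
#' spec <- task_model()
#' v <- solve_state_values(spec)
#' td_trace(spec, v, odor = 65, choice = "big", outcome = "medium")
#' @export
td_trace <- function(spec, values, odor, choice, outcome) {
  tt <- validate_trial_type(spec, odor, choice, outcome)
  choice <- tt$choice; outcome <- tt$outcome; correct <- tt$correct
  o_col <- match(odor, spec$odor_set)
  lik <- subjective_likelihood(spec)
  lik_norm <- sweep(lik, 2, colSums(lik), "/")
  p_choice_given_sub <- if (choice == "big") values$per_odor$p_big else values$per_odor$p_small
  w <- lik_norm[, o_col] * p_choice_given_sub
  p_choice_given_odor <- sum(w)
  if (p_choice_given_odor <= 1e-12) {
    abort(sprintf("Trial type (odor %g, choice %s) has zero probability under the %s policy.",
                  odor, toupper(choice), spec$policy),
          class = "tdaxon_input_error")
  }
  w <- w / p_choice_given_odor
  v_choice <- if (choice == "big") values$per_odor$v_big else values$per_odor$v_small
  v_sub <- sum(w * values$per_odor$v_sub_odor)
  v_commit <- sum(w * v_choice)
  v_water <- if (choice == "big") values$v_water_big else values$v_water_small
  v_outcome1 <- if (correct) v_water else values$v_nowater
  v_outcome2 <- if (correct) {
    unname(values$utilities[[outcome]])
  } else 0
  vals <- c(values$v_iti, values$v_odor_on, v_sub, v_sub,
            v_commit, v_commit, v_outcome1, v_outcome2)
  delta <- c(0, diff(vals))
  p_outcome <- if (correct) 0.5 else 1
  out <- tibble(
    state = factor(trial_state_names, levels = trial_state_names),
    value = vals,
    delta = delta,
    odor = odor, choice = choice, outcome = outcome, correct = correct)
  attr(out, "trial_type_probability") <-
    (1 / length(spec$odor_set)) * p_choice_given_odor * p_outcome
  class(out) <- c("td_trace", class(out))
  out
}

#' Model psychometric curve
#'
#' Analytic probability of choosing the BIG side for each presented odor:
#' the policy's choice probabilities averaged over the subjective-odor
#' distribution.
#'
#' @param spec A [task_model()].
#' @param values Optional precomputed [solve_state_values()] result.
#' @param presented Presented odor values (defaults to the model's odor set).
#' @return A tibble with `odor` and `p_big`.
#' @export
model_psychometric <- function(spec, values = NULL, presented = spec$odor_set) {
  values <- values %||% solve_state_values(spec)
  p_big <- vapply(presented, function(o) {
    w <- subjective_odor_distribution(spec, o)
    sum(w * values$per_odor$p_big)
  }, numeric(1))
  tibble(odor = presented, p_big = p_big)
}

#' Fit model noise parameters to a psychometric curve
#'
#' Grid search for the perceptual noise `sigma` (and policy parameter `tau`
#' or `epsilon`) minimising the mean squared error between an observed
#' psychometric curve and the model's analytic curve.
#'
#' @param psychometric A tibble with columns `odor` and `p_big` (observed
#'   choice proportion per presented odor).
#' @param spec Template [task_model()] supplying everything but the scanned
#'   parameters.
#' @param sigma_grid,param_grid Candidate values for `sigma` and for the
#'   policy parameter (`tau` for softmax, `epsilon` for epsilon-greedy;
#'   ignored for deterministic/matching).
#' @return A list with `sigma`, `param`, `mse`, and the full scan as a
#'   tibble (`scan`).
#' @export
fit_task_model <- function(psychometric,
                           spec = task_model(),
                           sigma_grid = seq(6, 34, by = 1),
                           param_grid = seq(0.06, 0.6, by = 0.02)) {
  stopifnot(all(c("odor", "p_big") %in% names(psychometric)))
  has_param <- spec$policy %in% c("softmax", "epsilon_greedy")
  if (!has_param) param_grid <- NA_real_
  scan <- tidyr::expand_grid(sigma = sigma_grid, param = param_grid)
  scan$mse <- purrr::map2_dbl(scan$sigma, scan$param, function(s, p) {
    cand <- spec
    cand$sigma <- s
    if (spec$policy == "softmax" && !is.na(p)) cand$tau <- p
    if (spec$policy == "epsilon_greedy" && !is.na(p)) cand$epsilon <- p
    pred <- model_psychometric(cand, presented = psychometric$odor)
    mean((pred$p_big - psychometric$p_big)^2)
  })
  best <- scan[which.min(scan$mse), ]
  list(sigma = best$sigma, param = best$param, mse = best$mse, scan = scan)
}

#' Per-trial TD-error impulses at task events
#'
#' For each trial of a generated session, the realised TD errors at the
#' within-trial transitions, mapped onto event times: odor detection at
#' `odor_on`, subjective-odor recognition shortly after, choice commitment
#' at `odor_out`, outcome detection at `outcome`, and amount discrimination
#' shortly after. Block-1 trials use a value table solved with equal (1.0x)
#' rewards; block-2 trials the full schedule. The five deltas of a trial sum
#' to its realised outcome utility.
#'
#' @param trials A trial table from [generate_session()].
#' @param spec The [task_model()] that generated the choices.
#' @param sub_odor_lag Latency (s) from odor onset to subjective-odor
#'   recognition.
#' @param discrim_lag Latency (s) from outcome detection to amount
#'   discrimination.
#' @return A tibble with `trial`, `event`, `time`, `delta`.
#' @export
trial_td_impulses <- function(trials, spec, sub_odor_lag = 0.2,
                              discrim_lag = 0.2) {
  values2 <- solve_state_values(spec)
  spec1 <- spec
  spec1$reward_multipliers <- c(big = 1, medium = 1, small = 1)
  values1 <- solve_state_values(spec1)
  per_block <- function(vals, tr, block) {
    j <- tr$sub_odor_idx
    v_sub <- vals$per_odor$v_sub_odor[j]
    v_choice <- ifelse(tr$choice == "big",
                       vals$per_odor$v_big[j], vals$per_odor$v_small[j])
    v_water <- ifelse(tr$choice == "big", vals$v_water_big, vals$v_water_small)
    util <- reward_utility(spec, tr$reward_size)
    util[tr$reward_size == 0] <- 0
    # block-1 utilities use the equal-reward table
    if (block == 1) util <- ifelse(tr$reward_size > 0, reward_utility(spec, 1), 0)
    tibble(
      trial = rep(tr$trial, 5),
      event = rep(c("odor_detect", "sub_odor", "commit",
                    "outcome_detect", "outcome_discrim"), each = nrow(tr)),
      time = c(tr$odor_on, tr$odor_on + sub_odor_lag, tr$odor_out,
               tr$outcome, tr$outcome + discrim_lag),
      delta = c(rep(vals$v_odor_on, nrow(tr)),
                v_sub - vals$v_odor_on,
                v_choice - v_sub,
                ifelse(tr$correct, v_water, 0) - v_choice,
                ifelse(tr$correct, util - v_water, 0)))
  }
  out <- bind_rows(
    per_block(values1, dplyr::filter(trials, .data$block == 1), 1),
    per_block(values2, dplyr::filter(trials, .data$block == 2), 2))
  dplyr::arrange(out, .data$time)
}
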