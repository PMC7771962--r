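#' Session configuration for the synthetic task
#'
#' Describes one recording session of the odor-guided choice task: a first
#' block with equal (standard) water on both sides, then a second block in
#' which one side becomes the BIG side (2.2 or 0.8 x standard, p = 0.5 each)
#' and the other the SMALL side (0.8 or 0.2 x standard). Odors are coded
#' throughout as % odor instructing the BIG-designated side.
#'
#' @param n_trials_block1,n_trials_block2 Trials per block.
#' @param odor_set Presented odor mixtures (% odor instructing BIG).
#' @param big_side Which physical port (`"left"`/`"right"`) is the BIG side
#'   in block 2.
#' @param reward_multipliers Water amounts in standard-water units
#'   (big > medium > small).
#' @param p_large_draw Probability of the larger drop at each side.
#' @param iti_reward_s,iti_error_s Inter-trial interval after rewarded and
#'   error outcomes (s).
#' @param rt_median,rt_sdlog Reaction-time distribution: odor sampling time
#'   is `1 + lognormal`, so its median is `rt_median` (>= 1 s stay enforced).
#' @param mt_median,mt_sdlog Movement-time (odor port out to water port in)
#'   log-normal median and log-sd.
#' @param init_median Log-normal median of the self-paced initiation delay
#'   appended to the ITI.
#' @param bias_shift_block2 Lateral psychometric shift (% odor, positive
#'   toward BIG) imposed on the agent's block-2 choices; used to emulate a
#'   reward-driven choice bias.
#' @param premature_exit Simulate premature water-port exits (higher rate on
#'   error trials); off by default.
#' @param premature_rates Exit probabilities for error and correct trials
#'   when `premature_exit` is on.
#' @param seed Optional integer seed.
#' @return A `session_config` list.
#' @export
session_config <- function(n_trials_block1 = 104,
                           n_trials_block2 = 134,
                           odor_set = c(0, 35, 65, 100),
                           big_side = c("left", "right"),
                           reward_multipliers = c(big = 2.2, medium = 0.8,
                                                  small = 0.2),
                           p_large_draw = 0.5,
                           iti_reward_s = 7,
                           iti_error_s = 9,
                           rt_median = 1.2, rt_sdlog = 0.3,
                           mt_median = 0.35, mt_sdlog = 0.25,
                           init_median = 0.3,
                           bias_shift_block2 = 0,
                           premature_exit = FALSE,
                           premature_rates = c(error = 0.3, correct = 0.05),
                           seed = NULL) {
  big_side <- match.arg(big_side)
  if (n_trials_block1 < 0 || n_trials_block2 < 0) {
    abort("Trial counts must be nonnegative.", class = "tdaxon_config_error")
  }
  if (length(odor_set) == 0 || any(odor_set < 0 | odor_set > 100)) {
    abort("`odor_set` must be a non-empty subset of [0, 100].",
          class = "tdaxon_config_error")
  }
  m <- reward_multipliers
  if (!(m[["big"]] > m[["medium"]] && m[["medium"]] > m[["small"]])) {
    abort("Reward multipliers must satisfy big > medium > small.",
          class = "tdaxon_config_error")
  }
  if (p_large_draw < 0 || p_large_draw > 1) {
    abort("`p_large_draw` must be a probability.", class = "tdaxon_config_error")
  }
  structure(as.list(environment()), class = "session_config")
}

#' Generate a behavioral session
#'
#' Simulates one session: odors drawn uniformly from the odor set, the
#' agent's subjective odor drawn from the model's perceptual-noise
#' distribution, choices from the policy (block 1 uses a value table solved
#' with equal rewards; block 2 the full schedule), rewards drawn per the
#' schedule on correct trials only, and event times satisfying the task's
#' timing constraints (odor stay >= 1 s; exactly 1 s from water port entry
#' to outcome).
#'
#' @param cfg A [session_config()].
#' @param agent A [task_model()] supplying perception and policy.
#' @return A tibble with one row per trial: `trial`, `block`, `odor`,
#'   `sub_odor`, `sub_odor_idx` (the agent's latent percept), `choice`
#'   (`"big"`/`"small"`), `choice_side`, `correct`, `reward_size`
#'   (standard-water units, 0 on errors), `reward_class`, and event times
#'   `odor_on < odor_out < port_in < outcome` plus `water_on` (NA on
#'   errors), `iti_start`, `iti_end`, `rt`, `mt`.
#' @examples
#' tr <- generate_session(session_config(seed = 1), task_model())
#' head(tr)
#' @export
generate_session <- function(cfg, agent) {
  stopifnot(inherits(cfg, "session_config"), inherits(agent, "task_model"))
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  agent1 <- agent
  agent1$reward_multipliers <- c(big = 1, medium = 1, small = 1)
  values1 <- solve_state_values(agent1)
  values2 <- solve_state_values(agent)
  n1 <- cfg$n_trials_block1; n2 <- cfg$n_trials_block2
  n <- n1 + n2
  if (n == 0) abort("Empty session.", class = "tdaxon_config_error")
  block <- rep(c(1L, 2L), c(n1, n2))
  odor <- sample(cfg$odor_set, n, replace = TRUE)

  lik_at <- function(presented) {
    vapply(presented, function(o) {
      d <- dnorm(agent$subjective_grid, o, agent$sigma)
      if (sum(d) == 0) d[which.min(abs(agent$subjective_grid - o))] <- 1
      d / sum(d)
    }, numeric(length(agent$subjective_grid)))
  }
  # the block-2 bias shift moves the percept distribution toward BIG; the
  # shifted centre is a latent quantity and may leave [0, 100]
  perceived <- ifelse(block == 2, odor + cfg$bias_shift_block2, odor)
  sub_idx <- integer(n)
  for (p in unique(perceived)) {
    sel <- perceived == p
    probs <- lik_at(p)[, 1]
    sub_idx[sel] <- sample.int(length(agent$subjective_grid), sum(sel),
                               replace = TRUE, prob = probs)
  }
  p_big <- ifelse(block == 1,
                  values1$per_odor$p_big[sub_idx],
                  values2$per_odor$p_big[sub_idx])
  choose_big <- runif(n) < p_big
  correct <- choose_big == (odor > 50)
  large <- runif(n) < cfg$p_large_draw
  m <- cfg$reward_multipliers
  reward_size <- numeric(n)
  reward_class <- rep("none", n)
  b2 <- block == 2
  reward_size[correct & !b2] <- 1
  reward_class[correct & !b2] <- "standard"
  sel <- correct & b2 & choose_big
  reward_size[sel] <- ifelse(large[sel], m[["big"]], m[["medium"]])
  reward_class[sel] <- ifelse(large[sel], "big", "medium")
  sel <- correct & b2 & !choose_big
  reward_size[sel] <- ifelse(large[sel], m[["medium"]], m[["small"]])
  reward_class[sel] <- ifelse(large[sel], "medium", "small")

  if (cfg$rt_median <= 1) {
    abort("`rt_median` must exceed the 1 s odor-stay requirement.",
          class = "tdaxon_config_error")
  }
  # 1 s enforced stay plus a log-normal excess whose median places the total
  # reaction time at rt_median
  rt <- 1 + rlnorm(n, log(cfg$rt_median - 1), cfg$rt_sdlog)
  mt <- rlnorm(n, log(cfg$mt_median), cfg$mt_sdlog)
  init <- rlnorm(n, log(cfg$init_median), 0.5)
  iti <- ifelse(correct, cfg$iti_reward_s, cfg$iti_error_s)
  odor_on <- numeric(n)
  t0 <- 2
  for (i in seq_len(n)) {
    odor_on[i] <- t0
    t0 <- t0 + rt[i] + mt[i] + 1 + iti[i] + init[i]
  }
  odor_out <- odor_on + rt
  port_in <- odor_out + mt
  outcome <- port_in + 1
  premature <- rep(FALSE, n)
  if (isTRUE(cfg$premature_exit)) {
    pr <- ifelse(correct, cfg$premature_rates[["correct"]],
                 cfg$premature_rates[["error"]])
    premature <- runif(n) < pr
  }
  tibble(
    trial = seq_len(n),
    block = block,
    odor = odor,
    sub_odor = agent$subjective_grid[sub_idx],
    sub_odor_idx = sub_idx,
    choice = ifelse(choose_big, "big", "small"),
    choice_side = ifelse(choose_big == (cfg$big_side == "left"),
                         "left", "right"),
    correct = correct,
    reward_size = reward_size,
    reward_class = reward_class,
    premature_exit = premature,
    rt = rt, mt = mt,
    odor_on = odor_on,
    odor_out = odor_out,
    port_in = port_in,
    outcome = outcome,
    water_on = ifelse(correct, outcome, NA_real_),
    iti_start = outcome + 1,
    iti_end = outcome + iti)
}

#' Generate several sessions
#'
#' Convenience wrapper around [generate_session()]; seeds each session from
#' `seed` deterministically and binds the tables with a `session` column.
#'
#' @param n_sessions Number of sessions.
#' @inheritParams generate_session
#' @param seed Integer seed for the whole batch.
#' @return A tibble of trials with a leading `session` column.
#' @export
generate_sessions <- function(n_sessions, cfg, agent, seed = NULL) {
  purrr::map_dfr(seq_len(n_sessions), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- if (is.null(seed)) NULL else seed + i - 1L
    dplyr::mutate(generate_session(cfg_i, agent), session = i, .before = 1)
  })
}
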