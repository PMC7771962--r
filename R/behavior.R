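#' Fit a psychometric function to choices
#'
#' Binomial GLM with logit link of the probability of choosing the BIG side
#' on the presented odor (% odor instructing BIG): `logit(mu) = b0 + b1 X`.
#' With `joint_blocks = TRUE` both blocks are fitted together with a shared
#' slope and a block-2 indicator, `logit(mu) = b0 + b1 X + b2 X2`, so the
#' block-2 bias shift is estimated at a fixed slope. Complete separation is
#' caught and refitted with a small ridge penalty (flagged on the result).
#'
#' @param trials Trial table with columns `odor`, `choice`, and (for joint
#'   fits) `block`.
#' @param joint_blocks Fit both blocks with a shared slope and a block
#'   indicator.
#' @return A `psychometric_fit`: coefficients `b0`, `b1` (and `b2`),
#'   covariance, `pse` (% odor at 50% BIG choice), `bias = 50 - pse`
#'   (positive toward BIG), block-wise PSEs for joint fits, convergence and
#'   separation flags.
#' @examples
#' tr <- generate_session(session_config(seed = 2), task_model())
#' fit_psychometric(tr, joint_blocks = TRUE)
#' @export
fit_psychometric <- function(trials, joint_blocks = FALSE) {
  stopifnot(all(c("odor", "choice") %in% names(trials)))
  if (length(unique(trials$odor)) < 2) {
    abort("Need at least 2 distinct odor levels.", class = "tdaxon_input_error")
  }
  if (length(unique(trials$choice)) < 2) {
    abort("Both choices must be represented.", class = "tdaxon_input_error")
  }
  dat <- trials %>%
    mutate(y = as.numeric(.data$choice == "big"),
           block2 = if (joint_blocks) as.numeric(.data$block == 2) else 0)
  agg <- dat %>%
    group_by(.data$odor, .data$block2) %>%
    summarise(n_big = sum(.data$y), n = dplyr::n(), .groups = "drop")
  form <- if (joint_blocks) {
    cbind(n_big, n - n_big) ~ odor + block2
  } else {
    cbind(n_big, n - n_big) ~ odor
  }
  fit <- suppressWarnings(
    glm(form, family = binomial(),
        data = agg, control = glm.control(epsilon = 1e-8, maxit = 100)))
  se_hat <- suppressWarnings(sqrt(diag(vcov(fit))))
  mu_hat <- fit$fitted.values
  separated <- !fit$converged || any(!is.finite(se_hat)) || any(se_hat > 10) ||
    all(abs(mu_hat - round(mu_hat)) < 1e-6)
  if (separated) {
    warn("Possible complete separation; refitting with a ridge penalty.")
    fit_pen <- ridge_logit(agg, joint_blocks)
    b <- fit_pen$coefficients
    covariance <- fit_pen$covariance
  } else {
    b <- coef(fit)
    covariance <- vcov(fit)
  }
  b0 <- unname(b[["(Intercept)"]])
  b1 <- unname(b[["odor"]])
  b2 <- if (joint_blocks) unname(b[["block2"]]) else NA_real_
  degenerate_slope <- !is.finite(b1) || abs(b1) < 1e-8
  if (degenerate_slope) {
    warn("Psychometric slope is ~0; PSE and bias are undefined.")
  }
  pse <- if (degenerate_slope) NA_real_ else -b0 / b1
  pse_block2 <- if (joint_blocks && !degenerate_slope) -(b0 + b2) / b1 else NA_real_
  out <- list(
    b0 = b0, b1 = b1, b2 = b2,
    covariance = covariance,
    pse = pse,
    bias = 50 - pse,
    pse_block1 = if (joint_blocks) pse else NA_real_,
    pse_block2 = pse_block2,
    bias_block2 = 50 - pse_block2,
    shift = if (joint_blocks && !degenerate_slope) b2 / b1 else NA_real_,
    joint_blocks = joint_blocks,
    converged = fit$converged && !separated,
    separated = separated,
    degenerate_slope = degenerate_slope,
    n = nrow(dat),
    data = agg,
    glm_fit = if (separated) NULL else fit)
  class(out) <- "psychometric_fit"
  out
}

# ridge-penalised IRLS fallback for separated data
ridge_logit <- function(agg, joint_blocks, lambda = 1e-3) {
  x <- cbind(1, agg$odor, if (joint_blocks) agg$block2)
  colnames(x) <- c("(Intercept)", "odor", if (joint_blocks) "block2")
  y <- agg$n_big; n <- agg$n
  beta <- rep(0, ncol(x))
  pen <- diag(lambda, ncol(x)); pen[1, 1] <- 0
  for (i in 1:100) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- n * mu * (1 - mu) + 1e-10
    z <- eta + (y - n * mu) / w
    h <- crossprod(x, w * x) + pen
    beta_new <- drop(solve(h, crossprod(x, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(coefficients = setNames(beta, colnames(x)),
       covariance = solve(h))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>\n")
  cat(sprintf("  b0 = %.4f, b1 = %.4f", x$b0, x$b1))
  if (x$joint_blocks) cat(sprintf(", b2 = %.4f", x$b2))
  cat("\n")
  if (x$joint_blocks) {
    cat(sprintf("  PSE: block 1 %.2f, block 2 %.2f; shift %.2f %%odor\n",
                x$pse_block1, x$pse_block2, x$shift))
  } else {
    cat(sprintf("  PSE %.2f %%odor, bias %.2f (positive toward BIG)\n",
                x$pse, x$bias))
  }
  if (x$separated) cat("  [ridge fallback: separation detected]\n")
  invisible(x)
}

#' Choice bias of a psychometric fit
#'
#' The lateral shift of the psychometric curve, `50 - pse` in % odor,
#' positive when choices are biased toward the BIG side. For joint
#' two-block fits, also the block-2 bias and the shift relative to block 1
#' (`b2 / b1`).
#'
#' @param fit A `psychometric_fit`.
#' @return A one-row tibble: `bias`, `pse`, and for joint fits
#'   `bias_block2`, `shift_vs_block1`.
#' @export
choice_bias <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (fit$degenerate_slope) {
    abort("Bias undefined: slope b1 is ~0.", class = "tdaxon_undefined_bias")
  }
  if (fit$joint_blocks) {
    tibble(bias = 50 - fit$pse_block2,
           pse = fit$pse_block2,
           bias_block1 = 50 - fit$pse_block1,
           shift_vs_block1 = fit$shift)
  } else {
    tibble(bias = fit$bias, pse = fit$pse)
  }
}

#' Reward landscape over choice bias
#'
#' For each candidate bias (lateral shift of a fixed-slope logistic choice
#' rule), computes the session-average accuracy, expected reward per trial
#' (standard-water units, zero on errors), and the coefficient of variation
#' of the per-trial reward distribution, under the block-2 schedule: the
#' BIG side pays 2.2/0.8 and the SMALL side 0.8/0.2, each with probability
#' 0.5, on correct choices only.
#'
#' @param slope Psychometric slope (log-odds per % odor, > 0).
#' @param bias_grid Candidate biases (% odor, positive toward BIG).
#' @param schedule A [session_config()] giving the odor set and reward
#'   multipliers.
#' @return A `reward_landscape` tibble: `bias`, `accuracy`,
#'   `expected_reward`, `cv`.
#' @examples
#' rl <- reward_landscape(0.1)
#' rl[which.max(rl$expected_reward), ]
#' @export
reward_landscape <- function(slope, bias_grid = seq(-30, 30, by = 0.25),
                             schedule = session_config()) {
  if (length(bias_grid) == 0) {
    abort("Empty bias grid.", class = "tdaxon_input_error")
  }
  stopifnot(slope > 0)
  m <- schedule$reward_multipliers
  p_l <- schedule$p_large_draw
  mean_big <- p_l * m[["big"]] + (1 - p_l) * m[["medium"]]
  mean_small <- p_l * m[["medium"]] + (1 - p_l) * m[["small"]]
  odors <- schedule$odor_set
  res <- purrr::map_dfr(bias_grid, function(bias) {
    pse <- 50 - bias
    p_big <- plogis(slope * (odors - pse))
    p_correct <- ifelse(odors > 50, p_big, 1 - p_big)
    exp_rew_odor <- ifelse(odors > 50, p_big * mean_big,
                           (1 - p_big) * mean_small)
    # per-trial reward distribution over (odor x choice x draw), incl. 0
    probs <- c()
    vals <- c()
    for (i in seq_along(odors)) {
      po <- 1 / length(odors)
      if (odors[i] > 50) {
        probs <- c(probs, po * p_big[i] * p_l, po * p_big[i] * (1 - p_l),
                   po * (1 - p_big[i]))
        vals <- c(vals, m[["big"]], m[["medium"]], 0)
      } else {
        probs <- c(probs, po * (1 - p_big[i]) * p_l,
                   po * (1 - p_big[i]) * (1 - p_l), po * p_big[i])
        vals <- c(vals, m[["medium"]], m[["small"]], 0)
      }
    }
    mu <- sum(probs * vals)
    sigma <- sqrt(sum(probs * (vals - mu)^2))
    tibble(bias = bias,
           accuracy = mean(p_correct),
           expected_reward = mean(exp_rew_odor),
           cv = sigma / mu)
  })
  class(res) <- c("reward_landscape", class(res))
  res
}

#' Trial-history choice bias
#'
#' Compares the choice bias on trials preceding (n-1) and following (n+1)
#' trials of a given type (reward-size class by difficulty). Both
#' sub-tables are fitted jointly with a shared slope (an n+1 indicator), so
#' the bias difference is a fixed-slope lateral shift, as in the block
#' comparison.
#'
#' @param trials Trial table (a `session` column, if present, bounds the
#'   lag/lead within sessions).
#' @param reward_class Conditioning reward class of trial n (`"big"`,
#'   `"medium"`, `"small"`, `"standard"`, or `"none"`).
#' @param difficulty Conditioning difficulty of trial n: `"easy"` (pure
#'   odors), `"difficult"` (mixtures), or `"any"`.
#' @param min_trials Minimum conditioned trials required.
#' @return A one-row tibble: `bias_prev`, `bias_next`, `difference`
#'   (next minus previous), `n_condition`.
#' @export
history_bias <- function(trials, reward_class, difficulty = "any",
                         min_trials = 50) {
  stopifnot(all(c("odor", "choice", "reward_class") %in% names(trials)))
  if (!"session" %in% names(trials)) trials$session <- 1L
  is_easy <- trials$odor %in% range(trials$odor)
  cond <- trials$reward_class == reward_class &
    switch(difficulty,
           easy = is_easy,
           difficult = !is_easy,
           any = TRUE)
  # neighbours of conditioning trials, within session bounds
  by_session <- split(seq_len(nrow(trials)), trials$session)
  prev_idx <- integer(0); next_idx <- integer(0)
  for (rows in by_session) {
    local_cond <- which(cond[rows])
    prev_idx <- c(prev_idx, rows[local_cond[local_cond > 1] - 1])
    next_idx <- c(next_idx, rows[local_cond[local_cond < length(rows)] + 1])
  }
  n_condition <- sum(cond)
  if (n_condition < min_trials || length(prev_idx) < min_trials ||
      length(next_idx) < min_trials) {
    abort(sprintf("Insufficient trials for condition (reward `%s`, difficulty `%s`): %d found, %d required.",
                  reward_class, difficulty, n_condition, min_trials),
          class = "tdaxon_insufficient_trials")
  }
  sub <- bind_rows(
    mutate(trials[prev_idx, ], block = 1L),
    mutate(trials[next_idx, ], block = 2L))
  fit <- fit_psychometric(sub, joint_blocks = TRUE)
  tibble(bias_prev = 50 - fit$pse_block1,
         bias_next = 50 - fit$pse_block2,
         difference = fit$shift,
         n_condition = n_condition)
}
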