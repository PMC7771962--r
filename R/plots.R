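#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline geom_vline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  obs <- object$data %>%
    mutate(p_big = .data$n_big / .data$n,
           block = factor(.data$block2 + 1))
  grid <- tidyr::expand_grid(odor = seq(0, 100, by = 1),
                             block2 = unique(object$data$block2))
  grid$p_big <- plogis(object$b0 + object$b1 * grid$odor +
                         ifelse(is.na(object$b2), 0, object$b2) * grid$block2)
  grid$block <- factor(grid$block2 + 1)
  ggplot(obs, aes(x = .data$odor, y = .data$p_big, colour = .data$block)) +
    geom_point(aes(size = .data$n), alpha = 0.7) +
    geom_line(data = grid, aes(group = .data$block)) +
    geom_hline(yintercept = 0.5, linetype = 3) +
    labs(x = "% odor instructing BIG", y = "P(choose BIG)",
         colour = "block", size = "trials") +
    theme_minimal()
}

#' @export
autoplot.reward_landscape <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("accuracy", "expected_reward", "cv"),
                              names_to = "measure")
  ggplot(long, aes(x = .data$bias, y = .data$value)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 3) +
    facet_wrap(~measure, scales = "free_y", ncol = 1) +
    labs(x = "choice bias (%odor, toward BIG)", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.td_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$state, group = 1)) +
    geom_line(aes(y = .data$value)) +
    geom_col(aes(y = .data$delta), alpha = 0.4) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(y = "value (line) / TD error (bars)",
         title = sprintf("odor %g, choice %s, outcome %s",
                         object$odor[1], object$choice[1], object$outcome[1])) +
    theme_minimal()
}

#' @export
autoplot.kernel_fit <- function(object, ...) {
  prof <- kernel_profiles(object)
  ggplot(prof, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    facet_wrap(~group, scales = "free_x") +
    labs(x = "time from lock event (s)", y = "kernel amplitude") +
    theme_minimal()
}

#' @export
autoplot.response_function_fit <- function(object, ...) {
  curves <- bind_rows(
    mutate(predict_response_function(object, small_side = FALSE),
           side = "BIG"),
    mutate(predict_response_function(object, small_side = TRUE),
           side = "SMALL"))
  ggplot(curves, aes(x = .data$amount, y = .data$response,
                     colour = .data$side)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "water amount (standard units)", y = "response") +
    theme_minimal()
}

#' Plot a circuit-model water response curve
#'
#' @param curve Output of [water_response_curve()].
#' @return A ggplot.
#' @export
plot_water_response <- function(curve) {
  zc <- attr(curve, "zero_crossing")
  p <- ggplot(curve, aes(x = .data$amount, y = .data$response)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "water amount (standard units)", y = "net postsynaptic response") +
    theme_minimal()
  if (!is.na(zc)) p <- p + geom_vline(xintercept = zc, linetype = 2)
  p
}
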