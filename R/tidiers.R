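#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.psychometric_fit <- function(x, ...) {
  terms <- c("b0", "b1", if (x$joint_blocks) "b2")
  est <- c(x$b0, x$b1, if (x$joint_blocks) x$b2)
  se <- sqrt(diag(x$covariance))[seq_along(terms)]
  tibble(term = terms, estimate = est, std_error = se)
}

#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble(n = x$n, pse = x$pse, bias = x$bias,
         shift = x$shift, converged = x$converged, separated = x$separated)
}

#' @export
tidy.response_function_fit <- function(x, ...) {
  tibble(term = c("k", "c1", "c2", "alpha"),
         estimate = c(x$k, x$c1, x$c2, x$alpha))
}

#' @export
glance.response_function_fit <- function(x, ...) {
  tibble(n = x$n, rss = x$rss, alpha = x$alpha,
         zero_crossing_big = x$zero_crossing_big,
         zero_crossing_small = x$zero_crossing_small,
         free_alpha = x$free_alpha)
}

#' @export
tidy.kernel_fit <- function(x, ...) {
  x$coefficients
}

#' @export
glance.kernel_fit <- function(x, ...) {
  tibble(lambda = x$lambda, rule = x$rule,
         percent_explained = x$percent_explained,
         n_samples = x$n_samples,
         n_nonzero = sum(x$coefficients$coefficient != 0))
}

#' @export
tidy.state_values <- function(x, ...) {
  x$per_odor
}

#' @export
glance.state_values <- function(x, ...) {
  tibble(method = x$method,
         v_iti = x$v_iti, v_odor_on = x$v_odor_on,
         v_water_big = x$v_water_big, v_water_small = x$v_water_small,
         v_nowater = x$v_nowater)
}

#' @export
tidy.bootstrap_comparison <- function(x, ...) {
  tibble(resample = seq_len(x$n_boot),
         r_a = x$r_a, r_b = x$r_b, delta_r = x$delta_r)
}

#' @export
glance.bootstrap_comparison <- function(x, ...) {
  tibble(p = x$p, mean_r_a = x$mean_r_a, mean_r_b = x$mean_r_b,
         n_boot = x$n_boot, n_per_type = x$n_per_type)
}
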