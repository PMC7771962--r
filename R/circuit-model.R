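#' Circuit-model parameters
#'
#' Weights of the mechanistic model in which a postsynaptic neuron receives
#' an excitatory input carrying the TD error and an inhibitory input
#' carrying its sign-flipped copy (RMTg-like). Both inputs transmit mainly
#' with excitation: below-baseline deflections are passed with gain
#' `inh_gain` (1/10 by default). Presets set the excitation:inhibition
#' weight ratio to 1:1 (balanced), 2:1 (more excitation, DLS-like) or 1:2
#' (more inhibition, DMS-like).
#'
#' @param ratio Preset name, or `NULL` to give weights directly.
#' @param w_exc,w_inh Input weights (> 0).
#' @param inh_gain Transmission gain of below-baseline deflections, in
#'   (0, 1].
#' @param inhibitory_input `"flipped"` (sign-flipped TD input, default) or
#'   `"same_sign"` (a TD-coding input wired inhibitorily).
#' @return A `circuit_params` list.
#' @export
circuit_params <- function(ratio = c("balanced", "more_excitation",
                                     "more_inhibition"),
                           w_exc = NULL, w_inh = NULL, inh_gain = 0.1,
                           inhibitory_input = c("flipped", "same_sign")) {
  inhibitory_input <- match.arg(inhibitory_input)
  if (is.null(w_exc) || is.null(w_inh)) {
    ratio <- match.arg(ratio)
    w <- switch(ratio,
                balanced = c(1, 1),
                more_excitation = c(2, 1),
                more_inhibition = c(1, 2))
    w_exc <- w[1]; w_inh <- w[2]
  } else {
    ratio <- "custom"
  }
  if (w_exc <= 0 || w_inh <= 0) {
    abort("Weights must be positive.", class = "tdaxon_parameter_error")
  }
  if (inh_gain <= 0 || inh_gain > 1) {
    abort("`inh_gain` must lie in (0, 1].", class = "tdaxon_parameter_error")
  }
  structure(list(ratio = ratio, w_exc = w_exc, w_inh = w_inh,
                 inh_gain = inh_gain, inhibitory_input = inhibitory_input),
            class = "circuit_params")
}

#' Asymmetric transmission of an input deflection
#'
#' Above-baseline deflections pass unchanged; below-baseline deflections
#' are attenuated to `inh_gain` (1/10 by default) of their size.
#'
#' @param a Input deflection(s).
#' @param inh_gain Gain applied to negative deflections.
#' @return Transmitted deflection(s).
#' @export
transmit <- function(a, inh_gain = 0.1) {
  ifelse(a >= 0, a, inh_gain * a)
}

#' Postsynaptic TD signal
#'
#' Output of a postsynaptic neuron receiving the TD error through an
#' excitatory input and (by default) its sign-flipped copy through an
#' inhibitory input, each passed through the asymmetric [transmit()] map:
#' `out = w_exc * transmit(td) - w_inh * transmit(-td)`. With balanced
#' weights the output is `(1 + inh_gain) * w * td`, i.e. perfectly
#' correlated with the input TD error; unbalanced weights rescale positive
#' and negative deflections differently.
#'
#' @param td A numeric TD-error trace, or a `td_trace` tibble (its `delta`
#'   column is transformed and returned in a `postsynaptic` column).
#' @param params A [circuit_params()].
#' @return Same shape as `td`.
#' @export
postsynaptic_td <- function(td, params) {
  stopifnot(inherits(params, "circuit_params"))
  f <- function(x) {
    inh_in <- if (params$inhibitory_input == "flipped") -x else x
    params$w_exc * transmit(x, params$inh_gain) -
      params$w_inh * transmit(inh_in, params$inh_gain)
  }
  if (is.data.frame(td)) {
    td$postsynaptic <- f(td$delta)
    td
  } else {
    f(td)
  }
}

#' Net water response versus amount, and its zero crossing
#'
#' For each delivered amount the water response is the sum of the two
#' outcome-phase TD steps -- detection (water versus no water, amount-
#' independent: `V_W - V_WaterPort`) and discrimination (amount recognised:
#' `u(R) - V_W`) -- each passed through the postsynaptic transmission map
#' and summed over the outcome window. Computed with the partial-learning
#' value table ([partial_learning_values()]), which mimics dopamine axon
#' water responses. The zero crossing is located by sign change on the
#' amount grid (linear interpolation); if the curve never changes sign the
#' crossing is flagged undefined.
#'
#' @param values A `state_values` object, normally from
#'   [partial_learning_values()].
#' @param params A [circuit_params()].
#' @param side `"big"` or `"small"`: which port's expectation applies.
#' @param amounts Amount grid (standard-water units).
#' @return A tibble `amount`, `response` with attributes `zero_crossing`
#'   and `params`.
#' @export
water_response_curve <- function(values, params, side = c("big", "small"),
                                 amounts = seq(0.01, 3, by = 0.002)) {
  side <- match.arg(side)
  stopifnot(inherits(values, "state_values"))
  v_w <- if (side == "big") values$v_water_big else values$v_water_small
  po <- values$per_odor
  p_choice <- if (side == "big") po$p_big else po$p_small
  f_side <- if (side == "big") po$f_big else po$f_small
  w <- po$p_marginal * p_choice
  p_reward <- sum(w * f_side) / sum(w)
  v_port <- p_reward * v_w
  delta_detect <- v_w - v_port
  alpha <- values$spec$alpha_utility
  delta_discrim <- amounts^alpha - v_w
  response <- postsynaptic_td(rep(delta_detect, length(amounts)), params) +
    postsynaptic_td(delta_discrim, params)
  out <- tibble(amount = amounts, response = response)
  attr(out, "zero_crossing") <- interpolate_crossing(amounts, response)
  attr(out, "params") <- params
  attr(out, "side") <- side
  attr(out, "v_waterport") <- v_port
  out
}

interpolate_crossing <- function(x, y) {
  s <- sign(y)
  flip <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(y == 0)
  if (length(exact)) return(x[exact[1]])
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i])
}

#' Zero crossing of a water response curve
#'
#' @param curve Output of [water_response_curve()].
#' @return The crossing amount, `NA` if the curve never changes sign.
#' @export
circuit_zero_crossing <- function(curve) {
  attr(curve, "zero_crossing")
}
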