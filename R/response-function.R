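#' Fit the reward response function
#'
#' Fits `r = k (R^alpha + c1 * S + c2)` to per-trial outcome responses,
#' where `R` is the delivered water amount (standard-water units) and
#' `S = 1` when water was delivered at the SMALL side. For a given `alpha`
#' the model is linear in `(k, k*c1, k*c2)` and solved by least squares;
#' `alpha = "free"` scans a grid (0.1-1.0 by 0.01) and keeps the
#' RSS-minimising exponent.
#'
#' @param responses A tibble with columns `response`, `amount`, and
#'   `small_side` (logical or 0/1). The four condition cells (big and
#'   medium at the BIG side, medium and small at the SMALL side) must all
#'   be present.
#' @param alpha Fixed exponent (default 0.7), or `"free"`.
#' @param alpha_grid Grid used when `alpha = "free"`.
#' @return A `response_function_fit`: `k`, `c1`, `c2`, `alpha`, `rss`, `n`,
#'   and the zero crossings for both sides (`NA` with a flag when the
#'   response never crosses zero).
#' @examples
#' tr <- tibble::tibble(amount = rep(c(2.2, 0.8, 0.8, 0.2), each = 20),
#'                      small_side = rep(c(0, 0, 1, 1), each = 20))
#' tr$response <- tr$amount^0.7 - 0.3 * tr$small_side - 0.6
#' fit_response_function(tr)
#' @export
fit_response_function <- function(responses, alpha = 0.7,
                                  alpha_grid = seq(0.1, 1, by = 0.01)) {
  stopifnot(all(c("response", "amount", "small_side") %in% names(responses)))
  responses <- responses[complete.cases(
    responses[, c("response", "amount", "small_side")]), ]
  responses$small_side <- as.numeric(responses$small_side)
  cells <- dplyr::distinct(responses, .data$amount, .data$small_side)
  for (side in c(0, 1)) {
    n_amt <- sum(cells$small_side == side)
    if (n_amt < 2) {
      abort(sprintf("Missing condition cell(s): need two amounts at the %s side.",
                    if (side == 1) "SMALL" else "BIG"),
            class = "tdaxon_input_error")
    }
  }
  fit_at <- function(a) {
    xr <- responses$amount^a
    fit <- lm(response ~ xr + small_side, data = responses)
    list(fit = fit, rss = sum(fit$residuals^2), alpha = a)
  }
  if (identical(alpha, "free")) {
    fits <- lapply(alpha_grid, fit_at)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  } else {
    best <- fit_at(alpha)
  }
  cf <- coef(best$fit)
  k <- unname(cf[["xr"]])
  if (abs(k) < 1e-12) {
    warn("Gain k is numerically zero; offsets are undefined.")
  }
  c1 <- unname(cf[["small_side"]]) / k
  c2 <- unname(cf[["(Intercept)"]]) / k
  out <- list(k = k, c1 = c1, c2 = c2, alpha = best$alpha,
              rss = best$rss, n = nrow(responses),
              lm_fit = best$fit,
              free_alpha = identical(alpha, "free"))
  out$zero_crossing_big <- crossing_value(out, small_side = FALSE)
  out$zero_crossing_small <- crossing_value(out, small_side = TRUE)
  class(out) <- "response_function_fit"
  out
}

crossing_value <- function(fit, small_side) {
  bracket <- -(fit$c2 + if (small_side) fit$c1 else 0)
  if (!is.finite(bracket) || bracket <= 0) return(NA_real_)
  bracket^(1 / fit$alpha)
}

#' @export
print.response_function_fit <- function(x, ...) {
  cat("<response_function_fit>  r = k (R^a + c1 S + c2)\n")
  cat(sprintf("  k = %.4f, c1 = %.4f, c2 = %.4f, alpha = %.2f%s (n = %d, rss = %.4g)\n",
              x$k, x$c1, x$c2, x$alpha,
              if (x$free_alpha) " [fitted]" else "", x$n, x$rss))
  cat(sprintf("  zero crossing: BIG %s, SMALL %s (standard-water units)\n",
              format_crossing(x$zero_crossing_big),
              format_crossing(x$zero_crossing_small)))
  invisible(x)
}

format_crossing <- function(z) {
  if (is.na(z)) "undefined (no sign change)" else sprintf("%.3f", z)
}

#' Zero-crossing amount of a fitted response function
#'
#' The delivered water amount at which the fitted response is zero:
#' `(-c2)^(1/alpha)` under BIG-side expectation and `(-c1-c2)^(1/alpha)`
#' under SMALL-side expectation. When the bracket is nonpositive the
#' response never crosses zero (all-positive responses, as in DLS) and the
#' crossing is flagged undefined (`NA`).
#'
#' @param fit A `response_function_fit`.
#' @param side `"big"` or `"small"`.
#' @return The crossing amount, or `NA` when undefined.
#' @export
zero_crossing <- function(fit, side = c("big", "small")) {
  side <- match.arg(side)
  if (side == "big") fit$zero_crossing_big else fit$zero_crossing_small
}

#' Predicted reward response curve
#'
#' @param fit A `response_function_fit`.
#' @param amounts Amount grid.
#' @param small_side Evaluate under SMALL-side expectation.
#' @return Tibble `amount`, `response`.
#' @export
predict_response_function <- function(fit, amounts = seq(0.01, 2.5, by = 0.01),
                                      small_side = FALSE) {
  tibble(amount = amounts,
         response = fit$k * (amounts^fit$alpha +
                               fit$c1 * as.numeric(small_side) + fit$c2))
}

#' Regression of zero crossings on anatomical location
#'
#' Multiple linear regression of per-animal zero-crossing amounts on the
#' fiber coordinates (anterior-posterior, dorsal-ventral, medial-lateral),
#' as used to test whether the excitation/inhibition boundary shifts along
#' striatal axes.
#'
#' @param records A tibble with columns `crossing`, `ap`, `dv`, `ml` (mm);
#'   at least 4 complete records.
#' @return A tibble with per-axis `estimate`, `std_error`, `statistic`,
#'   `p_value`; the model and condition number are attached as attributes.
#' @export
anatomy_regression <- function(records) {
  stopifnot(all(c("crossing", "ap", "dv", "ml") %in% names(records)))
  records <- records[complete.cases(records[, c("crossing", "ap", "dv", "ml")]), ]
  if (nrow(records) < 4) {
    abort("Need at least 4 records with coordinates.",
          class = "tdaxon_input_error")
  }
  x <- as.matrix(records[, c("ap", "dv", "ml")])
  kappa_x <- kappa(scale(x, scale = FALSE))
  if (!is.finite(kappa_x) || kappa_x > 1e6) {
    warn(sprintf("Coordinates are (near-)collinear (condition number %.3g).",
                 kappa_x))
  }
  fit <- lm(crossing ~ ap + dv + ml, data = records)
  sm <- summary(fit)$coefficients
  out <- tibble(term = rownames(sm),
                estimate = sm[, "Estimate"],
                std_error = sm[, "Std. Error"],
                statistic = sm[, "t value"],
                p_value = sm[, "Pr(>|t|)"])
  attr(out, "model") <- fit
  attr(out, "condition_number") <- kappa_x
  out
}

#' Evidence / value slope of windowed responses
#'
#' OLS slope of per-trial window responses on a predictor (sensory evidence
#' as % odor supporting the choice, or stimulus-associated value), computed
#' separately per choice side.
#'
#' @param responses A tibble with a response column, a predictor column,
#'   and a `choice` column.
#' @param response,predictor Column names (strings).
#' @return A tibble per choice: `choice`, `beta`, `std_error`, `statistic`,
#'   `p_value`, `n`.
#' @export
evidence_slope <- function(responses, response, predictor) {
  stopifnot(all(c(response, predictor, "choice") %in% names(responses)))
  purrr::map_dfr(unique(responses$choice), function(ch) {
    d <- responses[responses$choice == ch &
                     is.finite(responses[[response]]) &
                     is.finite(responses[[predictor]]), ]
    if (length(unique(d[[predictor]])) < 2) {
      abort(sprintf("Predictor `%s` has fewer than 2 levels for choice %s.",
                    predictor, ch),
            class = "tdaxon_input_error")
    }
    fit <- lm(d[[response]] ~ d[[predictor]])
    # degenerate (constant) responses make summary.lm warn; the slope is 0
    sm <- suppressWarnings(summary(fit))$coefficients
    tibble(choice = ch,
           beta = sm[2, "Estimate"],
           std_error = sm[2, "Std. Error"],
           statistic = sm[2, "t value"],
           p_value = sm[2, "Pr(>|t|)"],
           n = nrow(d))
  })
}
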