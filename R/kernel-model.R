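#' Raised-cosine temporal basis
#'
#' Basis bumps `0.5 * (1 + cos(2 pi (t - c) / w))` on `|t - c| <= w / 2`,
#' with centres spaced every `interval` across `[t_start, t_end]` inclusive.
#' With the default width 0.2 s and interval 0.04 s the interior of the span
#' is covered by a partition of unity (up to a constant factor).
#'
#' @param t_start,t_end Span of the kernel group (s, relative to its lock
#'   event).
#' @param width Bump width (s).
#' @param interval Centre spacing (s).
#' @return A tibble with one row per basis function: `center`, `width`.
#' @export
raised_cosine_basis <- function(t_start, t_end, width = 0.2, interval = 0.04) {
  tibble(center = seq(t_start, t_end, by = interval), width = width)
}

# basis value of a bump at lag dt from its centre
rc_value <- function(dt, width) {
  ifelse(abs(dt) <= width / 2, 0.5 * (1 + cos(2 * pi * dt / width)), 0)
}

#' Kernel-group specification for the encoding model
#'
#' The event-locked kernel groups of the encoding model: odor kernels
#' (a base kernel spanning -960..200 ms around odor onset in all trials,
#' plus pure-BIG / pure-SMALL / mixture kernels 0..1600 ms), movement
#' kernels (contra / ipsi turn, -1000..1200 ms around odor port out),
#' choice kernels (correct-BIG / correct-SMALL -400..1200 ms and error
#' -400..5200 ms around water port in), and water kernels (big /
#' medium-at-BIG-side / medium-at-SMALL-side / small, 0..4200 ms after
#' water onset). Each group carries a lock event, a span, and a trial
#' condition.
#'
#' @param recorded_side Hemisphere of the recording site (`"left"` or
#'   `"right"`); determines which choices are contra- versus ipsilateral.
#' @param width,interval Raised-cosine width and centre spacing (s).
#' @param groups Optional tibble overriding the default groups; must have
#'   columns `group`, `component`, `lock`, `t_start`, `t_end`, `condition`
#'   (list column of predicate functions of the trial table).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(recorded_side = c("left", "right"),
                        width = 0.2, interval = 0.04,
                        groups = NULL) {
  recorded_side <- match.arg(recorded_side)
  contra <- if (recorded_side == "left") "right" else "left"
  if (is.null(groups)) {
    groups <- tibble(
      group = c("odor_base", "pure_big", "pure_small", "mixture",
                "contra_turn", "ipsi_turn",
                "correct_big", "correct_small", "error",
                "water_big", "water_medium_big_side",
                "water_medium_small_side", "water_small"),
      component = c("odor", "odor", "odor", "odor",
                    "movement", "movement",
                    "choice", "choice", "choice",
                    "water", "water", "water", "water"),
      lock = c("odor_on", "odor_on", "odor_on", "odor_on",
               "odor_out", "odor_out",
               "port_in", "port_in", "port_in",
               "water_on", "water_on", "water_on", "water_on"),
      t_start = c(-0.96, 0, 0, 0, -1, -1, -0.4, -0.4, -0.4, 0, 0, 0, 0),
      t_end = c(0.2, 1.6, 1.6, 1.6, 1.2, 1.2, 1.2, 1.2, 5.2,
                4.2, 4.2, 4.2, 4.2),
      condition = list(
        function(tr) rep(TRUE, nrow(tr)),
        function(tr) tr$odor == 100,
        function(tr) tr$odor == 0,
        function(tr) tr$odor > 0 & tr$odor < 100,
        function(tr) tr$choice_side == contra,
        function(tr) tr$choice_side != contra,
        function(tr) tr$correct & tr$choice == "big",
        function(tr) tr$correct & tr$choice == "small",
        function(tr) !tr$correct,
        function(tr) tr$reward_class == "big",
        function(tr) tr$reward_class == "medium" & tr$choice == "big",
        function(tr) tr$reward_class == "medium" & tr$choice == "small",
        function(tr) tr$reward_class == "small"))
  }
  stopifnot(all((groups$t_end - groups$t_start) %% interval < 1e-9 |
                  interval - ((groups$t_end - groups$t_start) %% interval) < 1e-9))
  structure(list(groups = groups, width = width, interval = interval,
                 recorded_side = recorded_side),
            class = "kernel_spec")
}

#' Build the encoding-model design matrix
#'
#' One row per 20 ms sample of every valid trial window (-1 to +7 s from
#' odor onset by default); one column per (kernel group, basis centre).
#' A column is active only on samples of trials satisfying the group's
#' condition, with the raised-cosine value at the lag between the sample
#' and the centre (relative to the group's lock event). Trials missing the
#' lock event of an applicable group are dropped with a message.
#'
#' @param trials Trial table.
#' @param session A `photometry_session`; the response vector is the green
#'   channel linearly interpolated at the sample times.
#' @param spec A [kernel_spec()].
#' @param sample_step Sample spacing (s).
#' @param trial_window Window around odor onset (s).
#' @return A list: sparse design `x`, response `y`, `rows` (tibble `trial`,
#'   `time`), `columns` (tibble `group`, `center`), and the spec.
#' @export
build_design <- function(trials, session, spec,
                         sample_step = 0.02, trial_window = c(-1, 7)) {
  groups <- spec$groups
  drop <- rep(FALSE, nrow(trials))
  for (gi in seq_len(nrow(groups))) {
    applicable <- groups$condition[[gi]](trials)
    missing_ev <- is.na(trials[[groups$lock[gi]]])
    bad <- applicable & missing_ev & groups$lock[gi] != "water_on"
    if (any(bad)) {
      inform(sprintf("Dropping %d trial(s) lacking event `%s` for group `%s`.",
                     sum(bad), groups$lock[gi], groups$group[gi]))
      drop <- drop | bad
    }
  }
  trials <- trials[!drop, , drop = FALSE]
  rel <- seq(trial_window[1], trial_window[2], by = sample_step)
  n_per <- length(rel)
  n_tr <- nrow(trials)
  times <- rep(trials$odor_on, each = n_per) + rep(rel, n_tr)
  row_trial <- rep(trials$trial, each = n_per)
  tt <- (seq_along(session$green) - 1) / session$fs
  y <- approx(tt, session$green, xout = times, rule = 2)$y

  col_group <- character(0)
  col_center <- numeric(0)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  col_offset <- 0L
  half <- spec$width / 2
  for (gi in seq_len(nrow(groups))) {
    basis <- raised_cosine_basis(groups$t_start[gi], groups$t_end[gi],
                                 spec$width, spec$interval)
    nb <- nrow(basis)
    sel_tr <- groups$condition[[gi]](trials)
    lock_times <- trials[[groups$lock[gi]]]
    keep_tr <- sel_tr & !is.na(lock_times)
    if (any(keep_tr)) {
      row_sel <- which(rep(keep_tr, each = n_per))
      dt <- times[row_sel] - rep(lock_times[keep_tr], each = n_per)
      inside <- dt >= groups$t_start[gi] - half & dt <= groups$t_end[gi] + half
      row_sel <- row_sel[inside]
      dt <- dt[inside]
      if (length(dt)) {
        # each sample overlaps at most ceiling(width/interval)+1 centres
        k0 <- ceiling((dt - half - basis$center[1]) / spec$interval)
        n_overlap <- floor(spec$width / spec$interval) + 1
        for (off in 0:(n_overlap - 1)) {
          k <- k0 + off
          ok <- k >= 0 & k <= nb - 1
          if (!any(ok)) next
          cen <- basis$center[1] + k[ok] * spec$interval
          val <- rc_value(dt[ok] - cen, spec$width)
          nz <- val > 0
          ii <- c(ii, row_sel[ok][nz])
          jj <- c(jj, col_offset + k[ok][nz] + 1L)
          vv <- c(vv, val[nz])
        }
      }
    }
    col_group <- c(col_group, rep(groups$group[gi], nb))
    col_center <- c(col_center, basis$center)
    col_offset <- col_offset + nb
  }
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(length(y), col_offset))
  list(x = x, y = y,
       rows = tibble(trial = row_trial, time = times),
       columns = tibble(group = col_group, center = col_center),
       spec = spec)
}

#' Fit the kernel model with cross-validated lasso
#'
#' Lasso regression of the photometry samples on the kernel design, with
#' 10-fold cross-validation blocked by trial (all samples of a trial share
#' a fold) and the regularisation weight chosen by the one-standard-error
#' rule: the largest lambda whose CV error is within one SE of the minimum.
#' Columns are standardised internally; coefficients are returned on the
#' original scale and the intercept is unpenalised.
#'
#' @param design Output of [build_design()].
#' @param folds Number of CV folds.
#' @param seed Optional seed for the fold assignment.
#' @param rule `"1se"` (default) or `"min"`.
#' @return A `kernel_fit`: coefficient tibble (`group`, `center`,
#'   `coefficient`), `intercept`, `lambda`, the CV curve, fitted values,
#'   `percent_explained`, and the fold assignment.
#' @export
fit_kernels <- function(design, folds = 10, seed = NULL, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (var(design$y) == 0) {
    abort("Response has zero variance.", class = "tdaxon_input_error")
  }
  trials <- unique(design$rows$trial)
  if (length(trials) < folds) {
    abort(sprintf("Need at least %d trials for %d-fold CV.", folds, folds),
          class = "tdaxon_input_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  trial_fold <- sample(rep_len(seq_len(folds), length(trials)))
  foldid <- trial_fold[match(design$rows$trial, trials)]
  cv <- glmnet::cv.glmnet(design$x, design$y, foldid = foldid,
                          standardize = TRUE)
  lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.numeric(coef(cv, s = lambda))
  fitted <- as.numeric(predict(cv, design$x, s = lambda))
  out <- list(
    coefficients = dplyr::mutate(design$columns, coefficient = cf[-1]),
    intercept = cf[1],
    lambda = lambda,
    rule = rule,
    cv_curve = tibble(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
    fitted = fitted,
    residual_ss = sum((design$y - fitted)^2),
    percent_explained = 1 - var(design$y - fitted) / var(design$y),
    foldid = foldid,
    trial_fold = tibble(trial = trials, fold = trial_fold),
    n_samples = length(design$y),
    spec = design$spec)
  class(out) <- "kernel_fit"
  out
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit>\n")
  cat(sprintf("  lambda (%s rule): %.5g; %d basis coefficients (%d nonzero)\n",
              x$rule, x$lambda, nrow(x$coefficients),
              sum(x$coefficients$coefficient != 0)))
  cat(sprintf("  %% variance explained: %.1f%% over %d samples\n",
              100 * x$percent_explained, x$n_samples))
  invisible(x)
}

#' Fraction of variance explained by a kernel fit
#'
#' `1 - var(y - yhat) / var(y)` for a fitted model, optionally on a new
#' design/response pair.
#'
#' @param fit A `kernel_fit`.
#' @param design Optional [build_design()] output to evaluate on; defaults
#'   to the training fit.
#' @return A fraction (can be negative on held-out data).
#' @export
percent_explained <- function(fit, design = NULL) {
  if (is.null(design)) return(fit$percent_explained)
  cf <- fit$coefficients$coefficient
  yhat <- as.numeric(design$x %*% cf) + fit$intercept
  1 - var(design$y - yhat) / var(design$y)
}

#' Contribution of a model component
#'
#' Refits the model with one component's kernel groups removed -- the same
#' rows, response, fold assignment and lambda rule, minus the component's
#' columns -- and reports the increase in residual sum of squares relative
#' to the full model, also as a fraction of the reduced model's RSS.
#'
#' @param fit A full-model `kernel_fit`.
#' @param design The [build_design()] output the full model was fitted on.
#' @param component One of `"odor"`, `"movement"`, `"choice"`, `"water"`.
#' @return A tibble: `component`, `rss_full`, `rss_reduced`, `contribution`
#'   (RSS difference), `fraction`.
#' @export
component_contribution <- function(fit, design, component) {
  spec <- fit$spec
  if (!component %in% unique(spec$groups$component)) {
    abort(sprintf("Unknown component `%s`.", component),
          class = "tdaxon_input_error")
  }
  drop_groups <- spec$groups$group[spec$groups$component == component]
  keep <- !(design$columns$group %in% drop_groups)
  foldid <- fit$trial_fold$fold[match(design$rows$trial, fit$trial_fold$trial)]
  cv <- glmnet::cv.glmnet(design$x[, keep, drop = FALSE], design$y,
                          foldid = foldid, standardize = TRUE)
  lambda <- if (fit$rule == "1se") cv$lambda.1se else cv$lambda.min
  yhat <- as.numeric(predict(cv, design$x[, keep, drop = FALSE], s = lambda))
  rss_reduced <- sum((design$y - yhat)^2)
  tibble(component = component,
         rss_full = fit$residual_ss,
         rss_reduced = rss_reduced,
         contribution = rss_reduced - fit$residual_ss,
         fraction = (rss_reduced - fit$residual_ss) / rss_reduced)
}

#' Fitted kernel profiles
#'
#' Evaluates each group's fitted kernel (the coefficient-weighted sum of
#' raised-cosine bumps) on a fine time grid.
#'
#' @param fit A `kernel_fit`.
#' @param dt Evaluation step (s).
#' @return A tibble: `group`, `time`, `value`.
#' @export
kernel_profiles <- function(fit, dt = 0.01) {
  spec <- fit$spec
  purrr::map_dfr(unique(fit$coefficients$group), function(g) {
    cf <- dplyr::filter(fit$coefficients, .data$group == g)
    gr <- dplyr::filter(spec$groups, .data$group == g)
    t_eval <- seq(gr$t_start - spec$width / 2, gr$t_end + spec$width / 2,
                  by = dt)
    val <- vapply(t_eval, function(t0) {
      sum(cf$coefficient * rc_value(t0 - cf$center, spec$width))
    }, numeric(1))
    tibble(group = g, time = t_eval, value = val)
  })
}
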