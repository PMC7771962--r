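#' Classify trials into the eight comparison types
#'
#' Choice (BIG/SMALL) by odor difficulty (easy = pure odors, difficult =
#' mixtures) by accuracy (correct/error).
#'
#' @param trials Trial table.
#' @return The table with `difficulty` and `trial_type` columns.
#' @export
classify_trial_types <- function(trials) {
  pure <- range(trials$odor)
  trials %>%
    mutate(difficulty = ifelse(.data$odor %in% pure, "easy", "difficult"),
           trial_type = paste(.data$choice, .data$difficulty,
                              ifelse(.data$correct, "correct", "error"),
                              sep = "_"))
}

#' Per-animal mean responses by trial type and phase
#'
#' Averages per-trial window responses within animal, trial type, and phase
#' (before choice / after choice), producing the response set the bootstrap
#' comparison consumes.
#'
#' @param responses Event-response table (one row per trial) with columns
#'   `animal`, the two phase columns, `choice`, `odor`, `correct`.
#' @param before,after Names of the response columns for the two phases.
#' @return A tibble: `animal`, `trial_type`, `phase`, `value`.
#' @export
trial_type_means <- function(responses, before = "odor_pre_exit",
                             after = "post_choice") {
  stopifnot(all(c("animal", before, after) %in% names(responses)))
  classify_trial_types(responses) %>%
    tidyr::pivot_longer(cols = all_of(c(before, after)),
                        names_to = "phase", values_to = "value") %>%
    mutate(phase = ifelse(.data$phase == before, "before", "after")) %>%
    filter(is.finite(.data$value)) %>%
    group_by(.data$animal, .data$trial_type, .data$phase) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}

#' Model value predictions per trial type and phase
#'
#' The model's state values at the two phases for each of the eight trial
#' types: before choice the subjective-odor state value, after choice the
#' water-port (post-commitment) state value, both conditional on the
#' objective odor and choice via [td_trace()] and expressed relative to the
#' ITI value (0) -- the quantity a baseline-subtracted photometry response
#' tracks. With the symmetric four-odor set each trial type maps to one
#' objective odor per choice.
#'
#' @param spec A [task_model()].
#' @param values Optional precomputed values.
#' @return A tibble: `trial_type`, `phase`, `prediction`.
#' @export
trial_type_predictions <- function(spec, values = NULL) {
  values <- values %||% solve_state_values(spec)
  odors <- sort(spec$odor_set)
  stopifnot(length(odors) == 4)
  cells <- tidyr::expand_grid(choice = c("big", "small"),
                              difficulty = c("easy", "difficult"),
                              accuracy = c("correct", "error"))
  purrr::pmap_dfr(cells, function(choice, difficulty, accuracy) {
    correct <- accuracy == "correct"
    big_instructing <- (choice == "big") == correct
    odor <- if (difficulty == "easy") {
      if (big_instructing) odors[4] else odors[1]
    } else {
      if (big_instructing) odors[3] else odors[2]
    }
    # "medium" is deliverable at either side; pre-outcome values don't
    # depend on the drawn amount
    outcome <- if (!correct) "none" else "medium"
    tr <- td_trace(spec, values, odor = odor, choice = choice,
                   outcome = outcome)
    tibble(trial_type = paste(choice, difficulty, accuracy, sep = "_"),
           phase = c("before", "after"),
           prediction = c(tr$value[tr$state == "SubOdor1"],
                          tr$value[tr$state == "WaterPort1"]))
  })
}

#' Bootstrap comparison of two models against responses
#'
#' Resamples `n_per_type` animal-level values with replacement from every
#' trial-type-by-phase cell (so rare trial types weigh equally), computes
#' the Pearson correlation of each resample with the two models'
#' predictions, and reports the distribution of the correlation difference
#' and the probability that model B's correlation is equal to or smaller
#' than model A's (the p-value of the one-sided comparison favouring B).
#'
#' @param data Per-animal response set from [trial_type_means()] (columns
#'   `trial_type`, `phase`, `value`).
#' @param pred_a,pred_b Model predictions (columns `trial_type`, `phase`,
#'   `prediction`), e.g. from [trial_type_predictions()].
#' @param n_boot Number of bootstrap resamples.
#' @param n_per_type Values drawn per cell.
#' @param seed Optional integer seed.
#' @return A `bootstrap_comparison`: `p` (fraction of resamples with
#'   `r_b <= r_a`), `delta_r` vector, mean correlations, and settings.
#' @export
bootstrap_compare <- function(data, pred_a, pred_b, n_boot = 500,
                              n_per_type = 22, seed = NULL) {
  if (n_boot < 1) abort("`n_boot` must be >= 1.", class = "tdaxon_input_error")
  if (!is.null(seed)) withr::local_seed(seed)
  cells <- dplyr::distinct(pred_a[, c("trial_type", "phase")])
  cell_values <- purrr::pmap(cells, function(trial_type, phase) {
    v <- data$value[data$trial_type == trial_type & data$phase == phase]
    if (length(v) == 0) {
      abort(sprintf("No responses in cell (%s, %s).", trial_type, phase),
            class = "tdaxon_input_error")
    }
    v
  })
  pa <- dplyr::left_join(cells, pred_a, by = c("trial_type", "phase"))$prediction
  pb <- dplyr::left_join(cells, pred_b, by = c("trial_type", "phase"))$prediction
  stopifnot(!anyNA(pa), !anyNA(pb))
  pa_rep <- rep(pa, each = n_per_type)
  pb_rep <- rep(pb, each = n_per_type)
  delta_r <- numeric(n_boot)
  r_a_all <- numeric(n_boot); r_b_all <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    samp <- unlist(lapply(cell_values, function(v) {
      v[sample.int(length(v), n_per_type, replace = TRUE)]
    }))
    r_a_all[b] <- cor(samp, pa_rep)
    r_b_all[b] <- cor(samp, pb_rep)
    delta_r[b] <- r_b_all[b] - r_a_all[b]
  }
  out <- list(p = mean(delta_r <= 0),
              delta_r = delta_r,
              r_a = r_a_all, r_b = r_b_all,
              mean_r_a = mean(r_a_all), mean_r_b = mean(r_b_all),
              n_boot = n_boot, n_per_type = n_per_type)
  class(out) <- "bootstrap_comparison"
  out
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat("<bootstrap_comparison>\n")
  cat(sprintf("  mean r: model A %.3f, model B %.3f\n", x$mean_r_a, x$mean_r_b))
  cat(sprintf("  p(r_B <= r_A) = %.4f over %d resamples (%d values/cell)\n",
              x$p, x$n_boot, x$n_per_type))
  invisible(x)
}
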