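# Synthetic patient trajectories drawn from the model itself, and
# recovery of the transition probabilities from such panels. This gives
# the estimation path an end-to-end test bed with known ground truth: the
# generator plays the role of the trial data behind the published
# transition probabilities.

EVENT_LABELS <- c("none", "tur", "rc", "rc_death", "death")

#' Generate a panel of synthetic patient state trajectories
#'
#' Draws `n_patients` i.i.d. annual state sequences from the arm's
#' transition matrix. Each sequence starts tumor free after TUR and stops
#' at death or the horizon. Every transition is annotated with the event
#' it represents: `"tur"` (recurrence plus repeat resection), `"rc"`
#' (worsening, cystectomy survived), `"rc_death"` (death at cystectomy),
#' `"death"` (any other death) or `"none"`.
#'
#' The `"rc_death"` marker distinguishes surgical from other deaths, which
#' makes the RC surgical mortality recoverable from the panel. Real
#' registry data may not carry that distinction; set
#' `surgery_marker = FALSE` to record those deaths as plain `"death"` and
#' exercise the resulting non-identifiability (see [estimate_params()]).
#'
#' @param params A `bcg_params` object.
#' @param arm `"FD"` or `"LD"`.
#' @param n_patients Number of patients.
#' @param horizon Annual cycles per patient.
#' @param seed Integer RNG seed.
#' @param surgery_marker Keep the death-at-surgery marker?
#' @return A long tibble of class `bcg_panel` with columns `patient_id`,
#'   `cycle`, `state`, `event` (`NA` at cycle 0). Generating parameters,
#'   arm, seed, horizon and marker flag are attached as attributes.
#' @export
#' @examples
#' pan <- generate_panel(default_parameters(), "FD", n_patients = 100,
#'                       seed = 3)
#' head(pan)
generate_panel <- function(params, arm = c("FD", "LD"), n_patients,
                           horizon = 20, seed = 1L, surgery_marker = TRUE) {
  arm <- match.arg(arm)
  if (n_patients < 1) rlang::abort("n_patients must be >= 1")
  M <- build_matrix(params, arm)
  U <- withr::with_seed(seed, base::matrix(stats::runif(n_patients * horizon),
                                           n_patients, horizon))
  sim <- sim_core(M, n_patients, horizon, U)

  S <- sim$states
  first_dead <- apply(S == 5L, 1, function(z) if (any(z)) which(z)[1] - 1
                      else NA_integer_)
  last_cycle <- ifelse(is.na(first_dead), horizon, first_dead)

  n_rows <- last_cycle + 1L
  patient_id <- rep(seq_len(n_patients), n_rows)
  cycle <- unlist(lapply(last_cycle, function(k) 0:k), use.names = FALSE)
  state <- BCG_STATES[S[cbind(patient_id, cycle + 1L)]]
  ev_code <- rep(NA_integer_, length(cycle))
  has_ev <- cycle > 0
  ev_code[has_ev] <- sim$events[cbind(patient_id[has_ev], cycle[has_ev])]
  event <- ifelse(is.na(ev_code), NA_character_, EVENT_LABELS[ev_code + 1L])
  if (!surgery_marker) event[event == "rc_death"] <- "death"

  out <- tibble::tibble(patient_id = patient_id, cycle = cycle,
                        state = state, event = event)
  out <- dplyr::arrange(out, .data$patient_id, .data$cycle)
  structure(out, class = c("bcg_panel", class(out)),
            params = params, arm = arm, seed = seed, horizon = horizon,
            n_patients = n_patients, surgery_marker = surgery_marker)
}

#' Export a trajectory panel as long-format CSV
#'
#' @param panel A `bcg_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(tibble::as_tibble(panel), path, row.names = FALSE)
  invisible(path)
}

est_row <- function(parameter, events, exposure, status = "ok") {
  if (exposure == 0 || status != "ok") {
    return(tibble::tibble(
      parameter = parameter, estimate = NA_real_, events = events,
      exposure = exposure, conf_low = NA_real_, conf_high = NA_real_,
      status = if (exposure == 0 && status == "ok") "no_exposure" else status))
  }
  ci <- stats::binom.test(events, exposure)$conf.int
  tibble::tibble(parameter = parameter, estimate = events / exposure,
                 events = events, exposure = exposure,
                 conf_low = ci[1], conf_high = ci[2], status = "ok")
}

#' Recover transition probabilities from a trajectory panel
#'
#' Estimates each annual transition probability as events divided by
#' person-cycles at risk in the corresponding origin state, with exact
#' binomial 95 percent confidence intervals:
#' \itemize{
#'   \item recurrence without worsening: `"tur"` transitions over
#'     person-cycles in the two bladder-intact disease-free states;
#'   \item recurrence with worsening: `"rc"` plus `"rc_death"` transitions
#'     over the same exposure;
#'   \item RC surgical mortality: `"rc_death"` over worsening events;
#'   \item age-specific mortality: non-surgical deaths from the
#'     disease-free states over their person-cycles;
#'   \item metastasis after RC and metastatic death: the corresponding
#'     transitions over person-cycles in the origin state.
#' }
#'
#' If the panel lacks the death-at-surgery marker, the split of the
#' worsening exit into survived-RC versus surgical death is not
#' identifiable: the recurrence-with-worsening probability and the RC
#' surgical mortality are returned with `status = "not_identifiable"`, and
#' the identifiable combination — the probability of worsening and
#' surviving the operation, \eqn{p_w (1 - m)} — is reported as
#' `<arm>_rec_worse_survived`. Age-specific mortality then falls back to
#' deaths from the post-RC state only, where no surgical deaths occur.
#' Parameters with zero exposure are returned with `status =
#' "no_exposure"` and an absent estimate.
#'
#' @param panel A `bcg_panel` from [generate_panel()].
#' @return A tibble of class `bcg_estimates`: columns `parameter`,
#'   `estimate`, `events`, `exposure`, `conf_low`, `conf_high`, `status`.
#'   The panel's arm and generating parameters are attached as attributes.
#' @export
#' @examples
#' pan <- generate_panel(default_parameters(), "FD", n_patients = 5000,
#'                       seed = 11)
#' estimate_params(pan)
estimate_params <- function(panel) {
  if (nrow(panel) == 0) rlang::abort("panel is empty")
  arm <- tolower(attr(panel, "arm") %||% "fd")
  horizon <- attr(panel, "horizon") %||% max(panel$cycle)
  marker <- isTRUE(attr(panel, "surgery_marker"))

  df <- tibble::as_tibble(panel)
  df <- dplyr::arrange(df, .data$patient_id, .data$cycle)
  nxt <- dplyr::group_by(df, .data$patient_id)
  nxt <- dplyr::mutate(nxt,
    next_state = dplyr::lead(.data$state),
    next_event = dplyr::lead(.data$event))
  nxt <- dplyr::ungroup(nxt)
  # person-cycles at risk: rows with an observed transition out of them
  at_risk <- nxt[!is.na(nxt$next_state), ]

  tfnr <- at_risk[at_risk$state %in% c("tur_free", "no_recurrence"), ]
  rc <- at_risk[at_risk$state == "rc_free", ]
  met <- at_risk[at_risk$state == "metastasis", ]

  n_tur <- sum(tfnr$next_event == "tur")
  n_rc_surv <- sum(tfnr$next_event == "rc")
  n_rc_death <- sum(tfnr$next_event == "rc_death")
  n_worse <- n_rc_surv + n_rc_death

  rows <- list(
    est_row(paste0(arm, "_rec_no_worse"), n_tur, nrow(tfnr))
  )
  if (marker) {
    rows <- c(rows, list(
      est_row(paste0(arm, "_rec_worse"), n_worse, nrow(tfnr)),
      est_row("rc_mortality", n_rc_death, n_worse),
      est_row("age_mortality",
              sum(tfnr$next_event == "death") + sum(rc$next_event == "death"),
              nrow(tfnr) + nrow(rc))
    ))
  } else {
    rows <- c(rows, list(
      est_row(paste0(arm, "_rec_worse"), n_worse, nrow(tfnr),
              status = "not_identifiable"),
      est_row("rc_mortality", NA_integer_, n_worse,
              status = "not_identifiable"),
      est_row(paste0(arm, "_rec_worse_survived"), n_rc_surv, nrow(tfnr)),
      est_row("age_mortality", sum(rc$next_event == "death"), nrow(rc))
    ))
  }
  rows <- c(rows, list(
    est_row("met_after_rc", sum(rc$next_state == "metastasis"), nrow(rc)),
    est_row("met_death", sum(met$next_state == "death"), nrow(met))
  ))
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("bcg_estimates", class(out)),
            arm = toupper(arm), params = attr(panel, "params"),
            surgery_marker = marker)
}

#' Turn panel estimates back into a full parameter set
#'
#' Replaces every identifiable estimated parameter in `base` with its
#' panel estimate (the other arm's recurrence probabilities, and any
#' parameter without an estimate, keep their `base` values), so recovered
#' parameters can be fed straight back into [compare_arms()].
#'
#' @param estimates A `bcg_estimates` tibble.
#' @param base A `bcg_params` to fill unestimated parameters from
#'   (default: the panel's generating parameters).
#' @return A `bcg_params` object.
#' @export
estimates_to_parameters <- function(estimates, base = attr(estimates, "params")) {
  if (is.null(base)) rlang::abort("no base parameter set available")
  p <- unclass(base)
  ok <- estimates[estimates$status == "ok" &
                    estimates$parameter %in% PARAM_NAMES, ]
  for (i in seq_len(nrow(ok))) p[[ok$parameter[i]]] <- ok$estimate[i]
  do.call(bcg_parameters, p)
}
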