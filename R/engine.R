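# Deterministic five-state Markov cohort engine.
#
# States: tumor free after TUR, no recurrence, tumor free after RC,
# metastasis, death (absorbing). Competing events within a cycle are a
# single multinomial draw from the origin row; radical-cystectomy surgical
# mortality is embedded as a split of the worsening probability
# (p_w * m to death, p_w * (1 - m) to the post-RC state).

BCG_STATES <- c("tur_free", "no_recurrence", "rc_free", "metastasis", "death")

#' Health-state labels of the cohort model
#'
#' @return Character vector of the five states, in the column order used by
#'   [build_matrix()] and [run_cohort()]. Death is the absorbing state.
#' @export
bcg_states <- function() BCG_STATES

#' Build the per-cycle transition matrix for one treatment arm
#'
#' With p_r the arm's recurrence-without-worsening probability, p_w its
#' recurrence-with-worsening probability, mu the age-specific mortality,
#' m the RC surgical mortality, q the post-RC metastasis probability and
#' d the metastatic death probability, the rows are:
#' \itemize{
#'   \item tumor free after TUR: stays with p_r (recurrence plus repeat
#'     TUR and BCG), moves to the post-RC state with p_w(1 - m), dies with
#'     mu + p_w m, and moves to no recurrence with the remainder;
#'   \item no recurrence: same exits (recurrence risk persists);
#'   \item tumor free after RC: metastasis with q, death with mu, stays
#'     otherwise (RC is not reversible);
#'   \item metastasis: death with d, stays otherwise (no added age
#'     mortality; the state is not disease-free);
#'   \item death: absorbing.
#' }
#'
#' @param params A `bcg_params` object.
#' @param arm `"FD"` (81 mg) or `"LD"` (27 mg).
#' @return A 5 x 5 row-stochastic matrix of class `bcg_matrix`, rows =
#'   origin, columns = destination, with the arm and generating parameters
#'   attached as attributes.
#' @export
#' @examples
#' M <- build_matrix(default_parameters(), "FD")
#' rowSums(M)
build_matrix <- function(params, arm = c("FD", "LD")) {
  arm <- match.arg(arm)
  validate_params(params)
  pre <- tolower(arm)
  p_r <- params[[paste0(pre, "_rec_no_worse")]]
  p_w <- params[[paste0(pre, "_rec_worse")]]
  mu <- params$age_mortality
  m <- params$rc_mortality
  q <- params$met_after_rc
  d <- params$met_death

  M <- matrix(0, 5, 5, dimnames = list(BCG_STATES, BCG_STATES))
  M["tur_free", ] <- c(p_r, 1 - mu - p_r - p_w, p_w * (1 - m), 0, mu + p_w * m)
  M["no_recurrence", ] <- M["tur_free", ]
  M["rc_free", ] <- c(0, 0, 1 - mu - q, q, mu)
  M["metastasis", ] <- c(0, 0, 0, 1 - d, d)
  M["death", "death"] <- 1

  bad <- which(M < -1e-12 | M > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(paste0("transition matrix entry outside [0, 1] in row '",
                        BCG_STATES[bad[1, 1]], "'"))
  }
  M[M < 0] <- 0
  structure(M, class = c("bcg_matrix", "matrix", "array"),
            arm = arm, params = params)
}

#' Iterate the cohort trace over the model horizon
#'
#' Starts the whole cohort in the tumor-free-after-TUR state and applies
#' the transition matrix once per annual cycle. Alongside state occupancy
#' it tallies, per cycle, the expected fraction of the cohort undergoing a
#' repeat TUR (the recurrence-without-worsening flow out of the two
#' bladder-intact disease-free states, including the stay-in-state flow,
#' which represents recurrence plus repeat resection) and the fraction
#' undergoing RC (the full worsening flow, including patients dying at
#' surgery — operations performed, not survivors).
#'
#' @param matrix A `bcg_matrix` from [build_matrix()].
#' @param cycles Number of annual cycles (default 20).
#' @param age_mortality_vec Optional numeric vector of length `cycles`
#'   giving a per-cycle age-specific mortality; the matrix is rebuilt each
#'   cycle with that value in place of the constant. Requires the matrix
#'   to carry its generating parameters (matrices from [build_matrix()] do).
#' @return A tibble of class `bcg_trace` with one row per cycle
#'   (0 ... `cycles`): columns `cycle`, the five state occupancies,
#'   `tur_events`, `rc_events` (zero at cycle 0). The arm and matrix are
#'   attached as attributes.
#' @export
#' @examples
#' tr <- run_cohort(build_matrix(default_parameters(), "FD"))
#' tr[tr$cycle == 5, "death"]
run_cohort <- function(matrix, cycles = 20, age_mortality_vec = NULL) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(5, 5)))
  if (cycles < 1) rlang::abort("cycles must be >= 1")
  if (max(abs(rowSums(matrix) - 1)) > 1e-12) {
    rlang::abort("matrix rows must sum to 1")
  }
  mats <- if (is.null(age_mortality_vec)) {
    rep(list(matrix), cycles)
  } else {
    params <- attr(matrix, "params")
    if (is.null(params)) {
      rlang::abort("age_mortality_vec needs a matrix built by build_matrix()")
    }
    if (length(age_mortality_vec) != cycles) {
      rlang::abort("age_mortality_vec must have one value per cycle")
    }
    lapply(age_mortality_vec, function(mu) {
      p <- params
      p$age_mortality <- mu
      unclass(build_matrix(p, attr(matrix, "arm")))
    })
  }

  occ <- base::matrix(0, cycles + 1, 5, dimnames = list(NULL, BCG_STATES))
  occ[1, "tur_free"] <- 1
  tur <- rc <- numeric(cycles + 1)
  for (t in seq_len(cycles)) {
    M <- mats[[t]]
    occ[t + 1, ] <- occ[t, ] %*% M
    at_risk <- occ[t, "tur_free"] + occ[t, "no_recurrence"]
    p_r <- M["tur_free", "tur_free"]
    # worsening flow = transition into rc_free plus the surgical-death
    # share; the split needs rc_mortality, carried on matrices built by
    # build_matrix(). Without it only the survivors' flow is observable.
    params <- attr(matrix, "params")
    p_w_total <- if (!is.null(params)) {
      pre <- tolower(attr(matrix, "arm") %||% "FD")
      params[[paste0(pre, "_rec_worse")]]
    } else {
      M["tur_free", "rc_free"]
    }
    tur[t + 1] <- at_risk * p_r
    rc[t + 1] <- at_risk * p_w_total
  }

  out <- tibble::tibble(
    cycle = 0:cycles,
    tur_free = occ[, "tur_free"],
    no_recurrence = occ[, "no_recurrence"],
    rc_free = occ[, "rc_free"],
    metastasis = occ[, "metastasis"],
    death = occ[, "death"],
    tur_events = tur,
    rc_events = rc
  )
  structure(out, class = c("bcg_trace", class(out)),
            arm = attr(matrix, "arm"), matrix = matrix)
}

#' Summarise a cohort trace into survival outcomes and surgery counts
#'
#' Expected life-years use the trapezoidal half-cycle correction
#' \eqn{\sum_t \frac{1}{2}(a_{t-1} + a_t)} on the alive fraction
#' \eqn{a_t = 1 - \mathrm{death}_t}. Cumulative mortality is read off the
#' death occupancy at the requested cycles. Surgery counts are the summed
#' per-cycle event fractions scaled to a cohort of 10,000.
#'
#' @param trace A `bcg_trace` from [run_cohort()].
#' @param timepoints Cycles (years) at which to report cumulative
#'   mortality; must not exceed the trace horizon.
#' @return A `bcg_summary` object (list with `arm`, `expected_life_years`,
#'   `mortality_at`, `tur_count_per_10k`, `rc_count_per_10k`, `horizon`).
#' @export
#' @examples
#' summarize_trace(run_cohort(build_matrix(default_parameters(), "LD")))
summarize_trace <- function(trace, timepoints = c(5, 10, 20)) {
  horizon <- max(trace$cycle)
  if (any(timepoints > horizon) || any(timepoints < 0)) {
    rlang::abort(paste0("timepoints must lie within the horizon (0-",
                        horizon, " years)"))
  }
  alive <- 1 - trace$death
  ly <- sum((alive[-length(alive)] + alive[-1]) / 2)
  mort <- trace$death[match(timepoints, trace$cycle)]
  names(mort) <- paste0(timepoints, "y")
  structure(list(
    arm = attr(trace, "arm"),
    expected_life_years = ly,
    mortality_at = mort,
    tur_count_per_10k = 10000 * sum(trace$tur_events),
    rc_count_per_10k = 10000 * sum(trace$rc_events),
    horizon = horizon
  ), class = "bcg_summary")
}

#' @export
print.bcg_summary <- function(x, ...) {
  cat("<bcg_summary>", x$arm %||% "", "arm,", x$horizon, "year horizon\n")
  cat(sprintf("  expected life-years (half-cycle corrected): %.2f\n",
              x$expected_life_years))
  for (nm in names(x$mortality_at)) {
    cat(sprintf("  cumulative mortality at %-4s %6.2f%%\n", nm,
                100 * x$mortality_at[[nm]]))
  }
  cat(sprintf("  repeat TUR per 10,000 patients: %.0f\n", x$tur_count_per_10k))
  cat(sprintf("  RC per 10,000 patients:         %.0f\n", x$rc_count_per_10k))
  invisible(x)
}

#' @method tidy bcg_summary
#' @export
tidy.bcg_summary <- function(x, ...) {
  tibble::tibble(
    arm = x$arm %||% NA_character_,
    expected_life_years = x$expected_life_years,
    timepoint = as.numeric(sub("y$", "", names(x$mortality_at))),
    mortality = unname(x$mortality_at),
    tur_count_per_10k = x$tur_count_per_10k,
    rc_count_per_10k = x$rc_count_per_10k
  )
}

#' Run both treatment arms and compare expected survival
#'
#' Runs the deterministic cohort model for the full-dose and low-dose arms
#' with identical engine settings and reports the low-dose minus full-dose
#' difference in expected (half-cycle-corrected) life-years.
#'
#' @inheritParams run_cohort
#' @inheritParams summarize_trace
#' @param params A `bcg_params` object.
#' @return A `bcg_comparison` object: list with `fd` and `ld`
#'   `bcg_summary` objects, the two traces, and `os_difference`
#'   (LD minus FD expected life-years).
#' @export
#' @examples
#' cmp <- compare_arms(default_parameters())
#' glance(cmp)
compare_arms <- function(params, cycles = 20, timepoints = c(5, 10, 20)) {
  tr_fd <- run_cohort(build_matrix(params, "FD"), cycles)
  tr_ld <- run_cohort(build_matrix(params, "LD"), cycles)
  fd <- summarize_trace(tr_fd, timepoints)
  ld <- summarize_trace(tr_ld, timepoints)
  structure(list(
    fd = fd, ld = ld,
    trace_fd = tr_fd, trace_ld = tr_ld,
    os_difference = ld$expected_life_years - fd$expected_life_years
  ), class = "bcg_comparison")
}

#' @export
print.bcg_comparison <- function(x, ...) {
  cat("<bcg_comparison> full-dose vs low-dose BCG\n")
  cat(sprintf("  FD expected OS: %.2f y   LD expected OS: %.2f y\n",
              x$fd$expected_life_years, x$ld$expected_life_years))
  cat(sprintf("  LD - FD difference: %+.3f y  (%s preferred)\n",
              x$os_difference,
              if (x$os_difference > 0) "LD" else if (x$os_difference < 0)
                "FD" else "neither"))
  invisible(x)
}

#' @method tidy bcg_comparison
#' @export
tidy.bcg_comparison <- function(x, ...) {
  dplyr::bind_rows(generics::tidy(x$fd), generics::tidy(x$ld))
}

#' @method glance bcg_comparison
#' @export
glance.bcg_comparison <- function(x, ...) {
  tibble::tibble(
    fd_os = x$fd$expected_life_years,
    ld_os = x$ld$expected_life_years,
    os_difference = x$os_difference,
    preferred_arm = if (x$os_difference > 0) "LD"
      else if (x$os_difference < 0) "FD" else "tie"
  )
}

#' Stacked state-occupancy plot of a cohort trace
#'
#' @param object A `bcg_trace`.
#' @param ... Unused.
#' @return A ggplot object: stacked occupancy areas over the horizon.
#' @method autoplot bcg_trace
#' @export
autoplot.bcg_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("cycle", BCG_STATES)],
    -"cycle", names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = rev(BCG_STATES))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Year", y = "Fraction of cohort",
                  title = paste(attr(object, "arm") %||% "", "arm"),
                  fill = "State") +
    ggplot2::theme_minimal()
}

#' Overlaid survival curves of the two arms
#'
#' @param object A `bcg_comparison` from [compare_arms()].
#' @param ... Unused.
#' @return A ggplot object with one survival curve per arm.
#' @method autoplot bcg_comparison
#' @export
autoplot.bcg_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(cycle = object$trace_fd$cycle,
                   surviving = 1 - object$trace_fd$death, arm = "FD"),
    tibble::tibble(cycle = object$trace_ld$cycle,
                   surviving = 1 - object$trace_ld$death, arm = "LD"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle, .data$surviving,
                                   colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Surviving fraction", colour = "Arm") +
    ggplot2::theme_minimal()
}

#' Export a cohort trace to CSV
#'
#' One row per cycle with the five state occupancies and the per-cycle
#' repeat-TUR and RC event fractions.
#'
#' @param trace A `bcg_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(tibble::as_tibble(trace), path, row.names = FALSE)
  invisible(path)
}
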