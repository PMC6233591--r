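# Patient-level Monte Carlo simulation of the cohort model.
#
# Each patient draws one uniform per cycle from a pre-allocated matrix, so
# running both arms with the same seed uses common random numbers: the
# between-arm difference is then estimated with far less noise than two
# independent runs, which is the standard variance-reduction practice for
# head-to-head microsimulation comparisons.

# Internal core: simulate n patients through `cycles` annual transitions.
# Returns integer state matrix (n x cycles+1, states 1..5) and an event
# matrix (n x cycles) coded 0 = none, 1 = repeat TUR, 2 = RC (survived),
# 3 = death at RC surgery, 4 = other death. Requires a matrix built by
# build_matrix() so the surgical-death share of the worsening flow is
# known.
sim_core <- function(matrix, n, cycles, U) {
  params <- attr(matrix, "params")
  if (is.null(params)) {
    rlang::abort("patient-level simulation needs a matrix from build_matrix()")
  }
  pre <- tolower(attr(matrix, "arm"))
  p_r <- params[[paste0(pre, "_rec_no_worse")]]
  p_w <- params[[paste0(pre, "_rec_worse")]]
  mu <- params$age_mortality
  m <- params$rc_mortality
  q <- params$met_after_rc
  d <- params$met_death

  # cumulative outcome thresholds, fixed order for common-random-number
  # alignment across arms
  tf_cut <- cumsum(c(p_r, 1 - mu - p_r - p_w, p_w * (1 - m), p_w * m))
  tf_state <- c(1L, 2L, 3L, 5L, 5L)
  tf_event <- c(1L, 0L, 2L, 3L, 4L)
  rc_cut <- cumsum(c(1 - mu - q, q))
  me_cut <- 1 - d

  S <- base::matrix(1L, n, cycles + 1)
  E <- base::matrix(0L, n, cycles)
  st <- rep(1L, n)
  for (t in seq_len(cycles)) {
    u <- U[, t]
    i12 <- which(st <= 2L)
    if (length(i12) > 0) {
      out <- 1L + (u[i12] > tf_cut[1]) + (u[i12] > tf_cut[2]) +
        (u[i12] > tf_cut[3]) + (u[i12] > tf_cut[4])
      st[i12] <- tf_state[out]
      E[cbind(i12, t)] <- tf_event[out]
    }
    i3 <- which(st == 3L & S[, t] == 3L)
    if (length(i3) > 0) {
      out <- 1L + (u[i3] > rc_cut[1]) + (u[i3] > rc_cut[2])
      st[i3] <- c(3L, 4L, 5L)[out]
      E[cbind(i3, t)] <- c(0L, 0L, 4L)[out]
    }
    i4 <- which(st == 4L & S[, t] == 4L)
    if (length(i4) > 0) {
      died <- u[i4] > me_cut
      st[i4[died]] <- 5L
      E[cbind(i4[died], t)] <- 4L
    }
    S[, t + 1] <- st
  }
  list(states = S, events = E)
}

# Half-cycle-adjusted life-years per patient from a state matrix: a death
# during cycle t contributes t - 1/2 years, a horizon survivor the full
# horizon.
life_years_from_states <- function(S) {
  cycles <- ncol(S) - 1
  dead <- S == 5L
  first_dead <- apply(dead, 1, function(z) if (any(z)) which(z)[1] - 1 else NA)
  ifelse(is.na(first_dead), cycles, first_dead - 0.5)
}

# Median of half-cycle-valued survival times with linear interpolation
# inside the death cycle (deaths in cycle t are spread over (t-1, t)).
interpolated_median <- function(ly, horizon) {
  n <- length(ly)
  tab <- table(ly)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  cum <- cumsum(cnt)
  i <- which(cum >= n / 2)[1]
  v <- vals[i]
  if (v >= horizon) return(horizon)
  below <- if (i > 1) cum[i - 1] else 0
  (v - 0.5) + (n / 2 - below) / cnt[i]
}

#' Monte Carlo microsimulation of individual patients
#'
#' Simulates `n_patients` independent patients through the model: each
#' starts tumor free after TUR and draws annual transitions from the
#' matrix rows until death or the horizon. A patient dying during cycle t
#' contributes t - 1/2 life-years (half-cycle convention, consistent with
#' the deterministic engine's trapezoidal correction); a horizon survivor
#' contributes the full horizon. Repeat-TUR and RC operations are tallied
#' per transition taken (RC includes patients dying at surgery).
#'
#' Calling this with the same `seed` for both arms uses common random
#' numbers, which sharpens the estimate of the between-arm difference.
#'
#' @param matrix A `bcg_matrix` from [build_matrix()].
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer RNG seed; recorded in the result.
#' @param cycles Horizon in annual cycles.
#' @return A `bcg_microsim` object: list with `arm`, `n_patients`, `seed`,
#'   `cycles`, `life_years` (per patient), `mean_os`, `median_os`
#'   (linearly interpolated), `ci95_mean` (normal approximation),
#'   `tur_total`, `rc_total`.
#' @export
#' @examples
#' ms <- simulate_patients(build_matrix(default_parameters(), "FD"),
#'                         n_patients = 2000, seed = 1)
#' glance(ms)
simulate_patients <- function(matrix, n_patients, seed = 1L, cycles = 20) {
  if (n_patients < 1) rlang::abort("n_patients must be >= 1")
  U <- withr::with_seed(seed, base::matrix(stats::runif(n_patients * cycles),
                                           n_patients, cycles))
  sim <- sim_core(matrix, n_patients, cycles, U)
  ly <- life_years_from_states(sim$states)
  mean_os <- mean(ly)
  se <- stats::sd(ly) / sqrt(n_patients)
  structure(list(
    arm = attr(matrix, "arm"),
    n_patients = n_patients,
    seed = seed,
    cycles = cycles,
    life_years = ly,
    mean_os = mean_os,
    median_os = interpolated_median(ly, cycles),
    ci95_mean = c(mean_os - 1.96 * se, mean_os + 1.96 * se),
    tur_total = sum(sim$events == 1L),
    rc_total = sum(sim$events == 2L | sim$events == 3L)
  ), class = "bcg_microsim")
}

#' @export
print.bcg_microsim <- function(x, ...) {
  cat("<bcg_microsim>", x$arm, "arm,", x$n_patients, "patients, seed",
      x$seed, "\n")
  cat(sprintf("  mean OS %.3f y (95%% CI %.3f-%.3f), median %.3f y\n",
              x$mean_os, x$ci95_mean[1], x$ci95_mean[2], x$median_os))
  cat(sprintf("  repeat TUR: %d   RC: %d\n", x$tur_total, x$rc_total))
  invisible(x)
}

#' Per-patient survival durations as a tibble
#'
#' @param x A `bcg_microsim` object.
#' @param ... Unused.
#' @return A tibble with columns `patient_id`, `life_years`.
#' @method tidy bcg_microsim
#' @export
tidy.bcg_microsim <- function(x, ...) {
  tibble::tibble(patient_id = seq_len(x$n_patients), life_years = x$life_years)
}

#' One-row microsimulation summary
#'
#' @param x A `bcg_microsim` object.
#' @param ... Unused.
#' @return A one-row tibble with the arm, sample size, seed, mean and
#'   median survival, CI bounds and operation totals.
#' @method glance bcg_microsim
#' @export
glance.bcg_microsim <- function(x, ...) {
  tibble::tibble(
    arm = x$arm, n_patients = x$n_patients, seed = x$seed,
    mean_os = x$mean_os, median_os = x$median_os,
    ci_low = x$ci95_mean[1], ci_high = x$ci95_mean[2],
    tur_total = x$tur_total, rc_total = x$rc_total
  )
}

#' Histogram of simulated survival durations
#'
#' @param object A `bcg_microsim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcg_microsim
#' @export
autoplot.bcg_microsim <- function(object, ...) {
  ggplot2::ggplot(generics::tidy(object),
                  ggplot2::aes(.data$life_years)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_os, linetype = "dashed") +
    ggplot2::labs(x = "Survival (years)", y = "Patients",
                  title = paste(object$arm, "arm, mean",
                                sprintf("%.2f", object$mean_os), "years")) +
    ggplot2::theme_minimal()
}

#' Probabilistic sensitivity analysis over the parameter ranges
#'
#' A second-order (parameter-uncertainty) analysis: each draw samples
#' every parameter with a non-degenerate sensitivity range independently
#' and uniformly over that range, runs the model for both arms, and
#' records the arm outcomes and the preferred arm. By default each draw is
#' evaluated with the deterministic cohort model; give
#' `n_patients_per_draw` to evaluate draws by microsimulation instead.
#'
#' @inheritParams one_way
#' @param n_draws Number of parameter draws (>= 1).
#' @param seed Integer RNG seed.
#' @param n_patients_per_draw Optional microsimulation size per draw.
#' @return A tibble of class `bcg_psa`: one row per draw with the sampled
#'   parameter values, `fd_os`, `ld_os` and `preferred`; the fraction of
#'   draws preferring the low-dose arm is attached as attribute
#'   `ld_preferred_frac`.
#' @export
#' @examples
#' ps <- psa(default_parameters(), n_draws = 50, seed = 7)
#' attr(ps, "ld_preferred_frac")
psa <- function(params, ranges = default_ranges(), n_draws, seed = 1L,
                cycles = 20, n_patients_per_draw = NULL) {
  if (n_draws < 1) rlang::abort("n_draws must be >= 1")
  rng <- tibble::as_tibble(ranges)
  varied <- rng$parameter[rng$low < rng$high]
  sampled <- withr::with_seed(seed, {
    cols <- lapply(rng$parameter, function(nm) {
      i <- match(nm, rng$parameter)
      if (nm %in% varied) stats::runif(n_draws, rng$low[i], rng$high[i])
      else rep(rng$base[i], n_draws)
    })
    names(cols) <- rng$parameter
    list(draws = tibble::as_tibble(cols),
         seeds = sample.int(2^31 - 1, n_draws))
  })
  draws <- sampled$draws
  # parameters absent from the ranges table stay at their base value
  fixed <- setdiff(PARAM_NAMES, rng$parameter)
  for (nm in fixed) draws[[nm]] <- params[[nm]]

  os <- purrr::map(seq_len(n_draws), function(k) {
    p <- do.call(bcg_parameters, as.list(draws[k, PARAM_NAMES]))
    if (is.null(n_patients_per_draw)) {
      glance.bcg_comparison(compare_arms(p, cycles))
    } else {
      # common random numbers across arms within a draw
      s <- sampled$seeds[k]
      fd <- simulate_patients(build_matrix(p, "FD"), n_patients_per_draw,
                              seed = s, cycles = cycles)
      ld <- simulate_patients(build_matrix(p, "LD"), n_patients_per_draw,
                              seed = s, cycles = cycles)
      tibble::tibble(fd_os = fd$mean_os, ld_os = ld$mean_os)
    }
  })
  out <- draws
  out$draw <- seq_len(n_draws)
  out$fd_os <- purrr::map_dbl(os, "fd_os")
  out$ld_os <- purrr::map_dbl(os, "ld_os")
  d <- out$ld_os - out$fd_os
  out$preferred <- ifelse(d > 0, "LD", ifelse(d < 0, "FD", "tie"))
  out <- out[, c("draw", rng$parameter, "fd_os", "ld_os", "preferred")]
  structure(out, class = c("bcg_psa", class(out)),
            seed = seed,
            ld_preferred_frac = mean(out$preferred == "LD"))
}
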