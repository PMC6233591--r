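# One-way sweeps with crossover root-finding, tornado diagrams, and
# two-way dominance grids over the published sensitivity ranges.

set_param <- function(params, name, value) {
  p <- unclass(params)
  p[[name]] <- value
  do.call(bcg_parameters, p)
}

range_row <- function(ranges, parameter) {
  i <- match(parameter, ranges$parameter)
  if (is.na(i)) {
    rlang::abort(paste0("unknown parameter '", parameter, "'"))
  }
  ranges[i, ]
}

# Plain bisection on a continuous sign-changing function; the expected
# life-year difference is smooth in any single parameter, so this is
# robust without derivative information.
bisect <- function(f, lo, hi, tol = 1e-5) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) rlang::abort("root not bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' One-way sensitivity analysis with crossover localisation
#'
#' Sweeps a single parameter across its sensitivity range (all other
#' parameters at base case), recording each arm's expected life-years from
#' the deterministic cohort model at every grid point. If the LD-minus-FD
#' difference changes sign between adjacent grid points, the crossover —
#' the parameter value at which the two arms' expected survival is equal —
#' is located by bisection to a tolerance of 1e-5 in the parameter value.
#'
#' @param params Base-case `bcg_params`.
#' @param ranges A `bcg_ranges` tibble (default [default_ranges()]).
#' @param parameter Name of the parameter to sweep.
#' @param n_points Number of evenly spaced grid points (>= 2).
#' @param cycles Model horizon in annual cycles.
#' @return A tibble of class `bcg_oneway` with columns `value`, `fd_os`,
#'   `ld_os`; the swept parameter name and the crossover value (`NA` if
#'   none) are attached as attributes `parameter` and `crossover`.
#' @export
#' @examples
#' ow <- one_way(default_parameters(), parameter = "fd_rec_worse")
#' attr(ow, "crossover")
one_way <- function(params, ranges = default_ranges(), parameter,
                    n_points = 21, cycles = 20) {
  if (n_points < 2) rlang::abort("n_points must be >= 2")
  rr <- range_row(ranges, parameter)
  grid <- seq(rr$low, rr$high, length.out = n_points)
  os <- purrr::map(grid, function(v) {
    glance.bcg_comparison(compare_arms(set_param(params, parameter, v), cycles))
  })
  out <- tibble::tibble(
    value = grid,
    fd_os = purrr::map_dbl(os, "fd_os"),
    ld_os = purrr::map_dbl(os, "ld_os")
  )
  diff <- out$ld_os - out$fd_os
  crossover <- NA_real_
  # a crossover needs the preference to actually switch inside the range;
  # an identically-zero difference (tied arms) is not a crossover
  if (any(diff > 0) && any(diff < 0)) {
    flip <- which(diff[-1] * diff[-n_points] < 0)
    exact <- which(diff == 0)
    if (length(flip) > 0) {
      i <- flip[1]
      f <- function(v) {
        compare_arms(set_param(params, parameter, v), cycles)$os_difference
      }
      crossover <- bisect(f, grid[i], grid[i + 1], tol = 1e-5)
    } else if (length(exact) > 0) {
      crossover <- grid[exact[1]]
    }
  }
  structure(out, class = c("bcg_oneway", class(out)),
            parameter = parameter, crossover = crossover)
}

#' @export
print.bcg_oneway <- function(x, ...) {
  cat("<bcg_oneway>", attr(x, "parameter"), "\n")
  co <- attr(x, "crossover")
  if (is.na(co)) cat("  no crossover in range\n")
  else cat(sprintf("  crossover at %.5f (%.2f%%)\n", co, 100 * co))
  NextMethod()
}

#' @method autoplot bcg_oneway
#' @export
autoplot.bcg_oneway <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"value",
                              names_to = "arm", values_to = "os")
  long$arm <- toupper(sub("_os$", "", long$arm))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$os,
                                          colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "Expected life-years", colour = "Arm") +
    ggplot2::theme_minimal()
  co <- attr(object, "crossover")
  if (!is.na(co)) {
    p <- p + ggplot2::geom_vline(xintercept = co, linetype = "dashed")
  }
  p
}

#' Tornado diagram of one-way parameter influence
#'
#' For every parameter, evaluates the chosen arm's expected life-years at
#' the low and high endpoints of its sensitivity range (all other
#' parameters at base) and ranks parameters by the absolute swing. The
#' bars measure each arm's own expected survival; set `difference = TRUE`
#' to rank by the swing in the LD-minus-FD difference instead.
#'
#' Parameters whose range is degenerate (such as the age-specific
#' mortality, which has no published range) are given a symmetric relative
#' band of `rangeless_band` around the base value — an explicit analysis
#' convention, not a published range — so that their influence can still
#' be ranked; set `rangeless_band = 0` to leave them fixed.
#'
#' @inheritParams one_way
#' @param arm `"FD"` or `"LD"`.
#' @param rangeless_band Relative half-width applied to range-less
#'   parameters (default 0.2, i.e. plus or minus 20 percent).
#' @param difference Rank by the swing in the LD - FD difference?
#' @return A tibble of class `bcg_tornado`, sorted by descending `width`,
#'   with columns `parameter`, `low`, `high`, `os_at_low`, `os_at_high`,
#'   `width`; the base-case outcome is attached as attribute `base_os`.
#' @export
#' @examples
#' tornado(default_parameters(), arm = "LD")
tornado <- function(params, ranges = default_ranges(), arm = c("FD", "LD"),
                    rangeless_band = 0.2, difference = FALSE, cycles = 20) {
  arm <- match.arg(arm)
  outcome <- function(p) {
    cmp <- compare_arms(p, cycles)
    if (difference) cmp$os_difference
    else if (arm == "FD") cmp$fd$expected_life_years
    else cmp$ld$expected_life_years
  }
  rng <- tibble::as_tibble(ranges)
  degenerate <- rng$low == rng$high
  rng$low[degenerate] <- pmax(0, rng$base[degenerate] * (1 - rangeless_band))
  rng$high[degenerate] <- pmin(1, rng$base[degenerate] * (1 + rangeless_band))
  if (all(rng$low == rng$high)) {
    rlang::abort("all ranges are degenerate; nothing to vary")
  }
  rows <- purrr::pmap(rng, function(parameter, base, low, high) {
    tibble::tibble(
      parameter = parameter, low = low, high = high,
      os_at_low = outcome(set_param(params, parameter, low)),
      os_at_high = outcome(set_param(params, parameter, high))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$width <- abs(out$os_at_high - out$os_at_low)
  out <- dplyr::arrange(out, dplyr::desc(.data$width))
  structure(out, class = c("bcg_tornado", class(out)),
            arm = arm, difference = difference, base_os = outcome(params))
}

#' @method autoplot bcg_tornado
#' @export
autoplot.bcg_tornado <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(object, "base_os")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$os_at_low,
                                       xend = .data$os_at_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = if (attr(object, "difference"))
      "LD - FD expected life-years" else
        paste(attr(object, "arm"), "expected life-years"),
      y = NULL) +
    ggplot2::theme_minimal()
}

#' Two-way sensitivity analysis (dominance grid)
#'
#' Evaluates the preferred arm over a full-factorial grid of two
#' parameters (all others at base case). A grid cell is labelled by the
#' arm with the higher expected life-years; exact equality is labelled
#' `"tie"`.
#'
#' @inheritParams one_way
#' @param param_a,param_b Names of the two parameters (must differ).
#' @param n_a,n_b Grid sizes (>= 2).
#' @return A tibble of class `bcg_twoway` with columns `value_a`,
#'   `value_b`, `fd_os`, `ld_os`, `preferred`; parameter names attached as
#'   attribute `parameters`.
#' @export
#' @examples
#' tw <- two_way(default_parameters(), param_a = "fd_rec_worse",
#'               param_b = "ld_rec_worse", n_a = 5, n_b = 5)
#' table(tw$preferred)
two_way <- function(params, ranges = default_ranges(), param_a, param_b,
                    n_a = 11, n_b = 11, cycles = 20) {
  if (identical(param_a, param_b)) {
    rlang::abort("param_a and param_b must be different parameters")
  }
  if (n_a < 2 || n_b < 2) rlang::abort("grids need at least 2 points")
  ra <- range_row(ranges, param_a)
  rb <- range_row(ranges, param_b)
  grid <- tidyr::expand_grid(
    value_a = seq(ra$low, ra$high, length.out = n_a),
    value_b = seq(rb$low, rb$high, length.out = n_b)
  )
  os <- purrr::map2(grid$value_a, grid$value_b, function(a, b) {
    p <- set_param(set_param(params, param_a, a), param_b, b)
    glance.bcg_comparison(compare_arms(p, cycles))
  })
  out <- grid
  out$fd_os <- purrr::map_dbl(os, "fd_os")
  out$ld_os <- purrr::map_dbl(os, "ld_os")
  d <- out$ld_os - out$fd_os
  out$preferred <- ifelse(d > 0, "LD", ifelse(d < 0, "FD", "tie"))
  structure(out, class = c("bcg_twoway", class(out)),
            parameters = c(param_a, param_b))
}

#' @method autoplot bcg_twoway
#' @export
autoplot.bcg_twoway <- function(object, ...) {
  pars <- attr(object, "parameters")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$value_a, .data$value_b,
                               fill = .data$preferred)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = pars[1], y = pars[2], fill = "Preferred arm") +
    ggplot2::theme_minimal()
}
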