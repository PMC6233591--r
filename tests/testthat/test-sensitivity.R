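test_that("one-way sweep finds the worsening-probability crossovers", {
  p <- default_parameters()
  ow_fd <- one_way(p, parameter = "fd_rec_worse")
  co_fd <- attr(ow_fd, "crossover")
  expect_false(is.na(co_fd))
  # the difference changes sign across the crossover
  d <- ow_fd$ld_os - ow_fd$fd_os
  expect_true(any(d > 0) && any(d < 0))
  below <- max(d[ow_fd$value < co_fd])
  above <- min(d[ow_fd$value > co_fd])
  expect_true(sign(below) != sign(above))

  ow_ld <- one_way(p, parameter = "ld_rec_worse")
  co_ld <- attr(ow_ld, "crossover")
  expect_false(is.na(co_ld))
  # structural identity: survival depends on the worsening probability
  # only, so each crossover sits at the other arm's base worsening value
  expect_lt(abs(co_fd - p$ld_rec_worse), 1e-5)
  expect_lt(abs(co_ld - p$fd_rec_worse), 1e-5)
})

test_that("crossover is stable under grid refinement", {
  p <- default_parameters()
  co <- vapply(c(5, 21, 101), function(n) {
    attr(one_way(p, parameter = "fd_rec_worse", n_points = n), "crossover")
  }, numeric(1))
  expect_lt(max(co) - min(co), 2e-5)
})

test_that("a range excluding the crossover reports none", {
  rng <- default_ranges()
  i <- match("fd_rec_worse", rng$parameter)
  rng$low[i] <- 0.030
  rng$base[i] <- 0.037
  ow <- one_way(default_parameters(), rng, "fd_rec_worse")
  expect_true(is.na(attr(ow, "crossover")))
  expect_true(all(ow$ld_os > ow$fd_os))
})

test_that("symmetric arms stay tied across any shared-parameter sweep", {
  p <- bcg_parameters(fd_rec_no_worse = 0.047, fd_rec_worse = 0.027)
  ow <- one_way(p, parameter = "rc_mortality")
  expect_equal(ow$fd_os, ow$ld_os, tolerance = 1e-14)
  expect_true(is.na(attr(ow, "crossover")))
})

test_that("tornado ranks parameters by outcome swing with the documented
           band on range-less parameters", {
  p <- default_parameters()
  for (arm in c("FD", "LD")) {
    tn <- tornado(p, arm = arm)
    expect_true(all(diff(tn$width) <= 1e-15))
    expect_equal(tn$width, abs(tn$os_at_high - tn$os_at_low))
    # the two dominant parameters feed the death state directly
    expect_setequal(tn$parameter[1:2], c("age_mortality", "met_after_rc"))
    expect_equal(tn$parameter[3], paste0(tolower(arm), "_rec_worse"))
    # the other arm's parameters cannot move this arm's outcome
    other <- setdiff(c("fd", "ld"), tolower(arm))
    expect_lt(max(tn$width[tn$parameter %in%
                             paste0(other, c("_rec_worse", "_rec_no_worse"))]),
              1e-12)
  }
})

test_that("degenerate ranges give zero-width bars ranked last", {
  rng <- default_ranges()
  tn <- tornado(default_parameters(), rng, "FD", rangeless_band = 0)
  expect_equal(tn$width[tn$parameter == "age_mortality"], 0)
  expect_equal(tn$width[tn$parameter == "age_mortality"], min(tn$width))
})

test_that("widening a range never shrinks its tornado bar", {
  p <- default_parameters()
  rng <- default_ranges()
  tn0 <- tornado(p, rng, "LD")
  i <- match("met_after_rc", rng$parameter)
  rng$low[i] <- rng$low[i] - 0.002
  rng$high[i] <- rng$high[i] + 0.002
  tn1 <- tornado(p, rng, "LD")
  w0 <- tn0$width[tn0$parameter == "met_after_rc"]
  w1 <- tn1$width[tn1$parameter == "met_after_rc"]
  expect_gte(w1, w0)
})

test_that("tornado widths do not depend on evaluation order", {
  rng <- default_ranges()
  shuffled <- rng[rev(seq_len(nrow(rng))), ]
  tn_a <- tornado(default_parameters(), rng, "FD")
  tn_b <- tornado(default_parameters(), shuffled, "FD")
  expect_equal(tn_a$width[order(tn_a$parameter)],
               tn_b$width[order(tn_b$parameter)], tolerance = 1e-14)
})

test_that("two-way grid shows the expected dominance structure", {
  p <- default_parameters()
  tw <- two_way(p, param_a = "fd_rec_worse", param_b = "ld_rec_worse",
                n_a = 9, n_b = 9)
  expect_equal(nrow(tw), 81)
  # small FD worsening with large LD worsening favours the full dose
  expect_equal(tw$preferred[tw$value_a == min(tw$value_a) &
                              tw$value_b == max(tw$value_b)], "FD")
  expect_equal(tw$preferred[tw$value_a == max(tw$value_a) &
                              tw$value_b == min(tw$value_b)], "LD")
  # preference flips monotonically with the FD worsening probability
  expect_true(all(tw$preferred %in% c("FD", "LD", "tie")))
  expect_error(two_way(p, param_a = "fd_rec_worse",
                       param_b = "fd_rec_worse"), "different")
})

test_that("a grid point at the exact base case matches compare_arms", {
  p <- default_parameters()
  rng <- default_ranges()
  # shrink both ranges so the base case is an interior grid point
  for (nm in c("fd_rec_worse", "ld_rec_worse")) {
    i <- match(nm, rng$parameter)
    mid <- rng$base[i]
    rng$low[i] <- mid - 0.005
    rng$high[i] <- mid + 0.005
  }
  tw <- two_way(p, rng, "fd_rec_worse", "ld_rec_worse", n_a = 3, n_b = 3)
  at_base <- tw[abs(tw$value_a - p$fd_rec_worse) < 1e-12 &
                  abs(tw$value_b - p$ld_rec_worse) < 1e-12, ]
  expect_equal(nrow(at_base), 1)
  expect_equal(at_base$preferred, glance(compare_arms(p))$preferred_arm)
})

test_that("symmetric arms yield tie labels on the equal-worsening diagonal", {
  p <- bcg_parameters(fd_rec_no_worse = 0.047)  # equal rec_no_worse
  rng <- default_ranges()
  shared <- c(0.025, 0.035, 0.045)
  i <- match(c("fd_rec_worse", "ld_rec_worse"), rng$parameter)
  rng$low[i] <- min(shared); rng$high[i] <- max(shared)
  rng$base[i] <- 0.035
  p <- bcg_parameters(fd_rec_no_worse = 0.047, fd_rec_worse = 0.035,
                      ld_rec_worse = 0.035)
  tw <- two_way(p, rng, "fd_rec_worse", "ld_rec_worse", n_a = 3, n_b = 3)
  diag_rows <- tw[abs(tw$value_a - tw$value_b) < 1e-12, ]
  expect_equal(diag_rows$preferred, rep("tie", 3))
})
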