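test_that("transition matrix encodes the model structure", {
  p <- default_parameters()
  M <- build_matrix(p, "FD")
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  # hand arithmetic: death from the post-TUR states is mu + p_w * m
  expect_equal(M["tur_free", "death"], 0.0791 + 0.037 * 0.019,
               tolerance = 1e-12)
  expect_equal(M["tur_free", "rc_free"], 0.037 * (1 - 0.019),
               tolerance = 1e-12)
  # death absorbing, structural zeros
  expect_equal(unname(M["death", ]), c(0, 0, 0, 0, 1))
  expect_equal(M["tur_free", "metastasis"], 0)
  expect_equal(M["no_recurrence", "metastasis"], 0)
  expect_equal(unname(M["metastasis", 1:3]), c(0, 0, 0))
  expect_equal(unname(M["rc_free", 1:2]), c(0, 0))
  # recurrence risk persists in the no-recurrence state
  expect_equal(M["no_recurrence", ], M["tur_free", ])

  ld <- build_matrix(p, "LD")
  expect_equal(ld["tur_free", "tur_free"], 0.047)
  expect_equal(unname(rowSums(ld)), rep(1, 5), tolerance = 1e-12)
})

test_that("degenerate parameters give pure age-mortality attrition", {
  p <- bcg_parameters(ld_rec_no_worse = 0, ld_rec_worse = 0,
                      fd_rec_no_worse = 0, fd_rec_worse = 0,
                      met_after_rc = 0, met_death = 0)
  M <- build_matrix(p, "FD")
  mu <- p$age_mortality
  expect_equal(M["tur_free", "death"], mu)
  expect_equal(M["tur_free", "no_recurrence"], 1 - mu)
  expect_equal(M["rc_free", "rc_free"], 1 - mu)
})

test_that("matrix construction rejects structurally impossible rows", {
  # valid parameter set whose post-TUR row would still be fine, so force
  # the failure through the metastasis row instead via validate bypass:
  # an exit mass > 1 is already rejected at the parameter level
  expect_error(build_matrix(bcg_parameters(age_mortality = 0.9,
                                           met_after_rc = 0.2)),
               "met_after_rc")
})

test_that("cohort trace conserves mass, starts at TUR-free, death monotone", {
  withr::with_seed(421, {
    for (i in 1:20) {
      p <- random_valid_params()
      arm <- sample(c("FD", "LD"), 1)
      tr <- run_cohort(build_matrix(p, arm))
      occ <- as.matrix(tr[, bcg_states()])
      expect_lt(max(abs(rowSums(occ) - 1)), 1e-10)
      expect_true(all(diff(tr$death) >= -1e-15))
      expect_equal(unname(occ[1, ]), c(1, 0, 0, 0, 0))
      expect_true(all(occ >= -1e-15))
    }
  })
})

test_that("cohort trace equals the brute-force path-enumeration oracle", {
  withr::with_seed(99, {
    for (i in 1:5) {
      p <- random_valid_params()
      M <- build_matrix(p, "LD")
      tr <- run_cohort(M, cycles = 6)
      for (t in 1:6) {
        oracle <- enumerate_distribution(unclass(M), t)
        expect_equal(unlist(tr[tr$cycle == t, bcg_states()],
                            use.names = FALSE),
                     oracle, tolerance = 1e-12)
      }
    }
  })
})

test_that("no-death matrix keeps the whole cohort alive", {
  p <- bcg_parameters(age_mortality = 0, rc_mortality = 0, met_death = 0)
  tr <- run_cohort(build_matrix(p, "FD"))
  expect_equal(tr$death, rep(0, 21))
  expect_equal(summarize_trace(tr)$expected_life_years, 20)
})

test_that("life expectancy matches the closed geometric form under pure
           age mortality", {
  mu <- 0.0791
  p <- bcg_parameters(age_mortality = mu, ld_rec_no_worse = 0,
                      ld_rec_worse = 0, fd_rec_no_worse = 0,
                      fd_rec_worse = 0, met_after_rc = 0)
  tr <- run_cohort(build_matrix(p, "FD"), cycles = 20)
  closed <- sum(((1 - mu)^(0:19) + (1 - mu)^(1:20)) / 2)
  expect_equal(summarize_trace(tr)$expected_life_years, closed,
               tolerance = 1e-10)
})

test_that("summary honours the half-cycle correction and event accounting", {
  p <- default_parameters()
  tr <- run_cohort(build_matrix(p, "FD"))
  s <- summarize_trace(tr)
  alive <- 1 - tr$death
  expect_equal(s$expected_life_years,
               sum((alive[-21] + alive[-1]) / 2), tolerance = 1e-12)
  expect_equal(unname(s$mortality_at),
               tr$death[match(c(5, 10, 20), tr$cycle)])
  expect_true(all(diff(s$mortality_at) > 0))
  expect_equal(s$tur_count_per_10k, 10000 * sum(tr$tur_events))
  # first-cycle events come from the full cohort at risk
  expect_equal(tr$tur_events[2], p$fd_rec_no_worse, tolerance = 1e-12)
  expect_equal(tr$rc_events[2], p$fd_rec_worse, tolerance = 1e-12)
  expect_error(summarize_trace(tr, timepoints = 25), "horizon")
})

test_that("per-cycle mortality hook reduces to the constant default", {
  p <- default_parameters()
  M <- build_matrix(p, "LD")
  tr_const <- run_cohort(M)
  tr_vec <- run_cohort(M, age_mortality_vec = rep(p$age_mortality, 20))
  expect_equal(tibble::as_tibble(tr_vec), tibble::as_tibble(tr_const),
               tolerance = 1e-14)
  # a rising mortality schedule kills faster than its starting constant
  tr_rise <- run_cohort(M, age_mortality_vec = seq(0.0791, 0.3, length.out = 20))
  expect_gt(tr_rise$death[21], tr_const$death[21])
  expect_error(run_cohort(M, age_mortality_vec = c(0.1, 0.2)), "per cycle")
})

test_that("equal-arm parameters give exactly zero survival difference", {
  p <- bcg_parameters(fd_rec_no_worse = 0.047, fd_rec_worse = 0.027)
  cmp <- compare_arms(p)
  expect_identical(cmp$os_difference, 0)
  expect_identical(glance(cmp)$preferred_arm, "tie")
})

test_that("raising any death-feeding probability cannot extend survival", {
  withr::with_seed(77, {
    for (i in 1:10) {
      p <- random_valid_params()
      base_os <- summarize_trace(run_cohort(build_matrix(p, "FD")))$expected_life_years
      for (nm in c("age_mortality", "met_death", "rc_mortality")) {
        q <- unclass(p)
        q[[nm]] <- min(1 - 1e-9, q[[nm]] + 0.05)
        q <- do.call(bcg_parameters, q)
        bumped <- summarize_trace(
          run_cohort(build_matrix(q, "FD")))$expected_life_years
        expect_lte(bumped, base_os + 1e-12)
      }
    }
  })
})
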