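# Full analysis pipeline: runs the selected analyses in a fixed order and
# writes machine-readable outputs (CSV/JSON) plus an optional set of
# figures to an output directory. Output filenames and column schemas are
# fixed so downstream consumers can parse them without configuration.

REPORT_ANALYSES <- c("base-case", "one-way", "two-way", "tornado",
                     "microsim", "psa", "recovery")

#' Run the full model pipeline and write a report bundle
#'
#' Executes the selected analyses in a fixed order — base case, one-way
#' sensitivity (with crossover search on the two worsening probabilities),
#' two-way sensitivity, tornado diagrams, microsimulation, probabilistic
#' sensitivity analysis, and parameter recovery from a synthetic panel —
#' and writes their outputs to `output_dir`:
#' `trace_FD.csv` / `trace_LD.csv` (columns `cycle`, the five states,
#' `tur_events`, `rc_events`), `oneway_<parameter>.csv`,
#' `twoway.csv`, `tornado_FD.csv` / `tornado_LD.csv`,
#' `microsim_FD.csv` / `microsim_LD.csv`, `psa.csv`, `recovery.csv`, a
#' machine-readable `summary.json` (full precision) and `manifest.json`
#' recording the analyses run, seed, package version and completeness.
#' Any stage failure aborts with an error naming the stage; outputs
#' already written are retained and the manifest marks the run incomplete.
#'
#' All randomness derives from `seed`, so rerunning with an identical
#' configuration reproduces every output byte for byte.
#'
#' @param output_dir Directory to write into (created if needed).
#' @param params A `bcg_params` object, or a path to a YAML config for
#'   [load_parameters()].
#' @param ranges A `bcg_ranges` tibble.
#' @param analyses Subset of `"base-case"`, `"one-way"`, `"two-way"`,
#'   `"tornado"`, `"microsim"`, `"psa"`, `"recovery"`.
#' @param horizon Annual cycles.
#' @param seed Integer RNG seed.
#' @param n_patients Microsimulation and recovery-panel size.
#' @param n_draws PSA draw count.
#' @param plot Also write PNG figures?
#' @return The manifest (list), invisibly.
#' @export
run_report <- function(output_dir,
                       params = default_parameters(),
                       ranges = default_ranges(),
                       analyses = REPORT_ANALYSES,
                       horizon = 20,
                       seed = 1L,
                       n_patients = 10000,
                       n_draws = 1000,
                       plot = FALSE) {
  if (is.character(params)) params <- load_parameters(params)
  validate_params(params)
  analyses <- match.arg(analyses, REPORT_ANALYSES, several.ok = TRUE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bcgdose")),
    seed = seed, horizon = horizon, analyses = analyses,
    parameters = unclass(params), complete = FALSE, files = character(0)
  )
  summary_out <- list(seed = seed, horizon = horizon,
                      parameters = unclass(params))
  wrote <- function(...) {
    manifest$files <<- c(manifest$files, basename(c(...)))
  }
  save_plot <- function(p, name) {
    if (plot) {
      f <- file.path(output_dir, name)
      ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 150)
      wrote(f)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest()
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cmp <- stage("base-case", compare_arms(params, horizon))
  if ("base-case" %in% analyses) {
    stage("base-case", {
      write_trace_csv(cmp$trace_fd, file.path(output_dir, "trace_FD.csv"))
      write_trace_csv(cmp$trace_ld, file.path(output_dir, "trace_LD.csv"))
      wrote("trace_FD.csv", "trace_LD.csv")
      summary_out$base_case <- list(
        fd = unclass(cmp$fd)[c("expected_life_years", "mortality_at",
                               "tur_count_per_10k", "rc_count_per_10k")],
        ld = unclass(cmp$ld)[c("expected_life_years", "mortality_at",
                               "tur_count_per_10k", "rc_count_per_10k")],
        os_difference = cmp$os_difference,
        preferred_arm = glance.bcg_comparison(cmp)$preferred_arm
      )
      save_plot(autoplot.bcg_comparison(cmp), "survival.png")
      save_plot(autoplot.bcg_trace(cmp$trace_fd), "occupancy_FD.png")
      save_plot(autoplot.bcg_trace(cmp$trace_ld), "occupancy_LD.png")
    })
  }

  if ("one-way" %in% analyses) {
    stage("one-way", {
      crossovers <- list()
      for (parm in c("fd_rec_worse", "ld_rec_worse")) {
        ow <- one_way(params, ranges, parm, n_points = 21, cycles = horizon)
        f <- file.path(output_dir, paste0("oneway_", parm, ".csv"))
        utils::write.csv(tibble::as_tibble(ow), f, row.names = FALSE)
        wrote(f)
        crossovers[[parm]] <- attr(ow, "crossover")
        save_plot(autoplot.bcg_oneway(ow), paste0("oneway_", parm, ".png"))
      }
      summary_out$crossovers <- crossovers
    })
  }

  if ("two-way" %in% analyses) {
    stage("two-way", {
      tw <- two_way(params, ranges, "fd_rec_worse", "ld_rec_worse",
                    n_a = 11, n_b = 11, cycles = horizon)
      f <- file.path(output_dir, "twoway.csv")
      utils::write.csv(tibble::as_tibble(tw), f, row.names = FALSE)
      wrote(f)
      save_plot(autoplot.bcg_twoway(tw), "twoway.png")
    })
  }

  if ("tornado" %in% analyses) {
    stage("tornado", {
      rankings <- list()
      for (arm in c("FD", "LD")) {
        tn <- tornado(params, ranges, arm, cycles = horizon)
        f <- file.path(output_dir, paste0("tornado_", arm, ".csv"))
        utils::write.csv(tibble::as_tibble(tn), f, row.names = FALSE)
        wrote(f)
        rankings[[arm]] <- tn$parameter
        save_plot(autoplot.bcg_tornado(tn), paste0("tornado_", arm, ".png"))
      }
      summary_out$tornado_ranking <- rankings
    })
  }

  if ("microsim" %in% analyses) {
    stage("microsim", {
      ms <- list()
      for (arm in c("FD", "LD")) {
        sim <- simulate_patients(build_matrix(params, arm), n_patients,
                                 seed = seed, cycles = horizon)
        f <- file.path(output_dir, paste0("microsim_", arm, ".csv"))
        utils::write.csv(generics::tidy(sim), f, row.names = FALSE)
        wrote(f)
        ms[[arm]] <- unclass(sim)[c("n_patients", "seed", "mean_os",
                                    "median_os", "ci95_mean", "tur_total",
                                    "rc_total")]
        save_plot(autoplot.bcg_microsim(sim), paste0("microsim_", arm, ".png"))
      }
      summary_out$microsim <- ms
    })
  }

  if ("psa" %in% analyses) {
    stage("psa", {
      ps <- psa(params, ranges, n_draws = n_draws, seed = seed,
                cycles = horizon)
      f <- file.path(output_dir, "psa.csv")
      utils::write.csv(tibble::as_tibble(ps), f, row.names = FALSE)
      wrote(f)
      summary_out$psa <- list(n_draws = n_draws,
                              ld_preferred_frac = attr(ps, "ld_preferred_frac"))
    })
  }

  if ("recovery" %in% analyses) {
    stage("recovery", {
      pan <- generate_panel(params, "FD", n_patients = n_patients,
                            horizon = horizon, seed = seed)
      est <- estimate_params(pan)
      f <- file.path(output_dir, "recovery.csv")
      utils::write.csv(tibble::as_tibble(est), f, row.names = FALSE)
      wrote(f)
    })
  }

  stage("summary", {
    jsonlite::write_json(summary_out, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wrote("summary.json")
  })
  manifest$complete <- TRUE
  write_manifest()
  invisible(manifest)
}
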