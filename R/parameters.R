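# Parameter vocabulary for the five-state BCG dosing model.
#
# All probabilities are stored as fractions per annual cycle (0.047, not
# 4.7%). Display methods show both scales so the percent presentation used
# in clinical tables stays visible without risking silent x100 errors.

PARAM_NAMES <- c(
  "age_mortality",
  "ld_rec_no_worse", "ld_rec_worse",
  "fd_rec_no_worse", "fd_rec_worse",
  "rc_mortality", "met_after_rc", "met_death"
)

PARAM_LABELS <- c(
  age_mortality   = "Age-specific mortality (NA_DT)",
  ld_rec_no_worse = "Recurrence without worsening, LD arm (LD_RE)",
  ld_rec_worse    = "Recurrence with worsening, LD arm (LD_PD)",
  fd_rec_no_worse = "Recurrence without worsening, FD arm (FD_RE)",
  fd_rec_worse    = "Recurrence with worsening, FD arm (FD_PD)",
  rc_mortality    = "Mortality of RC surgery (DT_RC)",
  met_after_rc    = "Metastatic rate after RC (ME_PRC)",
  met_death       = "Death rate of metastatic state (DT_ME)"
)

#' Construct a validated transition-probability parameter set
#'
#' Bundles the eight annual transition probabilities that drive the
#' five-state cohort model: a shared age-specific mortality applied to the
#' disease-free states, arm-specific annual probabilities of recurrence
#' with and without worsening of disease, perioperative mortality of
#' radical cystectomy (RC), the annual metastasis probability after RC,
#' and the annual death probability in the metastatic state.
#'
#' Defaults are the published base case. All values are fractions in
#' \eqn{[0, 1]}; per arm the exit mass from the post-TUR states
#' (`age_mortality + rec_no_worse + rec_worse`) must not exceed 1, and
#' neither may `age_mortality + met_after_rc`.
#'
#' @param age_mortality Annual probability of death from age-related causes,
#'   applied in the disease-free states (tumor free after TUR, no
#'   recurrence, tumor free after RC).
#' @param ld_rec_no_worse,ld_rec_worse Low-dose (27 mg) arm annual
#'   probabilities of recurrence without / with worsening of disease.
#' @param fd_rec_no_worse,fd_rec_worse Full-dose (81 mg) arm annual
#'   probabilities of recurrence without / with worsening of disease.
#' @param rc_mortality Probability of death at radical cystectomy.
#' @param met_after_rc Annual probability of metastasis after RC.
#' @param met_death Annual probability of death in the metastatic state.
#'
#' @return A `bcg_params` object (named list of eight probabilities).
#' @seealso [default_parameters()], [default_ranges()], [load_parameters()]
#' @export
#' @examples
#' p <- bcg_parameters()
#' p$age_mortality
#' tidy(p)
bcg_parameters <- function(age_mortality = 0.0791,
                           ld_rec_no_worse = 0.047,
                           ld_rec_worse = 0.027,
                           fd_rec_no_worse = 0.033,
                           fd_rec_worse = 0.037,
                           rc_mortality = 0.019,
                           met_after_rc = 0.026,
                           met_death = 0.441) {
  p <- list(
    age_mortality = age_mortality,
    ld_rec_no_worse = ld_rec_no_worse,
    ld_rec_worse = ld_rec_worse,
    fd_rec_no_worse = fd_rec_no_worse,
    fd_rec_worse = fd_rec_worse,
    rc_mortality = rc_mortality,
    met_after_rc = met_after_rc,
    met_death = met_death
  )
  validate_params(p)
  structure(p, class = "bcg_params")
}

#' Published base-case parameter set
#'
#' The eight annual transition probabilities of the base case: age-specific
#' mortality 0.0791; LD-arm recurrence without/with worsening 0.047/0.027;
#' FD-arm recurrence without/with worsening 0.033/0.037; RC surgical
#' mortality 0.019; metastasis after RC 0.026; death in the metastatic
#' state 0.441.
#'
#' @return A `bcg_params` object.
#' @export
default_parameters <- function() bcg_parameters()

#' Published sensitivity ranges for the model parameters
#'
#' One row per parameter with its base-case value and the low/high
#' endpoints used for sensitivity analysis. The age-specific mortality has
#' no published range and is returned degenerate (`low == base == high`);
#' sensitivity routines that need a band for it apply a documented
#' relative band instead (see [tornado()]).
#'
#' @return A tibble of class `bcg_ranges` with columns `parameter`, `base`,
#'   `low`, `high`.
#' @export
#' @examples
#' default_ranges()
default_ranges <- function() {
  base <- default_parameters()
  rng <- tibble::tribble(
    ~parameter,        ~low,    ~high,
    "age_mortality",   0.0791,  0.0791,
    "ld_rec_no_worse", 0.0399,  0.0705,
    "ld_rec_worse",    0.0206,  0.0598,
    "fd_rec_no_worse", 0.0155,  0.0492,
    "fd_rec_worse",    0.0235,  0.0577,
    "rc_mortality",    0.01,    0.052,
    "met_after_rc",    0.023,   0.0797,
    "met_death",       0.4299,  0.50
  )
  rng$base <- unlist(base)[rng$parameter]
  out <- rng[, c("parameter", "base", "low", "high")]
  validate_ranges(out)
  structure(out, class = c("bcg_ranges", class(tibble::as_tibble(out))))
}

validate_params <- function(p, call = rlang::caller_env()) {
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")),
                 call = call)
  }
  extra <- setdiff(names(p), PARAM_NAMES)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown parameter(s): ", paste(extra, collapse = ", ")),
                 call = call)
  }
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      rlang::abort(paste0("parameter '", nm, "' must be a single finite number"),
                   call = call)
    }
    if (v < 0 || v > 1) {
      rlang::abort(paste0("parameter '", nm, "' = ", v,
                          " is not a probability in [0, 1]"), call = call)
    }
  }
  for (arm in c("ld", "fd")) {
    exit <- p$age_mortality + p[[paste0(arm, "_rec_no_worse")]] +
      p[[paste0(arm, "_rec_worse")]]
    if (exit > 1) {
      rlang::abort(paste0(
        "exit probabilities from the post-TUR state exceed 1 for the ",
        toupper(arm), " arm: age_mortality + rec_no_worse + rec_worse = ",
        signif(exit, 6)), call = call)
    }
  }
  if (p$age_mortality + p$met_after_rc > 1) {
    rlang::abort(paste0(
      "exit probabilities from the post-RC state exceed 1: ",
      "age_mortality + met_after_rc = ",
      signif(p$age_mortality + p$met_after_rc, 6)), call = call)
  }
  invisible(p)
}

validate_ranges <- function(rng, call = rlang::caller_env()) {
  need <- c("parameter", "base", "low", "high")
  if (!all(need %in% names(rng))) {
    rlang::abort("ranges need columns parameter, base, low, high", call = call)
  }
  bad <- rng$low > rng$base | rng$base > rng$high
  if (any(bad)) {
    rlang::abort(paste0("range violates low <= base <= high for: ",
                        paste(rng$parameter[bad], collapse = ", ")), call = call)
  }
  vals <- c(rng$low, rng$base, rng$high)
  if (any(vals < 0 | vals > 1)) {
    rlang::abort("range endpoints must be probabilities in [0, 1]", call = call)
  }
  invisible(rng)
}

#' @export
print.bcg_params <- function(x, ...) {
  cat("<bcg_params> annual transition probabilities\n")
  df <- generics::tidy(x)
  cat(sprintf("  %-45s %8s %9s\n", "parameter", "fraction", "percent"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-45s %8.4f %8.2f%%\n", df$label[i], df$value[i],
                df$percent[i]))
  }
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x A `bcg_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `label`, `value` (fraction)
#'   and `percent`.
#' @method tidy bcg_params
#' @export
tidy.bcg_params <- function(x, ...) {
  tibble::tibble(
    parameter = PARAM_NAMES,
    label = unname(PARAM_LABELS[PARAM_NAMES]),
    value = unname(unlist(x)[PARAM_NAMES]),
    percent = unname(100 * unlist(x)[PARAM_NAMES])
  )
}

#' Read a parameter set (and optional ranges) from a YAML config
#'
#' The config holds one key per parameter (fractions, e.g. `ld_rec_worse:
#' 0.027`) plus an optional `ranges` block with `low`/`high` pairs per
#' parameter. Unknown keys are rejected. Missing parameters are an error
#' unless `fill_defaults = TRUE`, in which case they are taken from
#' [default_parameters()].
#'
#' @param path Path to a YAML file written by [save_parameters()] or by hand.
#' @param fill_defaults Fill missing parameters from the base case?
#' @return A `bcg_params` object; if the file has a `ranges` block it is
#'   attached as the `"ranges"` attribute (a `bcg_ranges` tibble).
#' @export
load_parameters <- function(path, fill_defaults = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(paste0("failed to parse config '", path, "': ",
                          conditionMessage(e)))
    }
  )
  if (!is.list(raw)) rlang::abort("config must be a YAML mapping")
  rng_block <- raw[["ranges"]]
  raw[["ranges"]] <- NULL
  extra <- setdiff(names(raw), PARAM_NAMES)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown key(s) in config: ", paste(extra, collapse = ", ")))
  }
  if (fill_defaults) {
    defs <- unclass(default_parameters())
    raw <- utils::modifyList(defs, raw)
  } else {
    absent <- setdiff(PARAM_NAMES, names(raw))
    if (length(absent) > 0) {
      rlang::abort(paste0("missing parameter(s) in config: ",
                          paste(absent, collapse = ", "),
                          " (use fill_defaults = TRUE to take base-case values)"))
    }
  }
  p <- do.call(bcg_parameters, raw)
  if (!is.null(rng_block)) {
    rng <- default_ranges()
    for (nm in names(rng_block)) {
      if (!nm %in% PARAM_NAMES) {
        rlang::abort(paste0("unknown parameter in ranges block: ", nm))
      }
      i <- match(nm, rng$parameter)
      rng$base[i] <- p[[nm]]
      rng$low[i] <- rng_block[[nm]]$low
      rng$high[i] <- rng_block[[nm]]$high
    }
    rng$base <- unlist(p)[rng$parameter]
    validate_ranges(rng)
    attr(p, "ranges") <- rng
  }
  p
}

#' Write a parameter set (and optional ranges) to a YAML config
#'
#' Fractions are written with 17 significant digits so that a
#' save-then-load round trip reproduces the parameter set bit-identically;
#' each line carries the percent value as a comment for human readers.
#'
#' @param params A `bcg_params` object.
#' @param path Output file path.
#' @param ranges Optional `bcg_ranges` tibble to embed as a `ranges` block.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path, ranges = NULL) {
  validate_params(params)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# bcgdose model parameters (annual probabilities, fractions)",
    vapply(PARAM_NAMES, function(nm) {
      sprintf("%s: %s  # %.2f%%", nm, num(params[[nm]]), 100 * params[[nm]])
    }, character(1))
  )
  if (!is.null(ranges)) {
    validate_ranges(ranges)
    lines <- c(lines, "ranges:")
    for (i in seq_len(nrow(ranges))) {
      lines <- c(lines,
                 sprintf("  %s:", ranges$parameter[i]),
                 sprintf("    low: %s", num(ranges$low[i])),
                 sprintf("    high: %s", num(ranges$high[i])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
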