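#' Moment-matched Beta distribution
#'
#' Solves the Beta shape parameters that reproduce a given mean and standard
#' error, the usual way probability and utility parameters of a decision model
#' are given a sampling distribution.
#'
#' @param mean Mean of the quantity, strictly inside (0, 1).
#' @param se Standard error, with `0 < se^2 < mean * (1 - mean)`.
#' @return Named numeric vector with elements `shape1` (alpha) and `shape2`
#'   (beta); `shape1 / (shape1 + shape2)` equals `mean` and the analytic
#'   variance equals `se^2`.
#' @examples
#' beta_from_moments(0.224, 0.0018)
#' @export
beta_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta_from_moments: mean must lie strictly inside (0, 1), got ", mean)
  if (!is.finite(se) || se <= 0)
    stop("beta_from_moments: se must be positive, got ", se)
  if (se^2 >= mean * (1 - mean))
    stop("beta_from_moments: infeasible variance, se^2 = ", se^2,
         " >= mean*(1-mean) = ", mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched Gamma distribution
#'
#' Solves the Gamma shape and scale that reproduce a given mean and standard
#' error, used for cost parameters (and for the two complication probabilities
#' that the source data assign a Gamma family).
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @return Named numeric vector with elements `shape` and `scale`;
#'   `shape * scale == mean` and `shape * scale^2 == se^2` exactly.
#' @examples
#' gamma_from_moments(444400, 444400)  # mean == se forces shape 1
#' @export
gamma_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0)
    stop("gamma_from_moments: mean must be positive, got ", mean)
  if (!is.finite(se) || se <= 0)
    stop("gamma_from_moments: se must be positive, got ", se)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Single model input with sampling distribution
#'
#' A parameter estimate is a mean/standard-error pair plus the distribution
#' family used to propagate its uncertainty in probabilistic sensitivity
#' analysis. `se = 0` (or `family = "fixed"`) marks the parameter as fixed.
#'
#' @param mean Point estimate (probability, utility, or money in IDR).
#' @param se Standard error on the same scale, `>= 0`.
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param units,source Optional free-text annotations.
#' @return Object of class `parameter_estimate`.
#' @export
parameter_estimate <- function(mean, se = 0, family = c("beta", "gamma", "fixed"),
                               units = NA_character_, source = NA_character_) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("parameter_estimate: mean must be a finite number")
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se < 0)
    stop("parameter_estimate: se must be a finite non-negative number")
  structure(list(mean = as.numeric(mean), se = as.numeric(se), family = family,
                 units = units, source = source),
            class = "parameter_estimate")
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat(sprintf("<parameter_estimate> mean %g, se %g, family %s\n",
              x$mean, x$se, x$family))
  invisible(x)
}

# canonical scalar parameter names, in reporting order
.param_names <- c(
  "p_death_supportive_per_month", "p_peritonitis_pd",
  "p_vascular_complication_hd", "p_switch_hd_to_pd", "p_switch_pd_to_hd",
  "cost_supportive", "cost_initial_pd", "cost_initial_hd",
  "cost_maintenance_pd_annual", "cost_maintenance_hd_annual",
  "cost_complication_pd_annual", "cost_complication_hd_annual",
  "cost_nonmedical_supportive_lifetime", "cost_nonmedical_pd_annual",
  "cost_nonmedical_hd_annual", "cost_indirect_pd_annual",
  "cost_indirect_hd_annual", "utility_pd", "utility_hd",
  "utility_pd_complication", "utility_hd_complication")

.is_prob_name <- function(name) startsWith(name, "p_")
.is_utility_name <- function(name) startsWith(name, "utility_")
.is_cost_name <- function(name) startsWith(name, "cost_")

.new_esrd_parameters <- function(survival, estimates) {
  # utility for supportive care is tied to the dialysis-with-complication
  # utility (HD), a structural assumption of the model
  estimates$utility_supportive <- estimates$utility_hd_complication
  structure(list(survival = survival, estimates = estimates),
            class = "esrd_parameters")
}

#' @export
print.esrd_parameters <- function(x, ...) {
  cat("<esrd_parameters> dialysis-policy model inputs\n")
  cat(sprintf("  survival schedule: %d annual death probabilities (%s)\n",
              length(x$survival),
              paste(vapply(x$survival, function(e) format(e$mean), ""),
                    collapse = ", ")))
  cat(sprintf("  %d scalar parameters (probabilities, costs in IDR, utilities)\n",
              length(x$estimates)))
  diag <- validate_parameters(x)
  if (nrow(diag))
    cat(sprintf("  %d validation finding(s); see validate_parameters()\n", nrow(diag)))
  invisible(x)
}

#' Extract the mean of a named parameter
#'
#' @param params An `esrd_parameters` object.
#' @param name Parameter name (see [default_parameters()]).
#' @return Numeric mean.
#' @export
param_mean <- function(params, name) {
  stopifnot(inherits(params, "esrd_parameters"))
  est <- params$estimates[[name]]
  if (is.null(est)) stop("unknown parameter: ", name)
  est$mean
}

.parse_estimate <- function(x, name) {
  if (!is.list(x)) stop("parameter '", name, "': expected a mapping with mean/se/family")
  for (field in c("mean", "se", "family"))
    if (is.null(x[[field]]))
      stop("parameter '", name, "': missing field '", field, "'")
  if (!is.numeric(x$mean) || !is.numeric(x$se))
    stop("parameter '", name, "': mean and se must be numeric")
  if (!x$family %in% c("beta", "gamma", "fixed"))
    stop("parameter '", name, "': unknown family '", x$family, "'")
  parameter_estimate(x$mean, x$se, x$family,
                     units = x$units %||% NA_character_,
                     source = x$source %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load model parameters from a YAML configuration file
#'
#' The configuration schema (version 1) has a `survival` list of annual death
#' probabilities for years 1..K and a `parameters` mapping of every scalar
#' model input to a `{mean, se, family}` triple (optionally `units`,
#' `source`). The bundled defaults file reproduces the full published input
#' table; see `system.file("extdata", "table1_defaults.yaml", package =
#' "dialysisCEA")`.
#'
#' The supportive-care utility is not a config field: it is derived, equal to
#' the utility of dialysis with complication (HD).
#'
#' @param path Path to a YAML config file.
#' @return A validated `esrd_parameters` object.
#' @seealso [default_parameters()], [write_parameters()], [validate_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schema_version) && cfg$schema_version != 1)
    stop("unsupported schema_version: ", cfg$schema_version)
  if (is.null(cfg$survival) || length(cfg$survival) < 1L)
    stop("missing field 'survival' (annual death probabilities)")
  years <- vapply(cfg$survival, function(s) as.integer(s$year %||% NA), 1L)
  if (anyNA(years) || !identical(sort(years), seq_along(years)))
    stop("survival schedule must carry consecutive years 1..K")
  survival <- lapply(cfg$survival[order(years)], function(s)
    .parse_estimate(s, paste0("survival year ", s$year)))
  if (is.null(cfg$parameters)) stop("missing field 'parameters'")
  missing <- setdiff(.param_names, names(cfg$parameters))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  estimates <- lapply(.param_names, function(nm)
    .parse_estimate(cfg$parameters[[nm]], nm))
  names(estimates) <- .param_names
  params <- .new_esrd_parameters(survival, estimates)
  diag <- validate_parameters(params)
  bad <- diag[diag$level == "error", , drop = FALSE]
  if (nrow(bad))
    stop("invalid parameter set: ", paste(bad$message, collapse = "; "))
  params
}

#' Table 1 default parameter set
#'
#' Loads the parameter file bundled with the package (survival schedule,
#' transition probabilities, 2015 IDR costs, EQ-5D-3L utilities).
#'
#' @return An `esrd_parameters` object.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "table1_defaults.yaml",
                              package = "dialysisCEA", mustWork = TRUE))
}

#' Write model parameters to a YAML configuration file
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p`.
#'
#' @param params An `esrd_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "esrd_parameters"))
  as_cfg <- function(e) {
    out <- list(mean = e$mean, se = e$se, family = e$family)
    if (!is.na(e$units)) out$units <- e$units
    if (!is.na(e$source)) out$source <- e$source
    out
  }
  scalar <- params$estimates[.param_names]  # derived utility_supportive omitted
  cfg <- list(
    schema_version = 1L,
    survival = lapply(seq_along(params$survival), function(i)
      c(list(year = i), as_cfg(params$survival[[i]]))),
    parameters = lapply(scalar, as_cfg))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks every model invariant and returns diagnostics instead of raising:
#' non-negative standard errors, probabilities and utilities in `[0, 1]`,
#' non-negative costs, Beta moment-matching feasibility (`se^2 <
#' mean*(1-mean)`), the derived supportive-care utility, and a warning-level
#' finding for probability parameters that carry a Gamma family (the source
#' table lists Gamma for the two complication probabilities; draws are
#' truncated to `[0, 1]` during sampling).
#'
#' @param params An `esrd_parameters` object.
#' @return A data.frame with columns `parameter`, `rule`, `level`
#'   (`"error"`/`"warning"`), `value`, `message`; zero rows when all
#'   invariants hold.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "esrd_parameters"))
  rows <- list()
  note <- function(parameter, rule, level, value, message)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, rule = rule, level = level,
      value = value, message = message, stringsAsFactors = FALSE)
  check_common <- function(name, est, prob_like) {
    if (est$se < 0)
      note(name, "se_nonnegative", "error", est$se,
           sprintf("%s: se must be >= 0 (got %g)", name, est$se))
    if (prob_like) {
      if (est$mean < 0 || est$mean > 1)
        note(name, "bounded_01", "error", est$mean,
             sprintf("%s: mean must lie in [0, 1] (got %g)", name, est$mean))
      if (est$family == "beta" && est$se > 0 &&
          est$mean > 0 && est$mean < 1 &&
          est$se^2 >= est$mean * (1 - est$mean))
        note(name, "beta_feasible", "error", est$se,
             sprintf("%s: se^2 >= mean*(1-mean); Beta moment matching infeasible", name))
      if (est$family == "gamma" && est$se > 0)
        note(name, "gamma_probability", "warning", est$mean,
             sprintf("%s: probability parameter with Gamma family; draws are truncated to [0, 1]", name))
    } else {
      if (est$mean < 0)
        note(name, "cost_nonnegative", "error", est$mean,
             sprintf("%s: cost must be >= 0 (got %g)", name, est$mean))
    }
  }
  for (i in seq_along(params$survival)) {
    est <- params$survival[[i]]
    nm <- paste0("survival_year_", i)
    check_common(nm, est, prob_like = TRUE)
    if (est$mean <= 0 || est$mean >= 1)
      note(nm, "open_interval", "error", est$mean,
           sprintf("%s: annual death probability must lie in (0, 1)", nm))
  }
  for (nm in names(params$estimates))
    check_common(nm, params$estimates[[nm]],
                 prob_like = .is_prob_name(nm) || .is_utility_name(nm))
  us <- params$estimates$utility_supportive
  uc <- params$estimates$utility_hd_complication
  if (!is.null(us) && !isTRUE(all.equal(us$mean, uc$mean)))
    note("utility_supportive", "derived_equality", "error", us$mean,
         "utility_supportive must equal utility_hd_complication")
  if (length(rows)) do.call(rbind, rows)
  else data.frame(parameter = character(), rule = character(),
                  level = character(), value = numeric(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Export / import parameters as a flat CSV table
#'
#' One row per parameter with columns `name`, `mean`, `se`, `family`,
#' `units`, `source`. Survival-schedule rows are named `survival_year_<k>`.
#'
#' @param params An `esrd_parameters` object.
#' @param path CSV file path.
#' @return `parameters_to_csv` returns `path` invisibly;
#'   `parameters_from_csv` returns an `esrd_parameters` object.
#' @export
parameters_to_csv <- function(params, path) {
  stopifnot(inherits(params, "esrd_parameters"))
  all_est <- c(stats::setNames(params$survival,
                               paste0("survival_year_", seq_along(params$survival))),
               params$estimates[.param_names])
  df <- data.frame(
    name = names(all_est),
    mean = vapply(all_est, function(e) e$mean, 0),
    se = vapply(all_est, function(e) e$se, 0),
    family = vapply(all_est, function(e) e$family, ""),
    units = vapply(all_est, function(e) as.character(e$units), ""),
    source = vapply(all_est, function(e) as.character(e$source), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname parameters_to_csv
#' @export
parameters_from_csv <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("name", "mean", "se", "family"))
    if (is.null(df[[col]])) stop("CSV missing column '", col, "'")
  mk <- function(row) parameter_estimate(
    row$mean, row$se, row$family,
    units = if (is.null(row$units) || is.na(row$units)) NA_character_ else row$units,
    source = if (is.null(row$source) || is.na(row$source)) NA_character_ else row$source)
  sv_idx <- grep("^survival_year_", df$name)
  if (!length(sv_idx)) stop("CSV missing survival_year_* rows")
  sv_years <- as.integer(sub("^survival_year_", "", df$name[sv_idx]))
  survival <- lapply(order(sv_years), function(i) mk(df[sv_idx[i], ]))
  missing <- setdiff(.param_names, df$name)
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  estimates <- lapply(.param_names, function(nm) mk(df[df$name == nm, ][1, ]))
  names(estimates) <- .param_names
  params <- .new_esrd_parameters(survival, estimates)
  diag <- validate_parameters(params)
  bad <- diag[diag$level == "error", , drop = FALSE]
  if (nrow(bad))
    stop("invalid parameter set: ", paste(bad$message, collapse = "; "))
  params
}
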