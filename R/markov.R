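#' Annual death probability with constant-hazard extrapolation
#'
#' Returns the registry annual death probability of dialysis patients for the
#' requested model year; beyond the observed follow-up the last observed value
#' is carried forward (constant hazard). The same schedule applies to both
#' modalities, as the registry follow-up covers HD patients and no separate PD
#' survival is available.
#'
#' @param survival Either an `esrd_parameters` object or its `survival`
#'   component (a list of `parameter_estimate`s for years 1..K).
#' @param year Model year(s), integer `>= 1`; vectorized.
#' @return Numeric vector of annual death probabilities.
#' @examples
#' effective_death_prob(default_parameters(), c(3, 7, 100))
#' @export
effective_death_prob <- function(survival, year) {
  sched <- .survival_schedule(survival)
  year <- as.numeric(year)
  if (any(!is.finite(year)) || any(year < 1))
    stop("effective_death_prob: year must be >= 1")
  means <- vapply(sched, function(e) e$mean, 0)
  means[pmin(as.integer(year), length(means))]
}

.survival_schedule <- function(survival) {
  if (inherits(survival, "esrd_parameters")) survival <- survival$survival
  if (!is.list(survival) || !length(survival) ||
      !all(vapply(survival, inherits, TRUE, "parameter_estimate")))
    stop("expected an esrd_parameters object or a survival schedule")
  survival
}

#' Cumulative survival of the dialysis cohort
#'
#' Product of annual survival probabilities `(1 - death prob)` over years
#' `1..year`; `year = 0` returns 1.
#'
#' @inheritParams effective_death_prob
#' @param year Integer year `>= 0`; vectorized.
#' @return Numeric vector of survival fractions.
#' @examples
#' cumulative_survival(default_parameters(), 6)  # six-year survivorship
#' @export
cumulative_survival <- function(survival, year) {
  sched <- .survival_schedule(survival)
  year <- as.integer(year)
  if (anyNA(year) || any(year < 0)) stop("cumulative_survival: year must be >= 0")
  vapply(year, function(y) {
    if (y == 0L) return(1)
    prod(1 - effective_death_prob(sched, seq_len(y)))
  }, 0)
}

.trace_states <- c("PD", "PD_COMPLICATION", "HD", "HD_COMPLICATION",
                   "SUPPORTIVE", "DEAD")

.new_trace <- function(policy, cycle_unit, cycles) {
  occ <- as.matrix(cycles[, paste0("occ_", tolower(.trace_states))])
  bad <- abs(rowSums(occ) - 1) > 1e-9
  if (any(bad))
    stop("cohort trace violates occupancy conservation at cycle(s) ",
         paste(which(bad), collapse = ", "))
  if (any(diff(c(0, cycles$occ_dead)) < -1e-12))
    stop("cohort trace violates monotone mortality")
  structure(list(policy = policy, cycle_unit = cycle_unit, cycles = cycles),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$cycles)
  cat(sprintf("<cohort_trace> %s, %d %s cycle(s)\n", x$policy, n, x$cycle_unit))
  cat(sprintf("  residual living occupancy %.3g; dead %.3g\n",
              1 - x$cycles$occ_dead[n], x$cycles$occ_dead[n]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  cy <- x$cycles
  out <- do.call(rbind, lapply(.trace_states, function(s) data.frame(
    cycle_index = cy$cycle_index, time_years = cy$time_years, state = s,
    occupancy = cy[[paste0("occ_", tolower(s))]], stringsAsFactors = FALSE)))
  out[order(out$cycle_index), , drop = FALSE]
}

#' Run the deterministic cohort trace for a dialysis policy
#'
#' Simulates the state-transition model with one-year cycles. The cohort
#' starts fully in the policy's initial modality. Within each cycle the
#' events are: death by the annual schedule ([effective_death_prob()]);
#' modality switching among survivors (annual probabilities PD-to-HD and
#' HD-to-PD, recurring every year); complication episodes (peritonitis on PD,
#' vascular-access complications on HD) that occupy the complication
#' sub-state for `complication_months` of the year and then return to the
#' modality's base state. Death is absorbing; complication sub-state
#' occupancy is reported time-averaged over the cycle so that occupancies sum
#' to one.
#'
#' @param params An `esrd_parameters` object.
#' @param settings An `analysis_settings` object with policy `PD_FIRST` or
#'   `HD_FIRST`.
#' @return A `cohort_trace` whose `cycles` data.frame carries end-of-cycle
#'   state occupancies plus the start-of-cycle bookkeeping (`alive_start`,
#'   `mix_pd_start`, `mix_pd_end`, `death_prob`) used for cost accrual.
#' @seealso [run_supportive_trace()], [accrue_outcomes()]
#' @export
run_dialysis_trace <- function(params, settings) {
  stopifnot(inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  if (!settings$policy %in% c("PD_FIRST", "HD_FIRST"))
    stop("run_dialysis_trace: policy must be PD_FIRST or HD_FIRST")
  H <- settings$horizon_years
  cmf <- settings$complication_months / 12
  p_sw_pd_hd <- param_mean(params, "p_switch_pd_to_hd")
  p_sw_hd_pd <- param_mean(params, "p_switch_hd_to_pd")
  p_comp_pd <- param_mean(params, "p_peritonitis_pd")
  p_comp_hd <- param_mean(params, "p_vascular_complication_hd")
  q <- effective_death_prob(params, seq_len(H))
  alive_start <- mix_start <- mix_end <- surv <- numeric(H)
  alive <- 1
  m <- if (settings$policy == "PD_FIRST") 1 else 0  # PD share among the living
  for (t in seq_len(H)) {
    alive_start[t] <- alive
    mix_start[t] <- m
    surv[t] <- alive * (1 - q[t])
    m <- m * (1 - p_sw_pd_hd) + (1 - m) * p_sw_hd_pd
    mix_end[t] <- m
    alive <- surv[t]
  }
  pd_tot <- surv * mix_end
  hd_tot <- surv * (1 - mix_end)
  cycles <- data.frame(
    cycle_index = seq_len(H), time_years = as.numeric(seq_len(H)),
    occ_pd = pd_tot * (1 - p_comp_pd * cmf),
    occ_pd_complication = pd_tot * p_comp_pd * cmf,
    occ_hd = hd_tot * (1 - p_comp_hd * cmf),
    occ_hd_complication = hd_tot * p_comp_hd * cmf,
    occ_supportive = 0,
    occ_dead = 1 - surv,
    alive_start = alive_start, mix_pd_start = mix_start, mix_pd_end = mix_end,
    death_prob = q)
  .new_trace(settings$policy, "year", cycles)
}

#' Run the deterministic cohort trace for supportive care
#'
#' Monthly cycles with a constant per-month death probability. The month of
#' death is lived: occupancy is removed at the end of the month, so the
#' implied life expectancy is the mean of the geometric death-time
#' distribution, `1/p` months. The trace stops once residual living
#' occupancy falls below `1e-9` (or at the horizon).
#'
#' @inheritParams run_dialysis_trace
#' @return A `cohort_trace` with monthly cycles.
#' @export
run_supportive_trace <- function(params, settings) {
  stopifnot(inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  p <- param_mean(params, "p_death_supportive_per_month")
  max_cycles <- settings$horizon_years * 12L
  n <- if (p >= 1) 1L
       else min(max_cycles, max(1L, ceiling(log(1e-9) / log(1 - p))))
  t <- seq_len(n)
  alive_start <- (1 - p)^(t - 1)
  surv <- (1 - p)^t
  cycles <- data.frame(
    cycle_index = t, time_years = t / 12,
    occ_pd = 0, occ_pd_complication = 0, occ_hd = 0, occ_hd_complication = 0,
    occ_supportive = surv, occ_dead = 1 - surv,
    alive_start = alive_start, mix_pd_start = NA_real_, mix_pd_end = NA_real_,
    death_prob = p)
  .new_trace("SUPPORTIVE", "month", cycles)
}

#' Run the cohort trace for any policy
#'
#' Dispatches to [run_dialysis_trace()] or [run_supportive_trace()]
#' according to `settings$policy`.
#'
#' @inheritParams run_dialysis_trace
#' @return A `cohort_trace`.
#' @export
run_trace <- function(params, settings) {
  if (settings$policy == "SUPPORTIVE") run_supportive_trace(params, settings)
  else run_dialysis_trace(params, settings)
}
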