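#' Analysis settings
#'
#' Bundles the run configuration shared by the cohort engine, outcome
#' accrual, PSA and CLI: policy, costing perspective, discounting, horizon
#' and Monte-Carlo controls.
#'
#' Accrual conventions are fixed package-wide and recorded in the object:
#' costs accrue at the start of each cycle to everyone alive at cycle start
#' (in their start-of-cycle modality) and are discounted at cycle-start time;
#' life years and QALYs accrue at the end of each cycle to survivors (in
#' their end-of-cycle modality) and are discounted at cycle-end time. The
#' supportive-care arm uses monthly cycles in which the month of death is
#' lived. See the methods vignette for the rationale.
#'
#' @param policy `"PD_FIRST"`, `"HD_FIRST"` or `"SUPPORTIVE"`.
#' @param perspective `"societal"` (direct medical + direct non-medical +
#'   indirect costs) or `"provider"` (direct medical only).
#' @param discount_rate Annual discount rate for costs and outcomes
#'   (default 0.03).
#' @param horizon_years Model horizon in annual cycles (default 24; the
#'   package's lifetime-horizon convention, residual survivorship < 3%).
#' @param complication_months Duration of a complication episode within an
#'   annual cycle, in months (default 1).
#' @param apply_initiation_cost_on_switch Charge the new modality's
#'   initiation cost when a patient switches (default `TRUE`).
#' @param wtp_grid Willingness-to-pay grid in IDR per QALY for CEAC work
#'   (default 0 to 400 million in 2-million steps, covering the 43-million
#'   GDP-per-capita threshold).
#' @param psa_draws Number of PSA iterations (default 1000).
#' @param seed Integer RNG seed for PSA / microsimulation.
#' @return Object of class `analysis_settings`.
#' @export
analysis_settings <- function(policy = c("PD_FIRST", "HD_FIRST", "SUPPORTIVE"),
                              perspective = c("societal", "provider"),
                              discount_rate = 0.03,
                              horizon_years = 24L,
                              complication_months = 1L,
                              apply_initiation_cost_on_switch = TRUE,
                              wtp_grid = seq(0, 400e6, by = 2e6),
                              psa_draws = 1000L,
                              seed = 1L) {
  policy <- match.arg(policy)
  perspective <- match.arg(perspective)
  stopifnot(is.numeric(discount_rate), length(discount_rate) == 1L,
            is.finite(discount_rate), discount_rate >= 0)
  horizon_years <- as.integer(horizon_years)
  stopifnot(horizon_years >= 1L)
  complication_months <- as.integer(complication_months)
  if (complication_months < 1L || complication_months > 12L)
    stop("complication_months must lie in 1..12")
  stopifnot(is.logical(apply_initiation_cost_on_switch),
            length(apply_initiation_cost_on_switch) == 1L)
  stopifnot(is.numeric(wtp_grid), length(wtp_grid) >= 1L, all(wtp_grid >= 0))
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("wtp_grid must be strictly increasing")
  psa_draws <- as.integer(psa_draws)
  if (is.na(psa_draws) || psa_draws < 1L) stop("psa_draws must be >= 1")
  structure(list(
    policy = policy, perspective = perspective,
    discount_rate = discount_rate, horizon_years = horizon_years,
    complication_months = complication_months,
    apply_initiation_cost_on_switch = apply_initiation_cost_on_switch,
    wtp_grid = wtp_grid, psa_draws = psa_draws, seed = as.integer(seed),
    cost_accrual = "cycle_start", outcome_accrual = "cycle_end"),
    class = "analysis_settings")
}

#' @export
print.analysis_settings <- function(x, ...) {
  cat(sprintf("<analysis_settings> %s, %s perspective\n", x$policy, x$perspective))
  cat(sprintf("  discount %.1f%%/yr, horizon %d yr, complication episode %d mo\n",
              100 * x$discount_rate, x$horizon_years, x$complication_months))
  cat(sprintf("  PSA: %d draws, seed %d; WTP grid %s to %s IDR (%d points)\n",
              x$psa_draws, x$seed, format(min(x$wtp_grid), big.mark = ","),
              format(max(x$wtp_grid), big.mark = ","), length(x$wtp_grid)))
  invisible(x)
}

.with_policy <- function(settings, policy) {
  settings$policy <- policy
  settings
}
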