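#' Budget impact inputs
#'
#' Population and coverage assumptions for the payer budget projection:
#' prevalent dialysis-eligible patients enrolled in year 1 together with the
#' first incident cohort, then one incident cohort per later year, all scaled
#' by the coverage fraction.
#'
#' @param prevalence Prevalent ESRD patients at baseline (default 63,818,
#'   payer claims data).
#' @param incidence Incident ESRD patients per year (default 17,913,
#'   renal registry).
#' @param coverage Fraction of patients with access to dialysis, in `(0, 1]`
#'   (the study scenarios are 0.53 and 1.00).
#' @param years Projection horizon in years (default 5).
#' @param mortality_applied Apply cohort attrition by the survival schedule
#'   (default `TRUE`).
#' @return Object of class `bia_inputs`.
#' @export
bia_inputs <- function(prevalence = 63818, incidence = 17913,
                       coverage = 0.53, years = 5L,
                       mortality_applied = TRUE) {
  stopifnot(is.numeric(prevalence), prevalence >= 0,
            is.numeric(incidence), incidence >= 0,
            is.numeric(coverage), length(coverage) == 1L,
            coverage > 0, coverage <= 1,
            is.logical(mortality_applied), length(mortality_applied) == 1L)
  years <- as.integer(years)
  if (is.na(years) || years < 1L) stop("years must be >= 1")
  structure(list(prevalence = prevalence, incidence = incidence,
                 coverage = coverage, years = years,
                 mortality_applied = mortality_applied),
            class = "bia_inputs")
}

# per-cohort dynamics shared by every entry cohort: alive-at-start and PD mix
# by cohort age, from the same recurrence as the cohort engine
.bia_cohort_dynamics <- function(params, policy, inputs, settings) {
  s <- .with_policy(settings, policy)
  s$horizon_years <- max(inputs$years, 1L)
  tr <- run_dialysis_trace(params, s)$cycles
  alive <- if (inputs$mortality_applied) tr$alive_start else rep(1, nrow(tr))
  list(alive_start = alive, mix_pd_start = tr$mix_pd_start,
       mix_pd_end = tr$mix_pd_end, death_prob = tr$death_prob)
}

#' Project the treated population for a budget impact analysis
#'
#' Year 1 enrolls `coverage * (prevalence + incidence)`; each later year adds
#' `coverage * incidence` as a new entry cohort. Every cohort evolves through
#' the cohort engine's modality-switching (and, if enabled, mortality)
#' dynamics.
#'
#' @param inputs A `bia_inputs` object.
#' @param params An `esrd_parameters` object.
#' @param policy `"PD_FIRST"` or `"HD_FIRST"`.
#' @param settings An `analysis_settings` (complication/switching
#'   configuration; default settings).
#' @return Data.frame with one row per projection year and entry cohort:
#'   `year`, `cohort_entry_year`, `age_years`, `patients`, `on_pd`, `on_hd`
#'   (counts at the start of the year).
#' @export
project_population <- function(inputs, params, policy = c("PD_FIRST", "HD_FIRST"),
                               settings = analysis_settings()) {
  stopifnot(inherits(inputs, "bia_inputs"), inherits(params, "esrd_parameters"))
  policy <- match.arg(policy)
  dyn <- .bia_cohort_dynamics(params, policy, inputs, settings)
  entry_size <- c(inputs$coverage * (inputs$prevalence + inputs$incidence),
                  rep(inputs$coverage * inputs$incidence,
                      max(0L, inputs$years - 1L)))
  rows <- list()
  for (y in seq_len(inputs$years)) for (e in seq_len(y)) {
    a <- y - e + 1L  # cohort age in years
    n <- entry_size[e] * dyn$alive_start[a]
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, cohort_entry_year = e, age_years = a,
      patients = n,
      on_pd = n * dyn$mix_pd_start[a],
      on_hd = n * (1 - dyn$mix_pd_start[a]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Five-year payer budget projection
#'
#' Healthcare-provider perspective (direct medical costs only), undiscounted,
#' as is conventional for budget impact analysis. Per year and cohort the
#' payer cost is: entry initiation for new entrants, annual maintenance plus
#' expected complication treatment on the cohort's modality mix, and
#' switch-initiation costs on the expected switching flow. Costs are charged
#' on the alive-at-start population, consistent with the cohort engine's
#' accrual convention.
#'
#' @inheritParams project_population
#' @return Object of class `bia_table`: data.frame `table` with one row per
#'   year (`year`, `policy`, `coverage`, `enrolled`, `on_pd`, `on_hd`,
#'   `cost_idr`, `cumulative_cost_idr`).
#' @export
run_bia <- function(inputs, params, policy = c("PD_FIRST", "HD_FIRST"),
                    settings = analysis_settings()) {
  stopifnot(inherits(inputs, "bia_inputs"), inherits(params, "esrd_parameters"))
  policy <- match.arg(policy)
  pm <- function(nm) param_mean(params, nm)
  med_pd <- pm("cost_maintenance_pd_annual") +
    pm("p_peritonitis_pd") * pm("cost_complication_pd_annual")
  med_hd <- pm("cost_maintenance_hd_annual") +
    pm("p_vascular_complication_hd") * pm("cost_complication_hd_annual")
  entry_init <- if (policy == "PD_FIRST") pm("cost_initial_pd") else pm("cost_initial_hd")
  pop <- project_population(inputs, params, policy, settings)
  pop$cost <- pop$on_pd * med_pd + pop$on_hd * med_hd
  if (settings$apply_initiation_cost_on_switch)
    pop$cost <- pop$cost +
      pop$on_pd * pm("p_switch_pd_to_hd") * pm("cost_initial_hd") +
      pop$on_hd * pm("p_switch_hd_to_pd") * pm("cost_initial_pd")
  pop$cost[pop$age_years == 1L] <-
    pop$cost[pop$age_years == 1L] + pop$patients[pop$age_years == 1L] * entry_init
  tab <- do.call(rbind, lapply(split(pop, pop$year), function(d) data.frame(
    year = d$year[1], policy = policy, coverage = inputs$coverage,
    enrolled = sum(d$patients), on_pd = sum(d$on_pd), on_hd = sum(d$on_hd),
    cost_idr = sum(d$cost))))
  tab$cumulative_cost_idr <- cumsum(tab$cost_idr)
  rownames(tab) <- NULL
  structure(list(table = tab, inputs = inputs, policy = policy),
            class = "bia_table")
}

#' @export
print.bia_table <- function(x, ...) {
  cat(sprintf("<bia_table> %s, coverage %.0f%%, %d year(s)\n",
              x$policy, 100 * x$inputs$coverage, x$inputs$years))
  tab <- x$table
  tab$cost_trillion_idr <- sprintf("%.2f", tab$cost_idr / 1e12)
  tab$cumulative_trillion_idr <- sprintf("%.2f", tab$cumulative_cost_idr / 1e12)
  tab$enrolled <- round(tab$enrolled)
  print(tab[, c("year", "enrolled", "cost_trillion_idr", "cumulative_trillion_idr")],
        row.names = FALSE)
  invisible(x)
}

#' Export a budget impact table as CSV
#'
#' @param bia A `bia_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bia_csv <- function(bia, path) {
  stopifnot(inherits(bia, "bia_table"))
  utils::write.csv(bia$table, path, row.names = FALSE)
  invisible(path)
}
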