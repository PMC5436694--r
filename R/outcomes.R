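#' Discount factor
#'
#' `(1 + rate)^(-time_years)`, the present-value weight applied to costs and
#' health outcomes.
#'
#' @param rate Annual discount rate, `>= 0`.
#' @param time_years Time in years, `>= 0`; vectorized.
#' @return Numeric vector of discount factors.
#' @export
discount_factor <- function(rate, time_years) {
  if (!is.numeric(rate) || any(rate < 0)) stop("discount_factor: rate must be >= 0")
  if (!is.numeric(time_years) || any(time_years < 0))
    stop("discount_factor: time must be >= 0")
  (1 + rate)^(-time_years)
}

#' Accrue lifetime costs and effects from a cohort trace
#'
#' Turns a `cohort_trace` into lifetime (per-patient) life years, QALYs and
#' costs, discounted and undiscounted, for both costing perspectives.
#'
#' Accrual conventions (fixed package-wide, see the methods vignette):
#' * Costs accrue at the start of each cycle to everyone alive at cycle
#'   start, in their start-of-cycle modality, and are discounted at
#'   cycle-start time. The year's direct medical cost is maintenance plus
#'   the expected complication treatment cost (complication probability times
#'   the annual complication cost); switch-initiation costs are charged on
#'   the expected switching flow of those alive at cycle start; the entry
#'   initiation cost is charged undiscounted at entry.
#' * Life years and QALYs accrue at the end of each cycle to survivors, in
#'   their end-of-cycle modality, discounted at cycle-end time. Complication
#'   episodes contribute the complication utility for
#'   `complication_months/12` of the year.
#' * Supportive care runs on monthly cycles in which the month of death is
#'   lived; its medical cost is per month, its household (direct non-medical)
#'   cost is a single lifetime amount charged at entry.
#'
#' The societal perspective sums direct medical, direct non-medical and
#' indirect costs; the provider perspective counts direct medical costs only.
#'
#' @param trace A `cohort_trace` from [run_trace()].
#' @param params The `esrd_parameters` used to produce the trace.
#' @param settings The `analysis_settings` used to produce the trace.
#' @return Object of class `policy_outcome`: lifetime totals
#'   (`ly_undiscounted`, `qaly_undiscounted`, `qaly_discounted`,
#'   `cost_discounted_societal`, `cost_discounted_provider`, component
#'   vectors) plus a per-cycle `detail` data.frame.
#' @export
accrue_outcomes <- function(trace, params, settings) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  if (trace$policy != settings$policy)
    stop("trace was produced for policy ", trace$policy,
         " but settings request ", settings$policy)
  r <- settings$discount_rate
  cy <- trace$cycles
  pm <- function(nm) param_mean(params, nm)

  if (trace$cycle_unit == "year") {
    cmf <- settings$complication_months / 12
    p_comp_pd <- pm("p_peritonitis_pd")
    p_comp_hd <- pm("p_vascular_complication_hd")
    # expected within-cycle utility of an occupant of each modality
    eu_pd <- (1 - p_comp_pd) * pm("utility_pd") +
      p_comp_pd * ((1 - cmf) * pm("utility_pd") + cmf * pm("utility_pd_complication"))
    eu_hd <- (1 - p_comp_hd) * pm("utility_hd") +
      p_comp_hd * ((1 - cmf) * pm("utility_hd") + cmf * pm("utility_hd_complication"))
    med_pd <- pm("cost_maintenance_pd_annual") + p_comp_pd * pm("cost_complication_pd_annual")
    med_hd <- pm("cost_maintenance_hd_annual") + p_comp_hd * pm("cost_complication_hd_annual")
    t <- cy$cycle_index
    df_cost <- discount_factor(r, t - 1)
    df_out <- discount_factor(r, t)
    alive0 <- cy$alive_start
    m0 <- cy$mix_pd_start
    surv <- 1 - cy$occ_dead
    m1 <- cy$mix_pd_end
    cost_med <- alive0 * (m0 * med_pd + (1 - m0) * med_hd)
    if (settings$apply_initiation_cost_on_switch)
      cost_med <- cost_med + alive0 *
        (m0 * pm("p_switch_pd_to_hd") * pm("cost_initial_hd") +
         (1 - m0) * pm("p_switch_hd_to_pd") * pm("cost_initial_pd"))
    entry <- if (settings$policy == "PD_FIRST") pm("cost_initial_pd") else pm("cost_initial_hd")
    cost_med[1] <- cost_med[1] + entry  # charged at entry, cycle-start df = 1
    cost_nonmed <- alive0 * (m0 * pm("cost_nonmedical_pd_annual") +
                             (1 - m0) * pm("cost_nonmedical_hd_annual"))
    cost_indirect <- alive0 * (m0 * pm("cost_indirect_pd_annual") +
                               (1 - m0) * pm("cost_indirect_hd_annual"))
    ly <- surv
    qaly <- surv * (m1 * eu_pd + (1 - m1) * eu_hd)
  } else {
    t <- cy$cycle_index
    df_cost <- discount_factor(r, (t - 1) / 12)
    df_out <- discount_factor(r, t / 12)
    alive0 <- cy$alive_start
    cost_med <- alive0 * pm("cost_supportive")      # per-month medical cost
    cost_nonmed <- numeric(length(t))
    cost_nonmed[1] <- pm("cost_nonmedical_supportive_lifetime")  # once, at entry
    cost_indirect <- numeric(length(t))
    ly <- alive0 / 12
    qaly <- alive0 * pm("utility_supportive") / 12
  }

  detail <- data.frame(
    cycle_index = cy$cycle_index, time_years = cy$time_years,
    ly = ly, qaly = qaly, qaly_discounted = qaly * df_out,
    cost_direct_medical = cost_med,
    cost_direct_nonmedical = cost_nonmed,
    cost_indirect = cost_indirect,
    cost_direct_medical_discounted = cost_med * df_cost,
    cost_direct_nonmedical_discounted = cost_nonmed * df_cost,
    cost_indirect_discounted = cost_indirect * df_cost)

  comp_u <- c(direct_medical = sum(cost_med),
              direct_nonmedical = sum(cost_nonmed),
              indirect = sum(cost_indirect))
  comp_d <- c(direct_medical = sum(cost_med * df_cost),
              direct_nonmedical = sum(cost_nonmed * df_cost),
              indirect = sum(cost_indirect * df_cost))
  structure(list(
    policy = settings$policy,
    perspective = settings$perspective,
    discount_rate = r,
    ly_undiscounted = sum(ly),
    qaly_undiscounted = sum(qaly),
    qaly_discounted = sum(qaly * df_out),
    cost_components_undiscounted = comp_u,
    cost_components_discounted = comp_d,
    cost_undiscounted_societal = sum(comp_u),
    cost_undiscounted_provider = comp_u[["direct_medical"]],
    cost_discounted_societal = sum(comp_d),
    cost_discounted_provider = comp_d[["direct_medical"]],
    detail = detail), class = "policy_outcome")
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat(sprintf("<policy_outcome> %s (discount %.1f%%)\n", x$policy, 100 * x$discount_rate))
  cat(sprintf("  LY %.2f, QALY %.2f (undiscounted); QALY %.2f (discounted)\n",
              x$ly_undiscounted, x$qaly_undiscounted, x$qaly_discounted))
  cat(sprintf("  lifetime cost: societal %.1f M IDR, provider %.1f M IDR (discounted)\n",
              x$cost_discounted_societal / 1e6, x$cost_discounted_provider / 1e6))
  invisible(x)
}

#' Lifetime cost of an outcome under a perspective
#'
#' @param outcome A `policy_outcome`.
#' @param perspective `"societal"` or `"provider"`.
#' @param discounted Use discounted costs (default `TRUE`).
#' @return Total cost in IDR.
#' @export
outcome_cost <- function(outcome, perspective = c("societal", "provider"),
                         discounted = TRUE) {
  stopifnot(inherits(outcome, "policy_outcome"))
  perspective <- match.arg(perspective)
  key <- paste0(if (discounted) "cost_discounted_" else "cost_undiscounted_",
                perspective)
  outcome[[key]]
}

#' Cost components of an outcome under a perspective
#'
#' The provider perspective includes direct medical costs only; requesting a
#' non-medical or indirect component under it is an error.
#'
#' @inheritParams outcome_cost
#' @param component Optional single component name (`"direct_medical"`,
#'   `"direct_nonmedical"`, `"indirect"`); `NULL` returns all components the
#'   perspective includes.
#' @return Named numeric vector (or scalar when `component` is given), IDR.
#' @export
cost_components <- function(outcome, perspective = c("societal", "provider"),
                            component = NULL, discounted = TRUE) {
  stopifnot(inherits(outcome, "policy_outcome"))
  perspective <- match.arg(perspective)
  comp <- if (discounted) outcome$cost_components_discounted
          else outcome$cost_components_undiscounted
  included <- if (perspective == "societal") names(comp) else "direct_medical"
  if (is.null(component)) return(comp[included])
  if (!component %in% names(comp)) stop("unknown cost component: ", component)
  if (!component %in% included)
    stop("perspective mismatch: component '", component,
         "' is not part of the ", perspective, " perspective")
  comp[[component]]
}

#' Incremental cost-effectiveness ratio
#'
#' Compares an intervention against a reference on discounted costs and
#' discounted QALYs. Returns the ratio, or a dominance flag: `"dominated"`
#' when the intervention costs more for no QALY gain, `"dominant"` when it
#' costs no more and gains QALYs, `"equivalent"` when both differences are
#' zero.
#'
#' @param intervention,reference `policy_outcome` objects computed with the
#'   same discount rate.
#' @param perspective Costing perspective for the cost difference.
#' @return List of class `icer_result`: `delta_cost`, `delta_qaly`, `icer`
#'   (IDR per QALY, `NA` when a flag applies), `status`.
#' @export
icer <- function(intervention, reference,
                 perspective = c("societal", "provider")) {
  stopifnot(inherits(intervention, "policy_outcome"),
            inherits(reference, "policy_outcome"))
  perspective <- match.arg(perspective)
  if (!isTRUE(all.equal(intervention$discount_rate, reference$discount_rate)))
    stop("icer: outcomes were computed with different discount rates")
  dc <- outcome_cost(intervention, perspective) - outcome_cost(reference, perspective)
  de <- intervention$qaly_discounted - reference$qaly_discounted
  status <- if (dc == 0 && de == 0) "equivalent"
    else if (dc > 0 && de <= 0) "dominated"
    else if (dc <= 0 && de > 0) "dominant"
    else "icer"
  structure(list(
    intervention = intervention$policy, reference = reference$policy,
    perspective = perspective, delta_cost = dc, delta_qaly = de,
    icer = if (status == "icer") dc / de else NA_real_,
    status = status), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer> %s vs %s (%s): ", x$intervention, x$reference, x$perspective))
  if (x$status == "icer")
    cat(sprintf("%.1f M IDR per QALY (dC %.1f M, dQ %.3f)\n",
                x$icer / 1e6, x$delta_cost / 1e6, x$delta_qaly))
  else cat(x$status, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * discounted QALYs - discounted cost` under the chosen perspective.
#'
#' @param outcome A `policy_outcome`.
#' @param wtp Willingness to pay per QALY, IDR; vectorized, `>= 0`.
#' @param perspective Costing perspective (defaults to the outcome's own).
#' @return Numeric vector of net monetary benefits (IDR).
#' @export
net_monetary_benefit <- function(outcome, wtp, perspective = NULL) {
  stopifnot(inherits(outcome, "policy_outcome"))
  if (any(wtp < 0)) stop("net_monetary_benefit: wtp must be >= 0")
  perspective <- perspective %||% outcome$perspective
  wtp * outcome$qaly_discounted - outcome_cost(outcome, perspective)
}

#' Cost-effectiveness frontier with dominance analysis
#'
#' Orders policies by discounted QALYs, flags strictly dominated options
#' (more costly, no more effective than another single option) and
#' extendedly dominated options (removed when sequential ICERs are not
#' increasing), and computes incremental costs, effects and ICERs along the
#' efficient frontier.
#'
#' @param outcomes List of two or more `policy_outcome` objects.
#' @param perspective Costing perspective.
#' @return Object of class `cea_frontier`: a data.frame `table` with one row
#'   per policy (`policy`, `cost`, `qaly`, `status`, `delta_cost`,
#'   `delta_qaly`, `icer`), plus `frontier`, the ordered frontier policies.
#' @export
frontier <- function(outcomes, perspective = c("societal", "provider")) {
  perspective <- match.arg(perspective)
  stopifnot(is.list(outcomes), length(outcomes) >= 1,
            all(vapply(outcomes, inherits, TRUE, "policy_outcome")))
  tab <- data.frame(
    policy = vapply(outcomes, function(o) o$policy, ""),
    cost = vapply(outcomes, outcome_cost, 0, perspective = perspective),
    qaly = vapply(outcomes, function(o) o$qaly_discounted, 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$qaly, tab$cost), , drop = FALSE]
  tab$status <- "frontier"
  n <- nrow(tab)
  # strict dominance against any single alternative
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    if (tab$cost[i] >= tab$cost[j] && tab$qaly[i] <= tab$qaly[j] &&
        (tab$cost[i] > tab$cost[j] || tab$qaly[i] < tab$qaly[j]))
      tab$status[i] <- "dominated"
  }
  # extended dominance: sequential ICERs along the candidate frontier must increase
  repeat {
    idx <- which(tab$status == "frontier")
    if (length(idx) < 3) break
    ic <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
    drop <- which(diff(ic) <= 0)  # collinear middle points are removed too
    if (!length(drop)) break
    tab$status[idx[drop[1] + 1L]] <- "extendedly_dominated"
  }
  idx <- which(tab$status == "frontier")
  tab$delta_cost <- NA_real_; tab$delta_qaly <- NA_real_; tab$icer <- NA_real_
  if (length(idx) > 1) {
    tab$delta_cost[idx[-1]] <- diff(tab$cost[idx])
    tab$delta_qaly[idx[-1]] <- diff(tab$qaly[idx])
    tab$icer[idx[-1]] <- tab$delta_cost[idx[-1]] / tab$delta_qaly[idx[-1]]
  }
  rownames(tab) <- NULL
  structure(list(table = tab, frontier = tab$policy[idx],
                 perspective = perspective), class = "cea_frontier")
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat(sprintf("<cea_frontier> %s perspective\n", x$perspective))
  tab <- x$table
  tab$cost <- sprintf("%.1fM", tab$cost / 1e6)
  tab$qaly <- sprintf("%.3f", tab$qaly)
  tab$icer <- ifelse(is.na(tab$icer), "-", sprintf("%.1fM/QALY", tab$icer / 1e6))
  print(tab[, c("policy", "cost", "qaly", "status", "icer")], row.names = FALSE)
  invisible(x)
}

#' Deterministic cost-effectiveness analysis of the three policies
#'
#' Runs the cohort model at the parameter means for PD-first, HD-first and
#' supportive care, accrues outcomes, and performs the dominance/frontier
#' analysis under the requested perspective.
#'
#' @param params An `esrd_parameters` object.
#' @param settings An `analysis_settings` object (its `policy` field is
#'   ignored; all three are run).
#' @return Object of class `cea_result`: named list `outcomes` of
#'   `policy_outcome`s, summary data.frame `table` (one row per policy and
#'   perspective), and `frontier` (a `cea_frontier` for
#'   `settings$perspective`).
#' @export
run_cea <- function(params, settings = analysis_settings()) {
  policies <- c("PD_FIRST", "HD_FIRST", "SUPPORTIVE")
  outcomes <- lapply(policies, function(p) {
    s <- .with_policy(settings, p)
    accrue_outcomes(run_trace(params, s), params, s)
  })
  names(outcomes) <- policies
  table <- do.call(rbind, lapply(outcomes, function(o) data.frame(
    policy = o$policy,
    ly_undiscounted = o$ly_undiscounted,
    qaly_undiscounted = o$qaly_undiscounted,
    qaly_discounted = o$qaly_discounted,
    cost_discounted_societal = o$cost_discounted_societal,
    cost_discounted_provider = o$cost_discounted_provider,
    stringsAsFactors = FALSE)))
  rownames(table) <- NULL
  structure(list(outcomes = outcomes, table = table,
                 frontier = frontier(outcomes, settings$perspective),
                 settings = settings), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> deterministic cost-effectiveness analysis\n")
  tab <- x$table
  tab$cost_discounted_societal <- sprintf("%.1fM", tab$cost_discounted_societal / 1e6)
  tab$cost_discounted_provider <- sprintf("%.1fM", tab$cost_discounted_provider / 1e6)
  tab$ly_undiscounted <- sprintf("%.2f", tab$ly_undiscounted)
  tab$qaly_undiscounted <- sprintf("%.2f", tab$qaly_undiscounted)
  tab$qaly_discounted <- sprintf("%.2f", tab$qaly_discounted)
  print(tab, row.names = FALSE)
  print(x$frontier)
  invisible(x)
}

#' Write per-cycle trace accruals as tidy CSV
#'
#' One row per cycle and state with occupancy, plus the cycle's accrued life
#' years, QALYs and cost components attributed to the cycle (costs on the
#' cycle-start basis, outcomes on the cycle-end basis).
#'
#' @param trace A `cohort_trace`.
#' @param params,settings Inputs used to produce the trace.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, params, settings, path) {
  occ <- as.data.frame(trace)
  out <- accrue_outcomes(trace, params, settings)
  det <- out$detail[, c("cycle_index", "ly", "qaly", "cost_direct_medical",
                        "cost_direct_nonmedical", "cost_indirect")]
  merged <- merge(occ, det, by = "cycle_index", sort = FALSE)
  merged <- merged[order(merged$cycle_index), , drop = FALSE]
  utils::write.csv(merged, path, row.names = FALSE)
  invisible(path)
}
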