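#' Simulate one patient trajectory
#'
#' Patient-level counterpart of the cohort engine, using exactly the same
#' per-cycle probabilities, event ordering and accrual conventions; the mean
#' of many trajectories converges to the cohort-model expectations, which is
#' what makes the microsimulation an independent validation oracle.
#'
#' Dialysis arms run on annual cycles recorded on a monthly timeline: at
#' cycle start the year's treatment cost is committed in the start-of-cycle
#' modality (plus a complication-treatment cost drawn at the start-of-cycle
#' modality's complication probability, and the switch-initiation cost if a
#' switch is drawn); patients dying that year accrue the committed costs but
#' no life years or QALYs; survivors accrue one year in the end-of-cycle
#' modality, with a complication episode (drawn at that modality's
#' probability) contributing the complication utility for
#' `complication_months` of the year. Supportive care runs on monthly cycles
#' in which the month of death is lived.
#'
#' @param params An `esrd_parameters` object.
#' @param settings An `analysis_settings`; `settings$policy` selects the arm.
#' @return Object of class `patient_trajectory`: `events` data.frame
#'   (`time_months`, `event`) and accrued `ly`, `qaly`, `qaly_discounted`,
#'   `cost_components_discounted`.
#' @export
simulate_patient <- function(params, settings) {
  stopifnot(inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  res <- run_microsim(params, settings, n_patients = 1L, seed = NULL,
                      keep_patients = TRUE)
  pat <- res$patients
  ev <- res$events[[1]]
  structure(list(
    policy = settings$policy, events = ev,
    ly = pat$ly[1], qaly = pat$qaly[1], qaly_discounted = pat$qaly_discounted[1],
    cost_components_discounted = c(
      direct_medical = pat$cost_direct_medical_discounted[1],
      direct_nonmedical = pat$cost_direct_nonmedical_discounted[1],
      indirect = pat$cost_indirect_discounted[1])),
    class = "patient_trajectory")
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat(sprintf("<patient_trajectory> %s: %d event(s), LY %.2f, QALY %.3f\n",
              x$policy, nrow(x$events), x$ly, x$qaly))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Patient-level microsimulation of a policy arm
#'
#' Simulates `n_patients` independent trajectories (see [simulate_patient()]
#' for the event model) and averages their accruals, reporting Monte-Carlo
#' standard errors. Serves as the independent oracle against which the
#' deterministic cohort engine is validated: every cohort expectation must
#' lie within sampling error of the microsimulation estimate.
#'
#' @param params An `esrd_parameters` object.
#' @param settings An `analysis_settings`; `settings$policy` selects the arm.
#' @param n_patients Number of simulated patients, `>= 1`.
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param keep_patients Also return the per-patient accrual table (and, for
#'   small `n_patients`, per-patient event lists).
#' @return Object of class `microsim_result`: `estimate` and `mc_se` named
#'   vectors (`ly`, `qaly`, `qaly_discounted`, `cost_discounted_societal`,
#'   `cost_discounted_provider`), `n_patients`, and optionally `patients` /
#'   `events`.
#' @export
run_microsim <- function(params, settings, n_patients = 10000L, seed = 1L,
                         keep_patients = FALSE) {
  stopifnot(inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  n <- as.integer(n_patients)
  if (is.na(n) || n < 1L) stop("n_patients must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pat <- if (settings$policy == "SUPPORTIVE")
    .microsim_supportive(params, settings, n, keep_events = keep_patients && n <= 100L)
  else
    .microsim_dialysis(params, settings, n, keep_events = keep_patients && n <= 100L)
  df <- pat$patients
  df$cost_discounted_societal <- df$cost_direct_medical_discounted +
    df$cost_direct_nonmedical_discounted + df$cost_indirect_discounted
  df$cost_discounted_provider <- df$cost_direct_medical_discounted
  cols <- c("ly", "qaly", "qaly_discounted",
            "cost_discounted_societal", "cost_discounted_provider")
  est <- vapply(cols, function(cl) mean(df[[cl]]), 0)
  se <- vapply(cols, function(cl) stats::sd(df[[cl]]) / sqrt(n), 0)
  structure(list(estimate = est, mc_se = se, n_patients = n,
                 policy = settings$policy,
                 patients = if (keep_patients) df,
                 events = pat$events),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s, n = %d patients\n", x$policy, x$n_patients))
  for (nm in names(x$estimate))
    cat(sprintf("  %-26s %14.4f (MC SE %.4f)\n", nm, x$estimate[[nm]], x$mc_se[[nm]]))
  invisible(x)
}

.microsim_dialysis <- function(params, settings, n, keep_events = FALSE) {
  pm <- function(nm) param_mean(params, nm)
  H <- settings$horizon_years
  r <- settings$discount_rate
  cmf <- settings$complication_months / 12
  p_sw <- c(PD = pm("p_switch_pd_to_hd"), HD = pm("p_switch_hd_to_pd"))
  p_comp <- c(PD = pm("p_peritonitis_pd"), HD = pm("p_vascular_complication_hd"))
  maint <- c(PD = pm("cost_maintenance_pd_annual"), HD = pm("cost_maintenance_hd_annual"))
  comp_cost <- c(PD = pm("cost_complication_pd_annual"), HD = pm("cost_complication_hd_annual"))
  init <- c(PD = pm("cost_initial_pd"), HD = pm("cost_initial_hd"))
  nonmed <- c(PD = pm("cost_nonmedical_pd_annual"), HD = pm("cost_nonmedical_hd_annual"))
  indir <- c(PD = pm("cost_indirect_pd_annual"), HD = pm("cost_indirect_hd_annual"))
  u <- c(PD = pm("utility_pd"), HD = pm("utility_hd"))
  u_comp <- c(PD = pm("utility_pd_complication"), HD = pm("utility_hd_complication"))
  q <- effective_death_prob(params, seq_len(H))

  alive <- rep(TRUE, n)
  on_pd <- rep(settings$policy == "PD_FIRST", n)
  ly <- qaly <- qalyd <- numeric(n)
  cmed <- rep(init[[if (settings$policy == "PD_FIRST") "PD" else "HD"]], n)
  cnonmed <- cind <- numeric(n)
  events <- if (keep_events)
    lapply(seq_len(n), function(i)
      data.frame(time_months = 0, event = "entry", stringsAsFactors = FALSE))
  add_ev <- function(i, time, what) {
    if (keep_events)
      events[[i]] <<- rbind(events[[i]],
                            data.frame(time_months = time, event = what,
                                       stringsAsFactors = FALSE))
  }
  for (t in seq_len(H)) {
    idx <- which(alive)
    if (!length(idx)) break
    k <- length(idx)
    dfc <- (1 + r)^(-(t - 1))
    dfo <- (1 + r)^(-t)
    s0 <- ifelse(on_pd[idx], "PD", "HD")
    # costs committed at cycle start in the start-of-cycle modality
    cmed[idx] <- cmed[idx] + dfc * maint[s0]
    comp_billed <- stats::runif(k) < p_comp[s0]
    cmed[idx] <- cmed[idx] + dfc * ifelse(comp_billed, comp_cost[s0], 0)
    cnonmed[idx] <- cnonmed[idx] + dfc * nonmed[s0]
    cind[idx] <- cind[idx] + dfc * indir[s0]
    switch_drawn <- stats::runif(k) < p_sw[s0]
    if (settings$apply_initiation_cost_on_switch) {
      target <- ifelse(on_pd[idx], "HD", "PD")
      cmed[idx] <- cmed[idx] + dfc * ifelse(switch_drawn, init[target], 0)
    }
    died <- stats::runif(k) < q[t]
    # survivors take the drawn switch and live the year in the new modality
    surv_idx <- idx[!died]
    sw_surv <- switch_drawn[!died]
    on_pd[surv_idx[sw_surv]] <- !on_pd[surv_idx[sw_surv]]
    s1 <- ifelse(on_pd[surv_idx], "PD", "HD")
    comp_epi <- stats::runif(length(surv_idx)) < p_comp[s1]
    uy <- ifelse(comp_epi,
                 (1 - cmf) * u[s1] + cmf * u_comp[s1],
                 u[s1])
    ly[surv_idx] <- ly[surv_idx] + 1
    qaly[surv_idx] <- qaly[surv_idx] + uy
    qalyd[surv_idx] <- qalyd[surv_idx] + dfo * uy
    alive[idx[died]] <- FALSE
    if (keep_events) {
      for (j in seq_along(surv_idx)) {
        if (sw_surv[j])
          add_ev(surv_idx[j], 12 * (t - 1),
                 if (on_pd[surv_idx[j]]) "switch_to_pd" else "switch_to_hd")
        if (comp_epi[j]) add_ev(surv_idx[j], 12 * (t - 1) + 1, "complication")
      }
      for (i in idx[died]) add_ev(i, 12 * t, "death")
    }
  }
  list(patients = data.frame(
    ly = ly, qaly = qaly, qaly_discounted = qalyd,
    cost_direct_medical_discounted = cmed,
    cost_direct_nonmedical_discounted = cnonmed,
    cost_indirect_discounted = cind),
    events = events)
}

.microsim_supportive <- function(params, settings, n, keep_events = FALSE) {
  pm <- function(nm) param_mean(params, nm)
  p <- pm("p_death_supportive_per_month")
  r <- settings$discount_rate
  max_m <- settings$horizon_years * 12L
  # months lived; the month of death is lived, so death month ~ 1 + geometric
  t_death <- pmin(stats::rgeom(n, p) + 1L, max_m)
  m <- seq_len(max_m)
  disc_out <- cumsum((1 + r)^(-m / 12))        # outcomes discounted at month end
  disc_cost <- cumsum((1 + r)^(-(m - 1) / 12)) # costs discounted at month start
  u <- pm("utility_supportive")
  patients <- data.frame(
    ly = t_death / 12,
    qaly = t_death * u / 12,
    qaly_discounted = disc_out[t_death] * u / 12,
    cost_direct_medical_discounted = disc_cost[t_death] * pm("cost_supportive"),
    cost_direct_nonmedical_discounted =
      rep(pm("cost_nonmedical_supportive_lifetime"), n),
    cost_indirect_discounted = numeric(n))
  events <- if (keep_events)
    lapply(seq_len(n), function(i)
      data.frame(time_months = c(0, t_death[i]),
                 event = c("entry", "death"), stringsAsFactors = FALSE))
  list(patients = patients, events = events)
}

#' Generate a synthetic patient cost/utility survey
#'
#' Emulates the questionnaire data behind the household (direct non-medical)
#' costs, indirect costs and EQ-5D utilities: per-patient values drawn from
#' the moment-matched input distributions, so sample moments of a large
#' survey converge to the published means and standard errors (a
#' re-estimation round trip). The per-patient sampling distribution reuses
#' the between-patient spread implied by the reported standard errors of the
#' means scaled back to individual level via `sd = se * sqrt(n_study)` with
#' the study arm size of 52 patients per modality.
#'
#' @param params An `esrd_parameters` object.
#' @param n Number of patients to generate, `>= 1`.
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param modality `"both"` (default; alternating PD/HD), `"PD"` or `"HD"`.
#' @param n_study Study arm size used to scale standard errors of the mean
#'   to patient-level standard deviations (default 52).
#' @return Data.frame with columns `patient_id`, `modality`,
#'   `cost_nonmedical_annual`, `cost_indirect_annual`, `utility`,
#'   `utility_complication`.
#' @export
generate_synthetic_survey <- function(params, n, seed = 1L,
                                      modality = c("both", "PD", "HD"),
                                      n_study = 52L) {
  stopifnot(inherits(params, "esrd_parameters"))
  modality <- match.arg(modality)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mod <- switch(modality,
                both = rep_len(c("PD", "HD"), n),
                PD = rep("PD", n), HD = rep("HD", n))
  draw_for <- function(name_pd, name_hd, bounded) {
    vapply(mod, function(md) {
      est <- params$estimates[[if (md == "PD") name_pd else name_hd]]
      sd_i <- est$se * sqrt(n_study)  # patient-level spread
      if (sd_i == 0) return(est$mean)
      if (bounded) {
        if (sd_i^2 >= est$mean * (1 - est$mean))
          sd_i <- sqrt(est$mean * (1 - est$mean)) * 0.99
        ab <- beta_from_moments(est$mean, sd_i)
        stats::rbeta(1, ab[["shape1"]], ab[["shape2"]])
      } else {
        ks <- gamma_from_moments(est$mean, sd_i)
        stats::rgamma(1, shape = ks[["shape"]], scale = ks[["scale"]])
      }
    }, 0, USE.NAMES = FALSE)
  }
  data.frame(
    patient_id = seq_len(n),
    modality = mod,
    cost_nonmedical_annual = draw_for("cost_nonmedical_pd_annual",
                                      "cost_nonmedical_hd_annual", FALSE),
    cost_indirect_annual = draw_for("cost_indirect_pd_annual",
                                    "cost_indirect_hd_annual", FALSE),
    utility = draw_for("utility_pd", "utility_hd", TRUE),
    utility_complication = draw_for("utility_pd_complication",
                                    "utility_hd_complication", TRUE),
    stringsAsFactors = FALSE)
}

#' Refit parameter estimates from a synthetic survey
#'
#' Re-estimates the mean and standard error of the mean for one modality's
#' survey columns, the inverse of [generate_synthetic_survey()]; used to
#' check the survey round trip.
#'
#' @param survey A data.frame from [generate_synthetic_survey()].
#' @param modality `"PD"` or `"HD"`.
#' @return Named list of `parameter_estimate`s for the four survey columns.
#' @export
refit_survey_estimates <- function(survey, modality = c("PD", "HD")) {
  modality <- match.arg(modality)
  d <- survey[survey$modality == modality, , drop = FALSE]
  if (!nrow(d)) stop("no rows for modality ", modality)
  fit <- function(x, family) parameter_estimate(
    mean(x), stats::sd(x) / sqrt(length(x)), family)
  list(cost_nonmedical_annual = fit(d$cost_nonmedical_annual, "gamma"),
       cost_indirect_annual = fit(d$cost_indirect_annual, "gamma"),
       utility = fit(d$utility, "beta"),
       utility_complication = fit(d$utility_complication, "beta"))
}
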