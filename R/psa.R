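#' Draw one parameter set from the input distributions
#'
#' Replaces every parameter that has `se > 0` and a non-fixed family by a
#' draw from its moment-matched distribution: Beta for probabilities and
#' utilities, Gamma for costs. The two complication probabilities that carry
#' a Gamma family are drawn from the fitted Gamma and truncated to `[0, 1]`.
#' Parameters with `se = 0` (or `family = "fixed"`) pass through unchanged,
#' so a fully fixed set reproduces the base case through the same code path.
#' The supportive-care utility is re-derived from the sampled
#' dialysis-with-complication utility.
#'
#' Draws consume the current R RNG stream (set a seed beforehand for
#' reproducibility); the draw order is fixed (survival years, then scalar
#' parameters in canonical order).
#'
#' @param params Base `esrd_parameters`.
#' @return A new `esrd_parameters` whose means are the sampled values.
#' @export
sample_parameter_set <- function(params) {
  stopifnot(inherits(params, "esrd_parameters"))
  draw <- function(est, name) {
    if (est$family == "fixed" || est$se == 0) return(est)
    bounded <- .is_prob_name(name) || .is_utility_name(name) ||
      startsWith(name, "survival")
    val <- if (est$family == "beta") {
      ab <- beta_from_moments(est$mean, est$se)
      stats::rbeta(1, ab[["shape1"]], ab[["shape2"]])
    } else {
      ks <- gamma_from_moments(est$mean, est$se)
      x <- stats::rgamma(1, shape = ks[["shape"]], scale = ks[["scale"]])
      if (bounded) min(x, 1) else x  # truncate Gamma-family probabilities
    }
    est$mean <- val
    est
  }
  survival <- params$survival
  for (i in seq_along(survival))
    survival[[i]] <- draw(survival[[i]], paste0("survival_year_", i))
  estimates <- params$estimates[.param_names]
  for (nm in .param_names) estimates[[nm]] <- draw(estimates[[nm]], nm)
  .new_esrd_parameters(survival, estimates)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: each iteration draws one
#' parameter set ([sample_parameter_set()]) and runs the full deterministic
#' model for all three policies with that shared draw (common random numbers
#' across policies, which reduces the variance of incremental quantities).
#'
#' @param params Base `esrd_parameters`.
#' @param settings An `analysis_settings`; `psa_draws` and `seed` control the
#'   simulation.
#' @return Object of class `psa_result`: `draws` data.frame (one row per
#'   draw and policy with LY, QALYs and costs), `n_draws`, `seed`,
#'   `settings`, plus `mean_icer`, the across-draw average ICER of each
#'   dialysis policy against supportive care.
#' @export
run_psa <- function(params, settings = analysis_settings()) {
  stopifnot(inherits(params, "esrd_parameters"),
            inherits(settings, "analysis_settings"))
  n <- settings$psa_draws
  policies <- c("PD_FIRST", "HD_FIRST", "SUPPORTIVE")
  set.seed(settings$seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    drawn <- sample_parameter_set(params)
    res <- lapply(policies, function(p) {
      s <- .with_policy(settings, p)
      accrue_outcomes(run_trace(drawn, s), drawn, s)
    })
    rows[[i]] <- data.frame(
      draw = i, policy = policies,
      ly_undiscounted = vapply(res, function(o) o$ly_undiscounted, 0),
      qaly_undiscounted = vapply(res, function(o) o$qaly_undiscounted, 0),
      qaly_discounted = vapply(res, function(o) o$qaly_discounted, 0),
      cost_discounted_societal = vapply(res, function(o) o$cost_discounted_societal, 0),
      cost_discounted_provider = vapply(res, function(o) o$cost_discounted_provider, 0),
      stringsAsFactors = FALSE)
  }
  draws <- do.call(rbind, rows)
  rownames(draws) <- NULL
  cost_col <- paste0("cost_discounted_", settings$perspective)
  per_draw_icer <- function(policy) {
    a <- draws[draws$policy == policy, ]
    s <- draws[draws$policy == "SUPPORTIVE", ]
    (a[[cost_col]] - s[[cost_col]]) / (a$qaly_discounted - s$qaly_discounted)
  }
  mean_icer <- c(PD_FIRST = mean(per_draw_icer("PD_FIRST")),
                 HD_FIRST = mean(per_draw_icer("HD_FIRST")))
  structure(list(draws = draws, n_draws = n, seed = settings$seed,
                 settings = settings, mean_icer = mean_icer),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d), %s perspective\n",
              x$n_draws, x$seed, x$settings$perspective))
  cat(sprintf("  mean ICER vs supportive care: PD-first %.1f M, HD-first %.1f M IDR/QALY\n",
              x$mean_icer[["PD_FIRST"]] / 1e6, x$mean_icer[["HD_FIRST"]] / 1e6))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each policy has
#' the highest net monetary benefit across PSA draws; ties are split equally
#' among the tied policies, so probabilities sum to one at every grid point.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Strictly increasing non-negative WTP grid in IDR per QALY
#'   (default: the grid in the PSA's settings).
#' @param perspective Costing perspective (default: the PSA's).
#' @return Object of class `ceac_curve`: data.frame `curve` with column
#'   `wtp` and one probability column per policy.
#' @export
ceac <- function(psa, wtp_grid = NULL, perspective = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  wtp_grid <- wtp_grid %||% psa$settings$wtp_grid
  if (!length(wtp_grid)) stop("ceac: empty wtp grid")
  if (is.unsorted(wtp_grid, strictly = TRUE) || any(wtp_grid < 0))
    stop("ceac: wtp_grid must be strictly increasing and non-negative")
  perspective <- perspective %||% psa$settings$perspective
  cost_col <- paste0("cost_discounted_", perspective)
  policies <- unique(psa$draws$policy)
  q <- sapply(policies, function(p) psa$draws$qaly_discounted[psa$draws$policy == p])
  cost <- sapply(policies, function(p) psa$draws[[cost_col]][psa$draws$policy == p])
  q <- matrix(q, ncol = length(policies)); cost <- matrix(cost, ncol = length(policies))
  probs <- t(vapply(wtp_grid, function(w) {
    nmb <- w * q - cost
    best <- nmb == apply(nmb, 1, max)
    colMeans(best / rowSums(best))  # ties split equally
  }, numeric(length(policies))))
  curve <- data.frame(wtp = wtp_grid, probs)
  names(curve) <- c("wtp", policies)
  structure(list(curve = curve, policies = policies, perspective = perspective),
            class = "ceac_curve")
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat(sprintf("<ceac_curve> %d WTP points, %s perspective\n",
              nrow(x$curve), x$perspective))
  for (p in x$policies) {
    w <- ceac_crossing(x, p)
    cat(sprintf("  %s first most-probable at WTP %s\n", p,
                if (is.na(w)) "never (on this grid)"
                else sprintf("%.0f M IDR/QALY", w / 1e6)))
  }
  invisible(x)
}

#' First willingness-to-pay at which a policy leads the CEAC
#'
#' Smallest grid WTP at which the policy's probability of being optimal
#' strictly exceeds every other policy's.
#'
#' @param curve A `ceac_curve`.
#' @param policy Policy name present in the curve.
#' @return WTP in IDR per QALY, or `NA` (the "never" sentinel) if the policy
#'   never leads on the grid.
#' @export
ceac_crossing <- function(curve, policy) {
  stopifnot(inherits(curve, "ceac_curve"))
  if (!policy %in% curve$policies) stop("policy not in curve: ", policy)
  others <- setdiff(curve$policies, policy)
  p_self <- curve$curve[[policy]]
  lead <- if (length(others)) {
    p_other <- as.matrix(curve$curve[, others, drop = FALSE])
    p_self > apply(p_other, 1, max)
  } else rep(TRUE, length(p_self))
  if (!any(lead)) return(NA_real_)
  curve$curve$wtp[which(lead)[1]]
}

#' Export PSA draws / CEAC as CSV
#'
#' `write_psa_csv` writes one row per draw and policy (suitable for
#' incremental cost-effectiveness scatterplots); `write_ceac_csv` writes the
#' acceptability curve (WTP plus one probability column per policy).
#'
#' @param psa A `psa_result`.
#' @param curve A `ceac_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "psa_result"))
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @export
write_ceac_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ceac_curve"))
  utils::write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}
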