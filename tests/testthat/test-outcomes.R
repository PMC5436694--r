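test_that("discount factor follows (1+r)^-t", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 1), 0.97087, tolerance = 1e-5)
  expect_equal(discount_factor(0, c(1, 10, 50)), rep(1, 3))
  expect_error(discount_factor(-0.01, 1), ">= 0")
  expect_error(discount_factor(0.03, -1), ">= 0")
})

# independent brute-force accumulation: explicit per-month scalar loop over the
# trace, recomputing every stream from the raw parameters
brute_force_accrual <- function(trace, params, settings) {
  pm <- function(nm) param_mean(params, nm)
  r <- settings$discount_rate
  ly <- q <- qd <- cmed <- cnon <- cind <- 0
  if (trace$cycle_unit == "year") {
    cm <- settings$complication_months
    for (i in seq_len(nrow(trace$cycles))) {
      row <- trace$cycles[i, ]
      t <- row$cycle_index
      dfc <- (1 + r)^(-(t - 1)); dfo <- (1 + r)^(-t)
      surv <- 1 - row$occ_dead
      for (mo in 1:12) {
        # costs: one-twelfth slices, all committed at cycle start
        for (s in c("pd", "hd")) {
          w0 <- row$alive_start * (if (s == "pd") row$mix_pd_start else 1 - row$mix_pd_start)
          maint <- pm(paste0("cost_maintenance_", s, "_annual"))
          pcomp <- pm(if (s == "pd") "p_peritonitis_pd" else "p_vascular_complication_hd")
          ccomp <- pm(paste0("cost_complication_", s, "_annual"))
          cmed <- cmed + dfc * w0 * (maint + pcomp * ccomp) / 12
          cnon <- cnon + dfc * w0 * pm(paste0("cost_nonmedical_", s, "_annual")) / 12
          cind <- cind + dfc * w0 * pm(paste0("cost_indirect_", s, "_annual")) / 12
          # outcomes: survivors in the end-of-cycle modality; the first
          # complication months of the year carry the complication utility
          w1 <- surv * (if (s == "pd") row$mix_pd_end else 1 - row$mix_pd_end)
          ub <- pm(paste0("utility_", s))
          uc <- pm(paste0("utility_", s, "_complication"))
          um <- (1 - pcomp) * ub + pcomp * (if (mo <= cm) uc else ub)
          ly <- ly + w1 / 12
          q <- q + w1 * um / 12
          qd <- qd + dfo * w1 * um / 12
        }
      }
      if (settings$apply_initiation_cost_on_switch)
        cmed <- cmed + dfc * row$alive_start *
          (row$mix_pd_start * pm("p_switch_pd_to_hd") * pm("cost_initial_hd") +
           (1 - row$mix_pd_start) * pm("p_switch_hd_to_pd") * pm("cost_initial_pd"))
    }
    cmed <- cmed + pm(paste0("cost_initial_",
                             if (settings$policy == "PD_FIRST") "pd" else "hd"))
  } else {
    for (i in seq_len(nrow(trace$cycles))) {
      row <- trace$cycles[i, ]
      t <- row$cycle_index
      dfc <- (1 + r)^(-(t - 1) / 12); dfo <- (1 + r)^(-t / 12)
      cmed <- cmed + dfc * row$alive_start * pm("cost_supportive")
      ly <- ly + row$alive_start / 12
      q <- q + row$alive_start * pm("utility_supportive") / 12
      qd <- qd + dfo * row$alive_start * pm("utility_supportive") / 12
    }
    cnon <- pm("cost_nonmedical_supportive_lifetime")
  }
  list(ly = ly, qaly = q, qaly_discounted = qd,
       societal = cmed + cnon + cind, provider = cmed)
}

test_that("accrual matches an independent brute-force per-month accumulation", {
  for (spec in list(list("PD_FIRST", 1), list("HD_FIRST", 3),
                    list("SUPPORTIVE", 1), list("PD_FIRST", 4))) {
    prm <- random_params(spec[[2]] + 10)
    s <- default_settings(spec[[1]])
    tr <- run_trace(prm, s)
    out <- accrue_outcomes(tr, prm, s)
    bf <- brute_force_accrual(tr, prm, s)
    expect_equal(out$ly_undiscounted, bf$ly, tolerance = 1e-6)
    expect_equal(out$qaly_undiscounted, bf$qaly, tolerance = 1e-6)
    expect_equal(out$qaly_discounted, bf$qaly_discounted, tolerance = 1e-6)
    expect_equal(out$cost_discounted_societal, bf$societal, tolerance = 1e-6)
    expect_equal(out$cost_discounted_provider, bf$provider, tolerance = 1e-6)
  }
})

test_that("outcome invariants hold: bounds, discounting shrinkage, perspective ordering", {
  for (pol in c("PD_FIRST", "HD_FIRST", "SUPPORTIVE")) {
    s <- default_settings(pol)
    out <- accrue_outcomes(run_trace(table1, s), table1, s)
    expect_lte(out$qaly_undiscounted, out$ly_undiscounted)
    expect_lt(out$qaly_discounted, out$qaly_undiscounted)
    expect_lt(out$cost_discounted_societal, out$cost_undiscounted_societal)
    expect_lte(out$cost_discounted_provider, out$cost_discounted_societal)
  }
})

test_that("zero discounting and unit utility collapse QALYs onto life years", {
  prm <- table1
  prm$estimates$utility_pd$mean <- 1
  prm$estimates$utility_hd$mean <- 1
  prm$estimates$utility_pd_complication$mean <- 1
  prm$estimates$utility_hd_complication$mean <- 1
  s <- default_settings("PD_FIRST", discount_rate = 0)
  out <- accrue_outcomes(run_trace(prm, s), prm, s)
  expect_equal(out$qaly_discounted, out$ly_undiscounted, tolerance = 1e-12)
  expect_equal(out$qaly_undiscounted, out$ly_undiscounted, tolerance = 1e-12)
})

test_that("societal minus provider cost equals the recomputed household stream", {
  s <- default_settings("HD_FIRST")
  tr <- run_trace(table1, s)
  out <- accrue_outcomes(tr, table1, s)
  cy <- tr$cycles
  dfc <- discount_factor(s$discount_rate, cy$cycle_index - 1)
  household <- sum(dfc * cy$alive_start *
    (cy$mix_pd_start * (1554789 + 1743783) +
     (1 - cy$mix_pd_start) * (9004780 + 3156480)))
  expect_equal(out$cost_discounted_societal - out$cost_discounted_provider,
               household, tolerance = 1e-9)
})

test_that("perspective-mismatched component requests are rejected", {
  s <- default_settings("PD_FIRST")
  out <- accrue_outcomes(run_trace(table1, s), table1, s)
  expect_named(cost_components(out, "provider"), "direct_medical")
  expect_length(cost_components(out, "societal"), 3L)
  expect_error(cost_components(out, "provider", component = "indirect"),
               "perspective mismatch")
  expect_error(cost_components(out, "societal", component = "rent"), "unknown")
})

test_that("ICER arithmetic, dominance flags and scale equivariance", {
  mk <- function(cost, qaly) structure(list(
    policy = "X", perspective = "societal", discount_rate = 0.03,
    qaly_discounted = qaly, cost_discounted_societal = cost,
    cost_discounted_provider = cost), class = "policy_outcome")
  r <- icer(mk(100, 4), mk(0, 2))
  expect_equal(r$icer, 50)
  expect_identical(r$status, "icer")
  # published totals: HD-first costs more and yields fewer QALYs than PD-first
  expect_identical(icer(mk(735.4e6, 4.34), mk(696.6e6, 4.40))$status, "dominated")
  expect_identical(icer(mk(696.6e6, 4.40), mk(735.4e6, 4.34))$status, "dominant")
  expect_identical(icer(mk(1, 1), mk(1, 1))$status, "equivalent")
  k <- 3.7
  expect_equal(icer(mk(k * 100, 4), mk(0, 2))$icer, k * 50)
  bad <- mk(1, 1); bad$discount_rate <- 0.05
  expect_error(icer(bad, mk(0, 2)), "discount rates")
})

test_that("net monetary benefit follows wtp * QALY - cost", {
  mk <- function(cost, qaly) structure(list(
    policy = "X", perspective = "societal", discount_rate = 0.03,
    qaly_discounted = qaly, cost_discounted_societal = cost,
    cost_discounted_provider = cost), class = "policy_outcome")
  expect_equal(net_monetary_benefit(mk(1.7e6, 0.076), 43e6), 1.568e6)
  expect_equal(net_monetary_benefit(mk(5, 1), 0), -5)
  # NMB ordering between two options flips exactly at their ICER
  a <- mk(100, 4); b <- mk(0, 2)
  for (w in seq(0, 100, by = 5)) {
    pref_nmb <- net_monetary_benefit(a, w) > net_monetary_benefit(b, w)
    expect_identical(pref_nmb, w > icer(a, b)$icer)
  }
})

test_that("frontier removes dominated and extendedly dominated options", {
  mk <- function(pol, cost, qaly) structure(list(
    policy = pol, perspective = "societal", discount_rate = 0.03,
    qaly_discounted = qaly, cost_discounted_societal = cost,
    cost_discounted_provider = cost), class = "policy_outcome")
  # published pattern: supportive cheap, PD-first efficient, HD-first dominated
  fr <- frontier(list(mk("SUP", 1.7e6, 0.076), mk("PD", 696.6e6, 4.40),
                      mk("HD", 735.4e6, 4.34)))
  expect_setequal(fr$frontier, c("SUP", "PD"))
  expect_identical(fr$table$status[fr$table$policy == "HD"], "dominated")
  expect_false(any(is.na(fr$table$icer[fr$table$policy == "PD"])))

  fr1 <- frontier(list(mk("ONLY", 10, 1)))
  expect_identical(fr1$frontier, "ONLY")
  expect_true(all(is.na(fr1$table$icer)))

  # three collinear points: the middle option is extendedly dominated
  fr3 <- frontier(list(mk("A", 0, 0), mk("B", 50, 1), mk("C", 100, 2)))
  expect_identical(fr3$table$status[fr3$table$policy == "B"],
                   "extendedly_dominated")
  # extended dominance proper: middle above the A-C segment
  fr4 <- frontier(list(mk("A", 0, 0), mk("B", 80, 1), mk("C", 100, 2)))
  expect_identical(fr4$table$status[fr4$table$policy == "B"],
                   "extendedly_dominated")
  expect_setequal(fr4$frontier, c("A", "C"))
})

test_that("deterministic CEA table carries all policies and both perspectives", {
  res <- run_cea(table1, default_settings())
  expect_setequal(res$table$policy, c("PD_FIRST", "HD_FIRST", "SUPPORTIVE"))
  expect_true(all(res$table$cost_discounted_provider <=
                  res$table$cost_discounted_societal))
  expect_identical(res$frontier$table$status[
    res$frontier$table$policy == "HD_FIRST"], "dominated")
})

test_that("trace CSV export has the documented tidy layout", {
  s <- default_settings("PD_FIRST")
  tr <- run_trace(table1, s)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, table1, s, f)
  df <- read.csv(f)
  expect_true(all(c("cycle_index", "time_years", "state", "occupancy", "ly",
                    "qaly", "cost_direct_medical", "cost_direct_nonmedical",
                    "cost_indirect") %in% names(df)))
  expect_equal(nrow(df), nrow(tr$cycles) * 6L)
})
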