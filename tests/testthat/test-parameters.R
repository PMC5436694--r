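test_that("beta moment matching reproduces the requested moments", {
  cases <- list(c(0.224, 0.0018), c(0.405, 0.159), c(0.82, 0.03), c(0.37, 0.11))
  for (cs in cases) {
    ab <- beta_from_moments(cs[1], cs[2])
    m <- ab[["shape1"]] / sum(ab)
    v <- prod(ab) / (sum(ab)^2 * (sum(ab) + 1))
    expect_equal(m, cs[1], tolerance = 1e-12)
    expect_equal(sqrt(v), cs[2], tolerance = 1e-10)
  }
  # first-year survival parameter: very tight Beta
  ab <- beta_from_moments(0.224, 0.0018)
  expect_equal(unname(ab), c(12017.24, 41631.14), tolerance = 1e-6)
})

test_that("beta moment matching rejects infeasible or out-of-range inputs", {
  expect_error(beta_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_from_moments(0.5, sqrt(0.25)), "infeasible")
  expect_error(beta_from_moments(0, 0.1), "inside")
  expect_error(beta_from_moments(1.2, 0.1), "inside")
})

test_that("gamma moment matching reproduces the requested moments", {
  ks <- gamma_from_moments(444400, 444400)
  expect_equal(unname(ks), c(1, 444400))
  ks <- gamma_from_moments(88926820, 2978939)
  expect_equal(ks[["shape"]], (88926820 / 2978939)^2)
  expect_equal(ks[["scale"]], 2978939^2 / 88926820)
  expect_equal(ks[["shape"]], 891.1, tolerance = 1e-3)
  ks <- gamma_from_moments(13724975, 141669)
  expect_equal(ks[["shape"]] * ks[["scale"]], 13724975, tolerance = 1e-9)
  expect_error(gamma_from_moments(-1, 1), "positive")
  expect_error(gamma_from_moments(1, 0), "positive")
})

test_that("moment matching inverts the analytic moment formulas on random inputs", {
  set.seed(101)
  for (i in 1:50) {
    m <- runif(1, 0.01, 0.99)
    s <- runif(1, 1e-4, 0.95) * sqrt(m * (1 - m))
    ab <- beta_from_moments(m, s)
    expect_equal(ab[["shape1"]] / sum(ab), m, tolerance = 1e-12)
    expect_equal(prod(ab) / (sum(ab)^2 * (sum(ab) + 1)), s^2, tolerance = 1e-12)
    mu <- runif(1, 1, 1e8); sd <- runif(1, 0.01, 3) * mu
    ks <- gamma_from_moments(mu, sd)
    expect_equal(ks[["shape"]] * ks[["scale"]], mu, tolerance = 1e-9)
    expect_equal(ks[["shape"]] * ks[["scale"]]^2, sd^2, tolerance = 1e-6)
  }
})

test_that("bundled defaults reproduce the published input table", {
  expect_s3_class(table1, "esrd_parameters")
  expect_equal(param_mean(table1, "cost_maintenance_hd_annual"), 110402541)
  expect_equal(param_mean(table1, "cost_initial_pd"), 13724975)
  expect_equal(param_mean(table1, "p_switch_pd_to_hd"), 0.350)
  expect_equal(param_mean(table1, "utility_pd"), 0.82)
  expect_equal(vapply(table1$survival, function(e) e$mean, 0),
               c(0.224, 0.135, 0.122, 0.059, 0.063, 0.146))
  expect_equal(table1$estimates$cost_supportive$se, 444400)
  # supportive-care utility is derived from dialysis-with-complication (HD)
  expect_equal(param_mean(table1, "utility_supportive"),
               param_mean(table1, "utility_hd_complication"))
})

test_that("config loading rejects invalid or incomplete files", {
  cfg <- yaml::read_yaml(system.file("extdata", "table1_defaults.yaml",
                                     package = "dialysisCEA"))
  f <- withr::local_tempfile(fileext = ".yaml")

  bad <- cfg; bad$parameters$utility_pd$mean <- 1.4
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "utility_pd")

  bad <- cfg; bad$parameters$p_switch_pd_to_hd <- NULL
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "p_switch_pd_to_hd")

  bad <- cfg; bad$parameters$utility_hd$family <- "lognormal"
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "family")

  expect_error(load_parameters(tempfile()), "not found")
})

test_that("parameter serialization round trips (YAML and CSV)", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(table1, f)
  expect_equal(load_parameters(f), table1)

  g <- withr::local_tempfile(fileext = ".csv")
  parameters_to_csv(table1, g)
  back <- parameters_from_csv(g)
  expect_equal(vapply(back$estimates, function(e) e$mean, 0),
               vapply(table1$estimates, function(e) e$mean, 0))
  expect_equal(vapply(back$survival, function(e) e$se, 0),
               vapply(table1$survival, function(e) e$se, 0))
})

test_that("validation reports gamma-family probabilities as warnings, bad values as errors", {
  diag <- validate_parameters(table1)
  expect_true(all(diag$level == "warning"))
  # the input table assigns Gamma to both complication probabilities
  expect_setequal(diag$parameter,
                  c("p_peritonitis_pd", "p_vascular_complication_hd"))

  expect_identical(nrow(validate_parameters(fix_all(table1))), 0L)

  bad <- table1
  bad$estimates$cost_initial_hd$mean <- -5
  diag <- validate_parameters(bad)
  expect_true(any(diag$level == "error" & diag$parameter == "cost_initial_hd"))

  bad <- table1
  bad$estimates$p_switch_pd_to_hd$se <- 0.5  # se^2 > mean(1-mean)
  diag <- validate_parameters(bad)
  expect_true(any(diag$rule == "beta_feasible"))
})

test_that("sampling the fitted distributions recovers the stated means", {
  # moment round trip at scale: 1e5 draws per parameter, tolerance 4*se/sqrt(n)
  set.seed(202)
  n <- 1e5
  all_est <- c(table1$survival, table1$estimates[
    vapply(table1$estimates, function(e) e$se > 0, TRUE)])
  for (est in all_est) {
    if (est$family == "beta") {
      ab <- beta_from_moments(est$mean, est$se)
      x <- rbeta(n, ab[["shape1"]], ab[["shape2"]])
    } else {
      ks <- gamma_from_moments(est$mean, est$se)
      x <- rgamma(n, shape = ks[["shape"]], scale = ks[["scale"]])
    }
    expect_lt(abs(mean(x) - est$mean), 4 * est$se / sqrt(n))
  }
})
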