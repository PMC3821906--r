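test_that("noiseless minimal-model data are recovered within 1 percent", {
  syn <- generate_timecourse(quick_m_scenario(seed = 3, noise_cv = 0))
  f <- fit_model(syn$tc, "M", quick_cfg(n_starts = 10))
  truth <- c(V0 = 8.5, Td = 200, K = 15, D = 0.5)
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates[names(truth)] / truth - 1)), 0.01)
  expect_lt(f$sigma, 1e-3)
})

test_that("the fitted noise scale estimates the generating noise", {
  sig <- vapply(1:25, function(i) {
    syn <- generate_timecourse(quick_m_scenario(seed = 100 + i,
                                                noise_cv = 0.08))
    fit_model(syn$tc, "M", quick_cfg(n_starts = 4))$sigma
  }, 0)
  sdlog <- sqrt(log1p(0.08^2))   # lognormal CV 8% on the log scale
  expect_equal(mean(sig), sdlog, tolerance = 0.15)
})

test_that("underdetermined configurations are rejected", {
  tc <- timecourse(data.frame(day = c(-7, 0, 5), volume_cc = c(2, 2.1, 1.9)),
                   make_schedule("S", 9))
  expect_error(fit_model(tc, "St", quick_cfg()), "underdetermined")
})

test_that("rescaling all volumes shifts only V0", {
  syn <- generate_timecourse(quick_m_scenario(seed = 4, noise_cv = 0.06))
  f1 <- fit_model(syn$tc, "M", quick_cfg())
  obs2 <- syn$tc$observations
  obs2$volume_cc <- 10 * obs2$volume_cc
  tc2 <- timecourse(obs2, syn$tc$schedule)
  f2 <- fit_model(tc2, "M", quick_cfg())
  expect_equal(f2$estimates[["V0"]] / f1$estimates[["V0"]], 10,
               tolerance = 0.01)
  for (p in c("Td", "K", "D"))
    expect_equal(f2$estimates[[p]], f1$estimates[[p]], tolerance = 0.02)
  expect_equal(f2$delta_percent, f1$delta_percent, tolerance = 0.05)
  expect_equal(f2$sigma, f1$sigma, tolerance = 0.01)
})

test_that("missing pretreatment data triggers the dual fixed-Td fits", {
  sp <- quick_m_scenario(seed = 5, noise_cv = 0.05)
  sp$planning_scan_day <- NULL
  syn <- generate_timecourse(sp)
  expect_false(syn$tc$pretreatment_available)
  f <- fit_model(syn$tc, "M", quick_cfg())
  expect_true(f$Td_fixed %in% c(25, 150))
  expect_false("Td" %in% f$free)
  alt <- f$alternate_td
  expect_s3_class(alt, "rt_fit")
  expect_true(alt$Td_fixed != f$Td_fixed)
  expect_gte(f$logL, alt$logL)
})

test_that("deterministic refit: same configuration, same result", {
  syn <- generate_timecourse(quick_m_scenario(seed = 6, noise_cv = 0.07))
  f1 <- fit_model(syn$tc, "M", quick_cfg(n_starts = 6))
  f2 <- fit_model(syn$tc, "M", quick_cfg(n_starts = 6))
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$logL, f2$logL)
})

test_that("profile interval endpoints sit at the likelihood drop", {
  syn <- generate_timecourse(quick_m_scenario(seed = 8, noise_cv = 0.05))
  f <- fit_model(syn$tc, "M", quick_cfg())
  iv <- profile_ci(f, "K")
  expect_lt(iv[["low"]], f$estimates[["K"]])
  expect_gt(iv[["high"]], f$estimates[["K"]])
  target <- f$logL - qchisq(0.95, 1) / 2
  # re-profile at the endpoints: the drop equation must hold
  for (v in iv) {
    free2 <- setdiff(f$free, "K")
    obj <- rtkinetics:::make_objective(f$tc, f$model, free2,
                                       c(f$fixed, K = v), f$cfg)
    run <- rtkinetics:::.optimize_from(
      obj, matrix(f$estimates[free2], nrow = 1,
                  dimnames = list(NULL, free2)),
      free2,
      vapply(free2, function(n) f$cfg$bounds[[n]][1], 0),
      vapply(free2, function(n) f$cfg$bounds[[n]][2], 0), 200)
    expect_equal(-run$value, target, tolerance = 0.05)
  }
})

test_that("a parameter at its bound yields a one-sided interval", {
  # constrain the kill below its generating value: the estimate pins to
  # the bound and the upper side is flagged as truncated there
  syn <- generate_timecourse(quick_m_scenario(seed = 12, noise_cv = 0.05))
  cfg <- quick_cfg(bounds = list(K = c(0, 5)))
  f <- fit_model(syn$tc, "M", cfg)
  expect_equal(f$estimates[["K"]], 5, tolerance = 1e-6)
  iv <- profile_ci(f, "K")
  expect_true(attr(iv, "truncated_high"))
  expect_equal(iv[["high"]], 5)
  expect_false(attr(iv, "truncated_low"))
})
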