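test_that("zero noise reproduces the model trajectory exactly", {
  syn <- generate_timecourse(quick_m_scenario(seed = 1, noise_cv = 0))
  expect_equal(syn$tc$observations$volume_cc, syn$truth$volume_cc)
  expect_false(any(syn$tc$observations$censored))
})

test_that("a fixed seed gives a bit-identical series", {
  sp <- quick_m_scenario(seed = 5, noise_cv = 0.07)
  a <- generate_timecourse(sp)
  b <- generate_timecourse(sp)
  expect_identical(a$tc$observations, b$tc$observations)
  sp2 <- quick_m_scenario(seed = 6, noise_cv = 0.07)
  expect_false(identical(generate_timecourse(sp2)$tc$observations,
                         a$tc$observations))
})

test_that("empirical noise CV converges to the requested level", {
  # pool log-residuals across independently seeded replicates
  r <- unlist(lapply(1:20, function(i) {
    syn <- generate_timecourse(quick_m_scenario(seed = 200 + i,
                                                noise_cv = 0.07))
    log(syn$tc$observations$volume_cc) - log(syn$truth$volume_cc)
  }))
  cv_hat <- sqrt(expm1(var(r)))
  expect_equal(cv_hat, 0.07, tolerance = 0.08)
  expect_equal(mean(r), 0, tolerance = 3 * sd(r) / sqrt(length(r)))
})

test_that("high-kill hypofractionation falls below the detection limit", {
  # compartment-kill truth with Kp = 99: the late follow-up is censored
  g <- growth_params(Td = 30, GF = 0.06, Tc = tc_from_tpot(30, 0.06, 23.6))
  e <- effect_model("St", Kp = 99, Kq = 23, D = 0.2)
  sp <- scenario_spec("S", g, e, V0 = 0.4, schedule = make_schedule("S", 12),
                      noise_cv = 0.05, detection_limit = 0.1, seed = 3)
  syn <- generate_timecourse(sp)
  obs <- syn$tc$observations
  expect_true(any(obs$censored))
  expect_true(all(obs$volume_cc >= sp$detection_limit))
  expect_equal(obs$volume_cc[obs$censored],
               rep(sp$detection_limit, sum(obs$censored)))
  # the underlying true volume is genuinely below the limit there
  expect_true(all(syn$truth$volume_cc[obs$censored] < sp$detection_limit))
})

test_that("archetype battery covers every response type per group", {
  suite <- archetype_suite(seed = 1)
  expect_length(suite, 7)
  grp <- vapply(suite, function(s) s$group, "")
  ty <- vapply(suite, function(s) s$expected_type, "")
  expect_equal(unname(sort(ty[grp == "L"])), c("A", "B", "C"))
  expect_equal(unname(sort(ty[grp == "S"])), c("A", "B", "C", "D"))
  # seeded reproducibly and distinctly
  expect_equal(length(unique(vapply(suite, function(s) s$seed, 1L))), 7)
})

test_that("archetype fits recover the intended types on clean data", {
  suite <- archetype_suite(seed = 23, noise_cv = 0)
  for (nm in c("L_C", "S_C", "S_D")) {   # minimal-model archetypes
    syn <- generate_timecourse(suite[[nm]])
    sel <- select_model(syn$tc, quick_cfg(n_starts = 8))
    expect_equal(classify_response(suite[[nm]]$group,
                                   rtkinetics:::fit_kill(sel$best),
                                   rtkinetics:::getp(sel$best$estimates, "D")),
                 suite[[nm]]$expected_type, info = nm)
  }
})

test_that("schedules honor the group calendars", {
  s9 <- make_schedule("S", 9)
  expect_equal(nrow(s9), 5)
  expect_true(all(s9$day >= 0 & s9$day <= 8))
  expect_true(all(s9$dose_gy == 10))
  expect_error(make_schedule("S", 15), "less than 14")

  l46 <- make_schedule("L", 46)
  expect_equal(nrow(l46), 30)
  expect_true(all(l46$day %% 7 < 5))       # weekdays only (day 0 = Monday)
  expect_true(all(l46$dose_gy == 2.5))
  expect_error(make_schedule("L", 10), "slots")
})

test_that("generated time courses round-trip through the CSV format", {
  syn <- generate_timecourse(quick_m_scenario(seed = 2, noise_cv = 0.05))
  obs_path <- tempfile(fileext = ".csv")
  sch_path <- tempfile(fileext = ".csv")
  syn$tc$patient_id <- "P1"
  write_timecourse(syn$tc, obs_path, sch_path)
  back <- read_timecourse(obs_path, sch_path,
                          detection_limit = syn$spec$detection_limit)
  expect_equal(back$observations$volume_cc, syn$tc$observations$volume_cc)
  expect_equal(back$schedule$day, syn$tc$schedule$day)
})
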