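test_that("a fraction removes the stated percentages into dying stage I", {
  g <- growth_params(Td = 100, GF = 0.1, Tc = 3)
  s <- init_state(1000, g)   # Np = 100, Nq = 900
  e <- effect_model("St", Kp = 90, Kq = 5, D = 0.5)
  s1 <- apply_fraction(s, e)
  expect_equal(unclass(s1)[c("Np", "Nq", "Nd1")],
               c(Np = 10, Nq = 855, Nd1 = 135))
  expect_equal(attr(s1, "killed"), 135)

  # identity at zero kill
  s2 <- apply_fraction(s, effect_model("M", K = 0, D = 0.5))
  expect_equal(unclass(s2)[1:7], unclass(s)[1:7])
})

test_that("induced resistance converts surviving sensitive cells", {
  g <- growth_params(Td = 100, GF = 1, Tc = 100)
  s <- init_state(100, g)    # all cycling
  e <- effect_model("StResInd", Kp = 50, Kq = 0, D = 0.5, Rind = 0.04)
  s1 <- apply_fraction(s, e)
  expect_equal(s1[["Np"]], 48)
  expect_equal(s1[["Nrp"]], 2)
  expect_equal(s1[["Nd1"]], 50)
})

test_that("resistant cells are never reduced by a fraction", {
  g <- growth_params(Td = 100, GF = 0.2, Tc = 3)
  s <- init_state(1000, g, Rini = 0.4)
  e <- effect_model("StResIni", Kp = 99, Kq = 99, D = 1, Rini = 0.4)
  s1 <- apply_fraction(s, e)
  expect_equal(s1[["Nrp"]], s[["Nrp"]])
  expect_equal(s1[["Nrq"]], s[["Nrq"]])
})

test_that("uniform-kill and compartment-kill models agree when Kp = Kq", {
  # nontrivial equivalence: the M trajectory is computed on an all-cycling
  # population, the St one on a split population
  gM <- growth_params(Td = 150)
  gSt <- growth_params(Td = 150, GF = 0.2, Tc = 3)
  sched <- make_schedule("L", 46)
  days <- c(-10, 0, 10, 20, 45, 60)
  vM <- simulate_course(gM, effect_model("M", K = 12, D = 0.4), sched,
                        V0 = 5, sample_days = days)$volume_cc
  vSt <- simulate_course(gSt, effect_model("St", Kp = 12, Kq = 12, D = 0.4),
                         sched, V0 = 5, sample_days = days)$volume_cc
  expect_equal(vSt, vM, tolerance = 1e-9)
})

test_that("zero-resistance variants reproduce their base models", {
  g <- growth_params(Td = 150, GF = 0.2, Tc = 3)
  sched <- make_schedule("S", 9)
  days <- c(-7, 0, 4, 8, 30)
  base <- simulate_course(g, effect_model("St", Kp = 60, Kq = 5, D = 0.7),
                          sched, V0 = 4, sample_days = days)$volume_cc
  ini0 <- simulate_course(g, effect_model("StResIni", Kp = 60, Kq = 5,
                                          D = 0.7, Rini = 0),
                          sched, V0 = 4, sample_days = days)$volume_cc
  ind0 <- simulate_course(g, effect_model("StResInd", Kp = 60, Kq = 5,
                                          D = 0.7, Rind = 0),
                          sched, V0 = 4, sample_days = days)$volume_cc
  expect_equal(ini0, base, tolerance = 1e-12)
  expect_equal(ind0, base, tolerance = 1e-12)
})

test_that("raising the kill never raises any post-fraction volume", {
  g <- growth_params(Td = 200)
  sched <- make_schedule("L", 46)
  days <- seq(0, 70, by = 7)
  prev <- NULL
  for (K in c(0, 5, 15, 40, 80)) {
    v <- simulate_course(g, effect_model("M", K = K, D = 0.5), sched,
                         V0 = 8, sample_days = days)$volume_cc
    if (!is.null(prev)) expect_true(all(v <= prev + 1e-12))
    prev <- v
  }
})

test_that("resistant fraction is nondecreasing under sustained treatment", {
  g <- growth_params(Td = 150, GF = 0.2, Tc = 3)
  e <- effect_model("StResIni", Kp = 40, Kq = 10, D = 0.5, Rini = 0.2)
  sched <- make_schedule("L", 46)
  sim <- simulate_course(g, e, sched, V0 = 5, sample_days = 0:60,
                         compartments = TRUE)
  daily <- attr(sim, "daily")
  live <- daily[, "Np"] + daily[, "Nq"] + daily[, "Nrp"] + daily[, "Nrq"]
  rfrac <- (daily[, "Nrp"] + daily[, "Nrq"]) / live
  expect_true(all(diff(rfrac) >= -1e-12))
  expect_gt(rfrac[length(rfrac)], 0.9)  # resistant cells become prevalent
})

test_that("effective gamma switches only inside the recruitment window", {
  g <- growth_params(Td = 100, GF = 0.2, Tc = 3, gamma = 0.01)
  e_st <- effect_model("St", Kp = 50, Kq = 5, D = 0.5)
  expect_equal(effective_gamma(e_st, g, c(0, 5, 50)), rep(0.01, 3))
  e_rec <- effect_model("StRec", Kp = 50, Kq = 5, D = 0.5,
                        gamma_rec = 0.37, rec_window = c(1, 3))
  expect_equal(effective_gamma(e_rec, g, 2), 0.37)
  expect_equal(effective_gamma(e_rec, g, 10), 0.01)
  e_late <- effect_model("StRec", Kp = 50, Kq = 5, D = 0.5,
                         gamma_rec = 0.1, rec_window = c(22, Inf))
  expect_equal(effective_gamma(e_late, g, 10), 0.01)
  expect_equal(effective_gamma(e_late, g, 30), 0.1)
})

test_that("free-parameter counts follow the fit configuration", {
  expect_equal(model_parameter_count("St", gamma_free = TRUE), 8)
  expect_equal(model_parameter_count("St"), 7)
  expect_equal(model_parameter_count("M"), 4)
  expect_equal(model_parameter_count("StRec"),
               model_parameter_count("St") + 1)
  expect_equal(model_parameter_count("MResInd"),
               model_parameter_count("M") + 1)
  # no pretreatment data: Td drops out
  expect_equal(model_parameter_count("M", pretreatment = FALSE), 3)
})

test_that("effect model validation catches bad configurations", {
  expect_error(effect_model("X", K = 5, D = 0.5), "unknown model tag")
  expect_error(effect_model("M", K = 120, D = 0.5), "0, 100")
  expect_error(effect_model("M", K = 10), "'D'")
  expect_error(effect_model("StRec", Kp = 50, Kq = 5, D = 0.5,
                            gamma_rec = 0.005, rec_window = c(1, 3)),
               "gamma_rec")
  expect_error(effect_model("StRec", Kp = 50, Kq = 5, D = 0.5,
                            gamma_rec = 0.3), "rec_window")
})
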