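# Independent brute-force oracle: a literal day-by-day transcription of
# the difference equations, sharing no code with the package's kernel.
brute_force_m <- function(V0, Td, K, D, fx_days, t0, t1,
                          cells_per_cc = 1e9) {
  ln2 <- log(2)
  u <- ln2 / (Td * (exp(ln2) - 1))          # Tc = Td, all cells cycling
  dtp <- (exp(ln2 / Td) - 1) / (ln2 / Td)
  np <- V0 * cells_per_cc * 2^(t0 / Td)
  nd1 <- nd2 <- nd3 <- 0
  out <- numeric(t1 - t0 + 1)
  k <- 1
  for (t in t0:t1) {
    out[k] <- np + nd1 + nd2 + nd3; k <- k + 1
    if (t %in% fx_days) {   # volumes above were sampled pre-fraction
      killed <- K / 100 * np
      np <- np - killed
      nd1 <- nd1 + killed
    }
    # theta = 1 at GF = 1: both newborns stay in cycle
    np <- np + 2 * u * np * dtp - u * np * dtp
    nd3 <- (1 - D) * nd3 + D * nd2
    nd2 <- (1 - D) * nd2 + D * nd1
    nd1 <- (1 - D) * nd1
  }
  out / cells_per_cc
}

test_that("simulation matches a brute-force iteration of the equations", {
  # hypofractionated reference point: V0 = 2 cc, Td = 250, K = 8, D = 0.999
  fx <- c(0, 2, 4, 7, 9)
  oracle <- brute_force_m(2, 250, 8, 0.999, fx, t0 = -7, t1 = 40)
  days <- c(-7, 0, 5, 9, 20, 40)
  sim <- simulate_course(growth_params(Td = 250),
                         effect_model("M", K = 8, D = 0.999),
                         rt_schedule(fx, 10), V0 = 2, sample_days = days,
                         t_span = c(-7, 40))
  expect_equal(sim$volume_cc, oracle[days - (-7) + 1], tolerance = 1e-6)
})

test_that("dying-stage update order matches the oracle", {
  # a second parameter point with a slow dying process, where the stage
  # ordering inside one step matters
  fx <- c(0, 3, 6)
  oracle <- brute_force_m(5, 100, 40, 0.2, fx, t0 = 0, t1 = 30)
  sim <- simulate_course(growth_params(Td = 100),
                         effect_model("M", K = 40, D = 0.2),
                         rt_schedule(fx, 10), V0 = 5, sample_days = 0:30)
  expect_equal(sim$volume_cc, oracle, tolerance = 1e-9)
})

test_that("untreated simulation is exactly exponential", {
  g <- growth_params(Td = 123, GF = 0.2, Tc = 3)
  sim <- simulate_course(g, NULL, NULL, V0 = 1.7,
                         sample_days = c(-20, 0, 17, 60))
  expect_equal(sim$volume_cc, 1.7 * 2^(c(-20, 0, 17, 60) / 123),
               tolerance = 1e-9)
})

test_that("total kill drains the tumor within the three-stage delay", {
  g <- growth_params(Td = 200)
  e <- effect_model("M", K = 100, D = 1)
  sim <- simulate_course(g, e, rt_schedule(0, 10), V0 = 3,
                         sample_days = 0:5)
  v <- sim$volume_cc
  expect_true(all(diff(v) <= 1e-12))      # monotone nonincreasing
  expect_equal(v[4:6], rep(0, 3))         # empty from day 3 on
})

test_that("compiled path agrees with the single-step reference engine", {
  g <- growth_params(Td = 150, GF = 0.25, Tc = 2.5, gamma = 0.01)
  e <- effect_model("StRec", Kp = 60, Kq = 5, D = 0.5, gamma_rec = 0.4,
                    rec_window = c(1, 3))
  sched <- rt_schedule(c(0, 2, 4), 10)
  days <- 0:10
  sim <- simulate_course(g, e, sched, V0 = 2, sample_days = days)
  # replay with the R reference: step_state + apply_fraction
  d <- derive_rates(g)
  s <- init_state(2e9, g)
  vols <- numeric(length(days))
  for (t in 0:10) {
    if (t %in% days) vols[match(t, days)] <- state_volume(s)
    if (t %in% sched$day) s <- apply_fraction(s, e)
    if (t < 10) s <- step_state(s, d, D = e$D,
                                gamma = effective_gamma(e, g, t))
  }
  expect_equal(sim$volume_cc, vols, tolerance = 1e-12)
})

test_that("schedule outside the span is rejected", {
  g <- growth_params(Td = 100)
  expect_error(simulate_course(g, effect_model("M", K = 10, D = 0.5),
                               rt_schedule(c(0, 40), 10), V0 = 1,
                               sample_days = 0:10, t_span = c(0, 10)),
               "outside")
})
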