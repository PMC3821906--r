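test_that("initial state splits by growth fraction and resistant fraction", {
  g <- growth_params(Td = 100, GF = 0.2, Tc = 3)
  s <- init_state(1000, g)
  expect_equal(unclass(s)[1:4], c(Np = 200, Nq = 800, Nrp = 0, Nrq = 0))
  s2 <- init_state(1000, g, Rini = 0.3)
  expect_equal(unclass(s2)[1:4], c(Np = 140, Nq = 560, Nrp = 60, Nrq = 240))
  expect_equal(total_cells(s2), 1000)
  expect_error(init_state(0, g), "empty")
})

test_that("total cells and volume sum the seven compartments", {
  s <- rep(1e8, 7)
  expect_equal(total_cells(s), 7e8)
  expect_equal(state_volume(s), 0.7)
  expect_equal(total_cells(rep(0, 7)), 0)
  g <- growth_params(Td = 25, GF = 0.06, Tc = 1.9)
  expect_equal(state_volume(init_state(3.2e9, g)), 3.2)
})

test_that("one step multiplies a balanced population by 2^(dt/Td)", {
  for (p in list(c(100, 0.2, 3), c(250, 0.06, 1.9), c(15, 0.95, 13))) {
    bs <- balanced_state(1e9, Td = p[1], GF = p[2], Tc = p[3])
    s1 <- step_state(bs$s, bs$d)
    expect_equal(total_cells(s1) / total_cells(bs$s), 2^(1 / p[1]),
                 tolerance = 1e-9)
  }
})

test_that("growth fraction is stationary under balanced growth", {
  bs <- balanced_state(1e9, Td = 100, GF = 0.2, Tc = 3)
  s <- bs$s
  for (i in 1:50) {
    s <- step_state(s, bs$d)
    expect_equal(s[["Np"]] / (s[["Np"]] + s[["Nq"]]), 0.2, tolerance = 1e-10)
  }
  expect_equal(total_cells(s) / 1e9, 2^(50 / 100), tolerance = 1e-9)
})

test_that("dying stages advance one per day and empty at D = 1", {
  bs <- balanced_state()
  s <- as.numeric(init_state(1000, bs$g))
  s[1:4] <- 0; s[5] <- 100   # 100 cells entering stage I
  for (i in 1:3) s <- unclass(step_state(s, bs$d, D = 1))[1:7]
  expect_equal(sum(s[5:7]), 0)
  # D = 0: the dying pipeline is frozen
  s0 <- c(0, 0, 0, 0, 40, 30, 20)
  s1 <- unclass(step_state(s0, bs$d, D = 0))[1:7]
  expect_equal(s1[5:7], c(Nd1 = 40, Nd2 = 30, Nd3 = 20))
})

test_that("single-cell passage through the dying stages averages 3/D days", {
  # Monte-Carlo oracle: per-stage waits are geometric with success D
  set.seed(42)
  n <- 1e5
  for (D in c(0.2, 0.5, 0.75, 1)) {
    waits <- (rgeom(n, D) + 1) + (rgeom(n, D) + 1) + (rgeom(n, D) + 1)
    se <- sd(waits) / sqrt(n)
    expect_lt(abs(mean(waits) - mean_dying_time(D)), max(3 * se, 1e-12))
  }
})

test_that("kill bookkeeping is conservative through the dying pipeline", {
  g <- growth_params(Td = 250)
  e <- effect_model("M", K = 8, D = 0.999)
  sched <- rt_schedule(c(0, 2, 4, 7, 9), 10)
  sim <- simulate_course(g, e, sched, V0 = 2, sample_days = c(0, 9, 40))
  killed <- attr(sim, "killed")
  lost <- attr(sim, "lost")
  final <- attr(sim, "state")
  expect_gt(killed, 0)
  # everything ever killed is either already lost or still in a dying stage
  expect_equal(lost + sum(unclass(final)[5:7]), killed, tolerance = 1e-9)
  # untreated simulation kills nothing
  sim0 <- simulate_course(g, NULL, NULL, V0 = 2, sample_days = c(0, 40))
  expect_equal(attr(sim0, "killed"), 0)
  expect_equal(attr(sim0, "lost"), 0)
})
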