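test_that("dwell-time samplers have the prescribed moments", {
  set.seed(5)
  cfg1 <- gillespie_config("single_exponential")
  d1 <- sample_dwell(cfg1, rate = 4, n = 1e5)
  expect_equal(mean(d1), 0.25, tolerance = 0.01)

  # two-exponential defaults: mean 1/k1 + 1/k2 ~ 0.2565 s (3.9 AA/s) and
  # hypoexponential variance 1/k1^2 + 1/k2^2
  cfg2 <- gillespie_config("two_exponential")
  mu <- 1 / cfg2$k1 + 1 / cfg2$k2
  expect_equal(mu, 0.2565, tolerance = 1e-3)
  d2 <- sample_dwell(cfg2, rate = 1 / mu, n = 1e5)
  expect_equal(mean(d2), mu, tolerance = 0.01)
  expect_equal(stats::var(d2), 1 / cfg2$k1^2 + 1 / cfg2$k2^2, tolerance = 0.05)

  # per-codon scaling preserves the mean at 1/k_A,i
  d3 <- sample_dwell(cfg2, rate = 10, n = 1e5)
  expect_equal(mean(d3), 0.1, tolerance = 0.01)

  # k1 = k2 limit is Erlang-2: variance 2/k^2
  cfg3 <- gillespie_config("two_exponential", k1 = 4, k2 = 4)
  d4 <- sample_dwell(cfg3, rate = 2, n = 1e5)
  expect_equal(stats::var(d4), 2 / 4^2, tolerance = 0.05)
})

test_that("initiation sampling is exponential, and sinusoidal modulation shows its period", {
  set.seed(6)
  cfg <- gillespie_config(initiation = "constant", k_init = 2)
  gaps <- replicate(2e4, next_initiation(cfg, 0))
  expect_equal(mean(gaps), 0.5, tolerance = 0.02)

  # amplitude 0 reduces the sinusoidal model to the constant one
  cfg0 <- gillespie_config(initiation = "sinusoidal", k_init = 2, amplitude = 0)
  set.seed(8); a <- replicate(50, next_initiation(cfg0, 13))
  set.seed(8); b <- replicate(50, next_initiation(cfg, 13))
  expect_identical(a, b)

  # pooled sinusoidal event times oscillate in phase with the driving rate
  cfgs <- gillespie_config(initiation = "sinusoidal", k_init = 3.9,
                           amplitude = 0.8, period = 45)
  events <- numeric(0)
  for (run in 1:20) {
    t <- 0
    repeat {
      t <- t + next_initiation(cfgs, t)
      if (t > 450) break
      events <- c(events, t)
    }
  }
  phase_bin <- floor((events %% 45) / 5) + 1
  counts <- tabulate(phase_bin, nbins = 9)
  mids <- (seq_len(9) - 0.5) * 5
  expect_gt(stats::cor(counts, sin(2 * pi * mids / 45)), 0.5)

  # exact thinning targets the same intensity
  cfgt <- gillespie_config(initiation = "sinusoidal", k_init = 3.9,
                           amplitude = 0.8, period = 45, thinning = TRUE)
  n_thin <- 0
  for (run in 1:20) {
    t <- 0
    repeat { t <- t + next_initiation(cfgt, t); if (t > 450) break
             n_thin <- n_thin + 1 }
  }
  expect_equal(n_thin / length(events), 1, tolerance = 0.1)
})

test_that("the stochastic simulator is seed-reproducible and respects k_F = 0", {
  toy <- construct("toy", 40, 1, 10, bulk_kF = 3, bulk_kU = 0.1,
                   tunnel_length = 5, observable_codons = 1:20)
  sch <- uniform_schedule(40, 4)
  proto <- pulse_protocol(pulse = 5, chase = 40, delay = 1,
                          report_times = seq(0, 40, 2))
  cfg <- gillespie_config(replicates = 3)
  s1 <- simulate_pulse_chase_stochastic(toy, sch, proto, cfg, seed = 99)
  s2 <- simulate_pulse_chase_stochastic(toy, sch, proto, cfg, seed = 99)
  expect_identical(s1$replicate_curves, s2$replicate_curves)
  expect_identical(s1$n_labelled, s2$n_labelled)

  dead <- construct("dead", 40, 1, 10, bulk_kF = 0, bulk_kU = 1,
                    tunnel_length = 5, observable_codons = 1:20)
  s0 <- simulate_pulse_chase_stochastic(dead, sch, proto, cfg, seed = 1)
  expect_true(all(s0$replicate_curves[!is.na(s0$replicate_curves)] == 0))
})

test_that("the simulated length profile converges to the analytic recursion", {
  # moderate-size construct where the transition zone is fully visible
  cst <- construct("prof", 80, 1, 25, bulk_kF = 2, bulk_kU = 0.2,
                   tunnel_length = 10)
  sch <- uniform_schedule(80, 4)
  prof <- steady_state_profile(build_kinetics(cst), sch)
  sim <- simulate_length_profile(cst, sch, n_chains = 8000, seed = 21)
  z <- (sim$values - prof$values) / sim$se
  expect_true(all(abs(z) <= 3.5))
  expect_lt(mean(abs(sim$values - prof$values)), 0.01)
})
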