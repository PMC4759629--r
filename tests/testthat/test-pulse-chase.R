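test_that("cohort trajectories follow the cumulative mean dwell times", {
  sched <- uniform_schedule(1145, 3.9)
  tr <- cohort_trajectory(sched, t0 = 0)
  expect_equal(tr$release, 1145 / 3.9)          # ~293.6 s
  expect_equal(tr$release, 293.6, tolerance = 1e-3)

  # first codon at k_A = 2 is occupied on [0, 0.5)
  tr2 <- cohort_trajectory(translation_schedule(c(2, 4)), t0 = 0)
  expect_equal(tr2$position(0.49), 1)
  expect_equal(tr2$position(0.5), 2)
  expect_equal(tr2$position(0.5 + 0.25), 3)     # released
  # positions nondecreasing in t
  tt <- seq(-1, 2, by = 0.01)
  expect_true(all(diff(tr2$position(tt)) >= 0))
})

test_that("labelling requires an observable incorporation inside the window", {
  proto <- pulse_protocol(pulse = 45, delay = 10)
  sched <- uniform_schedule(1145, 3.9)

  # all observable residues made before the delay ends: unlabelled
  early <- is_labelled(cohort_trajectory(sched, t0 = -80), 1:143, proto)
  expect_false(early$labelled)
  # initiation after the window closes: unlabelled
  late <- is_labelled(cohort_trajectory(sched, t0 = 56), 1:143, proto)
  expect_false(late$labelled)
  # SFVP dC cohort starting at t0 = 0: observable codons 1-143 are made on
  # (0, 36.7] s, so instants inside [10, 55) exist
  mid <- is_labelled(cohort_trajectory(sched, t0 = 0), 1:143, proto)
  expect_true(mid$labelled)
  expect_equal(mid$label_time, ceiling(10 * 3.9) / 3.9, tolerance = 1e-9)
})

test_that("evolve_folding applies exact two-state relaxation along a trajectory", {
  cst <- construct("toy", M = 6, 1, 2, bulk_kF = 1.5, bulk_kU = 0.5,
                   tunnel_length = 2)   # onset = 4
  kin <- build_kinetics(cst)
  sched <- translation_schedule(c(2, 2, 1, 1, 2, 4))
  tr <- cohort_trajectory(sched, t0 = 0)

  # zero before the chain reaches the onset
  expect_equal(evolve_folding(kin, tr, c(0, 0.5, 1.9)), c(0, 0, 0))

  # closed form inside the onset dwell: P = Peq (1 - exp(-k (t - t_on)))
  t_on <- tr$incorporation[3]
  p <- evolve_folding(kin, tr, t_on + 0.7)
  expect_equal(p, 0.75 * -expm1(-2 * 0.7), tolerance = 1e-12)

  # after release the same bulk relaxation continues toward Peq
  p_rel <- evolve_folding(kin, tr, tr$release + c(0, 5, 50))
  expect_equal(p_rel[3], 0.75, tolerance = 1e-4)
  expect_true(all(diff(p_rel) > 0))

  # k_F = 0 everywhere: identically zero
  kin0 <- build_kinetics(construct("z", 6, 1, 2, 0, 1, tunnel_length = 2))
  expect_equal(evolve_folding(kin0, tr, seq(0, 10)), rep(0, 11))

  # cross-module consistency: a dC cohort's folding probability at release
  # matches the steady-state profile at the stop codon
  dc <- construct_presets()$SFVP_dC
  s39 <- uniform_schedule(dc$M, 3.9)
  trd <- cohort_trajectory(s39, 0)
  p_rel <- evolve_folding(build_kinetics(dc), trd, trd$release)
  prof <- steady_state_profile(build_kinetics(dc), s39)
  expect_equal(p_rel, prof$values[dc$M], tolerance = 0.01)
})

test_that("the predicted dC curve has the observed pulse-chase shape", {
  dc <- construct_presets()$SFVP_dC
  sched <- uniform_schedule(dc$M, 3.9)
  cv <- predict_pulse_chase(dc, sched, pulse_protocol())

  expect_true(all(cv$value >= 0 & cv$value <= 1))
  expect_gt(cv$value[cv$time == 0], 0)              # folding before the chase
  plateau <- cv$P_eq
  expect_equal(plateau, 20 / (20 + 4.34e-5))
  late <- cv$value[cv$time >= 100]
  expect_lt(max(abs(late - plateau)), 0.01)         # flat plateau
  rising <- cv$time >= 10 & cv$time <= 55
  fit <- stats::lm(cv$value[rising] ~ cv$time[rising])
  expect_gt(summary(fit)$r.squared, 0.99)           # linear rise
  expect_true(all(diff(cv$value) >= -1e-12))        # nondecreasing

  # k_F = 0: identically zero curve
  dead <- construct("dead", dc$M, 1, 155, bulk_kF = 0, bulk_kU = 1,
                    observable_codons = 1:143)
  cv0 <- predict_pulse_chase(dead, sched, pulse_protocol())
  expect_true(all(cv0$value == 0))
})

test_that("cohort bookkeeping conserves counts and normalizes the curve", {
  dc <- construct_presets()$SFVP_dC
  sched <- uniform_schedule(dc$M, 3.9)
  cv <- predict_pulse_chase(dc, sched, pulse_protocol())
  led <- cv$ledger

  # visible counts never decrease and saturate at the labelled total
  expect_true(all(diff(cv$n_visible) >= 0))
  expect_equal(max(cv$n_visible), sum(led$labelled))

  # with uniform rates the labelled initiation times tile the window
  # uniformly (steady-state consistency)
  expect_equal(diff(range(diff(led$t0))), 0, tolerance = 1e-9)

  # report times before any labelled cohort is visible are flagged NA
  proto_early <- pulse_protocol(report_times = c(-44, 0, 100) )
  cv2 <- predict_pulse_chase(dc, sched, proto_early)
  expect_true(is.na(cv2$value[1]))
  expect_equal(cv2$undefined_times, -44)
})

test_that("fraction of full-length protein is a normalized step function", {
  dc <- construct_presets()$SFVP_dC
  sched <- uniform_schedule(dc$M, 3.9)
  cv <- predict_pulse_chase(dc, sched, pulse_protocol())
  f <- fraction_full_length(cv)
  expect_equal(f$fraction[nrow(f)], 1)
  expect_true(all(diff(f$fraction) >= 0))
  expect_true(all(f$fraction >= 0 & f$fraction <= 1))

  # toy 10-codon construct: release happens exactly tau_cum(M) after
  # initiation, so the first released cohort sets the first step
  rates <- c(2, 2, 2, 4, 4, 4, 2, 2, 2, 4)
  toy <- construct("toy10", 10, 1, 4, bulk_kF = 5, bulk_kU = 0.1,
                   tunnel_length = 2, observable_codons = 1:9)
  sch <- translation_schedule(rates)
  proto <- pulse_protocol(pulse = 5, chase = 30, delay = 1, dt = 0.05,
                          report_times = seq(0, 30, 0.5))
  cvt <- predict_pulse_chase(toy, sch, proto)
  ft <- fraction_full_length(cvt)
  led <- cvt$ledger
  first_rel <- min(led$release_time[led$labelled]) - proto$pulse
  expect_true(all(ft$fraction[ft$time_s < first_rel] == 0))
  expect_gt(ft$fraction[min(which(ft$time_s >= first_rel))], 0)
})

test_that("halving the seeding step changes the curve negligibly", {
  dc <- construct_presets()$SFVP_dC
  sched <- uniform_schedule(dc$M, 3.9)
  c1 <- predict_pulse_chase(dc, sched, pulse_protocol(dt = 0.1))
  c2 <- predict_pulse_chase(dc, sched, pulse_protocol(dt = 0.05))
  expect_lt(max(abs(c1$value - c2$value)), 1e-3)
})

test_that("sensitivity sweeps vary one parameter at a time", {
  dc <- construct_presets()$SFVP_dC
  sched <- uniform_schedule(dc$M, 3.9)
  proto <- pulse_protocol(report_times = seq(0, 360, 5))
  sw <- sensitivity_sweep(dc, sched, proto,
                          kF_factors = 1, kU_factors = c(10, 0.1),
                          kA_factors = c(1.9487, 0.4872),
                          tunnel_lengths = c(20, 40))
  base <- sw$base$value

  # factor 1 reproduces the base curve exactly
  expect_equal(sw$`kF_x1`$value, base)
  # unfolding-rate insensitivity over two orders of magnitude
  expect_lt(max(abs(sw$`kU_x10`$value - base)), 1e-3)
  expect_lt(max(abs(sw$`kU_x0.1`$value - base)), 1e-3)
  # translation-rate changes shift the curve: faster translation delays
  # the rise relative to the chase axis, slower translation has the
  # opposite effect at matched late times; plateaus agree
  expect_equal(sw$`kA_x0.4872`$value[length(base)], base[length(base)],
               tolerance = 1e-6)
  expect_false(isTRUE(all.equal(sw$`kA_x0.4872`$value, base, tolerance = 1e-3)))
  # tunnel-length changes move the onset but not the plateau
  expect_equal(sw$tunnel_20$value[length(base)], base[length(base)],
               tolerance = 1e-6)
  expect_true(all(sw$tunnel_20$value >= sw$tunnel_40$value - 1e-9))
})
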