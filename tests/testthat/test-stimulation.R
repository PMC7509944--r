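test_that("release kernel matches its defining convolution integral and closed-form values", {
  # oracle: R(t) = int_0^min(t,d) b exp(-b (t - s)) ds, computed numerically
  conv <- function(t, d, b)
    stats::integrate(function(s) b * exp(-b * (t - s)), 0, min(t, d),
                     rel.tol = 1e-12)$value
  for (b in c(0.5, 1, 2)) for (d in c(1, 2)) {
    for (t in c(0.3, 0.9, d, d + 0.5, d + 3))
      expect_equal(release_kernel_R(t, d, b), conv(t, d, b),
                   tolerance = 1e-10)
  }
  expect_identical(release_kernel_R(0), 0)
  expect_equal(release_kernel_R(2), 1 - exp(-2))
  expect_equal(release_kernel_R(3), exp(-1) - exp(-3))
  # continuity at the end of stimulation
  expect_equal(release_kernel_R(2 - 1e-10), release_kernel_R(2 + 1e-10),
               tolerance = 1e-8)
})

test_that("the kernel integrates to the stimulation duration (total complex dumped)", {
  for (b in c(0.5, 1, 2)) for (d in c(1, 2, 4)) {
    mass <- stats::integrate(release_kernel_R, 0, 400, duration = d, b = b,
                             rel.tol = 1e-10, subdivisions = 2000)$value
    expect_equal(mass, d, tolerance = 1e-7)
  }
})

test_that("fire(t) is basal plus the kernel transient and scales linearly in r", {
  proto0 <- stim_protocol(r = 0)
  expect_equal(fire_rate(c(0, 5, 7, 30), proto0), rep(1, 4))
  proto <- stim_protocol(onset_s = 5, duration_s = 2, r = 18, b = 1)
  expect_equal(fire_rate(7, proto), 1 + 18 * (1 - exp(-2)))
  expect_equal(fire_rate(4.9999, proto), 1, tolerance = 1e-3)
  # total stimulated mass above basal is r * duration, exactly linear in r
  mass_r <- function(r) {
    pr <- stim_protocol(r = r)
    stats::integrate(function(t) fire_rate(t, pr) - pr$f_basal, 0, 500,
                     rel.tol = 1e-10, subdivisions = 2000)$value
  }
  expect_equal(mass_r(18), 18 * 2, tolerance = 1e-6)
  expect_equal(mass_r(36) / mass_r(18), 2, tolerance = 1e-8)
})

test_that("meal forcing doubles btrp after meals and averages to the daily mean exactly", {
  f <- meal_btrp()
  tt <- seq(0, 24, length.out = 24 * 3600 + 1)[-1]
  expect_equal(mean(f(tt)), 96, tolerance = 1e-10)
  expect_equal(f(19), 192)                    # inside the dinner window
  expect_equal(f(22), 960 / 17, tolerance = 1e-12)  # overnight low
  expect_equal(f(26 + 7), f(2 + 7))           # 24 h periodic
  expect_error(meal_btrp(meal_times_h = c(7, 8), durations_h = c(2, 2)),
               "overlap")
  # arbitrary non-overlapping schedules keep the mean constraint
  f2 <- meal_btrp(meal_times_h = c(1, 10, 20), durations_h = c(2, 2, 3))
  expect_equal(mean(f2(tt)), 96, tolerance = 1e-10)
})

test_that("histamine pulse family integrates to amplitude x decay and tabulated mode interpolates", {
  f0 <- eha_pulse(amplitude = 0)
  expect_equal(f0(c(0, 1, 10)), rep(1.39, 3))
  f <- eha_pulse(amplitude = 0.5, onset_s = 5, decay_s = 4)
  area <- stats::integrate(function(th) f(th) - 1.39, 0, 2,
                           rel.tol = 1e-10, subdivisions = 2000)$value
  expect_equal(area * 3600, 0.5 * 4, tolerance = 1e-5)
  tab <- data.frame(t_s = c(0, 5, 10), eha = c(1.39, 2.0, 1.5))
  ft <- eha_pulse(table = tab)
  expect_equal(ft(tab$t_s / 3600), tab$eha)
})

test_that("an unstimulated response stays at baseline", {
  resp <- simulate_response(sero_preset("custom"),
                            stim_protocol(r = 0), record_window_s = 10,
                            dt_s = 0.5)
  expect_lt(max(abs(resp$delta_eht_nM)), 1e-3)
})

test_that("post-stimulus undershoot requires the receptor machinery", {
  # receptor slopes zero and Uptake 2 disabled: monotone decay, no undershoot
  off <- simulate_response(
    sero_preset("custom",
                overrides = list(s_rel = 0, s_syn = 0, s_ha = 0,
                                 vmax_u2 = 1e-6)),
    stim_protocol(onset_s = 5, r = 18))
  expect_gt(min(off$delta_eht_nM), -1e-3)
  post_peak <- off$delta_eht_nM[off$t_s > off$t_s[which.max(off$delta_eht_nM)]]
  expect_true(all(diff(post_peak) < 1e-6))
  # the standard male preset does undershoot and then rebounds
  male <- simulate_response(sero_preset("male"))
  expect_lt(min(male$delta_eht_nM), -1)
  i_min <- which.min(male$delta_eht_nM)
  expect_lt(i_min, nrow(male))          # minimum is interior: rebound follows
  expect_gt(male$delta_eht_nM[nrow(male)], min(male$delta_eht_nM))
})

test_that("receptor activation cascades in order: bound receptor, then G*, then RGS*", {
  male <- simulate_response(sero_preset("male"), keep_state = TRUE)
  tr <- attr(male, "trajectory")
  t_b <- tr$time_h[which.max(tr$b_ht)]
  t_g <- tr$time_h[which.max(tr$g_ht_star)]
  t_t <- tr$time_h[which.max(tr$t_ht_star)]
  expect_lt(t_b, t_g)
  expect_lt(t_g, t_t)
})

test_that("the slow SNr preset peaks below the Uptake 2 gate ceiling", {
  slow <- simulate_response(sero_preset("slow"))
  peak_abs <- attr(slow, "baseline_eht_nM") + max(slow$delta_eht_nM)
  expect_lt(peak_abs, 65)     # gate_hi of the slow preset
  expect_gt(peak_abs, 55)     # and above gate_lo, so Uptake 2 engages late
})

test_that("presets load from packaged JSON with the published overrides", {
  male <- sero_preset("male")
  expect_equal(male$overrides$vmax_u2, 1680)
  expect_equal(male$r, 18)
  fem <- sero_preset("female")
  expect_equal(fem$overrides$gate_hi, 70.5)
  expect_equal(fem$r, 18.5)
  hyb <- sero_preset("hybrid")
  expect_equal(hyb$overrides$vmax_sert, 433)
  expect_equal(hyb$overrides$s_rel, 1.25)
})
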