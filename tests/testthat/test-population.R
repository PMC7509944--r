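test_that("variation specs validate and sampling respects the uniform bounds", {
  spec <- variation_spec("fig2")
  expect_setequal(spec$key,
                  c("vmax_trpin", "vmax_tph", "vmax_aadc", "vmax_mat",
                    "vmax_catab", "vmax_u2", "vmax_sert", "f_basal",
                    "s_rel"))
  set.seed(1)
  for (i in 1:200) {
    m <- sample_multipliers(spec)
    expect_true(all(m >= 0.75 & m <= 1.25))
  }
  # empirical mean of each multiplier approaches the interval midpoint
  set.seed(2)
  draws <- t(replicate(2000, sample_multipliers(spec)))
  se <- (0.5 / sqrt(12)) / sqrt(2000)
  expect_true(all(abs(colMeans(draws) - 1) < 4 * se))
  expect_error(variation_spec("custom",
                              table = data.frame(key = "vmax_sert",
                                                 lower = -1, upper = 2)),
               "lower")
})

test_that("a zero-width spec reproduces the deterministic baseline", {
  spec <- variation_spec("custom",
                         table = data.frame(key = "vmax_sert",
                                            lower = 1, upper = 1))
  db <- build_population(1, spec, seed = 5, anchors = baseline_eq$anchors)
  expect_identical(nrow(db$individuals), 1L)
  expect_equal(db$individuals$eht_nM, 1000 * baseline_eq$state[["eht"]],
               tolerance = 1e-6)
  s <- summarize_population(db)
  expect_identical(s$sd, NA_real_)   # single individual has no dispersion
})

test_that("populations are reproducible from the master seed", {
  spec <- variation_spec("fig2")
  db1 <- build_population(12, spec, seed = 11,
                          anchors = baseline_eq$anchors)
  db2 <- build_population(12, spec, seed = 11,
                          anchors = baseline_eq$anchors)
  expect_identical(db1$individuals, db2$individuals)
  db3 <- build_population(12, spec, seed = 12,
                          anchors = baseline_eq$anchors)
  expect_false(identical(db1$individuals$eht_nM, db3$individuals$eht_nM))
  # extensibility: the first individuals of a larger run are unchanged
  db4 <- build_population(6, spec, seed = 11,
                          anchors = baseline_eq$anchors)
  expect_equal(db4$individuals$eht_nM, db1$individuals$eht_nM[1:6])
})

test_that("autoreceptor strength orders the population dispersion of eht", {
  n <- 120
  anc <- baseline_eq$anchors
  spec <- variation_spec("fig2")
  sd_std <- summarize_population(
    build_population(n, spec, sero_params(), seed = 3, anchors = anc))$sd
  sd_off <- summarize_population(
    build_population(n, spec, params_off(), seed = 3, anchors = anc))$sd
  sd_dbl <- summarize_population(
    build_population(n, spec, sero_params(s_rel = 25, s_syn = 5), seed = 3,
                     anchors = anc))$sd
  expect_gt(sd_off, sd_std)
  expect_gt(sd_std, sd_dbl)
  # negative skew: the Uptake 2 gate compresses the right shoulder
  e <- build_population(n, spec, sero_params(), seed = 3,
                        anchors = anc)$individuals$eht_nM
  expect_lt(mean(((e - mean(e)) / stats::sd(e))^3), 0)
})

test_that("lowering blood tryptophan shifts the population eht distribution down", {
  n <- 60
  anc <- baseline_eq$anchors
  spec <- variation_spec("fig2")
  m96 <- summarize_population(
    build_population(n, spec, sero_params(), seed = 9, anchors = anc))$mean
  m50 <- summarize_population(
    build_population(n, spec, sero_params(btrp = 50), seed = 9,
                     anchors = anc))$mean
  expect_lt(m50, m96 - 3)
})

test_that("summaries report moments and fixed 2.5 nM histogram bins", {
  db <- build_population(40, variation_spec("fig2"), seed = 21,
                         anchors = baseline_eq$anchors)
  s <- summarize_population(db, "eht_nM")
  expect_equal(s$n, 40)
  expect_equal(s$mean, mean(db$individuals$eht_nM))
  expect_equal(diff(s$histogram$mid[1:2]), 2.5)
  expect_equal(sum(s$histogram$count), 40)
  expect_error(summarize_population(db, "not_a_field"), "not found")
})

test_that("attribute_variation recovers a planted linear driver and rejects degenerate input", {
  set.seed(31)
  n <- 150
  X <- data.frame(a = stats::runif(n, 0.75, 1.25),
                  b = stats::runif(n, 0.75, 1.25),
                  c = stats::runif(n, 0.75, 1.25))
  y <- 10 * X$b + stats::rnorm(n, sd = 0.1)
  out <- attribute_variation(X, y)
  expect_identical(out$parameter[1], "b")
  expect_gt(attr(out, "r_squared"), 0.9)
  expect_error(attribute_variation(X[1:4, ], y[1:4]), "at least")
  X0 <- X; X0$a <- 1
  expect_error(attribute_variation(X0, y[seq_len(n)]), "degenerate")
})

test_that("response populations share a grid, are seed-reproducible, and degenerate specs give zero sd", {
  spec0 <- variation_spec("custom",
                          table = data.frame(key = "vmax_sert",
                                             lower = 1, upper = 1))
  rp <- response_population(2, spec0, stim_protocol(onset_s = 5, r = 18),
                            seed = 4, record_window_s = 12, dt_s = 0.5)
  expect_equal(max(rp$sd_curve), 0)
  rp2 <- response_population(4, variation_spec("fig6ab"),
                             stim_protocol(onset_s = 5, r = 18), seed = 4,
                             record_window_s = 12, dt_s = 0.5)
  rp3 <- response_population(4, variation_spec("fig6ab"),
                             stim_protocol(onset_s = 5, r = 18), seed = 4,
                             record_window_s = 12, dt_s = 0.5)
  expect_identical(rp2$curves, rp3$curves)
  expect_gt(max(rp2$sd_curve), 0)
})

test_that("two-factor scans reproduce the drug-efficacy and vitamin-B6 patterns", {
  n <- 150
  db_sm <- build_population(n, variation_spec("ssri_mao"), seed = 13,
                            anchors = baseline_eq$anchors)
  sc <- two_factor_scan(db_sm)
  terc <- stats::quantile(sc$m_vmax_catab, c(1 / 3, 2 / 3))
  hi <- sc[sc$m_vmax_catab >= terc[2], ]
  lo <- sc[sc$m_vmax_catab <= terc[1], ]
  slope <- function(d) stats::coef(stats::lm(eht_nM ~ m_vmax_sert, d))[2]
  # lowering SERT raises eht much more in high-MAO individuals
  expect_lt(slope(hi), slope(lo))
  expect_lt(slope(hi), 0)

  db_ab <- build_population(n, variation_spec("aadc_b6"), seed = 13,
                            anchors = baseline_eq$anchors)
  sc2 <- two_factor_scan(db_ab)
  # eht is essentially uncorrelated with AADC expression
  expect_lt(abs(stats::cor(sc2$m_vmax_aadc, sc2$eht_nM)), 0.1)
  # flux compensation: AADC flux varies far less than AADC expression
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(sc2$v_aadc), 0.4 * cv(sc2$m_vmax_aadc))
  # the substrate builds up as the enzyme goes down (at fixed btrp)
  eq_htp <- function(m) {
    pp <- apply_multipliers(sero_params(), c(vmax_aadc = m))
    compute_equilibrium(pp, anchors = baseline_eq$anchors)$state[["htp"]]
  }
  htps <- vapply(c(0.25, 0.5, 1, 1.5), eq_htp, numeric(1))
  expect_true(all(diff(htps) < 0))
})
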