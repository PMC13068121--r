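test_that("fixed seed reproduces the cohort exactly and extension is stable", {
  cfg <- synth_config(n_patients = 20, n_controls = 10, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # adding subjects never changes earlier subjects
  bigger <- generate_cohort(synth_config(n_patients = 30, n_controls = 10,
                                         seed = 7))
  expect_identical(a$ll, bigger$ll[1:20])
  expect_identical(a$svv_3, bigger$svv_3[1:20])
})

test_that("configuration validation names the offending field", {
  expect_error(synth_config(n_patients = 0), "n_patients")
  expect_error(synth_config(p_right = 1.2), "p_right")
  expect_error(synth_config(missing_rates = c(vhit = 0, cvemp = 0,
                                              ovemp = 2, svv = 0,
                                              caloric = 0)),
               "missing_rates")
  expect_error(synth_config(vhit_bias = c(lateral = 0)), "vhit_bias")
  bad <- deficit_default(); bad$lateral_sd <- NULL
  expect_error(synth_config(deficit = bad), "deficit")
})

test_that("controls recover the injected vHIT bias and symmetry", {
  cfg <- synth_config(n_controls = 500, seed = 11, outlier_rate = 0,
                      vhit_bias = c(lateral = -0.06, anterior = -0.01,
                                    posterior = -0.03))
  ctl <- generate_controls(cfg)
  expect_true(all(is.na(ctl$true_side)))
  expect_lt(abs(mean(ctl$ll - ctl$rl) - (-0.06)), 0.01)
  cfg0 <- synth_config(n_controls = 500, seed = 11, outlier_rate = 0,
                       vhit_bias = c(lateral = 0, anterior = 0,
                                     posterior = 0))
  ctl0 <- generate_controls(cfg0)
  for (pair in list(c("ll", "rl"), c("la", "ra"), c("lp", "rp"))) {
    d <- ctl0[[pair[1]]] - ctl0[[pair[2]]]
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  }
})

test_that("zero deficit and zero bias give symmetric patients", {
  cfg <- synth_config(n_patients = 300, seed = 5,
                      deficit = deficit_null(), p_flip = 0,
                      vhit_bias = c(lateral = 0, anterior = 0,
                                    posterior = 0),
                      outlier_rate = 0)
  pat <- generate_cohort(cfg)
  prof <- canonicalize_signs(asymmetry_profile(pat))
  for (m in colnames(prof)) {
    v <- prof[, m]; v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
  }
})

test_that("strong deficits lateralize the caloric sign perfectly", {
  cfg <- synth_config(n_patients = 60, seed = 9, p_flip = 0,
                      missing_rates = c(vhit = 0, cvemp = 0, ovemp = 0,
                                        svv = 0, caloric = 0),
                      outlier_rate = 0)
  pat <- generate_cohort(cfg)
  cp <- canonicalize_signs(asymmetry_profile(pat))[, "caloric_cp"]
  expect_true(all(sign(cp) == pat$true_side))
})

test_that("label balance tracks p_right within binomial error", {
  for (p_right in c(0.3, 0.5, 0.7)) {
    cfg <- synth_config(n_patients = 400, p_right = p_right, seed = 21)
    frac <- mean(generate_cohort(cfg)$true_side == 1)
    expect_lt(abs(frac - p_right),
              3 * sqrt(p_right * (1 - p_right) / 400))
  }
})

test_that("missingness is injected block-wise at the configured rates", {
  cfg <- synth_config(n_patients = 4, seed = 2)
  pat <- generate_cohort(synth_config(n_patients = 2000, seed = 3,
                                      missing_rates = c(vhit = 0,
                                                        cvemp = 0,
                                                        ovemp = 0.044,
                                                        svv = 0.058,
                                                        caloric = 0.073)))
  # blocks vanish together
  cal <- pat[, c("caloric_right_cold", "caloric_right_warm",
                 "caloric_left_cold", "caloric_left_warm")]
  expect_true(all(rowSums(is.na(cal)) %in% c(0L, 4L)))
  svv <- pat[, paste0("svv_", 1:6)]
  expect_true(all(rowSums(is.na(svv)) %in% c(0L, 6L)))
  expect_true(all(!is.na(pat$ll)))
  expect_true(all(!is.na(pat$cvemp_left)))
  expect_lt(abs(mean(is.na(pat$ovemp_left)) - 0.044), 0.01)
  expect_lt(abs(mean(is.na(svv[, 1])) - 0.058), 0.01)
  expect_lt(abs(mean(is.na(cal[, 1])) - 0.073), 0.01)
  # degenerate rates
  none <- inject_missingness(generate_cohort(cfg),
                             c(vhit = 0, cvemp = 0, ovemp = 0, svv = 0,
                               caloric = 0), seed = 1)
  expect_identical(none, generate_cohort(cfg))
  allc <- inject_missingness(generate_cohort(cfg),
                             c(caloric = 1), seed = 1)
  expect_true(all(is.na(allc$caloric_left_warm)))
  expect_error(inject_missingness(generate_cohort(cfg),
                                  c(caloric = 1.5), seed = 1), "rates")
})

test_that("expected caloric asymmetry magnitude grows with the deficit", {
  mean_abs_cp <- function(factor, seed) {
    d <- deficit_default(); d$caloric_factor <- factor
    cfg <- synth_config(n_patients = 40, seed = seed, deficit = d,
                        p_flip = 0,
                        missing_rates = c(vhit = 0, cvemp = 0, ovemp = 0,
                                          svv = 0, caloric = 0))
    mean(abs(asymmetry_profile(generate_cohort(cfg))[, "caloric_cp"]))
  }
  wins <- 0
  for (s in 1:10) {
    m <- vapply(c(0.9, 0.6, 0.3), mean_abs_cp, 0, seed = s)
    if (m[1] < m[2] && m[2] < m[3]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
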