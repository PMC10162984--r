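test_that("initial-rate fits match the closed forms on consistent rates", {
  uni <- mech_uni_uni()
  set.seed(21)
  for (i in 1:20) {
    ra <- random_rate_assignment(uni)
    mac <- initial_rate_macroscopics(uni, ra$rates)
    cf <- uni_uni_closed_form(ra$rates)
    expect_equal(mac$kcat_f, cf$kcat_f, tolerance = 1e-4)
    expect_equal(mac$km_s, cf$km_s, tolerance = 1e-4)
    expect_equal(mac$kcat_b, cf$kcat_b, tolerance = 1e-4)
    expect_equal(mac$km_p, cf$km_p, tolerance = 1e-4)
    # thermodynamic identity between the macroscopic ratios and the route
    # product of the elementary constants
    expect_equal(mac$haldane_keq, ra$keq, tolerance = 1e-4)
    expect_lt(mac$residual_f, 1e-6)
  }
})

test_that("time rescaling doubles the turnover and leaves Km unchanged", {
  uni <- mech_uni_uni()
  set.seed(22)
  ra <- random_rate_assignment(uni, lo = 0.1)
  # halve first so the doubled constants stay within the normalized limit
  ra$rates[, c("k_f", "k_b")] <- ra$rates[, c("k_f", "k_b")] / 2
  m1 <- initial_rate_macroscopics(uni, ra$rates)
  r2 <- ra$rates
  r2[, c("k_f", "k_b")] <- 2 * r2[, c("k_f", "k_b")]
  m2 <- initial_rate_macroscopics(uni, r2)
  expect_equal(m2$kcat_f, 2 * m1$kcat_f, tolerance = 1e-6)
  expect_equal(m2$kcat_b, 2 * m1$kcat_b, tolerance = 1e-6)
  expect_equal(m2$km_s, m1$km_s, tolerance = 1e-6)
  expect_equal(m2$km_p, m1$km_p, tolerance = 1e-6)
})

test_that("bi-substrate macroscopics come from the titration route", {
  ord <- mech_ordered_bi_uni()
  set.seed(23)
  ra <- random_rate_assignment(ord)
  mac <- initial_rate_macroscopics(ord, ra$rates)
  expect_gt(mac$kcat_f, 0)
  expect_gt(mac$km_s, 0)
  expect_gt(mac$kcat_b, 0)
  expect_lt(mac$residual_f, 1e-3)
  # the titrated substrate defaults to the first binder
  expect_identical(mac$titrate_f, "A")
  expect_identical(mac$titrate_b, "P")
})
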