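test_that("characteristic concentration is the ratio of the rate limits", {
  expect_equal(characteristic_concentration(rate_limits(1e5, 1e9)), 1e-4)
  expect_equal(characteristic_concentration(rate_limits(1e4, 1e8)), 1e-4)
  expect_equal(characteristic_concentration(rate_limits(1e6, 1e8)), 1e-2)
  expect_error(rate_limits(-1, 1e9), "positive")
})

test_that("operating points normalize concentrations and compute the displacement", {
  uni <- mech_uni_uni()
  pt <- operating_point(uni, c(S = 1, P = 1), keq = 2)
  expect_equal(pt$gamma, 0.5)
  expect_false(pt$equilibrium)

  rb <- mech_random_bi_uni()
  ptb <- operating_point(rb, c(A = 1, B = 1, P = 1), keq = 2)
  expect_equal(ptb$gamma, 0.5)

  # molar input: 1e-4 M is one dimensionless unit at default limits, and the
  # equilibrium constant picks up one characteristic-concentration factor
  # per excess substrate
  raw <- operating_point(rb, c(A = 1e-4, B = 1e-4, P = 1e-4),
                         keq = 2 / 1e-4, dimensionless = FALSE)
  expect_equal(unname(raw$conc), c(1, 1, 1))
  expect_equal(raw$keq, 2)
  expect_equal(raw$gamma, 0.5)

  expect_error(operating_point(uni, c(S = 1, P = -1), keq = 2), "positive")
  expect_error(operating_point(uni, c(S = 1), keq = 2), "P")
})

test_that("displacement from concentrations equals displacement from free energy", {
  uni <- mech_uni_uni()
  set.seed(11)
  for (i in 1:20) {
    conc <- c(S = 10^runif(1, -2, 2), P = 10^runif(1, -2, 2))
    dg0 <- runif(1, -20, 20)
    pt <- operating_point(uni, conc, dg0_kj_mol = dg0)
    g8 <- gamma_from_dg(dg0, conc, "S", "P")
    expect_equal(pt$gamma, g8, tolerance = 1e-10)
  }
  # zero standard free energy at unit concentrations sits exactly at
  # equilibrium
  pt0 <- operating_point(uni, c(S = 1, P = 1), dg0_kj_mol = 0)
  expect_true(pt0$equilibrium)
})

test_that("the reverse transform is an involution and flags equilibrium", {
  uni <- mech_uni_uni()
  pt <- operating_point(uni, c(S = 1, P = 8), keq = 2)  # Gamma = 4
  expect_equal(pt$gamma, 4)
  rev <- reverse_point(pt)
  expect_equal(rev$gamma, 0.25)
  expect_equal(rev$keq, 0.5)
  expect_identical(rev$direction, "reverse")
  expect_identical(rev$substrates, "P")
  back <- reverse_point(rev)
  expect_equal(back$gamma, pt$gamma)
  expect_equal(back$keq, pt$keq)
  expect_identical(back$direction, "forward")

  fwd <- operating_point(uni, c(S = 4, P = 1), keq = 2)
  expect_warning(reverse_point(fwd), "already")

  eq <- operating_point(uni, c(S = 1, P = 2), keq = 2)
  expect_true(eq$equilibrium)
  expect_identical(reverse_point(eq), eq)
})

test_that("step concentration multipliers resolve binding direction", {
  uni <- mech_uni_uni()
  pt <- operating_point(uni, c(S = 3, P = 5), keq = 2)
  cc <- step_concentrations(uni, pt)
  expect_equal(cc$c_f, c(3, 1, 1))
  expect_equal(cc$c_b, c(1, 1, 5))

  rb <- mech_random_bi_uni()
  ptb <- operating_point(rb, c(A = 2, B = 7, P = 5), keq = 2)
  ccb <- step_concentrations(rb, ptb)
  expect_equal(ccb$c_f, c(2, 7, 1, 1, 7, 2))
  expect_equal(ccb$c_b, c(1, 1, 1, 5, 1, 1))

  bad <- uni
  bad$steps$forward_binds[1L] <- "Q"
  expect_error(step_concentrations(bad, pt), "unknown species")
})
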