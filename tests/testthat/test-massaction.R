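test_that("steady state solves the balance system and detects detailed balance", {
  uni <- mech_uni_uni()
  pt <- uni_point()
  # all rate constants equal at unit concentrations: the three-cycle is
  # symmetric, the distribution uniform and the system at detailed balance
  rates <- data.frame(index = 1:3, k_f = 1, k_b = 1)
  ss <- steady_state(uni, rates, pt)
  expect_equal(unname(ss$e), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ss$v_net, 0, tolerance = 1e-12)

  # a hand-checkable asymmetric case: E -> ES -> EP -> E irreversible,
  # with k1f = k2f = k3f = 1: uniform occupancy, unit cycle flux per enzyme
  irr <- data.frame(index = 1:3, k_f = 1, k_b = 0)
  ss2 <- steady_state(uni, irr, pt)
  expect_equal(unname(ss2$e), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ss2$v_net, 1 / 3, tolerance = 1e-12)

  # Kirchhoff balance on the branched mechanism: each branch combination
  # carries the overall net flux
  rb <- mech_random_bi_uni()
  set.seed(5)
  rr <- data.frame(index = 1:6, k_f = runif(6, 0.2, 1), k_b = runif(6, 0.2, 1))
  ssb <- steady_state(rb, rr, rb_point(A = 2, B = 0.5, P = 1))
  for (bk in rb$branch_combinations) {
    expect_equal(sum(ssb$v_steps$v_net[match(bk, ssb$v_steps$index)]),
                 ssb$v_net, tolerance = 1e-10)
  }
})

test_that("an absorbing state makes the steady-state system singular", {
  uni <- mech_uni_uni()
  # EP can be entered but never left
  rates <- data.frame(index = 1:3, k_f = c(1, 1, 0), k_b = c(1, 0, 0))
  expect_error(steady_state(uni, rates, uni_point()), "EP")
})

test_that("closed-form inner value agrees with the simplex LP", {
  set.seed(9)
  for (mech in list(mech_uni_uni(), mech_ordered_bi_uni())) {
    conc <- c(S = 2, P = 0.5, A = 2, B = 1.5)
    pt <- operating_point(mech, conc[c(mech$substrates, mech$products)], keq = 2)
    G <- pt$gamma
    plan <- discretization_plan(mech, G, 1e-2)
    for (rep in 1:50) {
      hat <- sort(runif(length(plan$ids), G, 1), decreasing = TRUE)
      names(hat) <- plan$ids
      gamma <- enzopt:::plan_gamma_values(plan, hat)
      v_closed <- inner_lp_value(mech, pt, gamma)
      v_lp <- inner_lp_value(mech, pt, gamma, method = "simplex")
      expect_equal(v_closed, v_lp, tolerance = 1e-9)
    }
  }
})

test_that("two-route split optimization agrees with the simplex LP", {
  rb <- mech_random_bi_uni()
  pt <- rb_point(A = 1, B = 2, P = 1)
  G <- pt$gamma
  plan <- discretization_plan(rb, G, 1e-2)
  set.seed(10)
  n_checked <- 0L
  while (n_checked < 50L) {
    hat <- runif(4, G, 1)
    names(hat) <- plan$ids
    hat["gcycle"] <- runif(1, G, min(hat["g1"], hat["g5"]))
    if (prod(hat[c("gcycle", "g3")]) < G) next
    gamma <- enzopt:::plan_gamma_values(plan, hat)
    if (any(gamma > 1 | gamma < 0)) next
    v_fast <- inner_lp_value(rb, pt, gamma)
    v_lp <- inner_lp_value(rb, pt, gamma, method = "simplex")
    expect_equal(v_fast, v_lp, tolerance = 1e-9)
    n_checked <- n_checked + 1L
  }
})

test_that("a displacement at 1 pins the flux to zero through that step", {
  uni <- mech_uni_uni()
  pt <- uni_point()
  expect_equal(inner_lp_value(uni, pt, c(1, 0.6, 0.5 / 0.6)), 0)
  # on a branch the other route still carries flux
  rb <- mech_random_bi_uni()
  g <- c(1, 0.55, 0.95, 0.5 / (0.55 * 0.95), 0.75, 0.55 / 0.75)
  v <- inner_lp_value(rb, rb_point(), g, details = TRUE)
  expect_gt(v$value, 0)
  expect_equal(v$beta, 0, tolerance = 1e-9)
})

test_that("brute-force optimum converges under grid refinement", {
  uni <- mech_uni_uni()
  pt <- uni_point()
  coarse <- brute_force_optimum(uni, pt, n_grid = 100)
  fine <- brute_force_optimum(uni, pt, n_grid = 400)
  expect_lt(abs(fine$value - coarse$value) / fine$value, 0.01)
  expect_true(all(fine$gamma >= pt$gamma - 1e-12 & fine$gamma <= 1 + 1e-12))
  expect_equal(prod(fine$gamma), pt$gamma, tolerance = 1e-10)
})
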