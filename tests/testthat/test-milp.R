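test_that("the MILP solves the three-step mechanism to the grid oracle", {
  uni <- mech_uni_uni()
  pt <- uni_point()
  sol <- uni_solution()
  expect_identical(sol$status, "optimal")
  oracle <- brute_force_optimum(uni, pt, n_grid = 200)
  expect_lt(abs(sol$objective - oracle$value) / oracle$value, 2 / 200)
  # polished solutions satisfy the physical identities to machine precision
  expect_equal(sum(sol$e), 1, tolerance = 1e-12)
  expect_true(all(sol$z_f <= sol$e[uni$steps$from] + 1e-9))
  expect_true(all(sol$z_b <= sol$e[uni$steps$to] + 1e-9))
  expect_true(all(sol$gamma >= pt$gamma - 1e-12 & sol$gamma <= 1 + 1e-12))
  expect_equal(prod(sol$gamma), pt$gamma, tolerance = 1e-12)
})

test_that("solver variables satisfy the Petersen products at the optimum", {
  # an untightened model keeps its binary expansions free, so the
  # linearization variables are present and checkable
  uni <- mech_uni_uni()
  pt <- uni_point()
  plan <- discretization_plan(uni, pt$gamma, 1e-2)
  model <- build_milp(uni, pt, plan, options = list(tighten = FALSE))
  sol <- solve_milp(model)
  expect_identical(sol$status, "optimal")
  x <- sol$raw
  # every linearization variable t[cont|bin] equals bin * cont
  tnames <- grep("^t\\[", model$names, value = TRUE)
  expect_gt(length(tnames), 0L)
  for (tn in tnames) {
    parts <- sub("^t\\[", "", sub("\\]$", "", tn))
    cont <- sub("\\|.*$", "", parts)
    bin <- sub("^.*?\\|", "", parts)
    expect_equal(unname(x[tn]), unname(round(x[bin]) * x[cont]),
                 tolerance = 1e-6)
  }
})

test_that("bin refinement never decreases the objective", {
  uni <- mech_uni_uni()
  pt <- uni_point()
  v_coarse <- solve_optimal(uni, pt, resolution = 1e-2)$objective
  v_fine <- solve_optimal(uni, pt, resolution = 5e-3)$objective
  expect_gte(v_fine, v_coarse - 1e-12)
})

test_that("equilibrium points short-circuit with zero flux", {
  for (mech in list(mech_uni_uni(), mech_random_bi_uni())) {
    conc <- c(S = 1, P = 2, A = 1, B = 1)
    names_needed <- c(mech$substrates, mech$products)
    conc_eq <- conc[names_needed]
    conc_eq[mech$products] <- 2 * prod(conc_eq[mech$substrates])
    pt <- operating_point(mech, conc_eq, keq = 2)
    expect_true(pt$equilibrium)
    sol <- solve_optimal(mech, pt)
    expect_identical(sol$status, "equilibrium")
    expect_identical(sol$objective, 0)
  }
})

test_that("points beyond equilibrium are solved in the reverse direction", {
  uni <- mech_uni_uni()
  pt <- operating_point(uni, c(S = 1, P = 8), keq = 2)  # Gamma = 4
  sol <- solve_optimal(uni, pt, resolution = 1e-3)
  expect_identical(sol$status, "optimal")
  expect_true(sol$reversed)
  expect_gt(sol$objective, 0)
  expect_lt(sol$v_net_signed, 0)
  # mirror point: S and P exchanged with the inverse equilibrium constant
  mirror <- operating_point(uni, c(S = 8, P = 1), keq = 0.5)
  sol_m <- solve_optimal(uni, mirror, resolution = 1e-3)
  expect_equal(sol$objective, sol_m$objective, tolerance = 1e-9)
})

test_that("pinning the objective preserves the optimum and relaxing keeps it feasible", {
  sol <- uni_solution()
  pinned <- fix_objective(sol$model, sol$objective, slack = 0)
  re <- solve_milp(pinned)
  expect_equal(re$objective, sol$objective, tolerance = 1e-9)
  relaxed <- fix_objective(sol$model, sol$objective, slack = 0.1)
  re2 <- solve_milp(relaxed)
  expect_gte(re2$objective, sol$objective * (1 - 1e-9))
  expect_error(fix_objective(sol$model, -1), "nonnegative")
})

test_that("exchanging the substrate concentrations mirrors the optimum", {
  rb <- mech_random_bi_uni()
  s1 <- solve_optimal(rb, rb_point(A = 0.5, B = 2), resolution = 1e-2)
  s2 <- solve_optimal(rb, rb_point(A = 2, B = 0.5), resolution = 1e-2)
  expect_equal(s1$objective, s2$objective, tolerance = 1e-9)
  a1 <- splitting_ratio(s1)
  a2 <- splitting_ratio(s2)
  expect_equal(a1 + a2, 1, tolerance = 2 * 1e-2)
})

test_that("the certified windows retain the optimum", {
  rb <- mech_random_bi_uni()
  pt <- rb_point(A = 2, B = 0.7)
  plan <- discretization_plan(rb, pt$gamma, 1e-2)
  dw <- displacement_windows(rb, pt, plan)
  expect_true(all(dw$windows$p_lo <= dw$p_best[dw$windows$id]))
  expect_true(all(dw$windows$p_hi >= dw$p_best[dw$windows$id]))
  expect_gte(dw$ub, dw$lb - 1e-15)
  # the windowed solve and the unrestricted solve agree
  sol_t <- solve_milp(build_milp(rb, pt, plan))
  sol_f <- solve_milp(build_milp(rb, pt, plan, options = list(tighten = FALSE)))
  expect_equal(sol_t$objective, sol_f$objective, tolerance = 1e-9)
})
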