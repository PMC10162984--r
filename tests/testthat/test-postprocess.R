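test_that("rate constants are recovered by dividing out the enzyme states", {
  # constructed solution: z = 0.2 against e = 0.4 gives k = 0.5; a tight
  # z = e gives the limit k = 1; a vanishing state flags NA
  uni <- mech_uni_uni()
  sol <- list(
    e = c(E = 0.4, ES = 0.5, EP = 1e-12),
    z_f = c(0.2, 0.5, 0.3),
    z_b = c(0.1, 0.2, 0.4),
    mech = uni
  )
  k <- back_calculate_k(sol, uni)
  expect_equal(k$k_f[1L], 0.5)
  expect_equal(k$k_f[2L], 1)
  expect_true(is.na(k$k_f[3L]))   # departs from EP, which is empty
  expect_true(is.na(k$k_b[2L]))   # arrives at EP
  expect_equal(k$k_b[1L], 0.1 / 0.5)
})

test_that("back-calculated constants reproduce the optimum through mass action", {
  sol <- uni_solution()
  uni <- mech_uni_uni()
  k <- back_calculate_k(sol, uni)
  ss <- steady_state(uni, k, uni_point())
  expect_equal(ss$v_net, sol$objective, tolerance = 1e-6)
  expect_equal(unname(ss$e[names(sol$e)]), unname(sol$e), tolerance = 1e-6)
})

test_that("saturation and free-energy shares have their defining properties", {
  sol <- uni_solution()
  expect_equal(saturation(sol), 1 - unname(sol$e["E"]))
  shares <- dg_fractions(sol)
  expect_equal(sum(shares), 1, tolerance = 1e-6)
  expect_true(all(shares >= -1e-12))

  # an unbranched mechanism has no splitting ratio
  a <- splitting_ratio(sol)
  expect_true(is.na(a))
  expect_true(isTRUE(attr(a, "not_applicable")))
})

test_that("the three-step optimum is unique under variability analysis", {
  sol <- uni_solution()
  vars <- c("v_net", "z_f[1]", "e[E]", "e[ES]",
            sprintf("gamma_hat[%s]", sol$plan$ids))
  va <- variability(sol$model, sol, vars)
  expect_true(all(va$reliable))
  expect_true(all(va$max - va$min <= 1e-5))
  expect_true(all(sol$objective >= va$min[1L] - 1e-9 &
                    sol$objective <= va$max[1L] + 1e-9))
})

test_that("the symmetric two-substrate point has a flexible splitting ratio", {
  sol <- rb_sym_solution()
  av <- alpha_variability(sol$model, sol)
  expect_gt(av$width, 0)
  expect_equal(av$midpoint, 0.5, tolerance = 2 * 1e-3)
  # relaxing the objective pin can only widen the range
  m_relaxed <- fix_objective(sol$model, sol$objective, slack = 0.05)
  sol_r <- solve_milp(m_relaxed)
  av_r <- alpha_variability(m_relaxed, sol_r)
  expect_gte(av_r$width, av$width - 1e-9)
})

test_that("alternative optima share saturation and displacements but not the split", {
  sol <- rb_sym_solution()
  smp <- sample_alternative_optima(sol$model, sol, n = 50, seed = 3)
  expect_gte(nrow(smp), 50)
  av <- alpha_variability(sol$model, sol)
  expect_lt(min(smp$alpha) - av$alpha_min, 0.1 * av$width + 1e-6)
  expect_gt(max(smp$alpha) - av$alpha_max, -0.1 * av$width - 1e-6)
  expect_lt(diff(range(smp$sigma)), 1e-4)
  gamma_cols <- grep("^gamma\\.", names(smp), value = TRUE)
  for (gc in gamma_cols) expect_lt(diff(range(smp[[gc]])), 1e-4)
  # total substrate-bound enzyme is conserved across the alternatives
  expect_lt(diff(range(smp$e.EA + smp$e.EB)), 1e-4)
  # every row satisfies the physical constraints
  e_cols <- grep("^e\\.", names(smp), value = TRUE)
  expect_true(all(abs(rowSums(smp[, e_cols]) - 1) < 1e-8))
  g <- as.matrix(smp[, gamma_cols])
  expect_true(all(g >= 0.5 - 1e-9 & g <= 1 + 1e-9))
})

test_that("suboptimal exploration respects the cut and widens with it", {
  sol <- rb_sym_solution()
  rb <- mech_random_bi_uni()
  pt <- rb_point()
  plan <- discretization_plan(rb, pt$gamma, 1e-3)
  m90 <- build_milp(rb, pt, plan, options = list(suboptimal_cut = 0.9))
  smp90 <- explore_suboptimal(m90, sol, c_l = 0.9, n = 25, seed = 5)
  expect_true(all(smp90$v_net >= 0.9 * sol$objective * (1 - 1e-9)))
  m99 <- build_milp(rb, pt, plan, options = list(suboptimal_cut = 0.99))
  smp99 <- explore_suboptimal(m99, sol, c_l = 0.99, n = 25, seed = 5)
  expect_gte(diff(range(smp90$alpha)), diff(range(smp99$alpha)) - 1e-6)
  expect_error(explore_suboptimal(m90, sol, c_l = 1.5), "c_l")
})
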