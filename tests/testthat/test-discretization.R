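test_that("bin counts follow the requested resolution", {
  uni <- mech_uni_uni()
  plan <- discretization_plan(uni, 0.6, 1e-4)
  expect_equal(plan$N, 4000L)
  expect_equal(plan$nbits, 12L)
  expect_equal(plan$width, 0.4 / 4000)

  # close to equilibrium the resolution tightens automatically
  plan_eq <- discretization_plan(uni, 0.95, 1e-3)
  expect_equal(plan_eq$resolution, 1e-4)
  expect_equal(plan_eq$N, 500L)

  expect_error(discretization_plan(uni, 1.2), "between 0 and 1")
  expect_warning(discretization_plan(uni, 0.5, 0.6), "degenerate")
})

test_that("default independent sets match the mechanism structure", {
  uni_plan <- discretization_plan(mech_uni_uni(), 0.5)
  expect_length(uni_plan$ids, 2L)

  ord_plan <- discretization_plan(mech_ordered_bi_uni(), 0.5)
  expect_length(ord_plan$ids, 3L)

  rb_plan <- discretization_plan(mech_random_bi_uni(), 0.5)
  expect_length(rb_plan$ids, 4L)
  expect_setequal(rb_plan$ids, c("g1", "g5", "gcycle", "g3"))
  # the cycle composite is ordered below both first binding displacements
  ords <- vapply(rb_plan$ordering, paste, character(1), collapse = "<=")
  expect_setequal(ords, c("gcycle<=g1", "gcycle<=g5"))
  expect_length(rb_plan$product_floor, 1L)
  expect_setequal(rb_plan$product_floor[[1L]], c("gcycle", "g3"))
})

test_that("substituting the expressions reproduces the route products exactly", {
  set.seed(4)
  for (mech in list(mech_uni_uni(), mech_ordered_bi_uni(),
                    mech_random_bi_uni())) {
    G <- 0.37
    plan <- discretization_plan(mech, G, 1e-2)
    for (rep in 1:25) {
      hat <- sort(runif(length(plan$ids), G, 1))
      names(hat) <- plan$ids
      # enforce the ordering / floor structure before substitution
      for (oc in plan$ordering) {
        if (hat[oc[1L]] > hat[oc[2L]]) {
          hat[c(oc[1L], oc[2L])] <- hat[c(oc[2L], oc[1L])]
        }
      }
      skip <- FALSE
      for (pf in plan$product_floor) if (prod(hat[pf]) < G) skip <- TRUE
      if (skip) next
      gamma <- enzopt:::plan_gamma_values(plan, hat)
      # every route product telescopes to the overall displacement
      for (route in mech$routes) {
        pos <- match(route, mech$steps$index)
        expect_equal(prod(gamma[pos]), G, tolerance = 1e-12)
      }
      # cycle products cancel to one
      for (cyc in mech$fundamental_cycles) {
        pos <- match(cyc$index, mech$steps$index)
        expect_equal(prod(gamma[pos]^cyc$sign), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("binary encoding spans the displacement range inclusively", {
  plan <- discretization_plan(mech_uni_uni(), 0.5, 1e-2)
  expect_equal(encode_displacement(plan, "g1", rep(0, plan$nbits)), 0.5)
  # p = N reaches exactly 1
  bits_N <- as.integer(intToBits(plan$N))[seq_len(plan$nbits)]
  expect_equal(encode_displacement(plan, "g1", bits_N), 1)
  # a middle bin
  expect_equal(encode_displacement(plan, "g1", c(1)), 0.5 + (1 - 0.5) / plan$N)
  expect_error(encode_displacement(plan, "g1", rep(1, plan$nbits + 2L)),
               "longer")
  expect_error(encode_displacement(plan, "nope", c(1)), "unknown")
})
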