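test_that("built-in mechanisms have the expected graph structure", {
  uni <- mech_uni_uni()
  expect_equal(uni$n_e, 3L)
  expect_equal(uni$n_b, 0L)
  expect_equal(uni$n_states, 3L)
  expect_equal(uni$unbranched_steps, 1:3)
  expect_length(uni$fundamental_cycles, 0L)
  expect_identical(uni$steps$forward_binds[1L], "S")
  expect_identical(uni$steps$backward_binds[3L], "P")

  ord <- mech_ordered_bi_uni()
  expect_equal(ord$n_e, 4L)
  expect_equal(ord$n_states, 4L)
  expect_equal(ord$n_b, 0L)
  expect_equal(ord$unbranched_steps, 1:4)
  expect_equal(ord$steps$forward_order[2L], 2L)
  expect_length(ord$branch_combinations, 0L)

  rb <- mech_random_bi_uni()
  expect_equal(rb$n_e, 6L)
  expect_equal(rb$n_states, 5L)
  expect_equal(rb$n_b, 1L)
  expect_equal(rb$unbranched_steps, c(3L, 4L))
  expect_setequal(
    vapply(rb$branch_combinations, paste, character(1), collapse = ","),
    c("1,5", "2,5", "1,6", "2,6")
  )
})

test_that("fundamental cycles are branch loops that conserve the start state", {
  rb <- mech_random_bi_uni()
  cycles <- find_fundamental_cycles(rb)
  expect_length(cycles, 1L)
  # the single cycle couples the two binding orders: steps (5,6) against (1,2)
  cyc <- cycles[[1L]]
  expect_setequal(cyc$index[cyc$sign == 1L], c(5L, 6L))
  expect_setequal(cyc$index[cyc$sign == -1L], c(1L, 2L))

  expect_length(find_fundamental_cycles(mech_uni_uni()), 0L)
  expect_length(find_fundamental_cycles(mech_three_route()), 2L)
})

test_that("validate_mechanism flags structural defects and passes built-ins", {
  for (m in list(mech_uni_uni(), mech_ordered_bi_uni(), mech_random_bi_uni(),
                 mech_three_route())) {
    expect_length(validate_mechanism(m), 0L)
  }

  two_free <- mech_uni_uni()
  two_free$states <- c("E", "ES", "EP", "E")
  expect_match(paste(validate_mechanism(two_free), collapse = ";"),
               "duplicate state|multiple free")

  bad_count <- mech_random_bi_uni()
  bad_count$n_b <- 0L
  expect_match(paste(validate_mechanism(bad_count), collapse = ";"),
               "state count mismatch")

  same_species <- mechanism(
    data.frame(index = 1:2, from = c("E", "ES"), to = c("ES", "E"),
               forward_binds = c("S", NA), backward_binds = c("S", NA)),
    free_state = "E"
  )
  expect_match(paste(validate_mechanism(same_species), collapse = ";"),
               "same species")
})

test_that("swapping the substrate labels relabels but preserves the mechanism", {
  rb <- mech_random_bi_uni()
  st <- rb$steps
  st$forward_binds <- chartr("AB", "BA", st$forward_binds)
  swapped <- mechanism(st, free_state = "E")
  expect_length(validate_mechanism(swapped), 0L)
  # relabeling steps 1<->5, 2<->6 and states EA<->EB recovers the original
  # binding annotations
  perm <- c(5L, 6L, 3L, 4L, 1L, 2L)
  expect_identical(swapped$steps$forward_binds[perm],
                   rb$steps$forward_binds)
  expect_identical(swapped$n_b, rb$n_b)
  expect_length(swapped$branch_combinations, length(rb$branch_combinations))
})

test_that("mechanism reversal is an involution that swaps binding sides", {
  for (m in list(mech_uni_uni(), mech_random_bi_uni())) {
    r <- reverse_mechanism(m)
    expect_identical(r$substrates, m$products)
    expect_identical(r$products, m$substrates)
    back <- reverse_mechanism(r)
    expect_identical(back$steps$from, m$steps$from)
    expect_identical(back$steps$forward_binds, m$steps$forward_binds)
    expect_length(validate_mechanism(r), 0L)
  }
})

test_that("JSON serialization round-trips and recomputes derived structure", {
  rb <- mech_random_bi_uni()
  path <- tempfile(fileext = ".json")
  mech_to_json(rb, path)
  back <- mech_from_json(path)
  expect_identical(back$steps$from, rb$steps$from)
  expect_identical(back$steps$forward_binds, rb$steps$forward_binds)
  expect_equal(back$unbranched_steps, rb$unbranched_steps)
  expect_length(back$fundamental_cycles, 1L)
  unlink(path)
})
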