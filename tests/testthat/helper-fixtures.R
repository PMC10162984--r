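# Shared fixtures; heavyweight solves are computed lazily and cached so
# several test files can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

uni_point <- function(S = 1, P = 1, keq = 2) {
  operating_point(mech_uni_uni(), c(S = S, P = P), keq = keq)
}

rb_point <- function(A = 1, B = 1, P = 1, keq = 2) {
  operating_point(mech_random_bi_uni(), c(A = A, B = B, P = P), keq = keq)
}

# symmetric random bi-uni optimum with model, reused by variability and
# sampling tests
rb_sym_solution <- function() {
  cached("rb_sym", {
    solve_optimal(mech_random_bi_uni(), rb_point(), resolution = 1e-3,
                  keep_model = TRUE)
  })
}

uni_solution <- function() {
  cached("uni_11", {
    solve_optimal(mech_uni_uni(), uni_point(), resolution = 1e-3,
                  keep_model = TRUE)
  })
}

# a three-route toy: E binds S through three parallel one-step routes via
# distinct intermediates, then releases P (used for cycle-count checks)
mech_three_route <- function() {
  mechanism(
    data.frame(
      index = 1:7,
      from = c("E", "X1", "E", "X2", "E", "X3", "EP"),
      to = c("X1", "EP", "X2", "EP", "X3", "EP", "E"),
      forward_binds = c("S", NA, "S", NA, "S", NA, NA),
      backward_binds = c(NA, NA, NA, NA, NA, NA, "P")
    ),
    free_state = "E"
  )
}
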