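test_that("isoline points keep the product-to-substrate ratio fixed", {
  pts <- isoline_points(0.6, keq = 2, n = 5)
  expect_equal(pts$P / pts$S, rep(1.2, 5))
  expect_true(all(diff(pts$S) > 0))
  eq <- isoline_points(1, keq = 2, n = 3)
  expect_true(attr(eq, "equilibrium"))
  expect_error(isoline_points(0, keq = 2), "gamma_target")
})

test_that("scans cover the grid, flag equilibrium and are reproducible", {
  spec <- fixture_suite(seed = 7)$equilibrium_line
  scan <- run_scan(spec)
  expect_equal(nrow(scan$points), 3L)
  expect_true(all(scan$points$status == "equilibrium"))
  expect_true(all(scan$points$v_net == 0))

  spec2 <- scan_spec("uni_uni", axes = list(S = c(0.4, 2)), fixed = c(P = 1),
                     keq = 2, resolution = 1e-3, outputs = c("sigma", "e"))
  s1 <- run_scan(spec2)
  s2 <- run_scan(spec2)
  expect_equal(nrow(s1$points), 2L)
  expect_true(all(s1$points$status == "optimal"))
  # identical spec, identical results (solver and presolve are deterministic)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$values, s2$values)
  # long values carry the enzyme states, which sum to one per point
  e_rows <- s1$values[s1$values$quantity == "e", ]
  sums <- tapply(e_rows$value, e_rows$point, sum)
  expect_true(all(abs(sums - 1) < 1e-8))

  paths <- write_scan_csv(s1, file.path(tempdir(), "scan_test"))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1L])
  expect_equal(nrow(back), 2L)
})

test_that("scan spec validation and failure isolation work", {
  expect_error(scan_spec("uni_uni", axes = list(), keq = 2), "at least one")
  expect_error(scan_spec("uni_uni", axes = list(S = 1:2, P = 1:3), keq = 2,
                         paired = TRUE), "same length")
  expect_error(resolve_mechanism("not_a_mechanism"), "unknown mechanism")

  # a point with a missing species errors but the scan continues
  spec <- scan_spec("uni_uni", axes = list(S = c(1, 2)), fixed = c(),
                    keq = 2, resolution = 1e-3)
  scan <- run_scan(spec)
  expect_true(all(grepl("^error", scan$points$status)))
  expect_equal(nrow(scan$points), 2L)
})

test_that("fixture suite manifests match its specifications", {
  fx <- fixture_suite(seed = 1)
  man <- attr(fx, "manifest")
  expect_setequal(names(fx), man$fixture)
  expect_s3_class(fx$uni_uni_oracle, "enz_scan_spec")
  expect_lte(length(fx$uni_uni_oracle$axes$S), 25L)
})
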