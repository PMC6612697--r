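test_that("per-point minimum DTA map matches hand-enumerated candidates", {
  st <- native_settings()
  ref <- row_grid(c(100, 100, 100))
  ev <- row_grid(c(110, 100, 100))
  # point 0: co-located dose 110 is out of tolerance; nearest in-tolerance
  # candidate (dose 100) sits 1 mm away with delta = 0
  m <- per_point_min_dta(ref, ev, 3, st)
  expect_equal(as.vector(m$values), c(1, 0, 0))

  ident <- per_point_min_dta(ref, ref, 3, st)
  expect_equal(as.vector(ident$values), c(0, 0, 0))

  # constant +5% offset: no candidate is ever within a 3% dose tolerance
  u5 <- per_point_min_dta(dose_grid(matrix(100, 5, 5)),
                          dose_grid(matrix(105, 5, 5)), 3, st)
  expect_true(all(u5$values == Inf))
})

test_that("per-point minimum dose-criterion map handles the strict DTA boundary", {
  st <- native_settings()
  # constant +5%: the co-located candidate dominates at any dta
  u <- per_point_min_dd(dose_grid(matrix(100, 5, 5)),
                        dose_grid(matrix(105, 5, 5)), 2, st)
  expect_equal(unname(u$values[u$included_mask]), rep(5, 25), tolerance = 1e-9)

  ident <- row_grid(c(100, 100, 100))
  expect_true(all(per_point_min_dd(ident, ident, 2, st)$values == 0))

  # single evaluated point at exactly r = dta with a dose mismatch:
  # r < dta fails strictly, so the point is unreachable; closer reference
  # points get the closed-form 100*|delta| / (norm * sqrt(1 - r^2/dta^2))
  ref <- row_grid(c(100, 100, 100))
  ev1 <- dose_grid(matrix(103, 1, 1), origin = c(2, 0))
  m <- per_point_min_dd(ref, ev1, 2, st)
  expect_equal(as.vector(m$values),
               c(Inf, 3 / sqrt(1 - 0.25), 3), tolerance = 1e-12)
})

test_that("per-point ratio-linked map follows its closed form", {
  st <- native_settings()
  u <- per_point_min_scale(dose_grid(matrix(100, 5, 5)),
                           dose_grid(matrix(103, 5, 5)), 3, st)
  expect_equal(unname(u$values[u$included_mask]), rep(1, 25),
               tolerance = 1e-9)  # (3%, 1 mm) pair

  ident <- row_grid(c(100, 100, 100))
  expect_true(all(per_point_min_scale(ident, ident, 3, st)$values == 0))

  # 2 mm analytic shift with a tight ratio (1 %/mm): in the steep penumbra
  # the dose term punishes any non-matching dose, so the requirement is
  # essentially the distance to the shifted in-dose twin, approached from
  # below along the gradient
  ref <- square_field(extent_mm = 40, spacing_mm = 1, field_width_mm = 24,
                      penumbra_sigma_mm = 2)
  ev <- shift_field(ref, 2, 0)
  m <- per_point_min_scale(ref, ev, 1, search_settings(max_dta_mm = 4))
  steep <- abs(abs(grid_x(ref)) - 12) < 2   # penumbra columns
  vals <- m$values[steep, 21][m$included_mask[steep, 21]]
  expect_true(all(vals <= 2 + 1e-6))
  expect_gt(max(vals), 1.9)
})

test_that("iterative IG search reproduces its specified examples", {
  st <- native_settings()
  ident <- row_grid(c(100, 100, 100))
  r <- ig_search(ident, ident, "fixed_dd", 3, 100, st)
  expect_equal(r$found_dta_mm, 0)
  expect_equal(r$status, "converged")
  expect_equal(r$achieved_gai_pct, 100)
  expect_equal(r$n_iterations, 1L)

  r <- ig_search(row_grid(c(100, 100, 100)), row_grid(c(110, 100, 100)),
                 "fixed_dd", 3, 100, st)
  expect_equal(r$found_dta_mm, 1.0)
  expect_equal(r$status, "converged")
  expect_equal(r$trace$criterion, seq(0, 1, by = 0.1), tolerance = 1e-12)
  expect_equal(r$trace$gai_pct[1], 100 * 2 / 3)
  expect_equal(tail(r$trace$gai_pct, 1), 100)

  r <- ig_search(dose_grid(matrix(100, 5, 5)), dose_grid(matrix(105, 5, 5)),
                 "fixed_dd", 3, 95, native_settings(max_dta_mm = 5))
  expect_equal(r$status, "cap_reached")
  expect_equal(r$achieved_gai_pct, 0)
  expect_true(is.na(r$found_dta_mm))
})

test_that("quantile fast path reads the search answer off the requirement map", {
  st <- native_settings()
  ref <- row_grid(c(100, 100, 100))
  m <- per_point_min_dta(ref, row_grid(c(110, 100, 100)), 3, st)
  expect_equal(quantile_fast_path(m, 100, 0.1), 1.0)

  zeros <- per_point_min_dta(ref, ref, 3, st)
  expect_equal(quantile_fast_path(zeros, 100, 0.1), 0)
  expect_equal(quantile_fast_path(zeros, 50, 0.1), 0)

  # one unreachable point out of three (its in-tolerance candidate sits
  # 1 mm away, beyond the 0.5 mm cap): the 100% quantile is a sentinel,
  # the two-thirds quantile is not
  mixed <- per_point_min_dta(row_grid(c(100, 100, 100)),
                             row_grid(c(150, 100, 100)),
                             3, native_settings(max_dta_mm = 0.5))
  expect_equal(as.vector(mixed$values), c(Inf, 0, 0))
  expect_equal(quantile_fast_path(mixed, 100, 0.1), Inf)
  expect_equal(quantile_fast_path(mixed, 200 / 3, 0.1), 0)
})

test_that("requirement histogram yields cumulative GAI read-off", {
  st <- native_settings()
  m <- per_point_min_dta(row_grid(c(100, 100, 100)),
                         row_grid(c(110, 100, 100)), 3, st)
  h <- requirement_histogram(m)
  expect_equal(h$value, c(0, 1))
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$cum_gai_pct, c(100 * 2 / 3, 100))

  zeros <- per_point_min_dta(row_grid(c(100, 100)), row_grid(c(100, 100)), 3, st)
  hz <- requirement_histogram(zeros)
  expect_equal(nrow(hz), 1L)
  expect_equal(hz$cum_gai_pct, 100)

  # one of four unreachable: cumulative tops out at 75%
  ref4 <- dose_grid(matrix(100, 4, 1))
  ev4 <- dose_grid(matrix(c(150, 100, 100, 100), 4, 1))
  m4 <- per_point_min_dta(ref4, ev4, 3, native_settings(max_dta_mm = 0.5))
  h4 <- requirement_histogram(m4)
  expect_equal(max(h4$cum_gai_pct), 75)
  expect_equal(attr(h4, "n_unreachable"), 1L)
})

test_that("accelerated search equals the iterative search, trace included", {
  for (seed in 51:53) {
    p <- smooth_pair(seed)
    for (mode in c("fixed_dd", "fixed_dta", "fixed_ratio")) {
      fixed <- switch(mode, fixed_dd = 3, fixed_dta = 2, fixed_ratio = 1.5)
      st <- native_settings(max_dta_mm = 10, max_dd_pct = 10)
      a <- ig_search(p$ref, p$ev, mode, fixed, 95, st)
      b <- ig_search(p$ref, p$ev, mode, fixed, 95, st, accelerate = TRUE)
      expect_equal(a$status, b$status)
      expect_equal(a$found_dta_mm, b$found_dta_mm, tolerance = 1e-12)
      expect_equal(a$found_dd_pct, b$found_dd_pct, tolerance = 1e-12)
      expect_equal(a$n_iterations, b$n_iterations)
      expect_equal(a$trace$criterion, b$trace$criterion, tolerance = 1e-12)
      expect_equal(a$trace$gai_pct, b$trace$gai_pct, tolerance = 1e-9)
    }
  }
})
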