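test_that("normalization dose is the reference maximum and rejects empty fields", {
  expect_equal(normalization_dose(dose_grid(matrix(c(2, 5, 100), 3, 1))), 100)
  expect_equal(normalization_dose(dose_grid(matrix(2, 4, 4))), 2)
  expect_error(normalization_dose(dose_grid(matrix(0, 3, 3))),
               "zero normalization dose")
})

test_that("inclusion mask applies the lower dose threshold inclusively", {
  g <- row_grid(c(2, 5, 100))
  expect_equal(as.vector(inclusion_mask(g, gamma_criteria(3, 2, 5))),
               c(FALSE, TRUE, TRUE))  # threshold dose 5 is included
  expect_true(all(inclusion_mask(g, gamma_criteria(3, 2, 0))))
  expect_true(all(inclusion_mask(dose_grid(matrix(7, 5, 5)),
                                 gamma_criteria(3, 2, 5))))
})

test_that("bilinear resampling halves the spacing and averages cell centres", {
  g <- dose_grid(matrix(c(0, 0, 0, 4), 2, 2), spacing = c(1, 1))
  r <- resample_evaluated(g, search_settings(interp_step_mm = 0.5))
  expect_equal(dim(r$values), c(3L, 3L))
  expect_equal(r$spacing, c(0.5, 0.5))
  expect_equal(r$values[2, 2], 1.0)   # mean of the four corners
  expect_equal(r$values[c(1, 3), c(1, 3)], g$values)  # nodes preserved

  # identity at native spacing; constants stay constant at any step
  expect_identical(resample_evaluated(g, search_settings(interp_step_mm = 1)), g)
  u <- dose_grid(matrix(5, 4, 6))
  ru <- resample_evaluated(u, search_settings(interp_step_mm = 0.3))
  expect_true(all(abs(ru$values - 5) < 1e-12))
  expect_true(all(ru$spacing <= 0.3 + 1e-12))
  expect_error(resample_evaluated(g, search_settings(interp_step_mm = 2)),
               "native")
})

test_that("gamma_point matches hand-enumerated candidates", {
  ident <- row_grid(c(100, 100, 100))
  expect_equal(gamma_point(c(0, 0), 100, ident, gamma_criteria(3, 3, 5), 100), 0)

  one <- dose_grid(matrix(103, 1, 1))
  expect_equal(gamma_point(c(0, 0), 100, one, gamma_criteria(3, 3, 5), 100), 1.0)

  # three candidates at x = 0, 1, 2 mm with doses 0, 53, 100; reference 50
  # at x = 1: co-located candidate gives gamma = |3|/3 = 1; the neighbours
  # give sqrt((50/3)^2 + 1) and are never the minimum
  ev <- row_grid(c(0, 53, 100))
  expect_equal(gamma_point(c(1, 0), 50, ev, gamma_criteria(3, 1, 5), 100,
                           radius_mm = 2), 1.0)
  # no candidate inside the radius -> Inf sentinel
  expect_equal(gamma_point(c(50, 0), 50, ev, gamma_criteria(3, 1, 5), 100,
                           radius_mm = 1), Inf)
})

test_that("gamma_map is exact on identity and uniform boundary cases", {
  p <- smooth_pair(11, nx = 12, ny = 9)
  res <- gamma_map(p$ref, p$ref, gamma_criteria(3, 2, 5), search_settings())
  expect_equal(res$gai_pct, 100)
  expect_lt(max(res$gamma[res$included_mask]), 1e-9)
  expect_true(all(is.na(res$gamma[!res$included_mask])))

  ref <- dose_grid(matrix(100, 10, 10))
  ev <- dose_grid(matrix(103, 10, 10))
  res <- gamma_map(ref, ev, gamma_criteria(3, 2, 5), search_settings())
  expect_equal(res$gai_pct, 100)           # inclusive gamma <= 1
  expect_equal(unname(res$gamma[res$included_mask]), rep(1, 100))
  expect_equal(res$n_included, 100L)
})

test_that("engine gamma map equals the exhaustive brute-force oracle", {
  for (seed in 1:5) {
    p <- smooth_pair(100 + seed, nx = sample(8:16, 1), ny = sample(8:16, 1))
    res <- gamma_map(p$ref, p$ev, gamma_criteria(3, 2, 5),
                     native_settings(), radius_mm = Inf)
    oracle <- brute_gamma_map(p$ref, p$ev, 3, 2, 5)
    expect_equal(res$gamma, oracle, tolerance = 1e-9)
  }
})

test_that("gai counts inclusively and treats Inf as failure", {
  expect_equal(gai(c(0.5, 1.0, 1.5)), 100 * 2 / 3)
  expect_equal(gai(matrix(0, 3, 3)), 100)
  expect_equal(gai(c(Inf, Inf)), 0)
  expect_error(gai(c(NA_real_, NA_real_)), "no points above threshold")
})

test_that("gamma is invariant to common translation and common dose scaling", {
  p <- smooth_pair(21)
  base <- gamma_map(p$ref, p$ev, gamma_criteria(3, 2, 5), native_settings())

  shift <- c(13.7, -4.2)
  ref2 <- dose_grid(p$ref$values, p$ref$spacing, p$ref$origin + shift)
  ev2 <- dose_grid(p$ev$values, p$ev$spacing, p$ev$origin + shift)
  moved <- gamma_map(ref2, ev2, gamma_criteria(3, 2, 5), native_settings())
  expect_equal(moved$gamma, base$gamma, tolerance = 1e-9)
  expect_equal(moved$gai_pct, base$gai_pct)

  scaled <- gamma_map(scale_dose(p$ref, 3.7), scale_dose(p$ev, 3.7),
                      gamma_criteria(3, 2, 5), native_settings())
  expect_equal(scaled$gamma, base$gamma, tolerance = 1e-9)
})

test_that("radius dta suffices for pass/fail: GAI is radius-independent", {
  for (seed in 31:33) {
    p <- smooth_pair(seed)
    cr <- gamma_criteria(3, 2, 5)
    narrow <- gamma_map(p$ref, p$ev, cr, native_settings(), radius_mm = 2)
    wide <- gamma_map(p$ref, p$ev, cr, native_settings(), radius_mm = Inf)
    expect_equal(narrow$n_passed, wide$n_passed)
    expect_equal(narrow$gai_pct, wide$gai_pct)
    # any finite gamma <= 1 must already be found at radius dta
    pass_n <- narrow$gamma <= 1
    pass_w <- wide$gamma <= 1
    expect_equal(pass_n[narrow$included_mask], pass_w[wide$included_mask])
  }
})

test_that("pointwise gamma never increases when either criterion is enlarged", {
  p <- smooth_pair(41)
  st <- native_settings()
  g1 <- gamma_map(p$ref, p$ev, gamma_criteria(3, 2, 5), st, radius_mm = Inf)
  g2 <- gamma_map(p$ref, p$ev, gamma_criteria(4, 2, 5), st, radius_mm = Inf)
  g3 <- gamma_map(p$ref, p$ev, gamma_criteria(3, 3, 5), st, radius_mm = Inf)
  inc <- g1$included_mask
  expect_true(all(g2$gamma[inc] <= g1$gamma[inc] + 1e-12))
  expect_true(all(g3$gamma[inc] <= g1$gamma[inc] + 1e-12))
  expect_gte(g2$gai_pct, g1$gai_pct)
  expect_gte(g3$gai_pct, g1$gai_pct)
})

test_that("censoring flags gamma values beyond the exact radius", {
  # uniform +50%: dose can never agree, so gamma = r/dta grows with the
  # nearest-candidate distance; values beyond radius_factor are lower bounds
  ref <- dose_grid(matrix(100, 8, 8))
  ev <- dose_grid(matrix(150, 8, 8))
  res <- gamma_map(ref, ev, gamma_criteria(3, 2, 0), native_settings())
  expect_true(all(res$gamma[res$included_mask] >=
                    min(50 / 3, res$settings$radius_factor)))
  expect_equal(res$gai_pct, 0)
})
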