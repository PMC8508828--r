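study_conc <- c(0.031, 0.125, 0.5, 2, 8, 32)

fourpl <- function(A, B, C, D, x) A + (D - A) / (1 + (C / x)^B)

test_that("noise-free 4PL points are recovered to high relative accuracy", {
  y <- fourpl(1, 1, 2, 3, study_conc)
  fit <- fit_4pl(study_conc, y, c_range = c(0.031, 32))
  expect_equal(fit$status, "fitted")
  expect_lt(abs(fit$A - 1), 1e-4)
  expect_lt(abs(fit$B - 1) / 1, 1e-4)
  expect_lt(abs(fit$C - 2) / 2, 1e-4)
  expect_lt(abs(fit$D - 3) / 3, 1e-4)
})

test_that("a flat response is flagged degenerate and input contracts hold", {
  fit <- fit_4pl(study_conc, rep(1, 6))
  expect_equal(fit$status, "degenerate")
  expect_error(fit_4pl(c(1, 2, 3), c(1, 1.2, 1.4)), "at least 4 distinct")
  expect_error(fit_4pl(study_conc, c(1, 2, NA, 1, 2, 3)), "nonfinite")
})

test_that("median midpoint recovery under 3% noise stays within 15%", {
  errs <- vapply(1:25, function(s) {
    y <- fourpl(1, 2, 0.8, 6, study_conc)
    noisy <- y * withr::with_seed(s, rlnorm(6, 0, 0.03))
    fit <- fit_4pl(study_conc, noisy, c_range = c(0.031, 32))
    abs(fit$C - 0.8) / 0.8
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("PELI1.5 inversion is analytic and censoring is exclusive", {
  fit <- structure(list(A = 1, B = 1, C = 2, D = 3, status = "fitted"),
                   class = "fit_4pl")
  ep <- peli15(fit, range = c(0.031, 32))
  expect_equal(ep$censor, "interval")
  expect_equal(ep$value, 2 / 3, tolerance = 1e-12)

  low_plateau <- structure(list(A = 1, B = 1, C = 2, D = 1.4, status = "fitted"),
                           class = "fit_4pl")
  ep2 <- peli15(low_plateau, range = c(0.031, 32))
  expect_equal(ep2$censor, "above_range")
  expect_equal(format(ep2), "N/A")

  potent <- structure(list(A = 1, B = 1, C = 0.0005, D = 6, status = "fitted"),
                      class = "fit_4pl")
  ep3 <- peli15(potent, range = c(0.031, 32))
  expect_equal(ep3$censor, "below_range")
  expect_equal(format(ep3), "<0.031")

  high_floor <- structure(list(A = 1.6, B = 1, C = 2, D = 6, status = "fitted"),
                          class = "fit_4pl")
  expect_error(peli15(high_floor), class = "pelitox_invalid_fit")
})

test_that("fit-then-invert round-trips the analytic crossing on clean data", {
  cases <- list(c(1, 1, 2, 3), c(1, 2, 0.8, 6), c(1.1, 0.8, 5, 4))
  for (p in cases) {
    y <- fourpl(p[1], p[2], p[3], p[4], study_conc)
    fit <- fit_4pl(study_conc, y, c_range = c(0.031, 32))
    xstar <- p[3] / ((p[4] - p[1]) / (1.5 - p[1]) - 1)^(1 / p[2])
    expect_equal(peli15(fit, c(0.031, 32))$value, xstar, tolerance = 1e-5)
  }
})

test_that("fitted curves are nondecreasing with a unique threshold crossing", {
  y <- fourpl(1, 2, 0.8, 6, study_conc)
  fit <- fit_4pl(study_conc, y)
  grid <- exp(seq(log(0.01), log(100), length.out = 200))
  expect_true(all(diff(eval_4pl(fit, grid)) >= -1e-12))
  expect_error(invert_4pl(fit, 0.5), "floor A < y < plateau D")
})

test_that("toxic equivalents invert the reference curve at the sample response", {
  ref <- structure(list(A = 1, B = 1, C = 1, D = 3, status = "fitted"),
                   class = "fit_4pl")
  # sample whose DNA-category response at its total PELI1.5 concentration is 2.0
  sample_fit <- structure(list(A = 1, B = 1, C = 0.6667, D = 3, status = "fitted"),
                          class = "fit_4pl")
  total_ep <- structure(list(value = 2 / 3, censor = "interval",
                             range = c(0.031, 32), threshold = 1.5),
                        class = "peli15_endpoint")
  p_star <- eval_4pl(sample_fit, 2 / 3)  # ~2.0 for C ~ 2/3
  teq <- compute_teq(sample_fit, total_ep, ref, ref_range = c(0.031, 32))
  expect_equal(teq$censor, "exact")
  expect_equal(teq$value, invert_4pl(ref, p_star), tolerance = 1e-12)
  expect_equal(teq$value, 1.0, tolerance = 1e-3)
})

test_that("a reference compound is its own unit equivalent", {
  ref <- structure(list(A = 1, B = 1.3, C = 1.5, D = 4, status = "fitted"),
                   class = "fit_4pl")
  ep <- peli15(ref, range = c(0.031, 32))
  teq <- compute_teq(ref, ep, ref, ref_range = c(0.031, 32))
  expect_equal(teq$value, ep$value, tolerance = 1e-9)
})

test_that("censored endpoints propagate to censored equivalents", {
  ref <- structure(list(A = 1, B = 1, C = 1, D = 2.2, status = "fitted"),
                   class = "fit_4pl")
  sample_fit <- structure(list(A = 1, B = 1, C = 0.001, D = 6, status = "fitted"),
                          class = "fit_4pl")
  below <- structure(list(value = 0.031, censor = "below_range",
                          range = c(0.031, 32), threshold = 1.5),
                     class = "peli15_endpoint")
  teq <- compute_teq(sample_fit, below, ref, ref_range = c(0.031, 32))
  expect_equal(teq$censor, "greater")  # p* above the reference's range response
  expect_match(format(teq), "^>")

  na_ep <- structure(list(value = NA_real_, censor = "above_range",
                          range = c(0.031, 32), threshold = 1.5),
                     class = "peli15_endpoint")
  expect_equal(compute_teq(sample_fit, na_ep, ref)$censor, "not_available")
})
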