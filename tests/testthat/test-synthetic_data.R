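test_that("a null plate yields identically zero ln I and unit PELI", {
  lib <- example_library()[1:10, ]
  truth <- synthetic_truth(lib, compounds = "X", potency = c(X = 1),
                           responsive_fraction = 0, noise_cv = 0, seed = 6)
  prof <- induction_profiles(normalize_expression(simulate_plate(truth)))
  expect_lt(max(abs(prof$ln_i)), 1e-9)
  pt <- peli_table(prof, lib)
  expect_lt(max(abs(pt$peli - 1)), 1e-9)
})

test_that("a single saturating responder recovers the closed-form PELI", {
  truth <- single_responder_truth()
  pt <- peli_table(
    induction_profiles(normalize_expression(simulate_plate(truth))),
    example_library())
  got <- pt$peli[pt$level == "orf" & pt$key == truth$orfs$orf[1] &
                   pt$concentration_mg_L == 32]
  expect_equal(unname(got), exp(0.5), tolerance = 1e-6)
})

test_that("generator output is a deterministic function of truth and seed", {
  lib <- example_library()[1:8, ]
  truth <- synthetic_truth(lib, compounds = "X", potency = c(X = 1),
                           concentrations = c(0.5, 2, 8, 32),
                           noise_cv = 0.05, seed = 42)
  a <- simulate_plate(truth)
  b <- simulate_plate(truth)
  expect_identical(a$od, b$od)
  expect_identical(a$gfp, b$gfp)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(truth, d1)
  write_synthetic_dataset(truth, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("generator datasets round-trip through the file readers", {
  lib <- example_library()[1:8, ]
  truth <- synthetic_truth(lib, compounds = c("X", "Y"),
                           potency = c(X = 1, Y = 2),
                           concentrations = c(0.5, 2, 8, 32),
                           replicates = 2, noise_cv = 0.05, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(truth, dir)
  pts <- simulate_plate(truth)
  back <- read_plate_export(paths[["plate"]],
                            read_plate_map(paths[["plate_map"]]))
  expect_equal(back$od[rownames(pts$od), ], pts$od, tolerance = 0)
  lib_back <- read_library(paths[["library"]])
  expect_equal(lib_back$orf, lib$orf)
  expect_equal(lib_back$category, lib$category)
})

test_that("reference tables with a sub-threshold plateau censor above range", {
  ref <- simulate_reference("MMC", params = list(D = 1.4))
  fit <- fit_4pl(ref$concentration_mg_L, ref$peli, c_range = c(0.031, 32))
  expect_equal(peli15(fit, c(0.031, 32))$censor, "above_range")
})

test_that("clean reference curves reproduce the analytic threshold crossing", {
  ref <- simulate_reference("MMC", params = list(A = 1, B = 1, C = 1, D = 3))
  fit <- fit_4pl(ref$concentration_mg_L, ref$peli, c_range = c(0.031, 32))
  # y = 1.5 at x = C / ((D-A)/(1.5-A) - 1)^(1/B) = 1/3
  expect_equal(peli15(fit, c(0.031, 32))$value, 1 / 3, tolerance = 1e-4)
})

test_that("noisy reference fits recover the midpoint within 15% in median", {
  errs <- vapply(1:25, function(s) {
    ref <- simulate_reference("H2O2", noise_cv = 0.03, seed = 500 + s)
    p <- attr(ref, "params")
    fit <- fit_4pl(ref$concentration_mg_L, ref$peli, c_range = c(0.031, 32))
    abs(fit$C - p$C) / p$C
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("phenotype endpoints realize the programmed correlation", {
  truth <- synthetic_truth(seed = 3)
  perfect <- simulate_phenotypes(truth, r_ros = 1, r_comet = 1)
  expect_equal(correlate(perfect$ros$fold_change, perfect$ros$driver)$r, 1,
               tolerance = 1e-9)

  rs <- vapply(1:200, function(s) {
    phen <- simulate_phenotypes(truth, r_ros = 0.75, seed = 1000 + s)
    correlate(phen$ros$fold_change, phen$ros$driver)$r
  }, 0)
  expect_lt(abs(median(rs) - 0.75), 0.15)

  null_rs <- vapply(1:200, function(s) {
    phen <- simulate_phenotypes(truth, r_ros = 0, seed = 3000 + s)
    correlate(phen$ros$fold_change, phen$ros$driver)$r
  }, 0)
  expect_lt(abs(median(null_rs)), 0.1)
})
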