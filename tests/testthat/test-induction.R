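test_that("blank-corrected normalization follows (GFP - blank)/(OD - blank)", {
  wells <- tibble::tibble(
    well = c("W1", "B1"),
    role = c("reporter", "blank_control"),
    orf = c("YAR101W", NA),
    compound = c("X", "X"),
    concentration_mg_L = c(2, 2),
    replicate = c(1L, 1L))
  pts <- tiny_plate(wells, od_values = c(0.5, 0.0), gfp_values = c(200, 100))
  norm <- normalize_expression(pts)
  expect_equal(unique(norm$p), 200)  # (200-100)/max(0.5-0, 0.01)
})

test_that("with zero blanks and GFP equal to OD the normalized expression is 1", {
  wells <- tibble::tibble(
    well = c("W1", "B1"),
    role = c("reporter", "blank_control"),
    orf = c("YAR101W", NA),
    compound = c("X", "X"),
    concentration_mg_L = c(2, 2),
    replicate = c(1L, 1L))
  pts <- tiny_plate(wells, od_values = c(0.7, 0), gfp_values = c(0.7, 0))
  norm <- normalize_expression(pts)
  expect_equal(unique(norm$p), 1)
})

test_that("a condition without a blank control is an error", {
  wells <- tibble::tibble(
    well = c("W1", "B1"),
    role = c("reporter", "blank_control"),
    orf = c("YAR101W", NA),
    compound = c("X", "X"),
    concentration_mg_L = c(2, 8),  # blank at the wrong concentration
    replicate = c(1L, 1L))
  pts <- tiny_plate(wells, od_values = c(0.5, 0), gfp_values = c(10, 0))
  expect_error(normalize_expression(pts), "no blank control")
})

test_that("induction factor identities: self-comparison, e-fold, replicate averaging", {
  p <- runif(25, 0.5, 2)
  expect_equal(induction_factor(p, p), rep(0, 25))
  expect_equal(induction_factor(exp(1) * p, p), rep(1, 25))
  expect_error(induction_factor(p, p[-1]), "same time grid")

  reps <- rep(log(2), 25)
  expect_equal(colMeans(rbind(reps, reps, reps)), rep(log(2), 25),
               tolerance = 1e-12)
})

test_that("ln I is invariant to a common GFP gain when blanks are zero", {
  lib <- example_library()[1:4, ]
  truth <- synthetic_truth(lib, compounds = "X", potency = c(X = 1),
                           concentrations = c(0.5, 2), replicates = 2,
                           noise_cv = 0, seed = 3)
  truth$background$gfp_per_mgL <- 0
  truth$background$od_per_mgL <- 0
  pts <- simulate_plate(truth)
  prof1 <- induction_profiles(normalize_expression(pts))
  pts$gfp <- pts$gfp * 7.3
  prof2 <- induction_profiles(normalize_expression(pts))
  expect_equal(prof2$ln_i, prof1$ln_i, tolerance = 1e-12)
})

test_that("noise-free synthetic plates recover the programmed ln I exactly", {
  lib <- example_library()
  truth <- synthetic_truth(lib, noise_cv = 0, seed = 5)
  pts <- simulate_plate(truth)
  prof <- induction_profiles(normalize_expression(pts))
  for (cp in truth$compounds[c(1, 5)]) {
    for (cc in c(0.031, 32)) {
      sub <- prof[prof$compound == cp & prof$concentration_mg_L == cc, ]
      sub <- sub[order(sub$orf, sub$time_min), ]
      expected <- unlist(lapply(sort(unique(sub$orf)), function(o) {
        expected_ln_i(truth, o, cp, cc)
      }))
      expect_lt(max(abs(sub$ln_i - expected)), 1e-6)
    }
  }
})

test_that("display clipping maps values beyond +/-2 onto the bound", {
  expect_equal(clip_for_display(2.7), 2)
  expect_equal(clip_for_display(-3.1), -2)
  expect_equal(clip_for_display(0.4), 0.4)
  expect_equal(clip_for_display(c(-5, 0, 5), bound = 1.5), c(-1.5, 0, 1.5))
})

test_that("the profile matrix is complete with conditions ordered by dose", {
  lib <- example_library()[1:6, ]
  truth <- synthetic_truth(lib, compounds = c("A", "B"),
                           potency = c(A = 1, B = 2),
                           concentrations = c(0.5, 2, 8), replicates = 2,
                           noise_cv = 0, seed = 9)
  prof <- induction_profiles(normalize_expression(simulate_plate(truth)))
  mat <- profile_matrix(prof)
  expect_equal(dim(mat), c(6L, 6L))
  expect_false(anyNA(mat))
  expect_equal(colnames(mat)[1:3], c("A@0.5", "A@2", "A@8"))
})
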