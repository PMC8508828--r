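test_that("a member set occupying the top ranks attains the extreme p-value", {
  # library-scale ranking: the chance a random subset ties the maximum is
  # 1/choose(74, 15) per permutation, i.e. negligible
  pelis <- setNames(seq(3, 1.1, length.out = 74), paste0("o", 1:74))
  res <- gsea_category(pelis, paste0("o", 1:15), n_perm = 199, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 200)
})

test_that("small-library exhaustive GSEA matches independent enumeration", {
  withr::with_seed(10, {
    for (i in 1:5) {
      pelis <- setNames(exp(runif(6, 0, 1)), paste0("g", 1:6))
      members <- sample(names(pelis), 2)
      res <- gsea_category(pelis, members, seed = i, exhaustive = TRUE)
      ranked <- sort(pelis, decreasing = TRUE)
      expect_equal(res$p_value, naive_gsea_exact_p(ranked, members),
                   tolerance = 1e-12)
      expect_equal(res$n_permutations, choose(6, 2))
    }
  })
})

test_that("sampled permutation p approaches the exhaustive p on a small library", {
  pelis <- setNames(c(2.5, 2.2, 1.9, 1.4, 1.2, 1.05, 1.02, 1.01),
                    paste0("g", 1:8))
  members <- c("g1", "g3")
  exact <- gsea_category(pelis, members, seed = 1, exhaustive = TRUE)$p_value
  sampled <- gsea_category(pelis, members, n_perm = 4000, seed = 2)$p_value
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(sampled - exact), 3 * se + 1 / 4000)
})

test_that("tied PELI ranking gives a calibrated (roughly uniform) null", {
  pelis <- setNames(rep(1.2, 12), paste0("g", 1:12))
  members <- paste0("g", 1:3)
  ps <- vapply(1:100, function(s) {
    gsea_category(pelis, members, n_perm = 99, seed = s)$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("GSEA output is bit-identical for a fixed seed and weight-scale invariant", {
  pelis <- setNames(exp(runif(20, 0, 0.8)), paste0("g", 1:20))
  members <- paste0("g", c(2, 5, 9, 13))
  a <- gsea_category(pelis, members, n_perm = 299, seed = 7)
  b <- gsea_category(pelis, members, n_perm = 299, seed = 7)
  expect_identical(a, b)
  # scaling the deviations |PELI - 1| by a constant preserves ranking and
  # relative weights, hence statistic and p
  scaled <- setNames(1 + 3 * (pelis - 1), names(pelis))
  c <- gsea_category(scaled, members, n_perm = 299, seed = 7)
  expect_equal(c$statistic, a$statistic, tolerance = 1e-12)
  expect_equal(c$p_value, a$p_value)
})

test_that("GSEA validates membership and permutation count", {
  pelis <- setNames(runif(6, 1, 2), paste0("g", 1:6))
  expect_error(gsea_category(pelis, c("g1", "zz"), seed = 1), "not in the library")
  expect_error(gsea_category(pelis, "g1", seed = 1), "at least 2")
  expect_error(gsea_category(pelis, paste0("g", 1:2), n_perm = 10, seed = 1),
               "at least 99")
})

test_that("hypergeometric ontology p-values equal exact enumeration", {
  # saturation: test set = whole library
  lib <- example_library()
  tm <- term_map_from_library(lib)
  res <- ontology_enrichment(lib$orf, lib, tm)
  expect_true(all(res$p_value == 1))
  expect_equal(res$overlap, res$term_size)

  # enumeration oracle across small instances
  for (N in c(10, 15, 20)) {
    small_lib <- biomarker_library(tibble::tibble(
      orf = paste0("o", 1:N), gene = paste0("g", 1:N),
      category = rep(stress_categories(), length.out = N),
      go_terms = "GO:1"))
    for (K in c(3, 5)) {
      term_map <- list(T1 = paste0("o", 1:K))
      for (n_test in c(2, 4, floor(N / 2))) {
        test_set <- paste0("o", head(seq(2, N, by = 2), n_test))
        res <- ontology_enrichment(test_set, small_lib, term_map)
        k <- length(intersect(term_map$T1, test_set))
        expect_equal(res$p_value, hyper_upper_tail(k, K, N, n_test),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a term disjoint from the test set has p = 1 under the upper tail", {
  lib <- example_library()
  tm <- list(TX = lib$orf[1:10])
  res <- ontology_enrichment(lib$orf[30:40], lib, tm)
  expect_equal(res$overlap, 0L)
  expect_equal(res$p_value, 1)
})

test_that("an empty test set produces an empty result with a notice", {
  lib <- example_library()
  expect_message(
    res <- ontology_enrichment(character(0), lib, term_map_from_library(lib)),
    "empty test set")
  expect_equal(nrow(res), 0L)
})
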