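make_layout <- function() {
  plate_layout(tibble::tibble(
    well = c("A1", "A2", "A3", "A4"),
    role = c("reporter", "reporter", "blank_control", "vehicle_control"),
    orf = c("YAR101W", "YAL102C", NA, "YAR101W"),
    compound = c("X", "X", "X", NA),
    concentration_mg_L = c(2, 2, 2, 0),
    replicate = c(1L, 2L, 1L, 1L)
  ))
}

long_export <- function(path, drop_row = NULL, channel_labels = c("OD600", "GFP")) {
  t <- seq(0, 120, by = 5)
  tab <- expand.grid(well = c("A1", "A2"), time_min = t,
                     channel = channel_labels, stringsAsFactors = FALSE)
  tab$value <- seq_len(nrow(tab)) / 10
  if (!is.null(drop_row)) tab <- tab[-drop_row, ]
  readr::write_csv(tab, path)
  path
}

test_that("long-form export parses into a complete 25-point grid", {
  path <- withr::local_tempfile(fileext = ".csv")
  long_export(path)
  pts <- read_plate_export(path, make_layout())
  expect_equal(length(pts$time_min), 25L)
  expect_equal(dim(pts$od), c(2L, 25L))
  expect_equal(dim(pts$gfp), c(2L, 25L))
  expect_setequal(rownames(pts$od), c("A1", "A2"))
})

test_that("a missing cell is an error naming the well and time, never imputed", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- readr::read_csv(long_export(path), show_col_types = FALSE)
  drop <- which(tab$well == "A2" & tab$time_min == 35 & tab$channel == "GFP")
  readr::write_csv(tab[-drop, ], path)
  expect_error(read_plate_export(path, make_layout()),
               "missing GFP reading for well A2 at time 35")
})

test_that("unknown channel labels and unknown wells are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  long_export(path, channel_labels = c("OD600", "FLUO"))
  expect_error(read_plate_export(path, make_layout()), "unknown channel")

  path2 <- withr::local_tempfile(fileext = ".csv")
  tab <- readr::read_csv(long_export(path2), show_col_types = FALSE)
  tab$well[tab$well == "A2"] <- "Z9"
  readr::write_csv(tab, path2)
  expect_error(read_plate_export(path2, make_layout()),
               "absent from plate map")
})

test_that("a nonuniform time grid is rejected naming the offending times", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- readr::read_csv(long_export(path), show_col_types = FALSE)
  tab$time_min[tab$time_min == 55] <- 57
  readr::write_csv(tab, path)
  expect_error(read_plate_export(path, make_layout()), "nonuniform time grid")
})

test_that("write-then-read round-trips matrices exactly in both dialects", {
  truth <- synthetic_truth(
    example_library()[1:6, ], compounds = "X", potency = c(X = 1),
    concentrations = c(0.5, 2, 8, 32), replicates = 2, noise_cv = 0.05,
    seed = 11)
  pts <- simulate_plate(truth)
  for (fmt in c("long", "wide")) {
    dialect <- plate_dialect(format = fmt)
    path <- withr::local_tempfile(fileext = ".csv")
    write_plate_export(pts, path, dialect)
    back <- read_plate_export(path, pts$layout, dialect)
    expect_equal(back$time_min, pts$time_min)
    expect_equal(back$od[rownames(pts$od), ], pts$od, tolerance = 0)
    expect_equal(back$gfp[rownames(pts$gfp), ], pts$gfp, tolerance = 0)
  }
})

test_that("library reader normalizes categories and validates uniqueness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    orf = paste0("YX", 1:5), gene = paste0("G", 1:5),
    category = c("General", "CHEMICAL", "dna", "Oxidative", "protein"),
    go_terms = rep("GO:0006950", 5))
  readr::write_tsv(tab, path)
  lib <- read_library(path)
  expect_s3_class(lib, "biomarker_library")
  expect_setequal(lib$category, stress_categories())

  tab$category[2] <- "thermal"
  readr::write_tsv(tab, path)
  expect_error(read_library(path), "unknown stress category.*allowed values")

  tab$category[2] <- "chemical"
  tab$orf[2] <- tab$orf[1]
  readr::write_tsv(tab, path)
  expect_error(read_library(path), "duplicate orf")
})

test_that("the shipped synthetic fixture has 74 entries partitioned into five categories", {
  lib <- example_library()
  expect_equal(nrow(lib), 74L)
  sizes <- table(lib$category)
  expect_setequal(names(sizes), stress_categories())
  expect_equal(sum(sizes), 74L)
})

test_that("layout validation enforces control roles and library coverage", {
  expect_error(plate_layout(tibble::tibble(
    well = "A1", role = "blank_control", orf = "YAR101W", compound = "X",
    concentration_mg_L = 1, replicate = 1L)), "blank-control wells")
  expect_error(plate_layout(tibble::tibble(
    well = "A1", role = "internal_control", orf = "YAR101W", compound = "X",
    concentration_mg_L = 1, replicate = 1L)), "housekeeping")

  layout <- make_layout()
  lib <- biomarker_library(tibble::tibble(
    orf = "YAR101W", gene = "HSP104", category = "general",
    go_terms = "GO:0006950"))
  expect_error(validate_layout_library(layout, lib), "YAL102C")
})

test_that("term maps round-trip through the two-column dialect", {
  lib <- example_library()
  tm <- term_map_from_library(lib)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    term = rep(names(tm), lengths(tm)), orf = unlist(tm, use.names = FALSE)),
    path)
  back <- read_term_map(path)
  expect_setequal(names(back), names(tm))
  for (term in names(tm)) expect_setequal(back[[term]], tm[[term]])
})
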