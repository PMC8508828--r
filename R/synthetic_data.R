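#' Ground-truth parameters for a synthetic plate experiment
#'
#' Defines the statistical structure the analysis assumes, as a recorded
#' truth object so recovery tests can compare pipeline output with
#' programmed values. Defaults emulate the study design: a 74-biomarker
#' library, 5 test compounds, 6 concentrations in a four-fold series
#' (0.031-32 mg/L), triplicates, readings every 5 min over 2 h, with blank,
#' vehicle, and housekeeping (PGK1) controls.
#'
#' Per responsive ORF, the expected induction at concentration c follows a
#' Hill curve max_ln_i * d^h / (ec50^h + d^h) (d = c x compound potency) and
#' ramps linearly in time from 0 at t = 0 to its plateau at t = T, so the
#' time-averaged |ln I| has the closed form |plateau| / 2. Material optical
#' interference is modeled as concentration-proportional additive OD and GFP
#' backgrounds, identical in blank wells, so blank subtraction is exactly
#' sufficient. Measurement noise is multiplicative lognormal with unit mean
#' at the stated CV.
#'
#' @param library A [biomarker_library()]; defaults to the shipped synthetic
#'   74-entry fixture.
#' @param compounds Character vector of test compound names.
#' @param concentrations Exposure concentrations in mg/L.
#' @param replicates Replicate count per condition.
#' @param responsive_fraction Fraction of library ORFs with a programmed
#'   response.
#' @param noise_cv Multiplicative noise coefficient of variation (0 for
#'   noise-free plates).
#' @param potency Optional named numeric: per-compound multiplier on the
#'   effective dose, emulating compound-to-compound toxicity differences.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of (truth, seed).
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(library = example_library(),
                            compounds = c("GO_untreated", "GO_UV",
                                          "GO_thermal", "GO_sonicated_45min",
                                          "GO_sonicated_2.5h"),
                            concentrations = c(0.031, 0.125, 0.5, 2, 8, 32),
                            replicates = 3,
                            responsive_fraction = 0.6,
                            noise_cv = 0.05,
                            potency = NULL,
                            seed = 1) {
  if (is.null(potency)) {
    # graded potencies with a strongly toxic final compound, emulating the
    # study's ordering (strongest response saturating already at low dose)
    potency <- exp(seq(log(0.8), log(2), length.out = length(compounds)))
    if (length(compounds) >= 2) potency[length(potency)] <- 30
    names(potency) <- compounds
  }
  stopifnot(all(compounds %in% names(potency)))
  orfs <- with_local_seed(seed, {
    n <- nrow(library)
    responsive <- runif(n) < responsive_fraction
    sign <- ifelse(runif(n) < 0.15, -1, 1)
    tibble::tibble(
      orf = library$orf,
      category = library$category,
      responsive = responsive,
      max_ln_i = ifelse(responsive, sign * runif(n, 0.6, 2.5), 0),
      ec50 = exp(runif(n, log(0.1), log(10))),
      hill = runif(n, 1, 2.5),
      basal = exp(runif(n, log(50), log(500)))
    )
  })
  structure(
    list(
      library = library,
      orfs = orfs,
      compounds = compounds,
      potency = potency[compounds],
      concentrations = sort(concentrations),
      replicates = as.integer(replicates),
      time_min = seq(0, 120, by = 5),
      growth = list(od0 = 0.2, rate = 0.006, capacity = 1.0),
      background = list(od_per_mgL = 0.002, gfp_per_mgL = 1.5),
      hk = list(orf = "PGK1", basal = 200),
      noise_cv = noise_cv,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d ORFs (%d responsive), %d compounds x %d concentrations x %d reps, cv=%.3g, seed=%d\n",
    nrow(x$orfs), sum(x$orfs$responsive), length(x$compounds),
    length(x$concentrations), x$replicates, x$noise_cv, x$seed))
  invisible(x)
}

# Programmed induction plateau for each ORF under (compound, concentration).
truth_effect <- function(truth, orf, compound, concentration) {
  i <- match(orf, truth$orfs$orf)
  pot <- ifelse(is.na(compound), 0, unname(truth$potency[compound]))
  d <- rep_len(concentration * pot, length(i))
  h <- truth$orfs$hill[i]
  eff <- truth$orfs$max_ln_i[i] * d^h / (truth$orfs$ec50[i]^h + d^h)
  eff[d <= 0] <- 0
  eff
}

#' Programmed ln I trajectory implied by a truth object
#'
#' Closed-form expected ln I(t) for one biomarker under one condition:
#' linear ramp from 0 to the Hill-curve plateau over the exposure window.
#'
#' @param truth A [synthetic_truth()].
#' @param orf,compound,concentration Condition selector.
#' @return Numeric vector over `truth$time_min`.
#' @export
expected_ln_i <- function(truth, orf, compound, concentration) {
  eff <- truth_effect(truth, orf, compound, concentration)
  eff * truth$time_min / max(truth$time_min)
}

#' Programmed category-level PELI implied by a truth object
#'
#' Geometric-mean aggregate of the closed-form per-ORF PELIs
#' exp(|plateau| / 2) over a category's members (or the whole library for
#' `category = "total"`). This is the generator-side counterpart of
#' [peli_table()] on noise-free data.
#'
#' @param truth A [synthetic_truth()].
#' @param category One of the five stress categories, or `"total"`.
#' @param compound,concentration Condition selector.
#' @return Scalar programmed PELI.
#' @export
expected_category_peli <- function(truth, category, compound, concentration) {
  sel <- if (identical(category, "total")) rep(TRUE, nrow(truth$orfs))
         else truth$orfs$category == category
  if (!any(sel)) return(1)  # category absent from this library: no response
  eff <- truth_effect(truth, truth$orfs$orf[sel], compound, concentration)
  exp(mean(abs(eff) / 2))
}

logistic_od <- function(growth, t) {
  k <- growth$capacity
  n0 <- growth$od0
  k * n0 * exp(growth$rate * t) / (k + n0 * (exp(growth$rate * t) - 1))
}

well_ids <- function(n) {
  plate <- (seq_len(n) - 1L) %/% 384L + 1L
  pos <- (seq_len(n) - 1L) %% 384L
  sprintf("P%03d:%s%02d", plate, LETTERS[pos %/% 24L + 1L], pos %% 24L + 1L)
}

#' Simulate a reporter-library plate experiment
#'
#' Generates the full well layout (reporter wells for every ORF x compound x
#' concentration x replicate, vehicle-control wells per ORF, housekeeping
#' internal controls and blank wells per condition) and the OD600/GFP time
#' series implied by the truth object, with multiplicative lognormal noise
#' at the truth's CV. Deterministic for a given truth (all randomness flows
#' from `truth$seed`).
#'
#' @param truth A [synthetic_truth()].
#' @return A [plate_timeseries()].
#' @export
simulate_plate <- function(truth) {
  conds <- tidyr::expand_grid(compound = truth$compounds,
                              concentration_mg_L = truth$concentrations)
  reps <- seq_len(truth$replicates)

  reporter <- tidyr::expand_grid(conds, orf = truth$orfs$orf, replicate = reps)
  reporter$role <- "reporter"
  vehicle <- tidyr::expand_grid(orf = truth$orfs$orf, replicate = reps)
  vehicle$compound <- NA_character_
  vehicle$concentration_mg_L <- 0
  vehicle$role <- "vehicle_control"
  hk_conds <- dplyr::bind_rows(
    conds, tibble::tibble(compound = NA_character_, concentration_mg_L = 0))
  hk <- tidyr::expand_grid(hk_conds, replicate = reps)
  hk$orf <- truth$hk$orf
  hk$role <- "internal_control"
  blank <- tidyr::expand_grid(hk_conds, replicate = reps)
  blank$orf <- NA_character_
  blank$role <- "blank_control"

  wells <- dplyr::bind_rows(reporter, vehicle, hk, blank)
  wells$well <- well_ids(nrow(wells))
  layout <- plate_layout(
    wells[, c("well", "role", "orf", "compound", "concentration_mg_L",
              "replicate")],
    hk_orf = truth$hk$orf
  )

  t <- truth$time_min
  nt <- length(t)
  nw <- nrow(layout)
  od_bio <- logistic_od(truth$growth, t)
  ramp <- t / max(t)

  has_yeast <- layout$role != "blank_control"
  basal <- numeric(nw)
  idx <- match(layout$orf, truth$orfs$orf)
  basal[has_yeast] <- ifelse(layout$orf[has_yeast] == truth$hk$orf,
                             truth$hk$basal,
                             truth$orfs$basal[idx[has_yeast]])
  eff <- numeric(nw)
  is_rep <- layout$role == "reporter"
  eff[is_rep] <- truth_effect(truth, layout$orf[is_rep],
                              layout$compound[is_rep],
                              layout$concentration_mg_L[is_rep])

  od_bg <- truth$background$od_per_mgL * layout$concentration_mg_L
  gfp_bg <- truth$background$gfp_per_mgL * layout$concentration_mg_L

  od <- matrix(rep(od_bg, nt), nrow = nw)
  od[has_yeast, ] <- od[has_yeast, ] +
    matrix(od_bio, nrow = sum(has_yeast), ncol = nt, byrow = TRUE)
  ln_i <- outer(eff, ramp)
  gfp <- matrix(rep(gfp_bg, nt), nrow = nw) +
    (basal * exp(ln_i)) * ifelse(has_yeast, 1, 0) *
    matrix(od_bio, nrow = nw, ncol = nt, byrow = TRUE)

  if (truth$noise_cv > 0) {
    s <- sqrt(log(1 + truth$noise_cv^2))
    noise <- with_local_seed(truth$seed + 7L, {
      list(od = matrix(rlnorm(nw * nt, -s^2 / 2, s), nrow = nw),
           gfp = matrix(rlnorm(nw * nt, -s^2 / 2, s), nrow = nw))
    })
    od <- od * noise$od
    gfp <- gfp * noise$gfp
  }
  rownames(od) <- rownames(gfp) <- layout$well
  plate_timeseries(t, od, gfp, layout)
}

#' Simulate a reference-compound concentration-response table
#'
#' Clean 4PL-shaped category-level PELI responses for the reference standard
#' chemicals used in toxic-equivalency calibration: an MMC-like genotoxicant
#' (DNA category) or an H2O2-like oxidant (oxidative category), with optional
#' multiplicative noise.
#'
#' @param compound `"MMC"` or `"H2O2"` (selects the default parameter set
#'   and category).
#' @param params List with elements `A`, `B`, `C`, `D` overriding the
#'   defaults.
#' @param concentrations Dose series in mg/L.
#' @param replicates Replicates per dose.
#' @param noise_cv Multiplicative lognormal noise CV (0 = exact curve).
#' @param seed Seed for the noise.
#' @return Tibble `compound, category, concentration_mg_L, replicate, peli`
#'   with the generating parameters in the `params` attribute.
#' @export
simulate_reference <- function(compound = c("MMC", "H2O2"), params = NULL,
                               concentrations = c(0.031, 0.125, 0.5, 2, 8, 32),
                               replicates = 3, noise_cv = 0, seed = 1) {
  compound <- match.arg(compound)
  defaults <- list(
    MMC = list(A = 1, B = 1.2, C = 0.8, D = 4, category = "DNA"),
    H2O2 = list(A = 1, B = 1.1, C = 5, D = 5, category = "oxidative")
  )[[compound]]
  p <- utils::modifyList(defaults, params %||% list())
  tab <- tidyr::expand_grid(concentration_mg_L = sort(concentrations),
                            replicate = seq_len(replicates))
  y <- p$A + (p$D - p$A) / (1 + (p$C / tab$concentration_mg_L)^p$B)
  if (noise_cv > 0) {
    s <- sqrt(log(1 + noise_cv^2))
    y <- y * with_local_seed(seed, rlnorm(length(y), -s^2 / 2, s))
  }
  out <- tibble::tibble(compound = compound, category = p$category,
                        concentration_mg_L = tab$concentration_mg_L,
                        replicate = tab$replicate, peli = y)
  attr(out, "params") <- p
  out
}

#' Simulate phenotypic endpoints correlated with molecular truth
#'
#' ROS fold changes (per compound at the two highest concentrations) and
#' comet-assay per-cell % Tail DNA (per compound, 25 cells x 4 replicates,
#' plus an untreated control group) generated as affine functions of the
#' programmed oxidative / DNA effect sizes plus Gaussian noise, so that the
#' sample correlation between endpoint and molecular driver has expectation
#' close to the programmed `r` (exactly 1 when `r = 1`).
#'
#' @param truth A [synthetic_truth()].
#' @param r_ros,r_comet Programmed correlations in \[0, 1\].
#' @param ros_concentrations Concentrations at which ROS is measured.
#' @param seed Seed (defaults to the truth's).
#' @return List with tibbles `ros` (`compound, concentration_mg_L, driver,
#'   fold_change`), `comet` (`compound, replicate, cell, tail_pct`; compound
#'   `"control"` is the untreated group), `comet_driver` (per-compound
#'   programmed driver), and `h2o2_standard` (monotone DCFDA fold standard
#'   curve for equivalency interpolation).
#' @export
simulate_phenotypes <- function(truth, r_ros = 0.75, r_comet = 0.7,
                                ros_concentrations = NULL, seed = NULL) {
  seed <- seed %||% (truth$seed + 13L)
  if (is.null(ros_concentrations)) {
    ros_concentrations <- utils::tail(truth$concentrations, 2)
  }
  ros <- tidyr::expand_grid(compound = truth$compounds,
                            concentration_mg_L = ros_concentrations)
  ros$driver <- mapply(function(cp, cc) {
    expected_category_peli(truth, "oxidative", cp, cc)
  }, ros$compound, ros$concentration_mg_L)

  comet_driver <- tibble::tibble(
    compound = truth$compounds,
    driver = vapply(truth$compounds, function(cp) {
      expected_category_peli(truth, "DNA", cp, max(truth$concentrations))
    }, 0)
  )

  zscore <- function(x) {
    if (length(x) < 2 || sd(x) == 0) rep(0, length(x))
    else (x - mean(x)) / sd(x)
  }
  with_local_seed(seed, {
    z <- zscore(ros$driver)
    y <- r_ros * z + sqrt(max(0, 1 - r_ros^2)) * rnorm(length(z))
    ros$fold_change <- pmax(2 + 0.6 * y, 0.05)

    zc <- zscore(comet_driver$driver)
    yc <- r_comet * zc + sqrt(max(0, 1 - r_comet^2)) * rnorm(length(zc))
    comet_mean <- 12 + 6 * yc
    cells <- tidyr::expand_grid(compound = c(truth$compounds, "control"),
                                replicate = 1:4, cell = 1:25)
    mu <- c(setNames(comet_mean, truth$compounds), control = 5)[cells$compound]
    cells$tail_pct <- pmin(pmax(rnorm(nrow(cells), mu, 6), 0), 100)

    h2o2_standard <- tibble::tibble(
      dose_mg_L = c(0.5, 2, 8, 32, 128),
      fold = 1 + 0.08 * sqrt(c(0.5, 2, 8, 32, 128))
    )
    list(ros = ros, comet = cells, comet_driver = comet_driver,
         h2o2_standard = h2o2_standard)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the same text dialects the readers consume: a long-form plate
#' export, the plate map, the library TSV, a term map derived from the
#' library annotations, reference-compound response tables, phenotype
#' tables, and a `truth.json` recording the generator parameters.
#'
#' @param truth A [synthetic_truth()].
#' @param dir Output directory (created if missing).
#' @param phenotypes Optionally a precomputed [simulate_phenotypes()] result.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir, phenotypes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- simulate_plate(truth)
  phen <- phenotypes %||% simulate_phenotypes(truth)
  refs <- dplyr::bind_rows(
    simulate_reference("MMC", seed = truth$seed + 3L),
    simulate_reference("H2O2", seed = truth$seed + 4L)
  )
  paths <- c(
    plate = file.path(dir, "plate_long.csv"),
    plate_map = file.path(dir, "plate_map.csv"),
    library = file.path(dir, "library.tsv"),
    term_map = file.path(dir, "term_map.tsv"),
    references = file.path(dir, "references.csv"),
    ros = file.path(dir, "ros.csv"),
    comet = file.path(dir, "comet.csv"),
    h2o2_standard = file.path(dir, "h2o2_standard.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_plate_export(pts, paths[["plate"]])
  write_plate_map(pts$layout, paths[["plate_map"]])
  lib_out <- tibble::tibble(
    orf = truth$library$orf, gene = truth$library$gene,
    category = truth$library$category,
    go_terms = vapply(truth$library$go_terms, paste, "", collapse = ";")
  )
  readr::write_tsv(lib_out, paths[["library"]])
  tm <- term_map_from_library(truth$library)
  readr::write_tsv(tibble::tibble(
    term = rep(names(tm), lengths(tm)), orf = unlist(tm, use.names = FALSE)
  ), paths[["term_map"]])
  readr::write_csv(refs, paths[["references"]])
  readr::write_csv(phen$ros, paths[["ros"]])
  readr::write_csv(phen$comet, paths[["comet"]])
  readr::write_csv(phen$h2o2_standard, paths[["h2o2_standard"]])
  truth_json <- list(
    orfs = truth$orfs, compounds = truth$compounds,
    potency = as.list(truth$potency),
    concentrations = truth$concentrations, replicates = truth$replicates,
    time_min = truth$time_min, growth = truth$growth,
    background = truth$background, hk = truth$hk,
    noise_cv = truth$noise_cv, seed = truth$seed
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
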