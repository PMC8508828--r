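#' Blank-corrected normalized expression per well
#'
#' Converts raw plate readings into a per-well normalized expression series
#' P(t) = (GFP - GFP_blank) / max(OD - OD_blank, od_floor), where the blank
#' signal is the average over the blank-control wells of the same
#' (compound, concentration) condition. Blank subtraction removes the test
#' material's autofluorescence and absorbance, which the synthetic generator
#' models as concentration-dependent backgrounds identical in blank wells.
#'
#' Corrected values that fall at or below zero (possible under instrument
#' noise) are floored at `p_floor`; the number of floored points is recorded
#' in the `n_floored` attribute and reported as a warning.
#'
#' @param pts A [plate_timeseries()].
#' @param od_floor Minimum blank-corrected OD (absorbance units) used as the
#'   denominator floor.
#' @param p_floor Floor for the normalized expression itself.
#' @return Tibble with columns `well`, `role`, `orf`, `compound`,
#'   `concentration_mg_L`, `replicate`, `time_min`, `p`.
#' @export
normalize_expression <- function(pts, od_floor = 0.01, p_floor = 1e-6) {
  layout <- pts$layout
  key <- cond_key(layout$compound, layout$concentration_mg_L)
  blanks <- layout$role == "blank_control"

  # per-condition mean blank trace for each channel
  blank_od <- rowsum(pts$od[layout$well, , drop = FALSE][blanks, , drop = FALSE],
                     group = key[blanks])
  blank_gfp <- rowsum(pts$gfp[layout$well, , drop = FALSE][blanks, , drop = FALSE],
                      group = key[blanks])
  counts <- as.vector(table(key[blanks])[rownames(blank_od)])
  blank_od <- blank_od / counts
  blank_gfp <- blank_gfp / counts

  sample_idx <- which(!blanks)
  missing_blank <- setdiff(unique(key[sample_idx]), rownames(blank_od))
  if (length(missing_blank) > 0) {
    abort(paste0("no blank control for condition(s): ",
                 paste(missing_blank, collapse = "; ")))
  }

  wells <- layout$well[sample_idx]
  od <- pts$od[wells, , drop = FALSE] -
    blank_od[key[sample_idx], , drop = FALSE]
  gfp <- pts$gfp[wells, , drop = FALSE] -
    blank_gfp[key[sample_idx], , drop = FALSE]
  p <- gfp / pmax(od, od_floor)
  n_floored <- sum(p < p_floor)
  if (n_floored > 0) {
    warn(sprintf("normalized expression floored at %g for %d point(s)",
                 p_floor, n_floored))
    p <- pmax(p, p_floor)
  }

  nt <- length(pts$time_min)
  out <- tibble::tibble(
    well = rep(wells, each = nt),
    role = rep(layout$role[sample_idx], each = nt),
    orf = rep(layout$orf[sample_idx], each = nt),
    compound = rep(layout$compound[sample_idx], each = nt),
    concentration_mg_L = rep(layout$concentration_mg_L[sample_idx], each = nt),
    replicate = rep(layout$replicate[sample_idx], each = nt),
    time_min = rep(pts$time_min, times = length(wells)),
    p = as.vector(t(p))
  )
  attr(out, "n_floored") <- n_floored
  out
}

#' Log induction factor between two expression series
#'
#' ln I(t) = ln(P_treated(t) / P_control(t)), both arguments floored at
#' `p_floor` first. The control is the vehicle-control series of the same
#' reporter strain.
#'
#' @param p_treated,p_control Normalized expression series on the same grid.
#' @param p_floor Expression floor applied to both arguments.
#' @return Numeric series of ln I values.
#' @export
induction_factor <- function(p_treated, p_control, p_floor = 1e-6) {
  if (length(p_treated) != length(p_control)) {
    abort("treated and control series must share the same time grid")
  }
  log(pmax(p_treated, p_floor) / pmax(p_control, p_floor))
}

#' Per-ORF log induction-factor trajectories
#'
#' For every reporter (orf, compound, concentration): computes replicate-wise
#' ln I(t) against the replicate-averaged vehicle-control expression of the
#' same ORF, then averages ln I across replicates. When `drift_correct` is
#' on, the housekeeping (internal-control) reporter's ln I under the same
#' condition is subtracted pointwise, removing plate-level drift.
#'
#' @param norm Output of [normalize_expression()].
#' @param drift_correct Subtract the housekeeping reporter's ln I trajectory
#'   per condition (default on).
#' @param p_floor Expression floor, as in [induction_factor()].
#' @param hk_orf Housekeeping reporter id.
#' @return Tibble `orf, compound, concentration_mg_L, time_min, ln_i,
#'   n_replicates`.
#' @export
induction_profiles <- function(norm, drift_correct = TRUE, p_floor = 1e-6,
                               hk_orf = "PGK1") {
  # vehicle baseline per reporter ORF; the housekeeping reporter's baseline
  # is its internal-control wells under the vehicle condition (no compound)
  veh <- norm[norm$role == "vehicle_control" |
                (norm$role == "internal_control" & is.na(norm$compound)), ,
              drop = FALSE]
  if (nrow(veh) == 0) abort("no vehicle-control wells in the plate")
  control <- dplyr::summarise(
    dplyr::group_by(veh, .data$orf, .data$time_min),
    p_control = mean(.data$p), .groups = "drop"
  )

  treated <- norm[(norm$role == "reporter" |
                     (norm$role == "internal_control" & !is.na(norm$compound))), ,
                  drop = FALSE]
  no_control <- setdiff(unique(treated$orf), unique(control$orf))
  if (length(no_control) > 0) {
    abort(paste0("no vehicle control for ORF(s): ",
                 paste(no_control, collapse = ", ")))
  }
  joined <- dplyr::inner_join(treated, control, by = c("orf", "time_min"))
  joined$ln_i <- induction_factor(joined$p, joined$p_control, p_floor)

  prof <- dplyr::summarise(
    dplyr::group_by(joined, .data$role, .data$orf, .data$compound,
                    .data$concentration_mg_L, .data$time_min),
    ln_i = mean(.data$ln_i),
    n_replicates = dplyr::n_distinct(.data$replicate),
    .groups = "drop"
  )

  reporters <- prof[prof$role == "reporter", , drop = FALSE]
  if (drift_correct) {
    hk <- prof[prof$role == "internal_control" & prof$orf == hk_orf, , drop = FALSE]
    if (nrow(hk) > 0) {
      hk <- dplyr::select(hk, "compound", "concentration_mg_L", "time_min",
                          hk_ln_i = "ln_i")
      reporters <- dplyr::left_join(
        reporters, hk, by = c("compound", "concentration_mg_L", "time_min")
      )
      reporters$ln_i <- reporters$ln_i -
        dplyr::coalesce(reporters$hk_ln_i, 0)
      reporters$hk_ln_i <- NULL
    }
  }
  dplyr::arrange(
    dplyr::select(reporters, "orf", "compound", "concentration_mg_L",
                  "time_min", "ln_i", "n_replicates"),
    .data$compound, .data$concentration_mg_L, .data$orf, .data$time_min
  )
}

#' Clip ln I values for heatmap display
#'
#' Display convention only: ln I beyond +/- `bound` is shown as +/- `bound`.
#' Never applied before PELI computation.
#'
#' @param ln_i Numeric values.
#' @param bound Clipping bound (default 2).
#' @return Clipped values.
#' @export
clip_for_display <- function(ln_i, bound = 2) {
  pmin(pmax(ln_i, -bound), bound)
}

#' Biomarker-by-condition profile matrix of mean ln I
#'
#' Collapses trajectories to their time mean, giving the matrix used for
#' hierarchical clustering and PCA (rows = biomarkers, columns = conditions
#' labelled `compound@concentration`, ordered by compound then increasing
#' concentration).
#'
#' @param profiles Output of [induction_profiles()].
#' @return Numeric matrix with orf rownames and condition colnames.
#' @export
profile_matrix <- function(profiles) {
  agg <- dplyr::summarise(
    dplyr::group_by(profiles, .data$orf, .data$compound,
                    .data$concentration_mg_L),
    mean_ln_i = mean(.data$ln_i), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$compound, .data$concentration_mg_L)
  agg$condition <- factor(
    cond_key(agg$compound, agg$concentration_mg_L),
    levels = unique(cond_key(agg$compound, agg$concentration_mg_L))
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(agg, "orf", "condition", "mean_ln_i"),
    names_from = "condition", values_from = "mean_ln_i"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$orf
  if (anyNA(mat)) {
    abort("profile matrix has missing cells; every ORF must be measured under every condition")
  }
  mat
}
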