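#' ROS induction fold change from fluorescence kinetics
#'
#' Fold change in intracellular ROS production from DCFDA fluorescence
#' monitored over the exposure window, summarized by trapezoidal AUC:
#' fold = (AUC(treated) - AUC(chemical control)) /
#'        (AUC(stained control) - AUC(blank medium control)).
#' The chemical control (dye + test material, no yeast) removes material
#' autofluorescence; the stained control (dye + yeast, no material) is the
#' baseline ROS signal. A final-timepoint summary is selectable instead of
#' the AUC.
#'
#' @param time_min Shared time grid in minutes.
#' @param treated,stained_control,chemical_control Fluorescence series on
#'   the shared grid.
#' @param blank_control Blank medium control series (dye only); defaults to
#'   zero.
#' @param summary `"auc"` (default) or `"final"` (last timepoint).
#' @return Scalar fold change.
#' @export
ros_fold_change <- function(time_min, treated, stained_control,
                            chemical_control,
                            blank_control = rep(0, length(time_min)),
                            summary = c("auc", "final")) {
  summary <- match.arg(summary)
  lens <- c(length(treated), length(stained_control),
            length(chemical_control), length(blank_control))
  if (any(lens != length(time_min))) {
    abort("all fluorescence series must share the time grid")
  }
  stat <- switch(summary,
                 auc = function(y) pracma::trapz(time_min, y),
                 final = function(y) y[length(y)])
  denom <- stat(stained_control) - stat(blank_control)
  if (denom <= 0) {
    abort("stained-control signal does not exceed the blank medium control")
  }
  (stat(treated) - stat(chemical_control)) / denom
}

#' H2O2-equivalent dose from a standard curve
#'
#' Inverse monotone piecewise-linear interpolation of an observed ROS fold
#' change onto the positive-control H2O2 dose axis. Folds outside the
#' standard curve's range are reported as censored bounds at the curve's
#' dose limits.
#'
#' @param fold Observed ROS fold change.
#' @param standard_curve Data frame with columns `dose_mg_L` and `fold`
#'   (>= 3 points, strictly monotone fold over increasing dose).
#' @return List with `value` (mg/L H2O2) and `censor` (one of
#'   interval/below_range/above_range).
#' @export
h2o2_equivalent <- function(fold, standard_curve) {
  if (!all(c("dose_mg_L", "fold") %in% names(standard_curve))) {
    abort("standard curve must have columns dose_mg_L, fold")
  }
  sc <- standard_curve[order(standard_curve$dose_mg_L), , drop = FALSE]
  if (nrow(sc) < 3) abort("standard curve needs at least 3 points")
  if (any(diff(sc$fold) <= 0)) {
    abort("standard curve must be strictly monotone in dose")
  }
  if (fold < min(sc$fold)) {
    return(list(value = min(sc$dose_mg_L), censor = "below_range"))
  }
  if (fold > max(sc$fold)) {
    return(list(value = max(sc$dose_mg_L), censor = "above_range"))
  }
  val <- stats::approx(x = sc$fold, y = sc$dose_mg_L, xout = fold)$y
  list(value = val, censor = "interval")
}

#' Comet-assay genotoxicity positivity
#'
#' One-sided Welch (unequal-variance) t-test for the per-cell % Tail DNA of
#' a treatment exceeding its untreated control; the treatment is genotoxicity
#' positive when the increase is significant at `alpha`. Degenerate input
#' (zero variance in both groups) yields p = 1 for equal means and p = 0 for
#' a strictly higher treatment mean.
#'
#' @param treatment_cells,control_cells Per-cell % Tail DNA values in
#'   \[0, 100\] (>= 2 cells per group; replicate slides pooled).
#' @param alpha Significance level (default 0.05).
#' @return List with `mean_treatment`, `mean_control`, `p_value`,
#'   `positive`.
#' @export
comet_positivity <- function(treatment_cells, control_cells, alpha = 0.05) {
  if (length(treatment_cells) < 2 || length(control_cells) < 2) {
    abort("need at least 2 cells per group")
  }
  p <- tryCatch(
    t.test(treatment_cells, control_cells, alternative = "greater",
           var.equal = FALSE)$p.value,
    error = function(e) {
      # constant data in both groups
      if (mean(treatment_cells) > mean(control_cells)) 0 else 1
    }
  )
  list(mean_treatment = mean(treatment_cells),
       mean_control = mean(control_cells),
       p_value = p,
       positive = p < alpha)
}

#' Pearson correlation of molecular and phenotypic endpoints
#'
#' Pearson r with the two-sided p-value from the t-transform on n - 2
#' degrees of freedom, as used for anchoring molecular PELI endpoints to
#' phenotypic ROS and comet endpoints.
#'
#' @param x,y Paired endpoint values (n >= 3, non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired")
  if (length(x) < 3) abort("need at least 3 paired points")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
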