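#' Fit a four-parameter logistic concentration-response curve
#'
#' Fits the increasing 4PL form y(x) = A + (D - A) / (1 + (C/x)^B) to
#' (concentration, PELI) points by bounded least squares (L-BFGS-B on
#' parameters (A, B, log C, D - A)), with a deterministic multi-start grid:
#' four log-spaced midpoint guesses crossed with two slope guesses. Bounds:
#' A in [1, 3], B in [0.1, 10], C in [c_min/10, 10 c_max], D in [1, 50] with
#' D >= A enforced by parameterization. Fits with a plateau rise D - A below
#' 0.05 are flagged degenerate (flat response).
#'
#' @param concentration Concentrations in mg/L (>= 4 distinct values, > 0).
#' @param peli Observed PELI values (finite, >= 1 up to noise).
#' @param c_range Study concentration range `(c_min, c_max)` used for the C
#'   bound; defaults to the data range.
#' @param n_starts Number of C starting guesses in the grid (default 4,
#'   crossed with 2 slope guesses).
#' @return A `fit_4pl` object: list with `A`, `B`, `C`, `D`, `sse`, `status`
#'   (`"fitted"` or `"degenerate"`), `n_points`.
#' @export
fit_4pl <- function(concentration, peli, c_range = NULL, n_starts = 4) {
  x <- as.numeric(concentration)
  y <- as.numeric(peli)
  if (length(x) != length(y)) abort("concentration and peli must be paired")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("nonfinite values in concentration-response points")
  }
  if (any(x <= 0)) abort("concentrations must be > 0 for 4PL fitting")
  if (length(unique(x)) < 4) {
    abort("need at least 4 distinct concentrations for a 4PL fit")
  }
  if (is.null(c_range)) c_range <- range(x)

  lower <- c(A = 1, B = 0.1, logC = log(c_range[1] / 10), dDA = 0)
  upper <- c(A = 3, B = 10, logC = log(c_range[2] * 10), dDA = 49)

  sse_fun <- function(par) {
    yhat <- par[1] + par[4] / (1 + exp(par[2] * (par[3] - log(x))))
    sum((y - yhat)^2)
  }

  a0 <- min(max(min(y), 1), 3)
  d0 <- min(max(max(y) - a0, 0.01), 49)
  c_starts <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_starts))
  b_starts <- c(0.7, 2)

  best <- NULL
  for (c0 in c_starts) {
    for (b0 in b_starts) {
      par0 <- pmin(pmax(c(a0, b0, log(c0), d0), lower), upper)
      fit <- tryCatch(
        optim(par0, sse_fun, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) abort("4PL optimization failed for all starting points")

  par <- best$par
  A <- par[1]; B <- par[2]; C <- exp(par[3]); D <- par[1] + par[4]
  status <- if ((D - A) < 0.05) "degenerate" else "fitted"
  structure(
    list(A = unname(A), B = unname(B), C = unname(C), D = unname(D),
         sse = best$value, status = status, n_points = length(x),
         c_range = c_range),
    class = "fit_4pl"
  )
}

#' Evaluate a 4PL curve
#'
#' @param fit A `fit_4pl` object (or any list with `A`, `B`, `C`, `D`).
#' @param x Concentrations in mg/L (>= 0; the x = 0 limit is the floor A).
#' @return Predicted response values.
#' @export
eval_4pl <- function(fit, x) {
  ifelse(x <= 0, fit$A, fit$A + (fit$D - fit$A) / (1 + (fit$C / x)^fit$B))
}

#' Invert a 4PL curve at a response value
#'
#' Unique analytic inverse x = C / ((D - A)/(y - A) - 1)^(1/B), valid for
#' A < y < D (the curve with B > 0 is strictly increasing).
#'
#' @param fit A `fit_4pl` object.
#' @param y Response value strictly between the floor A and plateau D.
#' @return Concentration in mg/L.
#' @export
invert_4pl <- function(fit, y) {
  if (any(y <= fit$A) || any(y >= fit$D)) {
    abort("inversion requires floor A < y < plateau D")
  }
  fit$C / ((fit$D - fit$A) / (y - fit$A) - 1)^(1 / fit$B)
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf("<fit_4pl> A=%.4g B=%.4g C=%.4g mg/L D=%.4g  sse=%.3g  [%s]\n",
              x$A, x$B, x$C, x$D, x$sse, x$status))
  invisible(x)
}

#' PELI1.5 effect concentration with censoring
#'
#' The concentration at which the fitted PELI concentration-response crosses
#' the positivity threshold (1.5). Within the studied range the analytic 4PL
#' inverse is used; outside it the endpoint is censored: `above_range`
#' (reported N/A) when the curve has not reached the threshold at the highest
#' studied concentration, `below_range` (reported "<c_min") when the response
#' already exceeds the threshold at the lowest studied concentration.
#'
#' @param fit A `fit_4pl` object (`fitted` or `degenerate`; a degenerate flat
#'   fit is censored by comparing its level to the threshold).
#' @param range Studied concentration range `(c_min, c_max)` in mg/L.
#' @param threshold Positivity threshold (default 1.5).
#' @return A `peli15_endpoint`: list with `value` (mg/L or NA), `censor`
#'   (one of interval/above_range/below_range), `range`, `threshold`.
#' @export
peli15 <- function(fit, range = c(0.031, 32), threshold = 1.5) {
  if (fit$A >= threshold) {
    abort(sprintf(
      "invalid fit: baseline A = %.3g is at or above the threshold %.3g",
      fit$A, threshold), class = "pelitox_invalid_fit")
  }
  y_lo <- eval_4pl(fit, range[1])
  y_hi <- eval_4pl(fit, range[2])
  if (y_hi <= threshold) {
    out <- list(value = NA_real_, censor = "above_range")
  } else if (y_lo >= threshold) {
    out <- list(value = range[1], censor = "below_range")
  } else {
    out <- list(value = invert_4pl(fit, threshold), censor = "interval")
  }
  structure(c(out, list(range = range, threshold = threshold)),
            class = "peli15_endpoint")
}

#' Render a PELI1.5 endpoint the way summary tables print it
#'
#' `interval` values print as numbers, `above_range` as `"N/A"`, and
#' `below_range` as `"<c_min"`.
#'
#' @param x A `peli15_endpoint`.
#' @param digits Significant digits for interval values.
#' @param ... Unused.
#' @return Character scalar.
#' @export
format.peli15_endpoint <- function(x, digits = 3, ...) {
  switch(x$censor,
         interval = formatC(x$value, format = "g", digits = digits),
         above_range = "N/A",
         below_range = paste0("<", formatC(x$range[1], format = "g", digits = digits)))
}

#' @export
print.peli15_endpoint <- function(x, ...) {
  cat(sprintf("<peli15_endpoint> %s mg/L (censor: %s)\n", format(x), x$censor))
  invisible(x)
}

#' Toxic equivalent against a reference compound
#'
#' Expresses a sample's category-level response as the dose of a reference
#' standard (mitomycin C for genotoxicity, H2O2 for oxidative stress)
#' producing the same response. The sample's category 4PL is evaluated at
#' the sample's total-level PELI1.5 concentration to obtain the response
#' p*, and the reference compound's same-category 4PL is inverted at p*.
#'
#' Censoring propagates: a `below_range` total PELI1.5 evaluates the
#' category curve at c_min and reports the equivalent as a `greater` bound
#' (the "> value" rendering); an `above_range` total PELI1.5 yields no
#' equivalent (`not_available`). If p* falls outside the reference curve's
#' response over its own studied range, the equivalent is censored at the
#' corresponding range limit.
#'
#' @param sample_cat_fit `fit_4pl` for the sample in the relevant stress
#'   category (DNA for geno-equivalents, oxidative for oxi-equivalents).
#' @param total_endpoint The sample's total-level [peli15()] endpoint.
#' @param reference_fit `fit_4pl` for the reference compound in the same
#'   category (non-degenerate).
#' @param ref_range Reference compound's studied concentration range (mg/L).
#' @return A `toxic_equivalent`: list with `value` (mg/L of reference),
#'   `censor` (exact/greater/less/not_available), `p_star`.
#' @export
compute_teq <- function(sample_cat_fit, total_endpoint, reference_fit,
                        ref_range = c(0.031, 32)) {
  if (reference_fit$status == "degenerate") {
    abort("reference compound fit is degenerate; cannot derive equivalents")
  }
  if (total_endpoint$censor == "above_range") {
    return(structure(list(value = NA_real_, censor = "not_available",
                          p_star = NA_real_),
                     class = "toxic_equivalent"))
  }
  lower_bound <- total_endpoint$censor == "below_range"
  x0 <- if (lower_bound) total_endpoint$range[1] else total_endpoint$value
  p_star <- eval_4pl(sample_cat_fit, x0)

  y_ref_lo <- eval_4pl(reference_fit, ref_range[1])
  y_ref_hi <- eval_4pl(reference_fit, ref_range[2])
  if (p_star >= y_ref_hi) {
    out <- list(value = ref_range[2], censor = "greater")
  } else if (p_star <= y_ref_lo) {
    out <- list(value = ref_range[1], censor = "less")
  } else {
    out <- list(value = invert_4pl(reference_fit, p_star),
                censor = if (lower_bound) "greater" else "exact")
  }
  structure(c(out, list(p_star = p_star)), class = "toxic_equivalent")
}

#' @export
format.toxic_equivalent <- function(x, digits = 4, ...) {
  switch(x$censor,
         exact = formatC(x$value, format = "g", digits = digits),
         greater = paste0(">", formatC(x$value, format = "g", digits = digits)),
         less = paste0("<", formatC(x$value, format = "g", digits = digits)),
         not_available = "N/A")
}

#' @export
print.toxic_equivalent <- function(x, ...) {
  cat(sprintf("<toxic_equivalent> %s mg/L reference-equivalents\n", format(x)))
  invisible(x)
}
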