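#' Protein expression level index for one biomarker
#'
#' PELI summarizes a reporter's time-integrated differential expression:
#' PELI_ORF = exp( (1/T) * integral of |ln I(t)| dt ) over the exposure
#' window, with trapezoidal integration on the measurement grid. A condition
#' with no differential expression (ln I identically 0) yields PELI = 1, and
#' the positivity threshold 1.5 corresponds to a 50% average fold alteration.
#'
#' The functional form is a single swappable strategy: any function with this
#' signature can be passed as `peli_fun` to [peli_table()] and
#' [run_config()].
#'
#' @param time_min Time grid (minutes), at least 2 points.
#' @param ln_i Log induction factor at each time point (unclipped).
#' @return Scalar PELI value, always >= 1.
#' @export
peli_orf <- function(time_min, ln_i) {
  if (length(time_min) != length(ln_i)) {
    abort("time grid and ln_i series must have equal length")
  }
  exp(time_avg_abs(time_min, ln_i))
}

#' Aggregate biomarker PELIs to a category or total PELI
#'
#' Default aggregation is the geometric mean of member ORF PELIs,
#' equivalently the exponential of the mean time-integrated |ln I| —
#' consistent with the exponential single-ORF form. An arithmetic-mean
#' alternative is available.
#'
#' @param orf_pelis Named numeric vector of per-ORF PELI values.
#' @param members Character vector of member ORFs (nonempty, all present in
#'   `orf_pelis`).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return Scalar aggregate PELI, bounded by the member range.
#' @export
peli_aggregate <- function(orf_pelis, members,
                           method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(members) == 0) abort("member set must be nonempty")
  missing_members <- setdiff(members, names(orf_pelis))
  if (length(missing_members) > 0) {
    abort(paste0("members absent from PELI map: ",
                 paste(missing_members, collapse = ", ")))
  }
  vals <- orf_pelis[members]
  switch(method,
         geometric = exp(mean(log(vals))),
         arithmetic = mean(vals))
}

#' PELI table at ORF, category, and total levels
#'
#' For every (compound, concentration) condition: per-ORF PELI from the
#' trajectory, category PELIs over the library's five-category partition,
#' and the total PELI over the whole library.
#'
#' @param profiles Output of [induction_profiles()].
#' @param library A [biomarker_library()]; all profile ORFs must be members.
#' @param method Aggregation method, see [peli_aggregate()].
#' @param peli_fun Strategy function computing the single-ORF index from
#'   `(time_min, ln_i)`; defaults to [peli_orf()].
#' @return Tibble `compound, concentration_mg_L, level, key, peli` with
#'   `level` in orf/category/total.
#' @export
peli_table <- function(profiles, library, method = c("geometric", "arithmetic"),
                       peli_fun = peli_orf) {
  method <- match.arg(method)
  unknown <- setdiff(unique(profiles$orf), library$orf)
  if (length(unknown) > 0) {
    abort(paste0("profile ORFs absent from the library: ",
                 paste(unknown, collapse = ", ")))
  }
  orf_rows <- dplyr::summarise(
    dplyr::group_by(profiles, .data$compound, .data$concentration_mg_L,
                    .data$orf),
    peli = peli_fun(.data$time_min, .data$ln_i), .groups = "drop"
  )
  categories <- setNames(library$category, library$orf)

  per_condition <- function(sub) {
    pelis <- setNames(sub$peli, sub$orf)
    cats <- split(names(pelis), categories[names(pelis)])
    cat_rows <- tibble::tibble(
      level = "category",
      key = names(cats),
      peli = unname(vapply(cats, function(m) peli_aggregate(pelis, m, method), 0))
    )
    total_row <- tibble::tibble(
      level = "total", key = "total",
      peli = peli_aggregate(pelis, names(pelis), method)
    )
    dplyr::bind_rows(
      tibble::tibble(level = "orf", key = sub$orf, peli = sub$peli),
      cat_rows, total_row
    )
  }
  out <- dplyr::reframe(
    dplyr::group_by(orf_rows, .data$compound, .data$concentration_mg_L),
    per_condition(dplyr::pick(dplyr::everything()))
  )
  tibble::as_tibble(out)
}

#' Classify toxicity positivity from a PELI value
#'
#' Positive toxicity is a PELI strictly greater than the threshold (1.5 in
#' the assay's convention); the rule applies identically at ORF, category,
#' and total levels.
#'
#' @param peli Numeric PELI value(s).
#' @param threshold Positivity threshold (default 1.5).
#' @return Logical vector.
#' @export
classify_toxicity <- function(peli, threshold = 1.5) {
  peli > threshold
}

#' Activated ORFs under a condition
#'
#' The set of biomarkers with PELI_ORF above the positivity threshold; used
#' as the test set for ontology enrichment.
#'
#' @param peli_tab A [peli_table()] result.
#' @param compound,concentration Condition selector.
#' @param threshold Positivity threshold (default 1.5).
#' @return Character vector of activated ORF ids (possibly empty).
#' @export
activated_orfs <- function(peli_tab, compound, concentration, threshold = 1.5) {
  rows <- peli_tab[peli_tab$level == "orf" &
                     peli_tab$compound == compound &
                     peli_tab$concentration_mg_L == concentration, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("no ORF-level PELI rows for condition %s @ %g mg/L",
                  compound, concentration))
  }
  rows$key[classify_toxicity(rows$peli, threshold)]
}
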