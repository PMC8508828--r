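#' Stress-category enrichment by permutation GSEA
#'
#' Ranks all library biomarkers by PELI (descending, ties broken by a seeded
#' shuffle) and computes the weighted Kolmogorov-Smirnov running-sum
#' enrichment score of the member set, with weights |PELI - 1| (exponent 1).
#' Significance comes from an empirical null of random member sets of equal
#' size drawn from the library: p = (1 + #\{null >= observed\}) / (1 + n_perm).
#' Because the statistic depends on the ranking only through order and the
#' weights through |PELI - 1|, p-values are invariant to monotone transforms
#' of the ranking.
#'
#' When all member weights are zero (PELI identically 1), the unweighted KS
#' statistic is used as a fallback.
#'
#' @param orf_pelis Named numeric vector of per-ORF PELI values for the whole
#'   library under one condition.
#' @param members Character vector: the category's member ORFs (subset of the
#'   library, 2 <= size < library size).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the tie-break shuffle and the permutation
#'   null (required; results are bit-identical for a fixed seed).
#' @param exhaustive Enumerate every member subset instead of sampling; the
#'   p-value is then the exact fraction of subsets with score >= observed.
#' @return List with `statistic`, `p_value`, `n_permutations`, `exhaustive`.
#' @export
gsea_category <- function(orf_pelis, members, n_perm = 1000, seed,
                          exhaustive = FALSE) {
  if (is.null(names(orf_pelis))) abort("orf_pelis must be named by ORF")
  bad <- setdiff(members, names(orf_pelis))
  if (length(bad) > 0) {
    abort(paste0("members not in the library ranking: ",
                 paste(bad, collapse = ", ")))
  }
  n <- length(orf_pelis)
  m <- length(members)
  if (m < 2) abort("member set must have at least 2 ORFs")
  if (m >= n) abort("member set must be a strict subset of the library")
  if (!exhaustive && n_perm < 99) abort("n_perm must be at least 99")
  if (missing(seed)) abort("a seed is required for GSEA")

  with_local_seed(seed, {
    ord <- order(-orf_pelis, sample.int(n))
    w <- abs(orf_pelis[ord] - 1)
    member_pos <- match(members, names(orf_pelis)[ord])

    observed <- gsea_running_score(member_pos, w, n)
    if (exhaustive) {
      sets <- combn(n, m)
      null <- apply(sets, 2, gsea_running_score, w = w, n = n)
      p <- sum(null >= observed) / ncol(sets)
      n_null <- ncol(sets)
    } else {
      null <- vapply(seq_len(n_perm), function(i) {
        gsea_running_score(sample.int(n, m), w, n)
      }, 0)
      p <- (1 + sum(null >= observed)) / (1 + n_perm)
      n_null <- n_perm
    }
    list(statistic = observed, p_value = p, n_permutations = n_null,
         exhaustive = exhaustive)
  })
}

# Weighted KS running-sum score for member positions within a ranked list.
# Hits advance by weight / total member weight, misses by 1 / (n - m); the
# score is the running-sum deviation of largest magnitude (signed).
gsea_running_score <- function(member_pos, w, n) {
  is_member <- logical(n)
  is_member[member_pos] <- TRUE
  wm <- sum(w[is_member])
  wts <- if (wm > 0) w else rep(1, n)
  p_hit <- cumsum(ifelse(is_member, wts, 0)) / sum(wts[is_member])
  p_miss <- cumsum(!is_member) / (n - length(member_pos))
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' GSEA over every stress category for a set of conditions
#'
#' Convenience wrapper running [gsea_category()] for each of the library's
#' five categories under each (compound, concentration) condition in an
#' ORF-level PELI table.
#'
#' @param peli_tab A [peli_table()] result.
#' @param library A [biomarker_library()].
#' @param n_perm Permutations per test.
#' @param seed Root seed; per-test seeds are derived deterministically.
#' @return Tibble `compound, concentration_mg_L, category, statistic,
#'   p_value, n_permutations, significant`.
#' @export
gsea_all_conditions <- function(peli_tab, library, n_perm = 1000, seed) {
  orf_tab <- peli_tab[peli_tab$level == "orf", , drop = FALSE]
  conds <- dplyr::distinct(orf_tab, .data$compound, .data$concentration_mg_L)
  cats <- split(library$orf, library$category)
  out <- vector("list", nrow(conds) * length(cats))
  k <- 0L
  for (i in seq_len(nrow(conds))) {
    sub <- orf_tab[orf_tab$compound == conds$compound[i] &
                     orf_tab$concentration_mg_L == conds$concentration_mg_L[i], ]
    pelis <- setNames(sub$peli, sub$key)
    for (j in seq_along(cats)) {
      k <- k + 1L
      res <- gsea_category(pelis, cats[[j]], n_perm = n_perm,
                           seed = (seed + 131L * i + j) %% .Machine$integer.max)
      out[[k]] <- tibble::tibble(
        compound = conds$compound[i],
        concentration_mg_L = conds$concentration_mg_L[i],
        category = names(cats)[j],
        statistic = res$statistic,
        p_value = res$p_value,
        n_permutations = res$n_permutations
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res$significant <- res$p_value < 0.05
  res
}

#' Ontology-term enrichment of activated biomarkers
#'
#' Hypergeometric overrepresentation test in the network-ontology-analysis
#' style: the reporter library itself is the reference population and the
#' activated ORFs (PELI_ORF above threshold) are the test set. For each term
#' the upper-tail probability of observing at least the overlap is computed;
#' terms with p below `alpha` are flagged overrepresented. No
#' multiple-testing correction by default (a Benjamini-Hochberg option is
#' provided).
#'
#' @param test_set Character vector of activated ORFs (subset of the
#'   library).
#' @param library A [biomarker_library()] (the reference set).
#' @param term_map Named list term -> character vector of annotated ORFs,
#'   e.g. from [read_term_map()] or [term_map_from_library()].
#' @param alpha Significance level for the overrepresentation flag.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble `term, overlap, term_size, test_set_size, reference_size,
#'   p_value, overrepresented`, one row per term; empty (with a notice) for
#'   an empty test set.
#' @export
ontology_enrichment <- function(test_set, library, term_map, alpha = 0.05,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  outside <- setdiff(test_set, library$orf)
  if (length(outside) > 0) {
    abort(paste0("test set ORFs absent from the reference library: ",
                 paste(outside, collapse = ", ")))
  }
  empty <- tibble::tibble(
    term = character(), overlap = integer(), term_size = integer(),
    test_set_size = integer(), reference_size = integer(),
    p_value = double(), overrepresented = logical()
  )
  if (length(test_set) == 0) {
    inform("empty test set: no activated ORFs, returning no enrichment rows")
    return(empty)
  }
  n_ref <- nrow(library)
  n_test <- length(test_set)
  rows <- purrr::map(names(term_map), function(term) {
    annotated <- intersect(term_map[[term]], library$orf)
    k_term <- length(annotated)
    overlap <- length(intersect(annotated, test_set))
    # P(X >= overlap) for X ~ Hypergeom(n_ref, k_term, n_test)
    p <- phyper(overlap - 1, k_term, n_ref - k_term, n_test,
                lower.tail = FALSE)
    tibble::tibble(term = term, overlap = overlap, term_size = k_term,
                   test_set_size = n_test, reference_size = n_ref,
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  p_used <- if (p_adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$overrepresented <- p_used < alpha
  if (p_adjust == "BH") out$p_adjusted <- p_used
  out
}
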