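#' Hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of profile-matrix rows or columns with
#' dissimilarity d(u, v) = 1 - Pearson r(u, v) and average linkage (complete
#' linkage selectable). Merge order and heights are deterministic for a
#' given input. Average linkage on any dissimilarity is monotone, but merge
#' heights are checked anyway and a warning is emitted if an inversion is
#' ever observed.
#'
#' @param mat Numeric matrix (e.g. from [profile_matrix()]).
#' @param axis Cluster `"rows"` (biomarkers) or `"columns"` (conditions).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An [stats::hclust] object with item labels.
#' @export
cluster_profiles <- function(mat, axis = c("rows", "columns"),
                             linkage = c("average", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2) abort("need at least 2 items to cluster")
  vars <- apply(mat, 1, var)
  if (any(vars == 0)) {
    abort(paste0("zero-variance item(s); correlation undefined for: ",
                 paste(rownames(mat)[vars == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(t(mat)))
  hc <- hclust(d, method = linkage)
  if (any(diff(hc$height) < -1e-9)) {
    warn("non-monotone merge heights in dendrogram")
  }
  hc
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' PCA of condition profiles
#'
#' Principal component analysis of the conditions (columns of the profile
#' matrix) in biomarker space: the condition-by-biomarker matrix is
#' column-mean-centered and decomposed by SVD. Variance fractions sum to 1
#' over the retained components (all of them). Sign convention: within each
#' component, the largest-magnitude biomarker loading is made positive.
#'
#' @param mat Numeric biomarker-by-condition matrix (>= 3 conditions).
#' @return List with `scores` (condition x component matrix), `loadings`
#'   (biomarker x component), `variance_fractions`.
#' @export
pca_profiles <- function(mat) {
  x <- t(mat)  # conditions as observations
  if (nrow(x) < 3) abort("PCA needs at least 3 conditions")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep)) abort("profile matrix has rank 0; PCA undefined")
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, nrow = length(d))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(d)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_along(d)))
  list(scores = scores, loadings = v,
       variance_fractions = d^2 / sum(d^2))
}

#' Tidy PCA tables
#'
#' @param pca Output of [pca_profiles()].
#' @return List of two tibbles: `scores` (`condition, component, score`) and
#'   `variance` (`component, variance_fraction`).
#' @export
pca_tables <- function(pca) {
  scores <- tibble::as_tibble(pca$scores, rownames = "condition")
  scores <- tidyr::pivot_longer(scores, cols = -"condition",
                                names_to = "component", values_to = "score")
  variance <- tibble::tibble(
    component = colnames(pca$scores),
    variance_fraction = pca$variance_fractions
  )
  list(scores = scores, variance = variance)
}
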