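# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals.

# Naive O(n^3) agglomerative clustering on a dissimilarity matrix, returning
# the cophenetic distance matrix (merge heights between every pair). Two
# clusterings agree iff their cophenetic matrices agree.
naive_linkage_cophenetic <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        pairs <- expand.grid(clusters[[i]], clusters[[j]])
        dij <- d[cbind(pairs[[1]], pairs[[2]])]
        val <- if (method == "average") mean(dij) else max(dij)
        if (val < best[1]) best <- c(val, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Exact upper-tail hypergeometric probability P(X >= k) by direct summation
# over the support, using only choose().
hyper_upper_tail <- function(k, K, N, n) {
  support <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(probs[support >= k])
}

# Independent weighted-KS enrichment score: plain loop, no shared code.
naive_gsea_score <- function(ranked_peli, member_set) {
  n <- length(ranked_peli)
  ids <- names(ranked_peli)
  w <- abs(ranked_peli - 1)
  inset <- ids %in% member_set
  if (sum(w[inset]) == 0) w <- rep(1, n)
  whit <- sum(w[inset])
  nmiss <- n - sum(inset)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (inset[i]) w[i] / whit else -1 / nmiss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exact GSEA enumeration p-value over all member subsets of the same size.
naive_gsea_exact_p <- function(ranked_peli, member_set) {
  n <- length(ranked_peli)
  m <- length(member_set)
  obs <- naive_gsea_score(ranked_peli, member_set)
  sets <- combn(names(ranked_peli), m)
  null <- apply(sets, 2, function(s) naive_gsea_score(ranked_peli, s))
  sum(null >= obs) / ncol(sets)
}

# Tiny plate constructor: constant-in-time readings for a handful of wells.
tiny_plate <- function(wells_df, od_values, gfp_values, nt = 5) {
  t <- seq(0, 20, length.out = nt)
  od <- matrix(rep(od_values, each = nt), ncol = nt, byrow = TRUE,
               dimnames = list(wells_df$well, NULL))
  gfp <- matrix(rep(gfp_values, each = nt), ncol = nt, byrow = TRUE,
                dimnames = list(wells_df$well, NULL))
  plate_timeseries(t, od, gfp, plate_layout(wells_df))
}

# Construct paired samples whose Pearson correlation is exactly `r`
# (Gram-Schmidt orthogonalization of noise against the driver).
exact_r_pair <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  e <- e - mean(e)
  xz <- (x - mean(x)) / sd(x)
  e <- e - sum(e * xz) / sum(xz * xz) * xz
  e <- e / sd(e)
  y <- r * xz + sqrt(1 - r^2) * e
  list(x = x, y = y)
}

# Small single-responder truth used by several tests: one programmed ORF with
# max_ln_i = 1 saturating at every study dose, no noise.
single_responder_truth <- function(lib = example_library(), seed = 1) {
  truth <- synthetic_truth(lib, compounds = "GO_test",
                           potency = c(GO_test = 1),
                           noise_cv = 0, seed = seed)
  truth$orfs$responsive <- FALSE
  truth$orfs$max_ln_i <- 0
  truth$orfs$responsive[1] <- TRUE
  truth$orfs$max_ln_i[1] <- 1
  truth$orfs$ec50[1] <- 1e-6
  truth$orfs$hill[1] <- 1
  truth
}
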