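# Clustering of anterior-posterior expression patterns and of enrichment
# term memberships.

#' Cluster anterior-posterior expression patterns
#'
#' Per probe, expression is min-max normalized to \[0, 1\], ordered from
#' posterior to anterior, and smoothed as a function of position with a
#' Gaussian kernel (Nadaraya-Watson, sd `smooth_mm`, which respects the
#' irregular sample spacing; `smooth_mm = 0` disables smoothing). The
#' smoothed pattern vectors are clustered spectrally (radial basis affinity
#' with `gamma`, k-means on the spectral embedding with 10 restarts) for
#' each k in `k_range`, and the mean silhouette width is reported per k.
#' The chosen k is the largest local silhouette peak, favoring more
#' expression patterns; callers can override it.
#'
#' @param expr Samples x probes matrix.
#' @param positions Axis position (mm) per sample.
#' @param probes Probes to cluster (default all).
#' @param k_range Candidate cluster counts.
#' @param smooth_mm Gaussian kernel sd in mm.
#' @param gamma Radial basis affinity parameter.
#' @param seed Seed for the k-means restarts.
#' @param chosen_k Override the silhouette-based choice.
#' @return List of class `cluster_solution`: `assignments` (tibble for the
#'   chosen k), `silhouette` (per k), `chosen_k`, `patterns` (smoothed
#'   pattern matrix) and `mean_patterns` (per-cluster means).
#' @export
cluster_expression_patterns <- function(expr, positions,
                                        probes = colnames(expr),
                                        k_range = 2:10, smooth_mm = 3,
                                        gamma = 1, seed = 1,
                                        chosen_k = NULL) {
  expr <- check_expression(expr)
  if (length(probes) < 2) abort("need at least 2 probes")
  ord <- order(positions)
  pos <- positions[ord]
  X <- expr[ord, probes, drop = FALSE]

  rng <- apply(X, 2, function(v) diff(range(v)))
  zero <- rng < 1e-12
  if (any(zero)) {
    warn(sprintf("excluding %d zero-range probe(s)", sum(zero)))
    X <- X[, !zero, drop = FALSE]
    probes <- colnames(X)
    if (ncol(X) < 2) abort("fewer than 2 probes left after exclusions")
  }
  X <- apply(X, 2, function(v) (v - min(v)) / diff(range(v)))

  if (smooth_mm > 0) {
    W <- exp(-outer(pos, pos, "-")^2 / (2 * smooth_mm^2))
    W <- W / rowSums(W)
    X <- W %*% X
  }
  patterns <- t(X)  # probes x ordered positions

  d <- dist(patterns)
  sols <- spectral_cluster_range(patterns, k_range, gamma, seed)
  sil <- tibble(
    k = k_range,
    silhouette = vapply(seq_along(k_range), function(i) {
      s <- mean_silhouette(sols[[i]], d)
      if (is.na(s)) 0 else s
    }, numeric(1))
  )
  k_star <- chosen_k %||% pick_silhouette_k(sil)
  assignment <- sols[[match(k_star, k_range)]]
  build_cluster_solution(probes, assignment, sil, k_star, patterns, pos)
}

# Ng-Jordan-Weiss spectral clustering with k-means (10 restarts) on the
# row-normalized eigenvector embedding; degenerate duplicate inputs fall
# back to grouping identical rows.
spectral_cluster_range <- function(X, k_range, gamma, seed) {
  n <- nrow(X)
  if (any(k_range > n)) abort("k exceeds the number of items")
  d2 <- as.matrix(dist(X))^2
  A <- exp(-gamma * d2)
  diag(A) <- 0
  dg <- rowSums(A)
  dg[dg < 1e-300] <- 1e-300
  L <- A / sqrt(outer(dg, dg))
  eg <- eigen(L, symmetric = TRUE)
  n_distinct <- nrow(unique(X))
  lapply(k_range, function(k) {
    if (n_distinct <= k) {
      key <- apply(X, 1, paste, collapse = "\r")
      return(as.integer(factor(key, levels = unique(key))))
    }
    V <- eg$vectors[, seq_len(k), drop = FALSE]
    rn <- sqrt(rowSums(V^2))
    rn[rn < 1e-12] <- 1
    V <- V / rn
    withr::with_seed(derive_seed(seed, k),
                     kmeans(V, centers = k, nstart = 10,
                            iter.max = 50)$cluster)
  })
}

# Largest k among local silhouette peaks (plateau-tolerant).
pick_silhouette_k <- function(sil) {
  s <- sil$silhouette
  k <- sil$k
  if (length(s) == 1) return(k[1])
  left <- c(-Inf, s[-length(s)])
  right <- c(s[-1], -Inf)
  peaks <- which(s >= left & s >= right & is.finite(s))
  if (length(peaks) == 0) return(k[which.max(s)])
  k[max(peaks)]
}

build_cluster_solution <- function(ids, assignment, sil, k_star, patterns,
                                   pos = NULL) {
  assignments <- tibble(id = ids, cluster = as.integer(assignment))
  mean_patterns <- NULL
  if (!is.null(patterns)) {
    mean_patterns <- rowsum(patterns, assignment) /
      as.vector(table(assignment))
  }
  structure(list(assignments = assignments, silhouette = sil,
                 chosen_k = k_star, patterns = patterns,
                 mean_patterns = mean_patterns, positions = pos),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k =", x$chosen_k, "over",
      nrow(x$assignments), "items\n")
  invisible(x)
}

#' Cluster genes by shared enrichment terms
#'
#' Agglomerative clustering of the rows of a binary gene x term matrix
#' under Jaccard distance with average linkage, constrained to merge only
#' clusters connected in the `n_neighbors`-nearest-neighbor graph (when the
#' constraint leaves no mergeable pair, the closest pair joins regardless,
#' connecting components). Genes without any term are excluded with a
#' warning. Silhouette is reported per k; the chosen k is the largest local
#' peak.
#'
#' @param gene_term_matrix Binary genes x terms matrix with rownames.
#' @param k_range Candidate cluster counts.
#' @param n_neighbors Connectivity-constraint neighborhood size.
#' @param chosen_k Override the silhouette-based choice.
#' @return A `cluster_solution` over genes.
#' @export
cluster_enrichment_terms <- function(gene_term_matrix, k_range = 2:20,
                                     n_neighbors = 10, chosen_k = NULL) {
  M <- as.matrix(gene_term_matrix)
  if (all(M == 0)) abort("gene x term matrix is all zero")
  if (is.null(rownames(M))) rownames(M) <- paste0("gene_", seq_len(nrow(M)))
  empty <- rowSums(M) == 0
  if (any(empty)) {
    warn(sprintf("excluding %d gene(s) without terms", sum(empty)))
    M <- M[!empty, , drop = FALSE]
  }
  n <- nrow(M)
  if (any(k_range > n)) abort("k exceeds the number of genes")

  d <- dist(M > 0, method = "binary")  # Jaccard distance for binary rows
  merges <- constrained_average_linkage(as.matrix(d), n_neighbors)

  sil <- tibble(
    k = k_range,
    silhouette = vapply(k_range, function(k) {
      s <- mean_silhouette(cut_merges(merges, n, k), d)
      if (is.na(s)) 0 else s
    }, numeric(1))
  )
  k_star <- chosen_k %||% pick_silhouette_k(sil)
  assignment <- cut_merges(merges, n, k_star)
  build_cluster_solution(rownames(M), assignment, sil, k_star, NULL)
}

# Average-linkage agglomeration restricted to a kNN connectivity graph.
# Returns the merge sequence (pairs of cluster representatives).
constrained_average_linkage <- function(D, n_neighbors) {
  n <- nrow(D)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])
    cand <- seq_len(n)[-i][nb[seq_len(min(n_neighbors, n - 1))]]
    adj[i, cand] <- TRUE
    adj[cand, i] <- TRUE
  }
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  merges <- matrix(0L, n - 1, 2)
  for (m in seq_len(n - 1)) {
    ids <- which(active)
    sub <- D[ids, ids, drop = FALSE]
    con <- adj[ids, ids, drop = FALSE]
    diag(sub) <- Inf
    sub[!con] <- Inf
    if (!any(is.finite(sub))) {           # graph exhausted: join components
      sub <- D[ids, ids, drop = FALSE]
      diag(sub) <- Inf
    }
    w <- arrayInd(which.min(sub), dim(sub))
    a <- ids[w[1]]
    b <- ids[w[2]]
    merges[m, ] <- c(a, b)
    # Lance-Williams average linkage update onto representative `a`
    for (j in which(active)) {
      if (j == a || j == b) next
      D[a, j] <- D[j, a] <-
        (size[a] * D[a, j] + size[b] * D[b, j]) / (size[a] + size[b])
    }
    adj[a, ] <- adj[a, ] | adj[b, ]
    adj[, a] <- adj[, a] | adj[b, ]
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
  }
  merges
}

cut_merges <- function(merges, n, k) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  n_merge <- n - k
  if (n_merge > 0) {
    for (m in seq_len(n_merge)) {
      parent[find(merges[m, 2])] <- find(merges[m, 1])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}
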