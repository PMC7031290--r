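# Relating HAGGIS to voxelwise brain maps.

#' Build an anterior-minus-posterior difference map
#'
#' Functional connectivity (`kind = "fc"`): inputs are per-sample volumes
#' (a samples x voxels matrix plus a template volume, as produced by
#' [make_brain_maps()], or a named list of volumes); the output is
#' mean(anterior maps) - mean(posterior maps). Structural covariance
#' (`kind = "sc"`): inputs are subject volumes plus seed voxel indices; for
#' each seed, per-voxel Pearson correlation across subjects is computed,
#' averaged within the anterior and posterior seed sets, differenced, and
#' z-scored over the mask.
#'
#' @param inputs For `"fc"`: `list(values = matrix, template = volume)` or
#'   a named list of `brain_volume`s. For `"sc"`: `list(values = subjects x
#'   voxels matrix, template = volume, hipp_voxel = named voxel indices)`.
#' @param anterior_ids,posterior_ids Sample ids in each pole group.
#' @param kind `"fc"` or `"sc"`.
#' @param mask Optional `brain_volume` restricting the sc z-scoring.
#' @return A [brain_volume()] difference map.
#' @export
build_difference_map <- function(inputs, anterior_ids, posterior_ids,
                                 kind = c("fc", "sc"), mask = NULL) {
  kind <- match.arg(kind)
  if (length(anterior_ids) == 0 || length(posterior_ids) == 0) {
    abort("both pole groups must be nonempty")
  }
  if (kind == "fc") {
    if (is.list(inputs) && !is.null(inputs$values)) {
      V <- inputs$values
      template <- inputs$template
    } else {
      template <- inputs[[1]]
      V <- t(vapply(inputs, function(v) as.vector(v$data),
                    numeric(length(template$data))))
    }
    missing <- setdiff(c(anterior_ids, posterior_ids), rownames(V))
    if (length(missing) > 0) abort("unknown sample ids in pole groups")
    d <- colMeans(V[anterior_ids, , drop = FALSE]) -
      colMeans(V[posterior_ids, , drop = FALSE])
    return(brain_volume(array(d, dim(template$data)), template$affine))
  }
  # structural covariance
  G <- inputs$values
  template <- inputs$template
  seeds <- inputs$hipp_voxel
  missing <- setdiff(c(anterior_ids, posterior_ids), names(seeds))
  if (length(missing) > 0) abort("unknown sample ids in pole groups")
  seed_mat <- G[, seeds[c(anterior_ids, posterior_ids)], drop = FALSE]
  C <- suppressWarnings(cor(seed_mat, G))  # seeds x voxels
  C[!is.finite(C)] <- 0
  na <- length(anterior_ids)
  d <- colMeans(C[seq_len(na), , drop = FALSE]) -
    colMeans(C[na + seq_along(posterior_ids), , drop = FALSE])
  inmask <- if (is.null(mask)) rep(TRUE, length(d)) else as.vector(mask$data) > 0.5
  d[inmask] <- (d[inmask] - mean(d[inmask])) / sd(d[inmask])
  d[!inmask] <- NA_real_
  brain_volume(array(d, dim(template$data)), template$affine)
}

#' Sample a map with cubes around coordinates
#'
#' The mean of in-mask voxel values whose centers fall inside the
#' axis-aligned cube of edge `cube_edge_mm` centered at each coordinate.
#' Coordinates whose cube contains no in-mask voxel (or that fall outside
#' the grid) yield `NA` with a warning.
#'
#' @param map A [brain_volume()].
#' @param coords n x 3 matrix or tibble of mm coordinates.
#' @param cube_edge_mm Full cube edge length in mm (a "radius" of r mm
#'   corresponds to an edge of 2 r).
#' @param mask Optional binary [brain_volume()] on the same grid.
#' @return Numeric vector of per-coordinate means.
#' @export
sample_map_values <- function(map, coords, cube_edge_mm = 5, mask = NULL) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  coords <- rbind_coords(coords)
  vs <- voxel_size(map)
  if (cube_edge_mm < max(vs)) abort("`cube_edge_mm` is below the voxel size")
  dm <- dim(map$data)
  mk <- if (is.null(mask)) NULL else mask$data > 0.5
  half <- cube_edge_mm / 2
  out <- rep(NA_real_, nrow(coords))
  n_bad <- 0
  for (i in seq_len(nrow(coords))) {
    lo <- world_to_voxel(map, coords[i, ] - half)
    hi <- world_to_voxel(map, coords[i, ] + half)
    rng <- lapply(1:3, function(a) {
      r <- sort(c(lo[a], hi[a]))
      seq(ceiling(r[1] - 1e-9), floor(r[2] + 1e-9))
    })
    rng <- lapply(seq_along(rng), function(a) rng[[a]][rng[[a]] >= 1 &
                                                         rng[[a]] <= dm[a]])
    if (any(lengths(rng) == 0)) {
      n_bad <- n_bad + 1
      next
    }
    idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    vals <- map$data[idx]
    if (!is.null(mk)) vals <- vals[mk[idx]]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) {
      n_bad <- n_bad + 1
      next
    }
    out[i] <- mean(vals)
  }
  if (n_bad > 0) {
    warn(sprintf("%d coordinate(s) had no in-mask voxels; returned NA", n_bad))
  }
  out
}

#' Correlate HAGGIS with sampled map values under a permutation null
#'
#' Observed Pearson r and r-squared, compared with the r-squared
#' distribution obtained by randomly shuffling the HAGGIS vector `n_perm`
#' times. The exact p-value is (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param haggis Numeric scores (or `haggis_scores` tibble).
#' @param map_values Paired sampled map values.
#' @param n_perm Number of permutations.
#' @param seed Seed for the shuffles.
#' @return List of class `permutation_result` with `r`, `r2`, `p`, `null`.
#' @export
correlate_with_permutation <- function(haggis, map_values, n_perm = 1000,
                                       seed = 1) {
  if (inherits(haggis, "haggis_scores")) haggis <- haggis$haggis
  ok <- is.finite(haggis) & is.finite(map_values)
  x <- haggis[ok]
  y <- map_values[ok]
  n <- length(x)
  if (n < 10) abort("need at least 10 paired finite values")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in input vector")
  r <- cor(x, y)
  xs <- (x - mean(x)) / (pop_sd(x) * sqrt(n))
  ys <- (y - mean(y)) / (pop_sd(y) * sqrt(n))
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(xs[sample.int(n)] * ys),
           numeric(1))
  })
  null_r2 <- perm^2
  p <- (1 + sum(null_r2 >= r^2)) / (n_perm + 1)
  structure(list(r = r, r2 = r^2, p = p, null = null_r2, n = n,
                 n_perm = n_perm), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> r =", signif(x$r, 3), " r2 =", signif(x$r2, 3),
      " p =", signif(x$p, 4), "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(r = x$r, r2 = x$r2, p = x$p, n = x$n, n_perm = x$n_perm)
}

#' Diffusion-map embedding of region-brain similarity
#'
#' Vectorizes the masked per-sample maps into a samples x voxels matrix,
#' computes the sample x sample Pearson correlation matrix, and reduces it
#' with diffusion-map embedding (anisotropic normalization alpha = 0.5,
#' diffusion time 0; negative affinities clamped to zero). Gradients are
#' zero-centered; variance explained per gradient is the eigenvalue share.
#'
#' @param maps `list(values = matrix, template = volume)`, a plain samples
#'   x voxels matrix, or a list of `brain_volume`s.
#' @param mask Optional binary [brain_volume()] restricting voxels.
#' @param n_components Gradients to return.
#' @param alpha Anisotropic diffusion normalization exponent.
#' @return List of class `embedding_gradients`: `gradients` (samples x
#'   components), `lambdas`, `variance_explained` (nonincreasing).
#' @export
embed_gradients <- function(maps, mask = NULL, n_components = 10,
                            alpha = 0.5) {
  if (is.list(maps) && !is.null(maps$values)) {
    M <- maps$values
  } else if (is.matrix(maps)) {
    M <- maps
  } else {
    M <- t(vapply(maps, function(v) as.vector(v$data),
                  numeric(length(maps[[1]]$data))))
  }
  if (!is.null(mask)) M <- M[, as.vector(mask$data) > 0.5, drop = FALSE]
  if (nrow(M) < 10) abort("need at least 10 samples to embed")
  if (any(apply(M, 1, sd) < 1e-12)) abort("constant map rows cannot be embedded")

  S <- cor(t(M))
  W <- S
  W[W < 0] <- 0
  diag(W) <- 1
  d <- rowSums(W)
  d[d < 1e-300] <- 1e-300
  W <- W / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  Msym <- W / sqrt(outer(d2, d2))
  eg <- eigen(Msym, symmetric = TRUE)
  # drop the trivial stationary component
  lam <- eg$values[-1]
  k <- min(n_components, length(lam))
  lam <- lam[seq_len(k)]
  psi <- eg$vectors[, 1 + seq_len(k), drop = FALSE] / sqrt(d2)
  # diffusion time 0 convention: scale by lambda / (1 - lambda)
  scaling <- lam / pmax(1 - lam, 1e-12)
  grads <- sweep(psi, 2, scaling, "*")
  grads <- scale(grads, center = TRUE, scale = FALSE)
  lam_pos <- pmax(lam, 0)
  ve <- if (sum(lam_pos) > 0) lam_pos / sum(pmax(eg$values[-1], 0)) else lam_pos
  colnames(grads) <- paste0("gradient_", seq_len(k))
  structure(list(gradients = grads, lambdas = lam, variance_explained = ve),
            class = "embedding_gradients")
}

#' @export
print.embedding_gradients <- function(x, ...) {
  cat("<embedding_gradients>", ncol(x$gradients), "gradients over",
      nrow(x$gradients), "samples; top variance share",
      signif(x$variance_explained[1], 3), "\n")
  invisible(x)
}

#' Relate embedding gradients to predicted axis positions
#'
#' Per gradient: r-squared against the scores, Bonferroni-adjusted p over
#' the gradients tested, and Steiger's z-test (dependent correlations
#' sharing one variable, two-sided) comparing the best gradient's
#' correlation against each other gradient.
#'
#' @param gradients An `embedding_gradients` (or samples x gradients
#'   matrix).
#' @param scores Predicted axis position / HAGGIS per sample.
#' @return Tibble with one row per gradient: `r`, `r2`, `p`, `p_bonf`,
#'   `steiger_p` (vs the best gradient; NA when fewer than 2 gradients).
#' @export
relate_gradients <- function(gradients, scores) {
  G <- if (inherits(gradients, "embedding_gradients")) gradients$gradients
  else as.matrix(gradients)
  if (nrow(G) != length(scores)) abort("sample counts differ")
  k <- ncol(G)
  res <- purrr::map_dfr(seq_len(k), function(j) {
    ct <- cor.test(G[, j], scores)
    tibble(gradient = colnames(G)[j] %||% paste0("gradient_", j),
           r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
           p = ct$p.value)
  })
  res$p_bonf <- pmin(1, res$p * k)
  best <- which.max(res$r2)
  res$steiger_p <- NA_real_
  if (k >= 2) {
    for (j in seq_len(k)) {
      res$steiger_p[j] <- steiger_test(
        r12 = res$r[best], r13 = res$r[j],
        r23 = cor(G[, best], G[, j]), n = nrow(G))
    }
  }
  res$best <- seq_len(k) == best
  res
}

# Steiger (1980) z for two dependent correlations sharing one variable.
steiger_test <- function(r12, r13, r23, n) {
  if (abs(r12 - r13) < 1e-15) return(1)
  z1 <- atanh(r12)
  z2 <- atanh(r13)
  rm2 <- (r12^2 + r13^2) / 2
  f <- min((1 - r23) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r23) * h))
  2 * pnorm(-abs(z))
}

#' Maximum explainable variance of a brain map from expression
#'
#' PLS regression of sampled map values on PCA-transformed expression, fit
#' for each candidate component count and scored by 10-fold cross-validation
#' (PCA and PLS are refit inside each training fold). The best CV r-squared
#' is the maximum explainable variance given the expression data; when
#' `haggis` is supplied, its r-squared with the map values is reported as a
#' proportion of that maximum. The top back-transformed PLS probes are
#' returned for overlap analyses.
#'
#' @param expr Samples x probes matrix.
#' @param map_values Sampled map value per sample.
#' @param haggis Optional HAGGIS per sample.
#' @param components Candidate PLS component counts.
#' @param k_top Size of the returned top-probe set.
#' @param seed Fold seed.
#' @return List of class `max_variance_result`: `cv` (r2 per component
#'   count), `best_ncomp`, `best_r2`, `haggis_r2`, `haggis_proportion`
#'   (NA-flagged when the best CV r2 is <= 0) and `top_probes`.
#' @export
fit_max_explainable <- function(expr, map_values, haggis = NULL,
                                components = 1:10, k_top = 100, seed = 1) {
  expr <- check_expression(expr)
  ok <- is.finite(map_values)
  X <- expr[ok, , drop = FALSE]
  y <- map_values[ok]
  n <- nrow(X)
  ncomp_max <- min(max(components), n - ceiling(n / 10) - 1)
  components <- components[components <= ncomp_max]
  if (length(components) == 0) abort("no feasible component count")

  foldid <- make_folds(n, 10, seed)
  P <- matrix(NA_real_, n, length(components))
  for (f in 1:10) {
    test <- foldid == f
    Xtr <- X[!test, , drop = FALSE]
    mu <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, mu)
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-10
    d <- sqrt(eg$values[keep])
    Pb <- crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*%
      diag(1 / d, sum(keep))
    Ztr <- Xc %*% Pb
    Zte <- sweep(X[test, , drop = FALSE], 2, mu) %*% Pb
    colnames(Ztr) <- colnames(Zte) <- paste0("pc_", seq_len(ncol(Ztr)))
    nc <- min(max(components), ncol(Ztr), nrow(Ztr) - 1)
    fit <- mixOmics::pls(Ztr, y[!test], ncomp = nc, mode = "regression",
                         scale = FALSE)
    pr <- predict(fit, Zte)$predict[, 1, , drop = FALSE]
    for (ci in seq_along(components)) {
      P[test, ci] <- pr[, 1, min(components[ci], nc)]
    }
  }
  cv <- tibble(ncomp = components,
               r2 = vapply(seq_along(components),
                           function(ci) r_squared(y, P[, ci]), numeric(1)))
  best_i <- which.max(cv$r2)
  best_ncomp <- cv$ncomp[best_i]
  best_r2 <- cv$r2[best_i]

  # final fit on all samples for the top-probe set
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  d <- sqrt(eg$values[keep])
  Pb <- crossprod(Xc, eg$vectors[, keep, drop = FALSE]) %*%
    diag(1 / d, sum(keep))
  Z <- Xc %*% Pb
  colnames(Z) <- paste0("pc_", seq_len(ncol(Z)))
  fit <- mixOmics::pls(Z, y, ncomp = best_ncomp, mode = "regression",
                       scale = FALSE)
  Bz <- predict(fit, Z)$B.hat[, 1, best_ncomp]
  Bp <- drop(Pb %*% Bz)
  names(Bp) <- colnames(X)
  top <- names(sort(abs(Bp), decreasing = TRUE))[seq_len(min(k_top,
                                                             length(Bp)))]
  hr2 <- NA_real_
  prop <- NA_real_
  if (!is.null(haggis)) {
    if (inherits(haggis, "haggis_scores")) haggis <- haggis$haggis
    hr2 <- cor(haggis[ok], y)^2
    prop <- if (best_r2 > 0) hr2 / best_r2 else NA_real_
  }
  structure(list(cv = cv, best_ncomp = best_ncomp, best_r2 = best_r2,
                 haggis_r2 = hr2, haggis_proportion = prop,
                 betas = Bp, top_probes = top),
            class = "max_variance_result")
}

#' Overlap between two top-feature sets with a random-set null
#'
#' Counts the overlap of two equal-size probe sets and compares it with the
#' overlap of random same-size draws from the probe pool against set A
#' (exact p as in the permutation test).
#'
#' @param set_a,set_b Probe-id vectors of equal size.
#' @param probe_pool All candidate probe ids.
#' @param n_null Random sets drawn.
#' @param seed Seed.
#' @return One-row tibble: `overlap`, `null_mean`, `p`.
#' @export
overlap_top_features <- function(set_a, set_b, probe_pool, n_null = 1000,
                                 seed = 1) {
  k <- length(set_a)
  if (length(set_b) != k) abort("sets must have the same size")
  if (k > length(probe_pool)) abort("set size exceeds the probe pool")
  obs <- length(intersect(set_a, set_b))
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_null),
           function(i) length(intersect(sample(probe_pool, k), set_a)),
           numeric(1))
  })
  tibble(overlap = obs, null_mean = mean(null),
         p = (1 + sum(null >= obs)) / (n_null + 1))
}

#' Mean HAGGIS within meta-analytic topic masks
#'
#' For each binary topic mask, samples whose coordinates fall inside the
#' mask are identified and the mean and sd of their HAGGIS is computed.
#' Masks overlapping fewer than `min_samples` samples are excluded
#' (reported in the `excluded` attribute).
#'
#' @param haggis Numeric per-sample scores (or `haggis_scores`).
#' @param sample_coords n x 3 matrix or tibble of mm coordinates.
#' @param topic_masks Named list of binary [brain_volume()]s.
#' @param min_samples Minimum sample overlap to retain a mask.
#' @return Tibble with `topic`, `n_samples`, `mean_haggis`, `sd_haggis` for
#'   retained masks; excluded mask names in `attr(, "excluded")`.
#' @export
score_topic_maps <- function(haggis, sample_coords, topic_masks,
                             min_samples = 500) {
  if (inherits(haggis, "haggis_scores")) haggis <- haggis$haggis
  if (is.data.frame(sample_coords)) {
    sample_coords <- as.matrix(sample_coords[, c("x", "y", "z")])
  }
  rows <- list()
  excluded <- character()
  for (nm in names(topic_masks)) {
    inmask <- sample_volume_at(topic_masks[[nm]], sample_coords)
    hit <- !is.na(inmask) & inmask > 0.5
    if (sum(hit) < min_samples) {
      excluded <- c(excluded, nm)
      next
    }
    rows[[nm]] <- tibble(topic = nm, n_samples = sum(hit),
                         mean_haggis = mean(haggis[hit]),
                         sd_haggis = sd(haggis[hit]))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) warn("no topic mask met the sample-overlap threshold")
  attr(out, "excluded") <- excluded
  out
}

#' Score gene-ontology cluster associations with a map
#'
#' Per cluster: the weighted mean expression of its genes (weights =
#' cluster centrality, nonnegative) gives one score per sample; the score
#' is correlated with the sampled map values, and the weights are shuffled
#' `n_shuffle` times to form a null. Associations whose |r| exceeds the
#' 95th percentile of the null are flagged.
#'
#' @param expr Samples x probes matrix.
#' @param cluster_gene_weights Tibble with `cluster`, `gene`, `weight`.
#' @param map_values Sampled map value per sample.
#' @param n_shuffle Weight shuffles per cluster.
#' @param seed Seed.
#' @return Tibble with `cluster`, `n_genes`, `r`, `p`, `flagged`,
#'   `degenerate` (single-gene clusters).
#' @export
score_go_cluster_associations <- function(expr, cluster_gene_weights,
                                          map_values, n_shuffle = 100,
                                          seed = 1) {
  expr <- check_expression(expr)
  if (any(cluster_gene_weights$weight < 0)) {
    abort("centrality weights must be nonnegative")
  }
  ok <- is.finite(map_values)
  purrr::map_dfr(split(cluster_gene_weights,
                       cluster_gene_weights$cluster), function(cw) {
    genes <- intersect(cw$gene, colnames(expr))
    cw <- cw[cw$gene %in% genes, ]
    X <- expr[ok, genes, drop = FALSE]
    w <- cw$weight[match(genes, cw$gene)]
    score_of <- function(wt) drop(X %*% wt) / sum(wt)
    s <- score_of(w)
    r_obs <- cor(s, map_values[ok])
    degenerate <- length(genes) < 2
    null <- withr::with_seed(derive_seed(seed, nchar(cw$cluster[1])), {
      vapply(seq_len(n_shuffle),
             function(i) cor(score_of(sample(w)), map_values[ok]),
             numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(r_obs))) / (n_shuffle + 1)
    tibble(cluster = cw$cluster[1], n_genes = length(genes), r = r_obs,
           p = p, flagged = abs(r_obs) > quantile(abs(null), 0.95),
           degenerate = degenerate)
  })
}

#' Sweep the association analysis over masks, cube sizes and signatures
#'
#' Runs the cube-sampling + permutation-correlation analysis for every
#' combination of brain mask, cube edge length and HAGGIS variant (e.g.
#' signatures restricted to individual gene sets), mirroring the
#' many-condition robustness sweep of the full analysis at configurable
#' resolution.
#'
#' @param map A [brain_volume()] to sample (difference or contrast map).
#' @param coords Sample coordinates (matrix or tibble with x/y/z).
#' @param signatures Named list of per-sample score vectors.
#' @param masks Named list of binary [brain_volume()]s.
#' @param cube_edges_mm Cube edge lengths to sweep.
#' @param n_perm Permutations per condition.
#' @param seed Seed.
#' @return Tidy tibble: one row per mask x cube edge x signature with
#'   `r`, `r2`, `p` and `n` (samples with in-mask values).
#' @export
sweep_associations <- function(map, coords, signatures, masks,
                               cube_edges_mm = c(3, 5, 7), n_perm = 1000,
                               seed = 1) {
  if (is.null(names(signatures)) || is.null(names(masks))) {
    abort("`signatures` and `masks` must be named lists")
  }
  grid <- tidyr::expand_grid(mask = names(masks),
                             cube_edge_mm = cube_edges_mm,
                             signature = names(signatures))
  purrr::pmap_dfr(grid, function(mask, cube_edge_mm, signature) {
    mv <- suppressWarnings(
      sample_map_values(map, coords, cube_edge_mm = cube_edge_mm,
                        mask = masks[[mask]]))
    pr <- correlate_with_permutation(
      signatures[[signature]], mv, n_perm = n_perm,
      seed = derive_seed(seed, nchar(mask) * 97 + round(cube_edge_mm * 13) +
                           nchar(signature)))
    tibble(mask = mask, cube_edge_mm = cube_edge_mm, signature = signature,
           n = pr$n, r = pr$r, r2 = pr$r2, p = pr$p)
  })
}

#' Centrality weights from a cluster solution
#'
#' Default "cluster centrality": each gene's mean Jaccard similarity to its
#' cluster co-members in the gene x term matrix.
#'
#' @param gene_term_matrix Binary genes x terms matrix.
#' @param solution A `cluster_solution` over its rows.
#' @return Tibble with `cluster`, `gene`, `weight`.
#' @export
centrality_weights <- function(gene_term_matrix, solution) {
  M <- as.matrix(gene_term_matrix) > 0
  sim <- 1 - as.matrix(dist(M, method = "binary"))
  asg <- solution$assignments
  purrr::map_dfr(split(asg$id, asg$cluster), function(genes) {
    idx <- match(genes, rownames(M))
    w <- if (length(idx) == 1) 1 else
      rowMeans(sim[idx, idx, drop = FALSE]) * length(idx) / (length(idx) - 1) -
      1 / (length(idx) - 1)
    tibble(cluster = paste0("cluster_",
                            asg$cluster[match(genes[1], asg$id)]),
           gene = genes, weight = pmax(as.numeric(w), 0))
  })
}
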