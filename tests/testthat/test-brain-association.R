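# Difference maps, cube sampling, permutation nulls, diffusion embedding,
# maximum explainable variance, overlaps, topic and GO-cluster scoring.

make_vol <- function(data, vox = 2, origin = c(0, 0, 0)) {
  affine <- diag(c(rep(vox, 3), 1))
  affine[1:3, 4] <- origin
  brain_volume(data, affine)
}

test_that("fc difference maps subtract pole means exactly", {
  dims <- c(4, 4, 4)
  M1 <- array(runif(64), dims)
  M2 <- array(runif(64), dims)
  template <- make_vol(array(0, dims))
  V <- rbind(s1 = as.vector(M1), s2 = as.vector(M1),
             s3 = as.vector(M2), s4 = as.vector(M2))
  out <- build_difference_map(list(values = V, template = template),
                              c("s1", "s2"), c("s3", "s4"), kind = "fc")
  expect_equal(out$data, M1 - M2)
  expect_error(build_difference_map(list(values = V, template = template),
                                    character(0), "s3", kind = "fc"),
               "nonempty")
})

test_that("sc difference maps are z-scored and recover the planted axis", {
  cfg <- synth_config(seed = 8, n_samples = 80, n_outliers = 0,
                      n_brain_samples = 250, n_probes = 100, n_planted = 20,
                      n_subjects_sc = 40)
  ds <- make_expression_dataset(cfg, "adult")
  hip <- dplyr::filter(ds$samples, kind == "hippocampus")
  brain <- dplyr::filter(ds$samples, kind == "brain")
  lat <- ds$ground_truth$true_latent
  maps <- make_brain_maps(cfg, brain, lat[brain$sample_id],
                          hipp_samples = hip, hipp_latent = lat[hip$sample_id])
  ant <- hip$sample_id[lat[hip$sample_id] > 0.6]
  post <- hip$sample_id[lat[hip$sample_id] < 0.4]
  sc <- build_difference_map(maps$gm, ant, post, kind = "sc")
  expect_lt(abs(mean(sc$data)), 1e-10)
  expect_equal(sd(sc$data), 1, tolerance = 1e-6)
  planted <- as.vector(maps$planted_axis_map$data)
  expect_gte(abs(cor(as.vector(sc$data), planted)), 0.7)
  # fc difference map also tracks the planted axis field
  fc <- build_difference_map(maps$fc, ant, post, kind = "fc")
  expect_gte(abs(cor(as.vector(fc$data), planted)), 0.7)
})

test_that("cube sampling averages in-cube, in-mask voxel centers", {
  dims <- c(10, 10, 10)
  const <- make_vol(array(3.5, dims))
  expect_equal(sample_map_values(const, rbind(c(10, 10, 10)),
                                 cube_edge_mm = 5), 3.5)
  # value = y coordinate: symmetric cube means recover the center y
  ij <- arrayInd(seq_len(prod(dims)), dims)
  yvol <- make_vol(array(voxel_to_world(const, ij)[, 2], dims))
  expect_equal(sample_map_values(yvol, rbind(c(9, 8, 9)), cube_edge_mm = 4),
               8)
  # straddling the mask boundary: only in-mask voxels count
  mask <- make_vol(array(as.numeric(ij[, 2] <= 5), dims))
  v <- sample_map_values(yvol, rbind(c(9, 8, 9)), cube_edge_mm = 4,
                         mask = mask)
  expect_equal(v, 7)  # in-mask y centers 6 and 8 only
  expect_warning(sample_map_values(yvol, rbind(c(100, 100, 100)),
                                   cube_edge_mm = 4), "no in-mask")
  expect_error(sample_map_values(yvol, rbind(c(1, 1, 1)), cube_edge_mm = 1),
               "voxel size")
})

test_that("permutation p-values are exact and identity maps score 1", {
  withr::with_seed(2, h <- rnorm(50))
  res <- correlate_with_permutation(h, h, n_perm = 1000, seed = 1)
  expect_equal(res$r2, 1)
  expect_equal(res$p, 1 / 1001)
  expect_equal(length(res$null), 1000)
  expect_error(correlate_with_permutation(h, rep(1, 50)), "zero variance")
  expect_error(correlate_with_permutation(h[1:5], h[1:5]), "at least 10")
})

test_that("permutation rejections are calibrated under independence", {
  rej <- 0
  for (i in 1:200) {
    xy <- withr::with_seed(3000 + i, list(x = rnorm(40), y = rnorm(40)))
    p <- correlate_with_permutation(xy$x, xy$y, n_perm = 99, seed = i)$p
    if (p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.1)
})

test_that("diffusion embedding recovers a single latent dimension", {
  withr::with_seed(7, {
    n <- 100
    nv <- 400
    a <- runif(n)
    F1 <- rnorm(nv)
    F2 <- rnorm(nv)
    M <- outer(cos(pi * a / 2), F1) + outer(sin(pi * a / 2), F2) +
      matrix(rnorm(n * nv, 0, 0.3), n)
  })
  em <- embed_gradients(M, n_components = 5)
  expect_gte(abs(cor(em$gradients[, 1], a)), 0.95)
  expect_true(all(diff(em$variance_explained) <= 1e-12))
  expect_lte(sum(em$variance_explained), 1 + 1e-9)
  expect_lt(max(abs(colMeans(em$gradients))), 1e-10)
  # identical samples embed to identical coordinates
  M2 <- rbind(M, M[1, ])
  em2 <- embed_gradients(M2, n_components = 3)
  expect_equal(em2$gradients[1, ], em2$gradients[nrow(M2), ],
               tolerance = 1e-8)
  expect_error(embed_gradients(matrix(1, 12, 5)), "constant")
})

test_that("gradient relation picks the true gradient and Steiger separates it", {
  withr::with_seed(9, {
    scores <- rnorm(200)
    G <- cbind(g1 = scores, g2 = rnorm(200), g3 = rnorm(200))
  })
  rel <- relate_gradients(G, scores)
  expect_true(rel$best[1])
  expect_equal(rel$steiger_p[1], 1)  # the best against itself
  expect_true(all(rel$steiger_p[-1] < 0.01))
  expect_true(all(rel$p_bonf >= rel$p))
  rel1 <- relate_gradients(G[, 1, drop = FALSE], scores)
  expect_true(is.na(rel1$steiger_p))
})

test_that("noise gradients are rarely Bonferroni-significant", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(400 + s, {
      scores <- rnorm(60)
      G <- matrix(rnorm(60 * 5), 60)
    })
    any(relate_gradients(G, scores)$p_bonf < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})

test_that("maximum explainable variance finds low-rank structure", {
  withr::with_seed(5, {
    n <- 80
    p <- 150
    L <- matrix(rnorm(n * 3), n)
    W <- matrix(rnorm(3 * p), 3)
    X <- L %*% W + matrix(rnorm(n * p, 0, 0.05), n)
    colnames(X) <- paste0("pr", seq_len(p))
    y <- L %*% c(1, -2, 0.5)
  })
  mx <- fit_max_explainable(X, as.vector(y), haggis = as.vector(y),
                            components = 1:8, seed = 2)
  expect_gte(mx$best_r2, 0.95)
  expect_lte(mx$best_ncomp, 5)
  expect_equal(mx$haggis_proportion, 1, tolerance = 0.1)
  # pure-noise outcome: nothing explainable, proportion flagged undefined
  ynoise <- withr::with_seed(6, rnorm(n))
  mx0 <- fit_max_explainable(X, ynoise, haggis = ynoise, components = 1:5,
                             seed = 2)
  expect_lte(mx0$best_r2, 0.05)
  if (mx0$best_r2 <= 0) expect_true(is.na(mx0$haggis_proportion))
})

test_that("top-feature overlap uses the random-set null correctly", {
  pool <- paste0("p", 1:2000)
  a <- pool[1:100]
  same <- overlap_top_features(a, a, pool, n_null = 1000, seed = 1)
  expect_equal(same$overlap, 100)
  expect_equal(same$p, 1 / 1001)
  disj <- overlap_top_features(a, pool[101:200], pool, n_null = 200, seed = 1)
  expect_equal(disj$overlap, 0)
  rnd <- overlap_top_features(a, pool[201:300], pool, n_null = 1000, seed = 2)
  expect_equal(rnd$null_mean, 100 * 100 / 2000, tolerance = 0.15)
  expect_error(overlap_top_features(pool, pool, pool[1:10]), "exceeds")
  expect_error(overlap_top_features(a, a[1:50], pool), "same size")
})

test_that("topic masks are scored and filtered by sample overlap", {
  fx <- small_fixture()
  brain <- dplyr::filter(fx$samples, kind == "brain")
  lat <- fx$gt$true_latent[brain$sample_id]
  maps <- make_brain_maps(fx$cfg, brain, lat)
  hg <- rep(2, nrow(brain))
  ts <- score_topic_maps(hg, brain, maps$topic_masks, min_samples = 50)
  # configured overlaps 100 and 60 retained, 30 excluded
  expect_equal(sort(ts$n_samples), c(60, 100))
  expect_true(all(ts$mean_haggis == 2))
  expect_equal(attr(ts, "excluded"), "topic_3")
  # a mask overlapping 499 samples is excluded at the default threshold
  expect_true(all(ts$n_samples[ts$n_samples < 500] < 500))
  expect_warning(empty <- score_topic_maps(hg, brain, maps$topic_masks,
                                           min_samples = 5000),
                 "no topic mask")
  expect_equal(nrow(empty), 0)
})

test_that("GO-cluster scores use centrality weights and a shuffle null", {
  fx <- small_fixture()
  brain <- dplyr::filter(fx$samples, kind == "brain")
  Xb <- fx$expr[brain$sample_id, ]
  lat <- fx$gt$true_latent[brain$sample_id]
  maps <- make_brain_maps(fx$cfg, brain, lat)
  mv <- sample_map_values(maps$disease_map, brain, cube_edge_mm = 5)
  lin <- fx$gt$probes$probe_id[fx$gt$probes$pattern == "linear" &
                                 fx$gt$probes$sign == 1]
  # uniform weights reduce to the plain mean, and symmetric-weight shuffles
  # collapse the null onto the observed value
  cw <- tibble::tibble(cluster = "driver", gene = lin, weight = 1)
  out <- score_go_cluster_associations(Xb, cw, mv, n_shuffle = 50, seed = 2)
  score <- rowMeans(Xb[, lin])
  expect_equal(out$r, cor(score, mv), tolerance = 1e-10)
  expect_equal(out$p, 1)
  expect_false(out$flagged)
  # distinct weights on a planted driver exceed the shuffle null
  cw2 <- tibble::tibble(cluster = "driver", gene = lin,
                        weight = seq(2, 0.1, length.out = length(lin)))
  out2 <- score_go_cluster_associations(Xb, cw2, mv, n_shuffle = 100,
                                        seed = 3)
  expect_gt(abs(out2$r), 0.3)
  expect_error(score_go_cluster_associations(
    Xb, tibble::tibble(cluster = "x", gene = lin, weight = -1), mv),
    "nonnegative")
})

test_that("the association sweep covers the full condition grid", {
  fx <- small_fixture()
  brain <- dplyr::filter(fx$samples, kind == "brain")
  lat <- fx$gt$true_latent[brain$sample_id]
  maps <- make_brain_maps(fx$cfg, brain, lat)
  shuf <- withr::with_seed(6, sample(lat))
  sw <- sweep_associations(maps$disease_map, brain,
                           signatures = list(full = lat,
                                             shuffled = shuf),
                           masks = maps$masks[c("whole_brain",
                                                "cortex_only")],
                           cube_edges_mm = c(3, 5), n_perm = 99, seed = 4)
  expect_equal(nrow(sw), 2 * 2 * 2)
  expect_true(all(sw$p > 0 & sw$p <= 1))
  full_p <- sw$p[sw$signature == "full" & sw$mask == "whole_brain"]
  expect_true(all(full_p <= 0.05))  # planted coupling detected everywhere
  # deterministic under the same seed
  sw2 <- sweep_associations(maps$disease_map, brain,
                            signatures = list(full = lat,
                                              shuffled = shuf),
                            masks = maps$masks[c("whole_brain",
                                                 "cortex_only")],
                            cube_edges_mm = c(3, 5), n_perm = 99, seed = 4)
  expect_equal(sw$p, sw2$p)
})
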