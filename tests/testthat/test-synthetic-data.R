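# Synthetic-data generator: configuration contracts, determinism, planted
# structure, and map coupling.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(pattern_mix = c(linear = 0.5, step = 0.2,
                                            sigmoid = 0.2, unimodal = 0.2)),
               "sum to 1")
  expect_error(synth_config(n_probes = 50L, n_planted = 60L), "exceed")
  expect_error(synth_config(map_coupling_rho = 1.2), "-1, 1")
  expect_error(synth_config(n_planted = 0L), "planted")
  expect_error(synth_config(external_separation = 2), "0, 1")
})

test_that("the same seed reproduces every output bit-identically", {
  cfg <- synth_config(seed = 42, n_samples = 20, n_outliers = 2,
                      n_brain_samples = 30, n_probes = 50, n_planted = 10)
  a <- make_expression_dataset(cfg, "adult")
  b <- make_expression_dataset(cfg, "adult")
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  e1 <- make_expression_dataset(cfg, "external")
  e2 <- make_expression_dataset(cfg, "external")
  expect_identical(e1$expression, e2$expression)
  sig <- a$ground_truth$true_latent[a$samples$sample_id[a$samples$kind == "brain"]]
  brain <- dplyr::filter(a$samples, kind == "brain")
  m1 <- make_brain_maps(cfg, brain, sig)
  m2 <- make_brain_maps(cfg, brain, sig)
  expect_identical(rlang::hash(m1$disease_map), rlang::hash(m2$disease_map))
})

test_that("the tube volume is consistent with its analytic centerline", {
  straight <- synth_config(seed = 1, arc_deg = 0, axis_length_mm = 20)
  vol <- make_hippocampus_volume(straight)
  cl <- attr(vol, "centerline")
  # all centerline points inside the mask
  v <- world_to_voxel(vol, cl)
  inside <- vol$data[round(v)]
  expect_true(all(inside == 1))
  # voxel (1,1,1) maps through the affine to the grid origin in mm
  expect_equal(as.vector(voxel_to_world(vol, c(1, 1, 1))),
               as.vector(vol$affine[1:3, 4]))
  expect_error(make_hippocampus_volume(synth_config(axis_length_mm = 5)),
               "degenerate")
})

test_that("generated hippocampal samples lie within 3 mm of the mask", {
  fx <- small_fixture()
  hip <- dplyr::filter(fx$samples, kind == "hippocampus", !excluded)
  expect_true(all(hip$dist_to_volume <= 3))
  out <- dplyr::filter(fx$samples, kind == "hippocampus", excluded)
  expect_equal(nrow(out), fx$cfg$n_outliers)
  expect_true(all(out$dist_to_volume > 3))
})

test_that("planted linear probes correlate strongly with position", {
  rs <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_samples = 60, n_outliers = 0,
                        n_brain_samples = 0, n_probes = 20, n_planted = 10,
                        pattern_mix = c(linear = 1, step = 0, sigmoid = 0,
                                        unimodal = 0),
                        donor_offsets = 0)
    ds <- make_expression_dataset(cfg, "adult")
    probe <- ds$ground_truth$planted_probe_ids[1]
    abs(cor(ds$expression[, probe], ds$samples$true_latent))
  }, numeric(1))
  expect_true(all(rs >= 0.8))
})

test_that("pattern labels are recoverable by correlation sign for linear probes", {
  fx <- small_fixture()
  probes <- fx$gt$probes
  lin <- probes[probes$pattern == "linear", ]
  hip <- dplyr::filter(fx$ds$samples, kind == "hippocampus")
  r <- as.vector(cor(fx$ds$expression[hip$sample_id, lin$probe_id],
                     hip$true_latent))
  expect_true(all(sign(r) == lin$sign))
})

test_that("donor offsets shift all probes additively before adjustment", {
  cfg <- synth_config(seed = 9, n_samples = 40, n_outliers = 0,
                      n_brain_samples = 0, n_probes = 30, n_planted = 5,
                      donor_offsets = c(5, -5))
  ds <- make_expression_dataset(cfg, "adult")
  d1 <- ds$samples$donor == "donor_1"
  diffs <- colMeans(ds$expression[d1, ]) - colMeans(ds$expression[!d1, ])
  expect_true(all(abs(diffs - 10) < 2))  # 10 +/- sampling noise
  expect_lt(abs(mean(diffs) - 10), 0.5)
})

test_that("voxel maps couple to the signature at the configured strength", {
  sampled_r <- function(s, rho) {
    cfg <- synth_config(seed = s, n_brain_samples = 500,
                        map_coupling_rho = rho)
    ds <- make_expression_dataset(cfg, "adult")
    brain <- dplyr::filter(ds$samples, kind == "brain")
    sig <- ds$ground_truth$true_latent[brain$sample_id]
    maps <- make_brain_maps(cfg, brain, sig)
    cor(sample_map_values(maps$disease_map, brain, cube_edge_mm = 5), sig)
  }
  r0 <- vapply(1:6, sampled_r, numeric(1), rho = 0)
  expect_true(all(abs(r0) < 0.1))
  r6 <- vapply(1:4, sampled_r, numeric(1), rho = 0.6)
  expect_true(all(abs(r6 - 0.6) < 0.1))
})

test_that("brain map generation validates its inputs", {
  cfg <- synth_config(seed = 2, n_samples = 10, n_outliers = 0,
                      n_brain_samples = 20, n_probes = 20, n_planted = 5)
  ds <- make_expression_dataset(cfg, "adult")
  brain <- dplyr::filter(ds$samples, kind == "brain")
  expect_error(make_brain_maps(cfg, brain, signature = rnorm(3)),
               "one value per brain sample")
})

test_that("external mode yields labeled classes separated along the axis", {
  cfg <- synth_config(seed = 5, n_external = 60, external_separation = 1)
  ext <- make_expression_dataset(cfg, "external")
  expect_setequal(unique(ext$samples$class), c("rostral", "caudal"))
  t_r <- ext$samples$true_latent[ext$samples$class == "rostral"]
  t_c <- ext$samples$true_latent[ext$samples$class == "caudal"]
  expect_gt(min(t_r), max(t_c) - 1e-9)  # fully disjoint at separation 1
})
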