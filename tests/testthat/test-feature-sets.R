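# Model deconstruction: iterative removal, gene-set definition, restricted
# refits with controls, and the local perturbation explainer.

test_that("targeted removal strips the planted signal in the first batch", {
  cfg <- synth_config(seed = 5, n_samples = 100, n_outliers = 0,
                      n_brain_samples = 0, n_probes = 1000, n_planted = 10,
                      pattern_mix = c(linear = 1, step = 0, sigmoid = 0,
                                      unimodal = 0))
  ds <- make_expression_dataset(cfg, "adult")
  expr <- regress_donor_effects(ds$expression, ds$samples$donor)
  y <- ds$samples$true_position_mm
  tr <- iterative_probe_removal(expr, y, batch = 100, mode = "targeted",
                                seed = 1, max_iter = 2)
  planted <- ds$ground_truth$planted_probe_ids
  expect_gte(length(intersect(tr$removed[[1]], planted)), 9)
  expect_lt(tr$cv_r2[2], 0.2)
  expect_gt(tr$cv_r2[1] - tr$cv_r2[2], 0.5)
})

test_that("random removal degrades accuracy only gradually", {
  cfg <- synth_config(seed = 6, n_samples = 80, n_outliers = 0,
                      n_brain_samples = 0, n_probes = 300, n_planted = 10,
                      pattern_mix = c(linear = 1, step = 0, sigmoid = 0,
                                      unimodal = 0))
  ds <- make_expression_dataset(cfg, "adult")
  expr <- regress_donor_effects(ds$expression, ds$samples$donor)
  y <- ds$samples$true_position_mm
  tr <- iterative_probe_removal(expr, y, batch = 50, mode = "random",
                                seed = 2)
  n_iter <- nrow(tr)
  # every round before the last two keeps usable accuracy
  expect_true(all(tr$cv_r2[seq_len(n_iter - 2)] > 0.1))
  # removed batches are disjoint and exhaust all probes
  removed <- unlist(tr$removed)
  expect_equal(sort(removed), sort(colnames(expr)))
  expect_equal(anyDuplicated(removed), 0)
})

test_that("a final short batch removes the remainder and terminates", {
  withr::with_seed(9, {
    X <- matrix(rnorm(40 * 120), 40, dimnames = list(NULL, paste0("p", 1:120)))
  })
  y <- X[, 1] * 3 + rnorm(40, 0, 0.2) + 100
  tr <- iterative_probe_removal(X, y, batch = 50, mode = "targeted", seed = 3)
  expect_equal(lengths(tr$removed), c(50, 50, 20))
  expect_error(iterative_probe_removal(X, y, batch = 0), "positive")
  expect_error(iterative_probe_removal(X, y, batch = 33, mode = "targeted"),
               "even")
})

test_that("gene sets partition removal ranks at the boundaries", {
  fake <- tibble::tibble(
    iteration = 1:7,
    n_remaining = seq(700, 100, by = -100),
    cv_r2 = c(0.9, 0.85, 0.5, 0.45, 0.4, 0.1, 0.05),
    cv_mae = 1,
    removed = split(paste0("p", 1:700), rep(1:7, each = 100))
  )
  class(fake) <- c("removal_trace", class(fake))
  gs <- define_gene_sets(fake, boundary_ranks = c(100, 600))
  expect_equal(unname(table(gs$set)["Set1"]), 100L)
  expect_equal(unname(table(gs$set)["Set2"]), 500L)
  expect_equal(gs$set[gs$removal_rank == 101], "Set2")
  expect_equal(gs$set[gs$removal_rank == 600], "Set2")
  # one boundary = one set holding everything up to it
  one <- define_gene_sets(fake, boundary_ranks = 700)
  expect_equal(unique(one$set), "Set1")
  expect_equal(nrow(one), 700)
  expect_error(define_gene_sets(fake, boundary_ranks = c(600, 100)),
               "increasing")
  expect_error(define_gene_sets(fake, boundary_ranks = c(100, 900)),
               "within")
  # default heuristic proposes boundaries at the largest accuracy drops
  auto <- define_gene_sets(fake, n_sets = 2)
  expect_true(all(attr(auto, "boundaries") %in% seq(100, 700, by = 100)))
})

test_that("set-restricted models recover or lose accuracy as planted", {
  cfg <- synth_config(seed = 7, n_samples = 100, n_outliers = 0,
                      n_brain_samples = 0, n_probes = 500, n_planted = 50,
                      pattern_mix = c(linear = 1, step = 0, sigmoid = 0,
                                      unimodal = 0))
  ds <- make_expression_dataset(cfg, "adult")
  expr <- regress_donor_effects(ds$expression, ds$samples$donor)
  y <- ds$samples$true_position_mm
  planted <- ds$ground_truth$planted_probe_ids
  sets <- list(planted = planted,
               complement = setdiff(colnames(expr), planted))
  full <- cross_validate(expr, y, repeats = 1, k = 10, seed = 3)
  ev <- evaluate_gene_set_models(expr, y, sets, n_boot = 3,
                                 controls = "random_matched", seed = 3)
  s <- ev$summary
  planted_r2 <- s$mean_r2[s$set == "planted" & s$kind == "gene_set"]
  comp_r2 <- s$mean_r2[s$set == "complement" & s$kind == "gene_set"]
  expect_lt(abs(planted_r2 - full$r2), 0.05)
  expect_lte(comp_r2, 0.1)
  expect_equal(sum(ev$replicates$set == "planted" &
                     ev$replicates$kind == "gene_set"), 3)
  expect_error(evaluate_gene_set_models(expr, y, list(tiny = planted[1])),
               "at least 2")
})

test_that("the local explainer concentrates importance on the true driver", {
  withr::with_seed(1, {
    X <- matrix(rnorm(120 * 10), 120,
                dimnames = list(NULL, paste0("probe_", 1:10)))
  })
  y <- X[, 1]
  imp <- explain_local_features(X, y, n_folds = 5, seed = 1,
                                n_perturb = 150, num_trees = 300)
  expect_equal(imp$n_explained, rep(120L, 10))
  expect_gt(imp$importance[1] / sum(imp$importance), 0.9)
})

test_that("pure-noise features get flat importances", {
  ratios <- vapply(1:6, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(60 * 8), 60, dimnames = list(NULL, paste0("p", 1:8)))
      y <- rnorm(60)
    })
    imp <- explain_local_features(X, y, n_folds = 5, seed = s,
                                  n_perturb = 100, num_trees = 200)
    max(imp$importance) / median(imp$importance)
  }, numeric(1))
  expect_lt(mean(ratios), 3)
})

test_that("explainer input contracts hold", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(explain_local_features(X, rnorm(20), probes = "a"),
               "at least 2")
  expect_error(explain_local_features(X, rnorm(20), n_folds = 30),
               "exceeds")
})
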