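# HAGGIS scores, external transfer, group statistics and split scanning.

test_that("HAGGIS is the intercept-free dot product with the betas", {
  expr <- matrix(c(2, 1, 7), 1, dimnames = list("s1", c("a", "b", "c")))
  b <- c(a = 1, b = -1, c = 0)
  expect_equal(compute_haggis(b, expr)$haggis, 1)
  expect_equal(compute_haggis(b, expr * 0)$haggis, 0)
})

test_that("on training samples HAGGIS equals prediction minus intercept", {
  fx <- small_fixture()
  fit <- small_fit()
  hg <- compute_haggis(fit, fx$X)
  expect_equal(hg$haggis, unname(predict(fit, fx$X) - fit$intercept))
})

test_that("HAGGIS is linear and additive over disjoint probe subsets", {
  fx <- small_fixture()
  fit <- small_fit()
  hg <- compute_haggis(fit, fx$X)
  expect_equal(compute_haggis(fit, 3 * fx$X)$haggis, 3 * hg$haggis)
  half <- floor(ncol(fx$X) / 2)
  b <- tidy(fit)
  b1 <- b[b$probe_id %in% colnames(fx$X)[1:half], ]
  b2 <- b[b$probe_id %in% colnames(fx$X)[(half + 1):ncol(fx$X)], ]
  suppressMessages({
    s1 <- compute_haggis(b1, fx$X)$haggis
    s2 <- compute_haggis(b2, fx$X)$haggis
  })
  expect_equal(s1 + s2, hg$haggis, tolerance = 1e-10)
})

test_that("probes absent from one side are dropped with a message", {
  expr <- matrix(1:4, 2, dimnames = list(NULL, c("a", "b")))
  expect_message(out <- compute_haggis(c(a = 1, zz = 5), expr), "absent")
  expect_equal(out$haggis, expr[, "a"] * 1, ignore_attr = TRUE)
  expect_error(compute_haggis(c(q = 1), expr), "no overlapping")
})

test_that("transfer separates classes planted along the axis", {
  fx <- small_fixture()
  fit <- small_fit()
  ext <- make_expression_dataset(fx$cfg, "external")
  ext_expr <- regress_donor_effects(ext$expression, ext$samples$donor)
  tr <- transfer_to_external(fit, ext_expr, ext$samples$class)
  expect_gt(tr$auc, 0.8)
  expect_lt(tr$t_test$p.value, 0.01)
  ros <- tr$scores$haggis[tr$scores$class == "rostral"]
  cau <- tr$scores$haggis[tr$scores$class == "caudal"]
  expect_gt(mean(ros), mean(cau))  # rostral predicted more anterior
})

test_that("transfer AUC rises monotonically with class separation", {
  fx <- small_fixture()
  fit <- small_fit()
  aucs <- vapply(c(0.2, 0.6, 1), function(sep) {
    cfg <- fx$cfg
    cfg$n_external <- 60L
    cfg$external_separation <- sep
    ext <- make_expression_dataset(cfg, "external", draw_seed = 13)
    ext_expr <- regress_donor_effects(ext$expression, ext$samples$donor)
    transfer_to_external(fit, ext_expr, ext$samples$class)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("perfectly separated scores give AUC and accuracy of 1", {
  expr <- matrix(c(1:5, 11:15), 10, 1, dimnames = list(NULL, "a"))
  labels <- rep(c("caudal", "rostral"), each = 5)
  tr <- transfer_to_external(c(a = 1), expr, labels)
  expect_equal(tr$auc, 1)
  expect_equal(tr$accuracy, 1)
  expect_error(transfer_to_external(c(a = 1), expr, rep("rostral", 10)),
               "2 classes")
})

test_that("group statistics reproduce published demographic rows", {
  # age row: means 62.0 (8.8, n=35) vs 61.4 (8.7, n=35)
  age <- compare_groups(tibble::tibble(group = c("AD", "FTD"),
                                       mean = c(62.0, 61.4),
                                       sd = c(8.8, 8.7), n = c(35, 35)))
  expect_equal(round(age$cohens_d, 2), 0.07)
  # sex counts 12/23 vs 19/16 and dementia-stage counts 22/13 vs 17/18
  sex <- compare_groups(matrix(c(12, 23, 19, 16), 2, byrow = TRUE),
                        kind = "contingency")
  expect_equal(round(sex$fisher_p, 2), 0.15)
  stage <- compare_groups(matrix(c(22, 13, 17, 18), 2, byrow = TRUE),
                          kind = "contingency")
  expect_equal(round(stage$fisher_p, 2), 0.34)
})

test_that("group statistics handle raw values and degenerate groups", {
  withr::with_seed(4, raw <- tibble::tibble(
    group = rep(c("a", "b"), each = 20), value = rnorm(40)))
  out <- compare_groups(raw)
  expect_true(is.finite(out$p_mw))
  same <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                         value = rep(1:5, 2))
  out2 <- suppressWarnings(compare_groups(same))
  expect_equal(out2$cohens_d, 0)
  expect_equal(out2$p_t, 1)
  const <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                          value = rep(2, 6))
  expect_warning(out3 <- compare_groups(const), "pooled sd")
  expect_true(is.na(out3$cohens_d))
  expect_error(compare_groups(matrix(1:6, 2, 3), kind = "contingency"),
               "2x2")
})

test_that("split scanning finds perfect separation for monotone scores", {
  fx <- small_fixture()
  sk <- fx$skeleton
  pos <- fx$y
  hg <- pos - mean(pos)  # strictly monotone in position
  ss <- scan_axis_splits(hg, pos, sk, min_pole_mm = 3, min_n = 10)
  valid <- ss$scan[ss$scan$valid, ]
  expect_true(all(valid$accuracy == 1))
  expect_gt(ss$anterior_cut, ss$posterior_cut)
  expect_setequal(unique(ss$assignment),
                  c("anterior", "posterior", "excluded"))
})

test_that("position-independent scores track the majority class", {
  fx <- small_fixture()
  withr::with_seed(7, hg <- rnorm(length(fx$y)))
  ss <- scan_axis_splits(hg, fx$y, fx$skeleton, min_n = 10)
  valid <- ss$scan[ss$scan$valid, ]
  majority <- pmax(valid$n_anterior, valid$n_posterior) /
    (valid$n_anterior + valid$n_posterior)
  expect_lt(mean(abs(valid$accuracy - majority)), 0.1)
})

test_that("split scanning needs enough samples per side", {
  sk <- tibble::tibble(x = 0, y = 90:110, z = 0)
  expect_error(scan_axis_splits(rnorm(30), runif(30, 90, 110), sk,
                                min_n = 20), "at least 40")
})
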