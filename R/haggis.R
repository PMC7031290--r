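# HAGGIS signature scores, transfer to an external labeled dataset,
# group-comparison statistics and anterior/posterior split scanning.

#' Compute HAGGIS signature scores
#'
#' The Hippocampal Axis Genomic Gradient Index of Similarity: the
#' intercept-free dot product of each sample's expression vector with the
#' axis model's per-probe betas. Positive values mean anterior-like
#' expression, negative posterior-like. Probes present in only one input
#' are dropped (contributing 0) with a message; the score is linear in
#' expression and additive over disjoint probe subsets.
#'
#' @param betas Named per-probe weight vector, an `axis_model`, or a tibble
#'   with `probe_id` and `beta` columns.
#' @param expr Samples x probes matrix.
#' @return Tibble of class `haggis_scores` with `sample_id` and `haggis`.
#' @export
compute_haggis <- function(betas, expr) {
  expr <- check_expression(expr)
  b <- as_beta_vector(betas)
  common <- intersect(names(b), colnames(expr))
  if (length(common) == 0) abort("no overlapping probes between betas and expression")
  n_miss <- length(b) - length(common)
  if (n_miss > 0) {
    inform(sprintf("%d beta probe(s) absent from expression; contributing 0",
                   n_miss))
  }
  s <- drop(expr[, common, drop = FALSE] %*% b[common])
  out <- tibble(
    sample_id = rownames(expr) %||% paste0("sample_", seq_len(nrow(expr))),
    haggis = unname(s)
  )
  class(out) <- c("haggis_scores", class(out))
  out
}

as_beta_vector <- function(betas) {
  if (inherits(betas, "axis_model")) return(betas$betas)
  if (is.data.frame(betas)) return(setNames(betas$beta, betas$probe_id))
  if (is.numeric(betas) && !is.null(names(betas))) return(betas)
  abort("`betas` must be a named vector, axis_model, or tidy beta table")
}

#' Transfer the axis model to an external labeled dataset
#'
#' Computes HAGGIS on the external expression, compares the two classes
#' with a t-test, and fits a single-predictor logistic regression of class
#' on HAGGIS, reporting training accuracy (0.5 threshold), the ROC curve
#' and its AUC. The positive class is `"rostral"` (anterior-like).
#'
#' @param betas As in [compute_haggis()].
#' @param external_expr Samples x probes matrix of the external dataset.
#' @param labels Character/factor vector with two classes, `"rostral"` and
#'   `"caudal"`.
#' @return List of class `transfer_result`: `scores`, `accuracy`, `auc`,
#'   `roc` (tibble), `t_test` and the glm fit.
#' @export
transfer_to_external <- function(betas, external_expr, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("`labels` must contain exactly 2 classes")
  hg <- compute_haggis(betas, external_expr)
  y <- as.integer(labels == "rostral")
  if (!"rostral" %in% classes) y <- as.integer(labels == classes[2])
  tt <- t.test(hg$haggis[y == 1], hg$haggis[y == 0])
  fit <- suppressWarnings(glm(y ~ haggis, data = cbind(hg, y = y),
                              family = binomial()))
  acc <- mean((fitted(fit) > 0.5) == y)
  roc_obj <- pROC::roc(response = y, predictor = hg$haggis, quiet = TRUE,
                       direction = "<")
  structure(list(
    scores = mutate(hg, class = labels),
    accuracy = acc,
    auc = as.numeric(pROC::auc(roc_obj)),
    roc = tibble(specificity = roc_obj$specificities,
                 sensitivity = roc_obj$sensitivities),
    t_test = tt,
    fit = fit
  ), class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result> accuracy:", signif(x$accuracy, 3),
      " AUC:", signif(x$auc, 3),
      " t-test p:", signif(x$t_test$p.value, 3), "\n")
  invisible(x)
}

#' @export
glance.transfer_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, auc = x$auc,
         t = unname(x$t_test$statistic), p_t = x$t_test$p.value)
}

#' Two-group comparison statistics
#'
#' Continuous data: Cohen's d with pooled sd, pooled-variance two-sample
#' t-test, and (for raw values) a Mann-Whitney test. The sign of d follows
#' group1 - group2 in order of appearance. Accepts either raw values
#' (tibble with `group` and `value`) or per-group summaries (tibble with
#' `group`, `mean`, `sd`, `n`), so statistics can be recomputed from
#' published tables. Contingency data: a 2x2 count matrix, compared with a
#' two-sided Fisher exact test (point-probability rule).
#'
#' @param data Tibble of raw values or summaries, or a 2x2 matrix.
#' @param kind `"continuous"` or `"contingency"`.
#' @return One-row tibble of class `group_stats`.
#' @export
compare_groups <- function(data, kind = c("continuous", "contingency")) {
  kind <- match.arg(kind)
  if (kind == "contingency") {
    m <- as.matrix(data)
    if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
      abort("contingency data must be a 2x2 matrix of nonnegative counts")
    }
    ft <- fisher.test(m)
    out <- tibble(fisher_p = ft$p.value, odds_ratio = unname(ft$estimate))
  } else {
    if (all(c("mean", "sd", "n") %in% names(data))) {
      if (nrow(data) != 2) abort("summary input needs exactly 2 rows")
      m <- data$mean; s <- data$sd; n <- data$n
      raw <- NULL
    } else {
      if (!all(c("group", "value") %in% names(data))) {
        abort("continuous data needs `group`+`value` or `mean`+`sd`+`n`")
      }
      g <- factor(data$group, levels = unique(data$group))
      if (nlevels(g) != 2) abort("need exactly 2 groups")
      sp <- split(data$value, g)
      if (any(lengths(sp) < 2)) abort("need >= 2 values per group")
      m <- vapply(sp, mean, 0); s <- vapply(sp, sd, 0)
      n <- lengths(sp); raw <- sp
    }
    pooled <- sqrt(((n[1] - 1) * s[1]^2 + (n[2] - 1) * s[2]^2) /
                     (n[1] + n[2] - 2))
    if (pooled < 1e-12) {
      warn("zero pooled sd; Cohen's d undefined")
      d <- NA_real_; tstat <- 0; p_t <- 1
    } else {
      d <- (m[1] - m[2]) / pooled
      tstat <- d * sqrt(n[1] * n[2] / (n[1] + n[2]))
      p_t <- 2 * pt(-abs(tstat), n[1] + n[2] - 2)
    }
    p_mw <- if (!is.null(raw)) {
      suppressWarnings(wilcox.test(raw[[1]], raw[[2]])$p.value)
    } else NA_real_
    out <- tibble(mean1 = m[1], sd1 = s[1], n1 = n[1],
                  mean2 = m[2], sd2 = s[2], n2 = n[2],
                  cohens_d = unname(d), t = unname(tstat),
                  df = unname(n[1] + n[2] - 2), p_t = unname(p_t),
                  p_mw = p_mw)
  }
  class(out) <- c("group_stats", class(out))
  out
}

#' Scan anterior/posterior split points along the skeleton
#'
#' At every candidate skeleton y-coordinate, samples are labeled anterior
#' or posterior relative to the split and a single-predictor logistic
#' regression of the label on HAGGIS is fit; its training accuracy is
#' recorded. Valid splits lie at least `min_pole_mm` from both skeleton
#' poles and keep at least `min_n` samples on each side. The chosen
#' anterior and posterior cut points are the anterior-most and
#' posterior-most local accuracy maxima among valid splits; samples between
#' the two cuts are flagged as excluded from anterior/posterior analyses.
#'
#' @param haggis Numeric HAGGIS per sample (or a `haggis_scores` tibble).
#' @param positions Axis position (mm) per sample.
#' @param skeleton A `skeleton_path` (its y range defines the poles).
#' @param min_pole_mm Minimum distance of a split from either pole.
#' @param min_n Minimum samples on each side of a split.
#' @return List of class `split_scan`: `scan` (accuracy per candidate
#'   split), `anterior_cut`, `posterior_cut` and `assignment`.
#' @export
scan_axis_splits <- function(haggis, positions, skeleton, min_pole_mm = 3,
                             min_n = 20) {
  if (inherits(haggis, "haggis_scores")) haggis <- haggis$haggis
  n <- length(haggis)
  if (length(positions) != n) abort("`haggis` and `positions` lengths differ")
  if (n < 2 * min_n) {
    abort(sprintf("need at least %d samples (min_n = %d per side); got %d",
                  2 * min_n, min_n, n))
  }
  ys <- sort(unique(round(skeleton$y)))
  poles <- range(skeleton$y)

  scan <- purrr::map_dfr(ys, function(y0) {
    ant <- positions > y0
    n_ant <- sum(ant)
    ok_pole <- (y0 - poles[1]) >= min_pole_mm & (poles[2] - y0) >= min_pole_mm
    ok_n <- n_ant >= min_n && (n - n_ant) >= min_n
    acc <- NA_real_
    if (n_ant > 0 && n_ant < n) {
      fit <- suppressWarnings(glm(ant ~ haggis, family = binomial()))
      acc <- mean((fitted(fit) > 0.5) == ant)
    }
    tibble(split_y = y0, accuracy = acc, n_anterior = n_ant,
           n_posterior = n - n_ant, valid = ok_pole && ok_n && !is.na(acc))
  })

  valid <- scan[scan$valid, ]
  if (nrow(valid) == 0) {
    abort(paste0("no qualifying split: every candidate violates the pole ",
                 "distance (", min_pole_mm, " mm) or per-side sample (",
                 min_n, ") constraint"))
  }
  a <- valid$accuracy
  left <- c(-Inf, a[-length(a)])
  right <- c(a[-1], -Inf)
  peaks <- which(a >= left & a >= right)
  anterior_cut <- valid$split_y[max(peaks)]
  posterior_cut <- valid$split_y[min(peaks)]
  assignment <- dplyr::case_when(
    positions > anterior_cut ~ "anterior",
    positions <= posterior_cut ~ "posterior",
    TRUE ~ "excluded"
  )
  structure(list(scan = scan, anterior_cut = anterior_cut,
                 posterior_cut = posterior_cut, assignment = assignment),
            class = "split_scan")
}

#' @export
print.split_scan <- function(x, ...) {
  cat("<split_scan> anterior cut y =", x$anterior_cut,
      ", posterior cut y =", x$posterior_cut, "(",
      sum(x$assignment == "excluded"), "samples between cuts )\n")
  invisible(x)
}
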