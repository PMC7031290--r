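# LASSO-PCR position model, back-transformation to probe space,
# cross-validation schemes and comparator models.

# PCA via the n x n cross-product SVD (p >> n); all non-null components.
pca_scores <- function(expr) {
  mu <- colMeans(expr)
  Xc <- sweep(expr, 2, mu)
  eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
  pos_ev <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(pos_ev)) abort("expression matrix has no variance")
  d <- sqrt(eg$values[pos_ev])
  U <- eg$vectors[, pos_ev, drop = FALSE]
  P <- crossprod(Xc, U) %*% diag(1 / d, length(d))  # probes x components
  Z <- U %*% diag(d, length(d))                     # component scores
  list(P = P, Z = Z, center = mu, d = d)
}

#' Fit the LASSO-PCR axis model
#'
#' Principal-component regression of axis position on expression: expression
#' is decomposed by SVD retaining all non-null components, component scores
#' enter an L1-penalized (LASSO) regression with the penalty chosen by inner
#' cross-validation, and the component coefficients A are back-transformed
#' to per-probe betas B = P A. The intercept is unpenalized and stored
#' separately, so predictions can be formed equivalently in component space
#' (Z A + a0) or probe space (X B + intercept).
#'
#' @param expr Samples x probes matrix of prepared (donor-adjusted,
#'   standardized) expression.
#' @param positions Axis position in mm per sample.
#' @param inner_folds Folds of the inner cross-validation selecting the
#'   LASSO penalty.
#' @param seed Seed for the inner fold assignment.
#' @return An object of class `axis_model` with elements `betas` (named
#'   per-probe weights, mm per expression unit), `intercept` (mm), `basis`
#'   P, `coefficients` A, `lambda` and training metadata.
#' @export
fit_lasso_pcr <- function(expr, positions, inner_folds = 5, seed = 1) {
  expr <- check_expression(expr)
  if (length(positions) != nrow(expr)) {
    abort("`positions` must have one value per sample")
  }
  if (anyNA(positions) || any(!is.finite(positions))) {
    abort("`positions` must be finite")
  }
  if (nrow(expr) < 10) abort("need at least 10 samples")
  if (sd(positions) == 0) abort("`positions` are constant")
  if (all(expr == 0)) abort("expression matrix is all zero")

  pca <- pca_scores(expr)
  P <- pca$P
  Z <- pca$Z
  mu <- pca$center

  # fold assignment keyed to sample names where available, so the fitted
  # betas are invariant to sample order
  foldid <- make_folds(nrow(expr), inner_folds, seed)
  if (!is.null(rownames(expr)) && !anyDuplicated(rownames(expr))) {
    foldid[order(rownames(expr))] <- foldid
  }
  cv <- glmnet::cv.glmnet(Z, positions, alpha = 1, foldid = foldid,
                          standardize = FALSE)
  cf <- as.numeric(coef(cv, s = "lambda.min"))
  a0 <- cf[1]
  A <- cf[-1]
  B <- drop(P %*% A)
  names(B) <- colnames(expr)

  structure(list(
    betas = B,
    intercept = a0 - sum(mu * B),
    a0 = a0,
    coefficients = A,
    basis = P,
    center = mu,
    lambda = cv$lambda.min,
    probe_ids = colnames(expr),
    n_samples = nrow(expr),
    n_components = length(pca$d),
    seed = seed
  ), class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat("<axis_model> ", x$n_samples, " samples, ", length(x$betas),
      " probes, ", x$n_components, " components, ",
      sum(x$coefficients != 0), " active (lambda = ",
      signif(x$lambda, 3), ")\n", sep = "")
  invisible(x)
}

#' Predict axis positions from expression
#'
#' @param object An `axis_model`.
#' @param newdata Samples x probes matrix containing the training probes.
#' @param ... Unused.
#' @return Numeric vector of predicted positions (mm).
#' @export
predict.axis_model <- function(object, newdata, ...) {
  if (!all(object$probe_ids %in% colnames(newdata))) {
    abort("`newdata` must contain all training probes")
  }
  drop(newdata[, object$probe_ids, drop = FALSE] %*% object$betas) +
    object$intercept
}

#' @rdname fit_lasso_pcr
#' @param x An `axis_model`.
#' @param ... Unused.
#' @export
tidy.axis_model <- function(x, ...) {
  tibble(probe_id = names(x$betas), beta = unname(x$betas)) |>
    arrange(dplyr::desc(abs(.data$beta))) |>
    mutate(rank = row_number())
}

#' @rdname fit_lasso_pcr
#' @export
glance.axis_model <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_probes = length(x$betas),
         n_components = x$n_components,
         n_active = sum(x$coefficients != 0),
         lambda = x$lambda, intercept = x$intercept)
}

#' Cross-validate an axis model
#'
#' Supports repeated k-fold cross-validation (each repeat predicts every
#' sample exactly once; r-squared is the variance explained of the pooled
#' out-of-fold predictions, averaged over repeats) and leave-one-group-out
#' schemes (one result per held-out donor or subfield).
#'
#' @param expr,positions As in [fit_lasso_pcr()].
#' @param scheme `"repeated_kfold"` or `"leave_one_group_out"`.
#' @param k,repeats Fold count and repeat count for the k-fold scheme.
#' @param groups Group label per sample for the group scheme.
#' @param fit_fun Model-fitting function `(expr, positions, seed)`; its
#'   return value must have a `predict(object, newdata)` method. `NULL`
#'   (default) cross-validates the LASSO-PCR model.
#' @param pca_scope With the default LASSO-PCR model, whether the PCA basis
#'   is computed once on the full dataset (`"full"`, the method's own
#'   definition: the reduction never sees the outcome, so held-out
#'   positions cannot leak) or refit inside every training fold
#'   (`"fold"`).
#' @param folds Optional precomputed fold assignment (overrides `k`; single
#'   repeat).
#' @param seed Seed for fold assignment.
#' @return An object of class `axis_cv`: tibbles `predictions` and
#'   `summary`, plus `r2` / `mae` (means across repeats or groups).
#' @export
cross_validate <- function(expr, positions,
                           scheme = c("repeated_kfold", "leave_one_group_out"),
                           k = 10, repeats = 10, groups = NULL,
                           fit_fun = NULL, pca_scope = c("full", "fold"),
                           folds = NULL, seed = 1) {
  expr <- check_expression(expr)
  scheme <- match.arg(scheme)
  pca_scope <- match.arg(pca_scope)
  n <- nrow(expr)

  # out-of-fold predictions for one fold assignment
  oof <- function(foldid, seed0) {
    p <- rep(NA_real_, n)
    if (is.null(fit_fun) && pca_scope == "full") {
      pca <- pca_scores(expr)
      for (f in unique(foldid)) {
        test <- foldid == f
        if (all(test)) {
          p[test] <- mean(positions)
          next
        }
        inner <- make_folds(sum(!test), 5, derive_seed(seed0, f))
        cv <- glmnet::cv.glmnet(pca$Z[!test, , drop = FALSE],
                                positions[!test], alpha = 1,
                                foldid = inner, standardize = FALSE)
        p[test] <- as.vector(predict(cv, pca$Z[test, , drop = FALSE],
                                     s = "lambda.min"))
      }
    } else {
      ff <- fit_fun %||% fit_lasso_pcr
      for (f in unique(foldid)) {
        test <- foldid == f
        fit <- ff(expr[!test, , drop = FALSE], positions[!test],
                  seed = derive_seed(seed0, f))
        p[test] <- predict(fit, expr[test, , drop = FALSE])
      }
    }
    p
  }

  preds <- list()
  if (scheme == "repeated_kfold") {
    if (!is.null(folds)) repeats <- 1
    for (r in seq_len(repeats)) {
      foldid <- folds %||% make_folds(n, k, derive_seed(seed, r))
      p <- oof(foldid, derive_seed(seed, r * 100))
      preds[[r]] <- tibble(repeat_id = r, sample = seq_len(n),
                           fold = foldid, observed = positions, predicted = p)
    }
    predictions <- bind_rows(preds)
    summary <- predictions |>
      group_by(.data$repeat_id) |>
      summarise(r2 = r_squared(.data$observed, .data$predicted),
                mae = mae(.data$observed, .data$predicted), .groups = "drop")
    out <- list(scheme = scheme, predictions = predictions, summary = summary,
                r2 = mean(summary$r2), mae = mean(summary$mae))
  } else {
    if (is.null(groups) || length(groups) != n) {
      abort("`groups` must label every sample")
    }
    gl <- unique(groups)
    p_all <- oof(match(groups, gl), derive_seed(seed, 999))
    rows <- lapply(gl, function(g) {
      test <- groups == g
      tibble(
        group = g, n = sum(test),
        r2 = if (sum(test) >= 2) {
          r_squared(positions[test], p_all[test])
        } else NA_real_,
        mae = mae(positions[test], p_all[test])
      )
    })
    summary <- bind_rows(rows)
    predictions <- tibble(sample = seq_len(n), group = groups,
                          observed = positions, predicted = p_all)
    out <- list(scheme = scheme, predictions = predictions, summary = summary,
                r2 = r_squared(positions, p_all),
                mae = mae(positions, p_all))
  }
  structure(out, class = "axis_cv")
}

#' @export
print.axis_cv <- function(x, ...) {
  cat("<axis_cv> scheme:", x$scheme, " r2:", signif(x$r2, 3),
      " MAE:", signif(x$mae, 3), "mm\n")
  invisible(x)
}

#' @export
glance.axis_cv <- function(x, ...) {
  tibble(scheme = x$scheme, r2 = x$r2, mae = x$mae,
         r2_min = min(x$summary$r2, na.rm = TRUE),
         r2_max = max(x$summary$r2, na.rm = TRUE))
}

#' Compare the LASSO-PCR model with simpler approaches
#'
#' Builds three top-`k_top` feature sets — LASSO-PCR betas, PLSR
#' back-transformed coefficients, and correlation ranking (top `k_top`/2
#' positive plus `k_top`/2 negative correlations with position) — then
#' refits a LASSO and a plain linear model on each set, scoring both by
#' 10-fold cross-validation, and reports pairwise overlap of the sets.
#'
#' @param expr,positions As in [fit_lasso_pcr()].
#' @param k_top Size of each feature set (must be even).
#' @param pls_ncomp Components of the PLSR comparator.
#' @param seed Seed for fold assignment.
#' @return List of class `model_comparison`: `sets` (named list of probe
#'   ids), `accuracy` (tibble of CV r2/MAE per set x model) and `overlap`.
#' @export
benchmark_alternatives <- function(expr, positions, k_top = 100,
                                   pls_ncomp = 5, seed = 1) {
  expr <- check_expression(expr)
  if (k_top %% 2 != 0) abort("`k_top` must be even")
  if (k_top > ncol(expr)) abort("`k_top` exceeds the probe count")

  fit <- fit_lasso_pcr(expr, positions, seed = seed)
  top_lasso <- tidy(fit)$probe_id[seq_len(k_top)]

  pls_fit <- mixOmics::pls(expr, positions, ncomp = pls_ncomp,
                           mode = "regression", scale = FALSE)
  B_pls <- predict(pls_fit, expr)$B.hat[, 1, pls_ncomp]
  top_pls <- names(sort(abs(B_pls), decreasing = TRUE))[seq_len(k_top)]

  r <- as.vector(cor(expr, positions))
  names(r) <- colnames(expr)
  top_corr <- c(names(sort(r, decreasing = TRUE))[seq_len(k_top / 2)],
                names(sort(r))[seq_len(k_top / 2)])

  sets <- list(lasso_pcr = top_lasso, plsr = top_pls, correlation = top_corr)

  cv_subset <- function(probes, model) {
    X <- expr[, probes, drop = FALSE]
    foldid <- make_folds(nrow(X), 10, derive_seed(seed, 7))
    p <- rep(NA_real_, nrow(X))
    for (f in 1:10) {
      test <- foldid == f
      if (model == "lasso") {
        cvfit <- glmnet::cv.glmnet(X[!test, , drop = FALSE], positions[!test],
                                   alpha = 1, nfolds = 5)
        p[test] <- as.vector(predict(cvfit, X[test, , drop = FALSE],
                                     s = "lambda.min"))
      } else {
        df <- data.frame(y = positions[!test], X[!test, , drop = FALSE])
        lmfit <- lm(y ~ ., data = df)
        # rank deficiency is expected when k_top approaches the fold size;
        # the comparator is reported as-is
        p[test] <- suppressWarnings(
          predict(lmfit, data.frame(X[test, , drop = FALSE])))
      }
    }
    tibble(r2 = r_squared(positions, p), mae = mae(positions, p))
  }

  accuracy <- purrr::map_dfr(names(sets), function(s) {
    bind_rows(
      mutate(cv_subset(sets[[s]], "lasso"), feature_set = s, model = "lasso"),
      mutate(cv_subset(sets[[s]], "linear"), feature_set = s, model = "linear")
    )
  }) |>
    select("feature_set", "model", "r2", "mae")

  pairs <- utils::combn(names(sets), 2)
  overlap <- tibble(
    set_a = pairs[1, ], set_b = pairs[2, ],
    overlap = purrr::map2_int(pairs[1, ], pairs[2, ],
                              ~ length(intersect(sets[[.x]], sets[[.y]])))
  )

  structure(list(sets = sets, accuracy = accuracy, overlap = overlap,
                 correlations = r, pls_betas = B_pls),
            class = "model_comparison")
}
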