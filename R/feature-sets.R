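# Iterative model deconstruction into gene sets, set-restricted refits with
# random-probe controls, and a local perturbation-based feature explainer.

#' Iteratively remove the most important probes from the model
#'
#' In targeted mode, the model is refit on the remaining probes at each
#' round, 10-fold cross-validation accuracy is recorded, and the `batch`/2
#' probes with the highest (anterior) and lowest (posterior) back-transformed
#' weights are removed, until no probes remain. Random mode removes
#' uniformly random batches as a control. Within-batch removal ranks follow
#' |beta| at the iteration of removal.
#'
#' @param expr,positions As in [fit_lasso_pcr()].
#' @param batch Probes removed per round (even in targeted mode).
#' @param mode `"targeted"` or `"random"`.
#' @param seed Seed for folds and random batches.
#' @param max_iter Stop after this many rounds (default: run to exhaustion).
#' @param cv_k Folds used when recording accuracy.
#' @return A tibble of class `removal_trace`: one row per round with
#'   `iteration`, `n_remaining`, `cv_r2`, `cv_mae` and a `removed` list
#'   column of probe ids in removal-rank order.
#' @export
iterative_probe_removal <- function(expr, positions, batch = 100,
                                    mode = c("targeted", "random"),
                                    seed = 1, max_iter = Inf, cv_k = 10) {
  expr <- check_expression(expr)
  mode <- match.arg(mode)
  if (batch <= 0) abort("`batch` must be positive")
  if (mode == "targeted" && batch %% 2 != 0) {
    abort("`batch` must be even in targeted mode (half top, half bottom)")
  }
  remaining <- colnames(expr)
  rows <- list()
  it <- 0
  while (length(remaining) > 0 && it < max_iter) {
    it <- it + 1
    X <- expr[, remaining, drop = FALSE]
    can_fit <- length(remaining) >= 2
    cv_r2 <- NA_real_
    cv_mae <- NA_real_
    fit <- NULL
    if (can_fit) {
      fit <- fit_lasso_pcr(X, positions, seed = derive_seed(seed, it))
      # the surviving probe panel is selected by the fitted model itself, so
      # the recorded accuracy refits the PCA inside every training fold; a
      # full-dataset basis would leak the selection (r2 ~0.3 on pure noise)
      cv <- cross_validate(X, positions, scheme = "repeated_kfold", k = cv_k,
                           repeats = 1, pca_scope = "fold",
                           seed = derive_seed(seed, 1000 + it))
      cv_r2 <- cv$r2
      cv_mae <- cv$mae
    }
    nb <- min(batch, length(remaining))
    if (mode == "targeted" && can_fit) {
      b <- fit$betas
      half <- nb %/% 2
      top <- names(sort(b, decreasing = TRUE))[seq_len(half)]
      bottom <- setdiff(names(sort(b)), top)[seq_len(min(half + nb %% 2,
                                                         length(b) - half))]
      removed <- union(top, bottom)
      if (length(removed) < nb) {
        removed <- union(removed, setdiff(remaining, removed)[
          seq_len(nb - length(removed))])
      }
      removed <- removed[order(-abs(b[removed]))]
    } else {
      removed <- withr::with_seed(derive_seed(seed, 2000 + it),
                                  sample(remaining, nb))
    }
    rows[[it]] <- tibble(iteration = it, n_remaining = length(remaining),
                         cv_r2 = cv_r2, cv_mae = cv_mae,
                         removed = list(removed))
    remaining <- setdiff(remaining, removed)
  }
  out <- bind_rows(rows)
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "batch") <- batch
  class(out) <- c("removal_trace", class(out))
  out
}

#' Group probes into gene sets by removal rank
#'
#' Probes removed between inflection points of the removal trace form gene
#' sets: Set i holds removal ranks in (boundary(i-1), boundary(i)]. When
#' `boundary_ranks` is not supplied, a change-point heuristic proposes them
#' (largest drops of a 3-point moving average of the accuracy trace); the
#' heuristic exists to be overridden.
#'
#' @param trace A `removal_trace` (targeted mode).
#' @param boundary_ranks Strictly increasing removal ranks ending each set.
#' @param n_sets Number of boundaries the heuristic should propose.
#' @return Tibble with `probe_id`, `removal_rank`, `set`; boundaries kept
#'   in the `boundaries` attribute.
#' @export
define_gene_sets <- function(trace, boundary_ranks = NULL, n_sets = 3) {
  removed <- unlist(trace$removed)
  n <- length(removed)
  if (is.null(boundary_ranks)) {
    boundary_ranks <- default_boundaries(trace, n_sets)
  }
  if (any(diff(boundary_ranks) <= 0)) {
    abort("`boundary_ranks` must be strictly increasing")
  }
  if (any(boundary_ranks < 1 | boundary_ranks > n)) {
    abort("`boundary_ranks` must lie within [1, n_probes]")
  }
  edges <- c(0, boundary_ranks)
  out <- tibble(
    probe_id = removed[seq_len(max(boundary_ranks))],
    removal_rank = seq_len(max(boundary_ranks)),
    set = paste0("Set", findInterval(seq_len(max(boundary_ranks)) - 1, edges))
  )
  attr(out, "boundaries") <- boundary_ranks
  out
}

default_boundaries <- function(trace, n_sets) {
  r2 <- trace$cv_r2
  batch_sizes <- lengths(trace$removed)
  cum <- cumsum(batch_sizes)
  if (length(r2) < 3) return(cum[seq_len(min(n_sets, length(cum)))])
  sm <- stats::filter(r2, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- r2[is.na(sm)]
  drops <- -diff(sm)
  picks <- order(drops, decreasing = TRUE)[seq_len(min(n_sets, length(drops)))]
  sort(cum[picks])
}

#' Refit the model on individual gene sets with random controls
#'
#' For each gene set (and matching random controls) the LASSO-PCR model is
#' refit restricted to the set's probes on `n_boot` bootstrap resamples of
#' the samples, scoring each replicate by 10-fold cross-validation.
#'
#' @param expr,positions As in [fit_lasso_pcr()].
#' @param sets Named list of probe-id vectors, or the tibble from
#'   [define_gene_sets()].
#' @param n_boot Bootstrap replicates per condition.
#' @param controls Any of `"random_matched"` (random probes of the same
#'   size) and `"random_100_within"` (random 100-probe subsets of the set).
#' @param seed Seed.
#' @return List of class `set_accuracy`: `replicates` (per-replicate r2 and
#'   MAE) and `summary` (mean and 95% CI per condition).
#' @export
evaluate_gene_set_models <- function(expr, positions, sets, n_boot = 10,
                                     controls = c("random_matched",
                                                  "random_100_within"),
                                     seed = 1) {
  expr <- check_expression(expr)
  if (is.data.frame(sets)) {
    sets <- split(sets$probe_id, sets$set)
  }
  if (any(lengths(sets) < 2)) abort("every set needs at least 2 probes")
  controls <- match.arg(controls, several.ok = TRUE)
  all_probes <- colnames(expr)

  run_one <- function(probes, label, kind, rep_id) {
    idx <- withr::with_seed(derive_seed(seed, rep_id * 17 + nchar(label)),
                            sample(nrow(expr), replace = TRUE))
    X <- expr[idx, probes, drop = FALSE]
    y <- positions[idx]
    # duplicates of a bootstrap-resampled sample stay in one fold
    orig_fold <- make_folds(nrow(expr), 10,
                            derive_seed(seed, rep_id * 31 + nchar(label)))
    cv <- cross_validate(X, y, scheme = "repeated_kfold",
                         folds = orig_fold[idx],
                         seed = derive_seed(seed, rep_id * 31 + nchar(label)))
    tibble(set = label, kind = kind, replicate = rep_id,
           n_probes = length(probes), r2 = cv$r2, mae = cv$mae)
  }

  rows <- list()
  for (s in names(sets)) {
    probes <- sets[[s]]
    for (b in seq_len(n_boot)) {
      rows[[length(rows) + 1]] <- run_one(probes, s, "gene_set", b)
      if ("random_matched" %in% controls) {
        rnd <- withr::with_seed(derive_seed(seed, 5000 + b),
                                sample(all_probes, length(probes)))
        rows[[length(rows) + 1]] <- run_one(rnd, s, "random_matched", b)
      }
      if ("random_100_within" %in% controls && length(probes) > 100) {
        rnd <- withr::with_seed(derive_seed(seed, 6000 + b),
                                sample(probes, 100))
        rows[[length(rows) + 1]] <- run_one(rnd, s, "random_100_within", b)
      }
    }
  }
  replicates <- bind_rows(rows)
  summary <- replicates |>
    group_by(.data$set, .data$kind) |>
    summarise(mean_r2 = mean(.data$r2),
              ci_lo = quantile(.data$r2, 0.025),
              ci_hi = quantile(.data$r2, 0.975),
              mean_mae = mean(.data$mae), .groups = "drop")
  structure(list(replicates = replicates, summary = summary),
            class = "set_accuracy")
}

#' Local perturbation-based feature importance
#'
#' Explains a random-forest position model locally: per cross-validation
#' fold a forest is trained, and for every held-out sample Gaussian
#' perturbations of its probe vector (at the training-set per-probe scale)
#' are scored by the forest, weighted by an exponential proximity kernel,
#' and summarized by a sparse linear surrogate. Mean absolute surrogate
#' coefficients per probe, with standard errors, aggregate the local
#' importances across all held-out samples.
#'
#' @param expr,positions As in [fit_lasso_pcr()].
#' @param probes Probe ids to explain (>= 2).
#' @param n_folds Cross-validation folds (each sample explained once).
#' @param seed Seed.
#' @param n_perturb Perturbations per explained sample.
#' @param num_trees Forest size.
#' @return Tibble with `probe_id`, `importance`, `se`, `n_explained`.
#' @export
explain_local_features <- function(expr, positions, probes = colnames(expr),
                                   n_folds = 10, seed = 1, n_perturb = 200,
                                   num_trees = 300) {
  expr <- check_expression(expr)
  if (length(probes) < 2) abort("need at least 2 probes to explain")
  if (n_folds > nrow(expr)) abort("`n_folds` exceeds the sample count")
  X <- expr[, probes, drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  foldid <- make_folds(n, n_folds, seed)
  kernel_width <- sqrt(p) * 0.75
  imp <- matrix(NA_real_, n, p, dimnames = list(NULL, probes))

  for (f in seq_len(n_folds)) {
    test <- which(foldid == f)
    train <- which(foldid != f)
    df <- data.frame(y = positions[train], X[train, , drop = FALSE])
    rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                         seed = derive_seed(seed, f))
    sds <- apply(X[train, , drop = FALSE], 2, sd)
    sds[sds < 1e-12] <- 1e-12
    for (i in test) {
      pert <- withr::with_seed(derive_seed(seed, i * 131 + f), {
        matrix(rnorm(n_perturb * p, mean = rep(X[i, ], each = n_perturb),
                     sd = rep(sds, each = n_perturb)), n_perturb, p,
               dimnames = list(NULL, probes))
      })
      pred <- predict(rf, data.frame(pert))$predictions
      dists <- sqrt(rowSums(scale(pert, center = X[i, ], scale = sds)^2))
      w <- exp(-dists^2 / kernel_width^2)
      co <- tryCatch({
        cvfit <- glmnet::cv.glmnet(pert, pred, weights = w, alpha = 1,
                                   nfolds = 5)
        as.numeric(coef(cvfit, s = "lambda.1se"))[-1]
      }, error = function(e) rep(0, p))
      imp[i, ] <- abs(co)
    }
  }
  tibble(
    probe_id = probes,
    importance = colMeans(imp),
    se = apply(imp, 2, sd) / sqrt(n),
    n_explained = n
  )
}
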