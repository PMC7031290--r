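# Orchestration: a single-command reproduction of the full synthetic
# analysis with a deterministic manifest.

PIPELINE_DEPS <- list(
  simulate = character(),
  prep = "simulate",
  axis = "simulate",
  model = c("prep", "axis"),
  haggis = "model",
  associate = c("haggis", "simulate")
)

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on data from the
#' synthetic generator: `simulate` (volume, adult + external expression,
#' brain maps), `prep` (donor regression, hippocampal selection), `axis`
#' (skeletonization, position assignment), `model` (LASSO-PCR fit and
#' cross-validation), `haggis` (signature scores, external transfer, split
#' scan) and `associate` (difference map, cube sampling, permutation
#' correlation, topic scoring). Rerunning with the same configuration
#' reproduces all numeric outputs exactly; the manifest records seeds and
#' content hashes per stage.
#'
#' @param config A [synth_config()].
#' @param stages Stages to run; upstream requirements must be included.
#' @param out_dir Optional directory for on-disk outputs (CSV/JSON/NIfTI).
#' @param cv_repeats Repeats of the 10-fold cross-validation.
#' @param n_perm Permutations for the association test.
#' @return List of class `pipeline_run`: `manifest` and `results`.
#' @export
run_pipeline <- function(config, stages = names(PIPELINE_DEPS),
                         out_dir = NULL, cv_repeats = 10, n_perm = 1000) {
  stopifnot(inherits(config, "synth_config"))
  stages <- match.arg(stages, names(PIPELINE_DEPS), several.ok = TRUE)
  for (s in stages) {
    missing <- setdiff(PIPELINE_DEPS[[s]], stages)
    if (length(missing) > 0) {
      abort(sprintf("stage '%s' requires upstream stage(s): %s",
                    s, paste(missing, collapse = ", ")))
    }
  }
  stages <- names(PIPELINE_DEPS)[names(PIPELINE_DEPS) %in% stages]
  res <- list()
  manifest <- list(
    package = "longaxis",
    version = as.character(utils::packageVersion("longaxis")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list()
  )

  for (s in stages) {
    out <- switch(s,
      simulate = stage_simulate(config),
      prep = stage_prep(config, res),
      axis = stage_axis(config, res),
      model = stage_model(config, res, cv_repeats),
      haggis = stage_haggis(config, res),
      associate = stage_associate(config, res, n_perm)
    )
    res[[s]] <- out
    manifest$stages[[s]] <- list(hash = rlang::hash(out$hashable))
  }

  if (!is.null(out_dir)) write_pipeline_outputs(res, manifest, out_dir)
  structure(list(manifest = manifest, results = res),
            class = "pipeline_run")
}

stage_simulate <- function(config) {
  adult <- make_expression_dataset(config, "adult")
  external <- make_expression_dataset(config, "external")
  volume <- adult$ground_truth$volume
  brain <- dplyr::filter(adult$samples, .data$kind == "brain")
  maps <- make_brain_maps(
    config, brain,
    signature = adult$ground_truth$true_latent[brain$sample_id],
    hipp_samples = dplyr::filter(adult$samples, .data$kind == "hippocampus"),
    hipp_latent = adult$ground_truth$true_latent[
      adult$samples$sample_id[adult$samples$kind == "hippocampus"]]
  )
  list(adult = adult, external = external, volume = volume, maps = maps,
       hashable = list(adult$expression, adult$samples, external$expression))
}

stage_prep <- function(config, res) {
  adult <- res$simulate$adult
  expr <- regress_donor_effects(adult$expression, adult$samples$donor)
  hip_labels <- c("CA1 field", "CA2 field", "CA3 field", "CA4 field",
                  "Dentate Gyrus", "Subiculum")
  hip <- select_hippocampal_samples(adult$samples, hip_labels,
                                    res$simulate$volume)
  list(expression = expr, hippocampal = hip,
       hashable = list(dim(expr), sum(expr), hip$sample_id))
}

stage_axis <- function(config, res) {
  skeleton <- skeletonize_volume(res$simulate$volume)
  samples <- assign_axis_positions(res$simulate$adult$samples, skeleton,
                                   res$simulate$volume)
  list(skeleton = skeleton, samples = samples,
       hashable = list(nrow(skeleton), samples$position))
}

stage_model <- function(config, res, cv_repeats) {
  hip_ids <- res$prep$hippocampal$sample_id
  pos <- res$axis$samples$position[match(hip_ids,
                                         res$axis$samples$sample_id)]
  keep <- !is.na(pos)
  hip_ids <- hip_ids[keep]
  pos <- pos[keep]
  X <- res$prep$expression[hip_ids, , drop = FALSE]
  fit <- fit_lasso_pcr(X, pos, seed = derive_seed(config$seed, 41))
  cv <- cross_validate(X, pos, scheme = "repeated_kfold", k = 10,
                       repeats = cv_repeats,
                       seed = derive_seed(config$seed, 42))
  list(fit = fit, cv = cv, hip_ids = hip_ids, positions = pos,
       hashable = list(fit$betas, cv$summary))
}

stage_haggis <- function(config, res) {
  all_scores <- compute_haggis(res$model$fit, res$prep$expression)
  hip_scores <- all_scores[match(res$model$hip_ids, all_scores$sample_id), ]
  ext <- res$simulate$external
  ext_expr <- regress_donor_effects(ext$expression, ext$samples$donor)
  transfer <- transfer_to_external(res$model$fit, ext_expr,
                                   ext$samples$class)
  splits <- scan_axis_splits(hip_scores$haggis, res$model$positions,
                             res$axis$skeleton)
  list(scores = all_scores, hip_scores = hip_scores, transfer = transfer,
       splits = splits,
       hashable = list(all_scores$haggis, transfer$auc,
                       splits$anterior_cut, splits$posterior_cut))
}

stage_associate <- function(config, res, n_perm) {
  maps <- res$simulate$maps
  brain <- dplyr::filter(res$axis$samples, .data$kind == "brain")
  brain_scores <- res$haggis$scores$haggis[
    match(brain$sample_id, res$haggis$scores$sample_id)]
  mv <- sample_map_values(maps$disease_map, brain, cube_edge_mm = 5,
                          mask = maps$masks$no_brainstem_cerebellum)
  perm <- correlate_with_permutation(brain_scores, mv, n_perm = n_perm,
                                     seed = derive_seed(config$seed, 51))
  asg <- res$haggis$splits$assignment
  hipids <- res$model$hip_ids
  fc_diff <- build_difference_map(maps$fc,
                                  anterior_ids = hipids[asg == "anterior"],
                                  posterior_ids = hipids[asg == "posterior"],
                                  kind = "fc")
  fc_vals <- sample_map_values(fc_diff, brain, cube_edge_mm = 5,
                               mask = maps$masks$no_brainstem_cerebellum)
  fc_perm <- correlate_with_permutation(brain_scores, fc_vals,
                                        n_perm = n_perm,
                                        seed = derive_seed(config$seed, 52))
  topics <- score_topic_maps(brain_scores, brain, maps$topic_masks,
                             min_samples = 500)
  list(disease_perm = perm, fc_perm = fc_perm, topics = topics,
       map_values = mv,
       hashable = list(perm$r2, perm$p, fc_perm$r2, topics))
}

write_pipeline_outputs <- function(res, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$simulate)) {
    utils::write.csv(res$simulate$adult$samples,
                     file.path(out_dir, "samples.csv"), row.names = FALSE)
    write_volume(res$simulate$volume, file.path(out_dir, "hippocampus.nii.gz"))
  }
  if (!is.null(res$axis)) {
    utils::write.csv(res$axis$skeleton, file.path(out_dir, "skeleton.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$model)) {
    utils::write.csv(tidy(res$model$fit), file.path(out_dir, "betas.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$haggis)) {
    utils::write.csv(res$haggis$scores, file.path(out_dir, "haggis.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages:", paste(names(x$manifest$stages),
                                      collapse = ", "), "\n")
  invisible(x)
}
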