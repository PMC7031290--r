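# Shared fixtures, built once per test run.

hip_labels <- c("CA1 field", "CA2 field", "CA3 field", "CA4 field",
                "Dentate Gyrus", "Subiculum")

# Small end-to-end fixture: 60 hippocampal + 6 outlier + 120 brain samples,
# 300 probes (40 planted), through skeleton, positions and donor removal.
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 11, n_samples = 60, n_outliers = 6,
                          n_brain_samples = 120, n_probes = 300,
                          n_planted = 40, n_subjects_sc = 25,
                          topic_mask_sizes = c(100L, 60L, 30L),
                          n_external = 40)
      ds <- make_expression_dataset(cfg, "adult")
      vol <- ds$ground_truth$volume
      sk <- skeletonize_volume(vol)
      samples <- assign_axis_positions(ds$samples, sk, vol)
      expr <- regress_donor_effects(ds$expression, ds$samples$donor)
      sel <- select_hippocampal_samples(samples, hip_labels, vol)
      cache <<- list(
        cfg = cfg, ds = ds, vol = vol, skeleton = sk, samples = samples,
        expr = expr, sel = sel,
        X = expr[sel$sample_id, , drop = FALSE],
        y = sel$position,
        gt = ds$ground_truth
      )
    }
    cache
  }
})

# Fitted LASSO-PCR model on the small fixture.
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- small_fixture()
      cache <<- fit_lasso_pcr(fx$X, fx$y, seed = 21)
    }
    cache
  }
})

# Distance from each point (rows of `pts`) to the nearest point of `ref`.
nearest_dist <- function(pts, ref) {
  pts <- as.matrix(pts)
  ref <- as.matrix(ref)
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
  sqrt(pmax(apply(d2, 1, min), 0))
}

# Controlled two-family pattern matrix (linear ramps vs steps) for
# clustering-recovery tests.
two_family_patterns <- function(seed = 2, n = 120, per_family = 15,
                                noise = 0.1) {
  withr::with_seed(seed, {
    pos <- sort(runif(n, 80, 120))
    t <- (pos - 80) / 40
    lin <- sapply(seq_len(per_family),
                  function(i) t * runif(1, 0.8, 1.2) + rnorm(n, 0, noise))
    stp <- sapply(seq_len(per_family),
                  function(i) as.numeric(t > runif(1, 0.45, 0.55)) +
                    rnorm(n, 0, noise))
    X <- cbind(lin, stp)
    colnames(X) <- paste0("p", seq_len(ncol(X)))
    list(X = X, positions = pos,
         truth = rep(1:2, each = per_family))
  })
}
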