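# Synthetic data generator.
#
# Emulates the statistical structure of the study inputs: bulk microarray
# expression with planted anterior-posterior gradient probes (linear, step,
# sigmoid, unimodal) plus additive per-donor offsets and Gaussian noise; a
# curved hippocampus-like labeled volume with an analytic centerline; brain
# samples scattered on a voxel grid with maps whose coupling to a planted
# signature is configurable; and an external rostral/caudal-labeled dataset
# sharing the adult probe panel. Every output is a deterministic function of
# the configuration seed.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the desk-scale stand-in for the study inputs: 170 hippocampal
#' samples (plus 18 candidates placed more than 3 mm outside the volume) and
#' 600 brain samples across 2,000 probes, of which 100 carry planted axis
#' patterns, with 3 donors carrying additive offsets.
#'
#' @param seed Integer master seed; fully determines all outputs.
#' @param n_samples Hippocampal samples inside the volume.
#' @param n_outliers Hippocampal-labeled candidates placed > 3 mm outside the
#'   volume (exercise the exclusion rule).
#' @param n_brain_samples Non-hippocampal brain samples.
#' @param n_probes Total probes.
#' @param n_planted Probes carrying a planted axis pattern.
#' @param pattern_mix Proportions of planted probes following linear, step,
#'   sigmoid and unimodal patterns; must sum to 1. All remaining probes are
#'   pure noise.
#' @param noise_sd Gaussian noise sd (expression units) on planted probes;
#'   patterns are scaled to unit variance along the axis.
#' @param donor_offsets Additive per-donor expression shifts; length gives
#'   the donor count.
#' @param axis_length_mm Arc length of the hippocampal centerline, mm.
#' @param arc_deg Total turning angle of the circular-arc centerline
#'   (0 = straight tube). The arc lies in the x-y plane and is monotone in y.
#' @param tube_radius_mm Tube radius, mm.
#' @param origin_mm World coordinates (mm) of the centerline midpoint.
#' @param brain_box_mm,brain_vox_mm Edge length and voxel size of the brain
#'   sampling grid (centered on `origin_mm`).
#' @param map_coupling_rho Correlation in \[-1, 1\] between the planted
#'   signature and values of generated voxel maps at brain-sample locations.
#' @param fc_noise_sd,sc_noise_sd Voxel noise for per-sample connectivity
#'   maps and subject gray-matter volumes (relative to planted field sd).
#' @param n_subjects_sc Subject count for structural-covariance volumes.
#' @param topic_mask_sizes Sample-overlap counts for generated topic masks.
#' @param n_external External (prenatal-like) sample count.
#' @param external_separation Class separation in \[0, 1\] of rostral vs
#'   caudal axis positions in the external set (0 = identical distributions).
#' @param n_donors_external Donor count in the external set.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_samples = 170L,
                         n_outliers = 18L,
                         n_brain_samples = 600L,
                         n_probes = 2000L,
                         n_planted = 100L,
                         pattern_mix = c(linear = 0.5, step = 0.2,
                                         sigmoid = 0.15, unimodal = 0.15),
                         noise_sd = 0.3,
                         donor_offsets = c(-2, 0, 2),
                         axis_length_mm = 40,
                         arc_deg = 60,
                         tube_radius_mm = 4,
                         origin_mm = c(0, 100, 0),
                         brain_box_mm = 64,
                         brain_vox_mm = 2,
                         map_coupling_rho = 0.6,
                         fc_noise_sd = 0.2,
                         sc_noise_sd = 0.3,
                         n_subjects_sc = 60L,
                         topic_mask_sizes = c(520L, 510L, 505L, 499L, 450L, 300L),
                         n_external = 53L,
                         external_separation = 0.8,
                         n_donors_external = 4L) {
  cfg <- as.list(environment())
  if (abs(sum(pattern_mix) - 1) > 1e-8) abort("`pattern_mix` must sum to 1")
  if (!all(names(pattern_mix) %in% c("linear", "step", "sigmoid", "unimodal"))) {
    abort("`pattern_mix` names must be linear/step/sigmoid/unimodal")
  }
  if (n_planted > n_probes) abort("`n_planted` must not exceed `n_probes`")
  if (n_planted == 0 && any(pattern_mix > 0)) {
    abort("`pattern_mix` requires planted probes but `n_planted` is 0")
  }
  if (abs(map_coupling_rho) > 1) abort("`map_coupling_rho` must lie in [-1, 1]")
  if (external_separation < 0 || external_separation > 1) {
    abort("`external_separation` must lie in [0, 1]")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  structure(cfg, class = "synth_config")
}

# ---- centerline & volume ---------------------------------------------------

# Analytic centerline: circular arc of given length and turning angle in the
# x-y plane, monotone in y, centered on origin_mm. Returns mm coordinates,
# unit tangents and normalized arc position.
axis_centerline <- function(config, n_points = 601) {
  L <- config$axis_length_mm
  t <- seq(0, 1, length.out = n_points)
  if (config$arc_deg <= 1e-8) {
    pts <- cbind(0, (t - 0.5) * L, 0)
    tan <- matrix(rep(c(0, 1, 0), each = n_points), ncol = 3)
  } else {
    theta <- config$arc_deg * pi / 180
    R <- L / theta
    phi <- (t - 0.5) * theta
    pts <- cbind(R * cos(phi), R * sin(phi), 0)
    pts[, 1] <- pts[, 1] - mean(range(pts[, 1]))
    tan <- cbind(-sin(phi), cos(phi), 0)
  }
  pts <- sweep(pts, 2, config$origin_mm, "+")
  list(points = pts, tangents = tan, arc = t)
}

#' Generate a curved hippocampus-like labeled volume
#'
#' Builds a binary tube of the configured radius around a circular-arc
#' centerline (1 mm isotropic voxels). The analytic centerline is attached
#' as an attribute so skeleton extraction can be checked against an oracle.
#'
#' @param config A [synth_config()].
#' @return A [brain_volume()] with attributes `centerline` (n x 3 mm
#'   coordinates ordered posterior to anterior) and `arc` (normalized
#'   position along it).
#' @export
make_hippocampus_volume <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$axis_length_mm < 10) {
    abort("degenerate axis: `axis_length_mm` must be >= 10 mm")
  }
  cl <- axis_centerline(config)
  margin <- config$tube_radius_mm + 3
  lo <- floor(apply(cl$points, 2, min) - margin)
  hi <- ceiling(apply(cl$points, 2, max) + margin)
  dims <- as.integer(hi - lo + 1)
  affine <- diag(4)
  affine[1:3, 4] <- lo
  arr <- array(0, dims)
  vol <- brain_volume(arr, affine)
  # rasterize the centerline, then threshold its distance transform
  idx <- round(world_to_voxel(vol, cl$points))
  arr[unique(idx[, 1] + (idx[, 2] - 1) * dims[1] +
                (idx[, 3] - 1) * dims[1] * dims[2])] <- 1
  vol$data <- arr
  d <- distance_to_mask(vol)
  mask <- array(as.numeric(d$data <= config$tube_radius_mm), dims)
  out <- brain_volume(mask, affine)
  attr(out, "centerline") <- cl$points
  attr(out, "tangents") <- cl$tangents
  attr(out, "arc") <- cl$arc
  out
}

# ---- planted expression patterns -------------------------------------------

# Pattern generators on t in [0,1], each normalized to zero mean and unit
# variance under t ~ U(0,1) so noise_sd is interpretable as 1/SNR.
pattern_value <- function(type, t, param) {
  switch(type,
    linear = (t - 0.5) * sqrt(12),
    step = (as.numeric(t > param) - (1 - param)) / sqrt(param * (1 - param)),
    sigmoid = {
      f <- function(x) 1 / (1 + exp(-10 * (x - param)))
      g <- f(seq(0, 1, length.out = 2001))
      (f(t) - mean(g)) / pop_sd(g)
    },
    unimodal = {
      f <- function(x) exp(-(x - param)^2 / (2 * 0.15^2))
      g <- f(seq(0, 1, length.out = 2001))
      (f(t) - mean(g)) / pop_sd(g)
    },
    noise = rep(0, length(t))
  )
}

# Deterministic probe panel shared by the adult and external datasets.
make_probe_spec <- function(config) {
  withr::with_seed(derive_seed(config$seed, 10), {
    n <- config$n_probes
    npl <- config$n_planted
    counts <- round(config$pattern_mix * npl)
    # fix rounding drift onto the largest class
    counts[which.max(counts)] <- counts[which.max(counts)] + npl - sum(counts)
    types <- c(rep(names(counts), counts), rep("noise", n - npl))
    tibble(
      probe_id = sprintf("probe_%04d", seq_len(n)),
      pattern = types,
      sign = sample(c(-1, 1), n, replace = TRUE),
      param = runif(n, 0.3, 0.7)
    )
  })
}

expression_from_positions <- function(spec, t, donor_idx, config) {
  n <- length(t)
  offsets <- config$donor_offsets
  if (length(offsets) < max(donor_idx)) {
    offsets <- rep_len(offsets, max(donor_idx))
  }
  X <- matrix(rnorm(n * nrow(spec)), n, nrow(spec))
  planted <- spec$pattern != "noise"
  for (j in which(planted)) {
    X[, j] <- spec$sign[j] * pattern_value(spec$pattern[j], t, spec$param[j]) +
      rnorm(n, 0, config$noise_sd)
  }
  X <- X + offsets[donor_idx]
  colnames(X) <- spec$probe_id
  X
}

balanced_assign <- function(labels, n) sample(rep_len(labels, n))

# ---- expression datasets ---------------------------------------------------

#' Generate a synthetic expression dataset with known ground truth
#'
#' `mode = "adult"` yields hippocampal candidates placed along the tube
#' (including candidates beyond the 3 mm exclusion distance) together with
#' brain-wide samples on the brain grid, mimicking an atlas-style dataset.
#' `mode = "external"` yields a rostral/caudal-labeled dataset on the same
#' probe panel, emulating transfer to a prenatal atlas.
#'
#' @param config A [synth_config()].
#' @param mode `"adult"` or `"external"`.
#' @param draw_seed Optional seed for the sampling stream only; the planted
#'   probe panel (patterns, signs, parameters) stays tied to `config$seed`,
#'   so repeated draws share one panel — e.g. independent external cohorts
#'   measured on the adult platform.
#' @return A list with `samples` (tibble of metadata), `expression`
#'   (samples x probes matrix of raw values) and `ground_truth` (planted
#'   probe spec, true positions/latents, map coupling).
#' @export
make_expression_dataset <- function(config, mode = c("adult", "external"),
                                    draw_seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  spec <- make_probe_spec(config)
  draw_seed <- draw_seed %||% config$seed
  if (mode == "adult") make_adult_dataset(config, spec, draw_seed)
  else make_external_dataset(config, spec, draw_seed)
}

make_adult_dataset <- function(config, spec, draw_seed = config$seed) {
  vol <- make_hippocampus_volume(config)
  cl <- attr(vol, "centerline")
  tg <- attr(vol, "tangents")
  npts <- nrow(cl)
  subfields <- c("CA1 field", "CA2 field", "CA3 field", "CA4 field",
                 "Dentate Gyrus", "Subiculum")
  regions <- c("cortex", "subcortex", "brainstem", "cerebellum")
  withr::with_seed(derive_seed(draw_seed, 1), {
    n_hip <- config$n_samples
    n_out <- config$n_outliers
    n_brain <- config$n_brain_samples

    place <- function(t, radial_mm) {
      if (length(t) == 0) return(matrix(numeric(), 0, 3))
      i <- pmin(pmax(round(t * (npts - 1)) + 1, 1), npts)
      base <- cl[i, , drop = FALSE]
      tang <- tg[i, , drop = FALSE]
      # orthonormal frame perpendicular to the local tangent
      n1 <- cbind(-tang[, 2], tang[, 1], 0)
      n1 <- n1 / sqrt(rowSums(n1^2))
      n2 <- matrix(c(0, 0, 1), length(t), 3, byrow = TRUE)
      phi <- runif(length(t), 0, 2 * pi)
      base + radial_mm * (cos(phi) * n1 + sin(phi) * n2)
    }

    t_hip <- runif(n_hip)
    xyz_hip <- place(t_hip, (config$tube_radius_mm - 1.5) *
                       runif(n_hip)^(1 / 2))
    t_out <- runif(n_out)
    xyz_out <- place(t_out, config$tube_radius_mm + runif(n_out, 4.2, 6))

    # brain samples sit on distinct voxel centers of the brain grid
    grid <- brain_grid(config)
    gd <- dim(grid$data)
    if (n_brain > 0) {
      vox <- sample(prod(gd), n_brain)
      xyz_brain <- voxel_to_world(grid, arrayInd(vox, gd))
    } else {
      xyz_brain <- matrix(numeric(), 0, 3)
    }
    t_brain <- runif(n_brain)

    n_total <- n_hip + n_out + n_brain
    donors <- balanced_assign(seq_along(config$donor_offsets), n_total)
    samples <- tibble(
      sample_id = sprintf("S%04d", seq_len(n_total)),
      donor = paste0("donor_", donors),
      structure = c(balanced_assign(subfields, n_hip + n_out),
                    sample(regions, n_brain, replace = TRUE,
                           prob = c(0.7, 0.15, 0.075, 0.075))),
      kind = rep(c("hippocampus", "hippocampus", "brain"),
                 c(n_hip, n_out, n_brain)),
      x = c(xyz_hip[, 1], xyz_out[, 1], xyz_brain[, 1]),
      y = c(xyz_hip[, 2], xyz_out[, 2], xyz_brain[, 2]),
      z = c(xyz_hip[, 3], xyz_out[, 3], xyz_brain[, 3]),
      true_latent = c(t_hip, t_out, t_brain),
      true_position_mm = c(cl[pmin(pmax(round(t_hip * (npts - 1)) + 1, 1), npts), 2],
                           cl[pmin(pmax(round(t_out * (npts - 1)) + 1, 1), npts), 2],
                           rep(NA_real_, n_brain))
    )
    expr <- expression_from_positions(spec, samples$true_latent, donors, config)
    rownames(expr) <- samples$sample_id
    list(
      samples = samples,
      expression = expr,
      ground_truth = list(
        probes = spec,
        planted_probe_ids = spec$probe_id[spec$pattern != "noise"],
        true_positions = setNames(samples$true_position_mm, samples$sample_id),
        true_latent = setNames(samples$true_latent, samples$sample_id),
        map_coupling_rho = config$map_coupling_rho,
        volume = vol
      )
    )
  })
}

make_external_dataset <- function(config, spec, draw_seed = config$seed) {
  withr::with_seed(derive_seed(draw_seed, 2), {
    n <- config$n_external
    lab <- balanced_assign(c("rostral", "caudal"), n)
    sep <- config$external_separation
    slack <- (1 - sep) / 2
    t <- ifelse(lab == "rostral",
                runif(n, 0.5 - slack, 1),
                runif(n, 0, 0.5 + slack))
    donors <- balanced_assign(seq_len(config$n_donors_external), n)
    samples <- tibble(
      sample_id = sprintf("E%04d", seq_len(n)),
      donor = paste0("ext_donor_", donors),
      structure = "hippocampus",
      class = lab,
      true_latent = t
    )
    expr <- expression_from_positions(spec, t, donors, config)
    rownames(expr) <- samples$sample_id
    list(
      samples = samples,
      expression = expr,
      ground_truth = list(probes = spec,
                          planted_probe_ids = spec$probe_id[spec$pattern != "noise"],
                          true_latent = setNames(t, samples$sample_id))
    )
  })
}

brain_grid <- function(config) {
  nvox <- as.integer(round(config$brain_box_mm / config$brain_vox_mm))
  affine <- diag(c(rep(config$brain_vox_mm, 3), 1))
  affine[1:3, 4] <- config$origin_mm - config$brain_box_mm / 2 +
    config$brain_vox_mm / 2
  brain_volume(array(0, rep(nvox, 3)), affine)
}

# ---- voxel maps ------------------------------------------------------------

#' Generate brain maps coupled to a signature
#'
#' Produces every voxel-map input of the association analyses: a disease-like
#' contrast map whose values at brain-sample locations correlate with
#' `signature` at strength `map_coupling_rho`; per-hippocampal-sample
#' connectivity maps moving along the axis latent (for difference maps and
#' diffusion embedding); subject gray-matter volumes embedding a covariance
#' axis that tracks the signature; binary topic masks with configured sample
#' overlaps; and region masks.
#'
#' @param config A [synth_config()].
#' @param brain_samples Tibble of brain samples (needs `sample_id`, `x`,
#'   `y`, `z`, `structure`), normally the `kind == "brain"` rows of
#'   [make_expression_dataset()].
#' @param signature Numeric score per brain sample (e.g. its HAGGIS or the
#'   planted latent).
#' @param hipp_samples,hipp_latent Optional hippocampal sample tibble and
#'   axis latent in \[0, 1\] used to build per-sample connectivity maps and
#'   to seed structural-covariance volumes.
#' @return A list of class `synth_brain_maps`; see Details in the vignette.
#' @export
make_brain_maps <- function(config, brain_samples, signature,
                            hipp_samples = NULL, hipp_latent = NULL) {
  stopifnot(inherits(config, "synth_config"))
  rho <- config$map_coupling_rho
  if (abs(rho) > 1) abort("`map_coupling_rho` must lie in [-1, 1]")
  n <- nrow(brain_samples)
  if (length(signature) != n) {
    abort("`signature` must have one value per brain sample")
  }
  grid <- brain_grid(config)
  gd <- dim(grid$data)
  nvox <- prod(gd)
  coords <- as.matrix(brain_samples[, c("x", "y", "z")])

  withr::with_seed(derive_seed(config$seed, 3), {
    # coupled target values at sample locations
    zs <- (signature - mean(signature)) / pop_sd(signature)
    e <- rnorm(n)
    e <- (e - mean(e)) / pop_sd(e)
    v <- rho * zs + sqrt(1 - rho^2) * e

    near <- nearest_sample_index(grid, coords)
    field <- array(v[near], gd)
    sample_vox <- world_to_voxel(grid, coords)
    sample_lin <- as.integer(round(sample_vox[, 1]) +
                               (round(sample_vox[, 2]) - 1) * gd[1] +
                               (round(sample_vox[, 3]) - 1) * gd[1] * gd[2])

    disease <- brain_volume(field + array(rnorm(nvox, 0, 0.05), gd),
                            grid$affine)
    planted <- brain_volume(field, grid$affine)

    fc <- NULL
    if (!is.null(hipp_samples)) {
      if (is.null(hipp_latent) || length(hipp_latent) != nrow(hipp_samples)) {
        abort("`hipp_latent` must have one value per hippocampal sample")
      }
      fsd <- pop_sd(as.vector(field))
      w1 <- rnorm(nvox, 0, fsd)
      w2 <- rnorm(nvox, 0, fsd)
      F1 <- -as.vector(field) + w1
      F2 <- as.vector(field) + w2
      a <- pmin(pmax(hipp_latent, 0), 1)
      vals <- outer(cos(pi * a / 2), F1) + outer(sin(pi * a / 2), F2)
      vals <- vals + matrix(rnorm(length(vals), 0, config$fc_noise_sd * fsd),
                            nrow(vals))
      rownames(vals) <- hipp_samples$sample_id
      fc <- list(values = vals, template = grid)
    }

    gm <- NULL
    if (!is.null(hipp_samples)) {
      fsd <- pop_sd(as.vector(field))
      C <- as.vector(field)
      hv <- world_to_voxel(grid, as.matrix(hipp_samples[, c("x", "y", "z")]))
      hl <- as.integer(round(hv[, 1]) + (round(hv[, 2]) - 1) * gd[1] +
                         (round(hv[, 3]) - 1) * gd[1] * gd[2])
      hl_ok <- hl >= 1 & hl <= nvox
      C[hl[hl_ok]] <- (hipp_latent[hl_ok] - 0.5) * 2 * fsd
      b <- rnorm(config$n_subjects_sc)
      gmat <- outer(b, C) +
        matrix(rnorm(config$n_subjects_sc * nvox, 0, config$sc_noise_sd * fsd),
               config$n_subjects_sc)
      gm <- list(values = gmat, template = grid,
                 hipp_voxel = setNames(hl, hipp_samples$sample_id))
    }

    topic_masks <- lapply(config$topic_mask_sizes, function(k) {
      k <- min(k, n)
      pick <- sample(n, k)
      m <- array(0, gd)
      m[sample_lin[pick]] <- 1
      brain_volume(m, grid$affine)
    })
    names(topic_masks) <- paste0("topic_", seq_along(topic_masks))

    region <- brain_samples$structure[near]
    masks <- list(
      whole_brain = brain_volume(array(1, gd), grid$affine),
      no_brainstem_cerebellum = brain_volume(
        array(as.numeric(!region %in% c("brainstem", "cerebellum")), gd),
        grid$affine),
      cortex_only = brain_volume(array(as.numeric(region == "cortex"), gd),
                                 grid$affine)
    )

    structure(list(
      disease_map = disease,
      planted_axis_map = planted,
      coupled_values = setNames(v, brain_samples$sample_id),
      fc = fc,
      gm = gm,
      topic_masks = topic_masks,
      masks = masks,
      template = grid,
      sample_voxel = setNames(sample_lin, brain_samples$sample_id)
    ), class = "synth_brain_maps")
  })
}

# Index of the nearest sample for every voxel center (chunked brute force).
nearest_sample_index <- function(grid, coords) {
  gd <- dim(grid$data)
  ijk <- arrayInd(seq_len(prod(gd)), gd)
  ctr <- voxel_to_world(grid, ijk)
  out <- integer(nrow(ctr))
  chunk <- 4096L
  cs2 <- rowSums(coords^2)
  for (start in seq(1, nrow(ctr), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(ctr))
    d2 <- outer(rowSums(ctr[idx, , drop = FALSE]^2), cs2, "+") -
      2 * ctr[idx, , drop = FALSE] %*% t(coords)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}
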