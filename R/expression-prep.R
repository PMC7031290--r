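# Donor-effect removal and hippocampal sample selection.

#' Remove donor-specific expression patterns
#'
#' For each probe, fits ordinary least squares on dummy-coded donor
#' indicators (equivalently, centers each probe within donor) and returns
#' standardized residuals: mean 0, population sd 1 per probe across all
#' samples. Fit across all samples (brain-wide) before any subsetting.
#'
#' @param expr Samples x probes numeric matrix of raw expression.
#' @param donors Per-sample donor labels (length `nrow(expr)`).
#' @return Matrix of standardized residual expression, same dimnames.
#' @export
regress_donor_effects <- function(expr, donors) {
  expr <- check_expression(expr)
  if (length(donors) != nrow(expr)) {
    abort("`donors` must label every sample")
  }
  if (anyNA(donors)) abort("`donors` must label every sample")
  donors <- as.factor(donors)
  # OLS on donor dummies == within-donor centering of each probe
  means <- rowsum(expr, donors) / as.vector(table(donors))
  resid <- expr - means[donors, , drop = FALSE]
  s <- sqrt(colMeans(resid^2))  # residual mean is 0 per probe
  zero <- s < 1e-12
  if (any(zero)) {
    warn(sprintf("%d probe(s) have zero residual variance; residuals set to 0",
                 sum(zero)))
    s[zero] <- 1
  }
  out <- sweep(resid, 2, s, "/")
  out[, zero] <- 0
  out
}

#' Select hippocampal samples by structure label and volume distance
#'
#' Retains samples whose structure label belongs to `allowed_labels` and
#' which lie within `exclusion_mm` of the labeled volume.
#'
#' @param samples Sample tibble with `structure` and `x`, `y`, `z` columns.
#' @param allowed_labels Character set of hippocampal structure labels.
#' @param volume Labeled [brain_volume()]; `NULL` applies the label filter
#'   only.
#' @param exclusion_mm Maximum distance (mm) outside the volume.
#' @return Filtered sample tibble (with `dist_to_volume` when a volume is
#'   given).
#' @export
select_hippocampal_samples <- function(samples, allowed_labels, volume = NULL,
                                       exclusion_mm = 3) {
  if (!"structure" %in% names(samples)) {
    abort("`samples` must have a `structure` column")
  }
  if (length(allowed_labels) == 0) abort("`allowed_labels` is empty")
  out <- dplyr::filter(samples, .data$structure %in% allowed_labels)
  if (!is.null(volume)) {
    dmap <- distance_to_mask(volume)
    xyz <- as.matrix(out[, c("x", "y", "z")])
    d <- sample_volume_at(dmap, xyz)
    if (anyNA(d)) {
      mp <- volume_points(volume)
      for (i in which(is.na(d))) {
        d[i] <- sqrt(min(colSums((t(mp) - xyz[i, ])^2)))
      }
    }
    out$dist_to_volume <- d
    out <- dplyr::filter(out, .data$dist_to_volume <= exclusion_mm)
  }
  if (nrow(out) == 0) abort("no samples retained")
  out
}
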