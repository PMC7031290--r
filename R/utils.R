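# Internal helpers shared across modules.

# Population (1/n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Variance explained of predictions: 1 - SS_res / SS_tot.
r_squared <- function(observed, predicted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sst
}

mae <- function(observed, predicted) mean(abs(observed - predicted))

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Fold assignment: k roughly equal folds over n samples.
make_folds <- function(n, k, seed) {
  if (k > n) abort("cannot make more folds than samples")
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("`expr` must be a numeric samples x probes matrix")
  }
  if (anyNA(expr)) abort("`expr` contains missing values")
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("probe_", seq_len(ncol(expr)))
  }
  expr
}

# Mean silhouette width for a hard clustering; 0 when all distances collapse.
mean_silhouette <- function(assignment, d) {
  if (length(unique(assignment)) < 2) return(NA_real_)
  sil <- cluster::silhouette(assignment, d)
  w <- sil[, "sil_width"]
  w[!is.finite(w)] <- 0
  mean(w)
}

# Adjusted Rand index between two labelings (used by tests and examples).
#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster labelings of the same
#' items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
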