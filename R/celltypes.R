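# Marker-gene cell-type scoring along the axis.

#' Score marker-defined cell types along the longitudinal axis
#'
#' For each cell type, a PCA is run on the samples x marker-genes matrix;
#' the loadings of each gene on the first component (sign-aligned so the
#' score correlates positively with the plain marker mean) serve as weights
#' in a weighted mean of marker expression, giving one score per sample.
#' Scores are then correlated with axis position (BH-FDR across cell types)
#' and compared across subfields with one-way ANOVA.
#'
#' @param expr Samples x probes matrix (probes named by gene here).
#' @param marker_sets Named list of marker-gene vectors, or a tibble with
#'   `cell_type` and `gene` columns.
#' @param positions Axis position (mm) per sample.
#' @param subfields Subfield label per sample.
#' @param fdr_q FDR level used for the `significant` flag.
#' @return List of class `cell_type_scores`: `table` (one row per cell
#'   type: axis r, p, q, ANOVA F, p, q) and `scores` (samples x cell types).
#' @export
score_cell_types <- function(expr, marker_sets, positions, subfields,
                             fdr_q = 0.1) {
  expr <- check_expression(expr)
  if (is.data.frame(marker_sets)) {
    marker_sets <- split(marker_sets$gene, marker_sets$cell_type)
  }
  subfields <- as.factor(subfields)

  scores <- list()
  rows <- list()
  for (ct in names(marker_sets)) {
    genes <- intersect(unique(marker_sets[[ct]]), colnames(expr))
    if (length(genes) < 2) {
      warn(sprintf("cell type '%s': fewer than 2 marker genes present; skipped",
                   ct))
      next
    }
    M <- expr[, genes, drop = FALSE]
    pc <- prcomp(M, center = TRUE, scale. = FALSE)
    w <- pc$rotation[, 1]
    raw_mean <- rowMeans(M)
    s <- drop(M %*% w)
    if (isTRUE(cor(s, raw_mean) < 0)) w <- -w
    denom <- sum(w)
    if (abs(denom) < 1e-12) denom <- sum(abs(w))
    score <- drop(M %*% w) / denom
    scores[[ct]] <- score

    ct_test <- cor.test(score, positions)
    af <- anova(aov(score ~ subfields))
    rows[[ct]] <- tibble(
      cell_type = ct, n_genes = length(genes),
      r = unname(ct_test$estimate), p = ct_test$p.value,
      f = af$`F value`[1], p_anova = af$`Pr(>F)`[1]
    )
  }
  if (length(rows) == 0) abort("no cell type had >= 2 marker genes present")
  tab <- bind_rows(rows) |>
    mutate(q = p.adjust(.data$p, "BH"),
           q_anova = p.adjust(.data$p_anova, "BH"),
           significant = .data$q < fdr_q) |>
    select("cell_type", "n_genes", "r", "p", "q", "f", "p_anova",
           "q_anova", "significant")
  structure(list(table = tab,
                 scores = do.call(cbind, scores)),
            class = "cell_type_scores")
}

#' @export
print.cell_type_scores <- function(x, ...) {
  cat("<cell_type_scores>", nrow(x$table), "cell types,",
      sum(x$table$significant), "significant axis associations\n")
  invisible(x)
}
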