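#' Quality-control configuration
#'
#' @param n_pcs number of principal components used for the isolation score.
#' @param score_threshold individual-level isolation-score threshold in SD
#'   units (individuals above it are flagged as failed sorts).
#' @param sd_threshold per-PC distance threshold (in SDs of the labelled cell
#'   type) for the sample-retention filter.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(n_pcs = 2L, score_threshold = 5, sd_threshold = 2) {
  if (n_pcs < 1L) stop_config("n_pcs must be at least 1")
  if (score_threshold <= 0 || sd_threshold <= 0)
    stop_config("thresholds must be positive")
  structure(list(n_pcs = as.integer(n_pcs),
                 score_threshold = score_threshold,
                 sd_threshold = sd_threshold),
            class = "qc_config")
}

#' Principal components of a beta matrix
#'
#' PCA of the site-centered beta matrix over all samples (sites are
#' variables, samples are observations; no scaling). Because cell-type
#' identity is the dominant source of variation in DNAm, the leading
#' components cluster samples by cell type. For sign stability, each
#' component is oriented so its largest-magnitude site loading is positive.
#'
#' @param beta beta matrix (sites x samples).
#' @param n_components number of components to retain.
#' @param most_variable optional integer; restrict the PCA to this many most
#'   variable sites (speed option, off by default).
#' @return an object of class `pc_scores`: list with `sample_ids`, `scores`
#'   (samples x components), `explained_variance`.
#' @export
compute_pcs <- function(beta, n_components = 10L, most_variable = NULL) {
  assert_beta_matrix(beta)
  if (ncol(beta) < 2) stop("need at least 2 samples for PCA")
  n_components <- min(n_components, nrow(beta), ncol(beta) - 1L)
  if (!is.null(most_variable) && most_variable < nrow(beta)) {
    v <- rowVars_fast(beta)
    beta <- beta[order(v, decreasing = TRUE)[seq_len(most_variable)], ,
                 drop = FALSE]
  }
  if (all(abs(beta - beta[, 1]) < .Machine$double.eps^0.5))
    stop("degenerate input: beta matrix is constant across samples")
  pc <- prcomp(t(beta), center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(sample_ids = colnames(beta),
                 scores = scores,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[
                   seq_len(ncol(scores))]),
            class = "pc_scores")
}

rowVars_fast <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1L)
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("PC scores: %d samples x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

# per-cell-type centroids and per-PC SDs over the first n_pcs components
celltype_pc_stats <- function(pcs, sheet, n_pcs) {
  sheet <- sheet[match(pcs$sample_ids, sheet$sample_id), ]
  n_pcs <- min(n_pcs, ncol(pcs$scores))
  sc <- pcs$scores[, seq_len(n_pcs), drop = FALSE]
  small <- names(which(table(sheet$cell_type) < 3))
  if (length(small))
    stop("insufficient group size: cell type(s) with fewer than 3 samples: ",
         paste(small, collapse = ", "))
  cts <- unique(sheet$cell_type)
  list(sheet = sheet, scores = sc,
       centroid = sapply(cts, function(ct)
         colMeans(sc[sheet$cell_type == ct, , drop = FALSE])),
       sds = sapply(cts, function(ct)
         pmax(apply(sc[sheet$cell_type == ct, , drop = FALSE], 2, sd),
              .Machine$double.eps)))
}

# per-sample per-PC z-scores relative to the labelled cell type
sample_pc_z <- function(pcs, sheet, n_pcs) {
  st <- celltype_pc_stats(pcs, sheet, n_pcs)
  idx <- match(st$sheet$cell_type, colnames(st$centroid))
  z <- (st$scores - t(st$centroid)[idx, , drop = FALSE]) /
    t(st$sds)[idx, , drop = FALSE]
  rownames(z) <- st$sheet$sample_id
  list(z = z, sheet = st$sheet)
}

#' Individual-level isolation efficiency score
#'
#' For each cell type, the centroid and per-component SD of its labelled
#' samples are computed on the leading principal components; each sample's
#' z-distance is the Euclidean norm of its per-PC z-scores relative to its
#' labelled cell type. The isolation score of an individual is the maximum
#' z-distance over that donor's samples, so that a single failed fraction is
#' enough to flag the sort. Individuals with a score above
#' `config$score_threshold` (default 5) are flagged.
#'
#' @param pcs a [compute_pcs()] result.
#' @param sheet sample sheet.
#' @param config a [qc_config()].
#' @return data.frame with `individual_id`, `score`, `flagged`.
#' @export
isolation_efficiency_score <- function(pcs, sheet, config = qc_config()) {
  zz <- sample_pc_z(pcs, sheet, config$n_pcs)
  dist <- sqrt(rowSums(zz$z^2))
  agg <- tapply(dist, zz$sheet$individual_id, max)
  out <- data.frame(individual_id = names(agg), score = as.numeric(agg),
                    flagged = as.numeric(agg) > config$score_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$individual_id), ]
}

#' Per-PC cell-type distance filter
#'
#' A sample is retained iff its distance to the labelled cell-type mean is
#' within `sd_threshold` SDs separately on each of the first two principal
#' components. Statistics are computed once on the full sample set (single
#' pass; iterating would shrink the SDs and over-exclude).
#'
#' @inheritParams isolation_efficiency_score
#' @return data.frame with `sample_id`, per-PC z columns and `retained`.
#' @export
celltype_distance_filter <- function(pcs, sheet, config = qc_config()) {
  zz <- sample_pc_z(pcs, sheet, 2L)
  z <- zz$z
  retained <- rowSums(abs(z) > config$sd_threshold) == 0
  out <- data.frame(sample_id = rownames(z), z_pc1 = z[, 1],
                    z_pc2 = if (ncol(z) > 1) z[, 2] else NA_real_,
                    retained = retained, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stage-3 quality control: confirm the labelled cell type
#'
#' Runs the PC-based stage of the QC pipeline: PCA of all samples, the
#' individual-level isolation efficiency score, and the per-PC 2-SD distance
#' filter. Stages 1 (array quality) and 2 (sex/genotype concordance) require
#' raw array channels and are reported as not evaluated.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param config a [qc_config()].
#' @return an object of class `qc_report` with elements `samples`
#'   (per-sample distances and retained flag), `individuals` (isolation
#'   scores), `summary`, `stages`.
#' @export
run_stage3 <- function(beta, sheet, config = qc_config()) {
  sheet <- align_beta_sheet(beta, sheet)
  pcs <- compute_pcs(beta, n_components = max(2L, config$n_pcs))
  ind <- isolation_efficiency_score(pcs, sheet, config)
  filt <- celltype_distance_filter(pcs, sheet, config)
  samples <- merge(sheet[, c("sample_id", "individual_id", "cell_type")],
                   filt, by = "sample_id", sort = FALSE)
  structure(list(
    samples = samples,
    individuals = ind,
    pcs = pcs,
    summary = c(n_samples = nrow(samples),
                n_retained = sum(samples$retained),
                n_individuals = nrow(ind),
                n_flagged_individuals = sum(ind$flagged)),
    stages = c(stage1_array_quality = "not evaluated",
               stage2_individual_concordance = "not evaluated",
               stage3_cell_type = "evaluated"),
    config = config), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Stage-3 QC report (cell-type confirmation)\n")
  cat(sprintf("  samples retained by 2-SD PC filter: %d / %d\n",
              x$summary["n_retained"], x$summary["n_samples"]))
  cat(sprintf("  individuals flagged by isolation score (> %g): %d / %d\n",
              x$config$score_threshold,
              x$summary["n_flagged_individuals"], x$summary["n_individuals"]))
  cat("  stage 1 (array quality):", x$stages[1], "\n")
  cat("  stage 2 (individual concordance):", x$stages[2], "\n")
  invisible(x)
}

#' @export
plot.qc_report <- function(x, ...) {
  sc <- x$pcs$scores
  ct <- factor(x$samples$cell_type[match(x$pcs$sample_ids,
                                         x$samples$sample_id)])
  keep <- x$samples$retained[match(x$pcs$sample_ids, x$samples$sample_id)]
  plot(sc[, 1], sc[, 2], col = as.integer(ct), pch = ifelse(keep, 1, 4),
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$pcs$explained_variance[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$pcs$explained_variance[2]),
       main = "Stage-3 QC: samples in PC space", ...)
  legend("topright", bty = "n",
         legend = c(levels(ct), "excluded"),
         col = c(seq_len(nlevels(ct)), 1),
         pch = c(rep(1, nlevels(ct)), 4))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  df <- x$samples
  df$isolation_score <- x$individuals$score[
    match(df$individual_id, x$individuals$individual_id)]
  df$individual_flagged <- x$individuals$flagged[
    match(df$individual_id, x$individuals$individual_id)]
  df
}
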