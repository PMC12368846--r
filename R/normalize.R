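#' Between-sample quantile normalization within sample groups
#'
#' Within each group of samples, every sample's values are replaced rank-wise
#' by the mean of the group's order statistics (ties receive the average over
#' their rank range). With `groups = NULL` all samples form a single group
#' (joint normalization); passing the cell-type labels normalizes each cell
#' type separately. The rank transformation is delegated to
#' \code{limma::normalizeQuantiles}.
#'
#' @param beta beta matrix (sites x samples), values in [0, 1].
#' @param groups optional vector over samples defining the partition.
#' @return normalized beta matrix of the same shape.
#' @export
quantile_normalize <- function(beta, groups = NULL) {
  assert_beta_matrix(beta)
  if (is.null(groups)) groups <- rep("all", ncol(beta))
  if (length(groups) != ncol(beta))
    stop("`groups` must have one entry per sample")
  out <- beta
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      stop("singleton group '", g, "': quantile normalization needs >= 2 samples")
    out[, idx] <- limma::normalizeQuantiles(beta[, idx, drop = FALSE],
                                            ties = TRUE)
  }
  out
}

get_class_sites <- function(annotation, class, required = TRUE) {
  sites <- annotation$site_id[annotation$site_class == class]
  if (required && length(sites) == 0)
    stop("no sites of class '", class, "' in the annotation")
  sites
}

#' Imprinted-region stability score (DMRSE analogue)
#'
#' Imprinted differentially methylated regions sit near 50\% methylation in
#' every sample, so between-sample spread of their mean is pure noise. The
#' score is the standard error (SD / sqrt(n)) of the per-sample means over
#' imprinted sites; lower is better.
#'
#' @param beta beta matrix.
#' @param annotation site annotation with a `site_class` column.
#' @return non-negative scalar score.
#' @export
dmrse <- function(beta, annotation) {
  sites <- get_class_sites(annotation, "imprinted_dmr")
  means <- colMeans(beta[intersect(rownames(beta), sites), , drop = FALSE])
  sd(means) / sqrt(length(means))
}

#' SNP-probe genotype clustering score (GCOSE analogue)
#'
#' Probes overlapping common SNPs produce three genotype bands near 0, 0.5
#' and 1. Each (site, sample) value is assigned its nearest band centre and
#' the score is the mean squared deviation from the assigned centre; lower is
#' better.
#'
#' @inheritParams dmrse
#' @return non-negative scalar score.
#' @export
gcose <- function(beta, annotation) {
  sites <- get_class_sites(annotation, "snp_probe")
  x <- beta[intersect(rownames(beta), sites), , drop = FALSE]
  centres <- c(0, 0.5, 1)
  assigned <- centres[max.col(-abs(outer(as.vector(x), centres, `-`)))]
  mean((as.vector(x) - assigned)^2)
}

#' X-inactivation sex-separation score (seabird analogue)
#'
#' X-linked sites separate the sexes (female X-inactivation pushes values
#' towards 0.5). Per sample, the mean over X-linked sites is computed; the
#' score is 1 minus the Mann-Whitney AUC of separating the sexes by this
#' summary, oriented so that the score is at most 0.5 and 0 means perfect
#' separation; lower is better.
#'
#' @inheritParams dmrse
#' @param sheet sample sheet (for the `sex` column).
#' @return score in [0, 0.5].
#' @export
seabird <- function(beta, annotation, sheet) {
  sheet <- align_beta_sheet(beta, sheet)
  sites <- get_class_sites(annotation, "x_linked")
  if (length(unique(sheet$sex)) < 2)
    stop("seabird requires both sexes in the cohort")
  means <- colMeans(beta[intersect(rownames(beta), sites), , drop = FALSE])
  f <- means[sheet$sex == "F"]
  m <- means[sheet$sex == "M"]
  # Mann-Whitney AUC
  r <- rank(c(f, m))
  auc <- (sum(r[seq_along(f)]) - length(f) * (length(f) + 1) / 2) /
    (length(f) * length(m))
  min(auc, 1 - auc)
}

#' Per-sample transformation magnitude
#'
#' Quantifies how much normalization moved each sample: the mean and SD
#' across sites of the absolute difference between normalized and raw
#' values.
#'
#' @param raw,normalized aligned beta matrices.
#' @return data.frame with `sample_id`, `mean_abs_diff`, `sd_abs_diff`.
#' @export
transformation_magnitude <- function(raw, normalized) {
  if (!identical(dim(raw), dim(normalized)) ||
      !identical(colnames(raw), colnames(normalized)))
    stop("raw and normalized matrices are not aligned")
  d <- abs(normalized - raw)
  data.frame(sample_id = colnames(raw),
             mean_abs_diff = colMeans(d),
             sd_abs_diff = apply(d, 2, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare normalization strategies for cell-sorted data
#'
#' Scores three strategies - raw (no normalization), joint quantile
#' normalization of all samples, and per-cell-type quantile normalization -
#' with the imprinted-region (DMRSE), SNP-probe (GCOSE) and X-inactivation
#' (seabird) signal-to-noise metrics, where lower is better, plus the
#' per-sample transformation magnitude of each normalized strategy.
#'
#' @param beta raw beta matrix.
#' @param annotation site annotation.
#' @param sheet sample sheet.
#' @return an object of class `norm_comparison`: list with `metrics`
#'   (strategy x metric data.frame) and `magnitude` (per-sample, per-strategy
#'   transformation magnitudes with cell-type labels).
#' @export
compare_strategies <- function(beta, annotation, sheet) {
  sheet <- align_beta_sheet(beta, sheet)
  mats <- list(raw = beta,
               joint = quantile_normalize(beta),
               per_cell_type = quantile_normalize(beta, sheet$cell_type))
  metrics <- do.call(rbind, lapply(names(mats), function(s) {
    data.frame(strategy = s,
               dmrse = dmrse(mats[[s]], annotation),
               gcose = gcose(mats[[s]], annotation),
               seabird = seabird(mats[[s]], annotation, sheet),
               stringsAsFactors = FALSE)
  }))
  magnitude <- do.call(rbind, lapply(c("joint", "per_cell_type"), function(s) {
    tm <- transformation_magnitude(beta, mats[[s]])
    tm$strategy <- s
    tm$cell_type <- sheet$cell_type[match(tm$sample_id, sheet$sample_id)]
    tm
  }))
  structure(list(metrics = metrics, magnitude = magnitude),
            class = "norm_comparison")
}

#' @export
print.norm_comparison <- function(x, ...) {
  cat("Normalization strategy comparison (lower scores = better)\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  agg <- aggregate(mean_abs_diff ~ strategy + cell_type, x$magnitude, mean)
  cat("\nMean per-sample transformation magnitude by cell type:\n")
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}
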