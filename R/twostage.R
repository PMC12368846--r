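#' Two-stage analysis configuration
#'
#' @param discovery_threshold stage-1 within-cell-type significance
#'   threshold (default epigenome-wide 9e-8).
#' @param relaxation optional relaxed discovery threshold; never allowed
#'   above 1e-6 (more permissive discovery thresholds accumulate false
#'   positives faster than they add true ones).
#' @param het_alpha stage-2 heterogeneity test level, Bonferroni-adjusted
#'   over the discovered DMPs (default 0.05).
#' @param reference cell-type reference level for the stage-2 model.
#' @param per_term use per-interaction-term tests instead of the joint Wald
#'   heterogeneity test.
#' @return object of class `two_stage_config`.
#' @export
two_stage_config <- function(discovery_threshold = 9e-8, relaxation = NULL,
                             het_alpha = 0.05, reference = NULL,
                             per_term = FALSE) {
  if (!is.null(relaxation)) {
    if (relaxation > 1e-6)
      stop_config("discovery relaxation must not exceed 1e-6")
    discovery_threshold <- relaxation
  }
  if (het_alpha <= 0 || het_alpha >= 1)
    stop_config("het_alpha must lie in (0, 1)")
  structure(list(discovery_threshold = discovery_threshold,
                 het_alpha = het_alpha, reference = reference,
                 per_term = isTRUE(per_term)),
            class = "two_stage_config")
}

#' Stage 1: within-cell-type discovery
#'
#' Fits the within-cell-type linear regression (`ctlr`) separately in every
#' cell type and returns the union of sites passing the discovery
#' threshold in at least one cell type, with the discovering cell types
#' recorded, sorted by the minimum stage-1 p-value.
#'
#' @param beta beta matrix.
#' @param sheet sample sheet with assigned phenotype.
#' @param config a [two_stage_config()].
#' @return data.frame with `site_id`, `discovered_in` (comma-separated),
#'   `min_p`, plus per-cell-type `p_<ct>` columns.
#' @export
discover <- function(beta, sheet, config = two_stage_config()) {
  sheet <- align_beta_sheet(beta, sheet)
  cts <- sort(unique(sheet$cell_type))
  pmat <- sapply(cts, function(ct)
    ewas_fit(beta, sheet, "ctlr", cell_type = ct)$results$p)
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = 1)
  rownames(pmat) <- rownames(beta)
  hit <- !is.na(pmat) & pmat < config$discovery_threshold
  keep <- which(rowSums(hit) > 0)
  out <- data.frame(site_id = rownames(beta)[keep],
                    discovered_in = apply(hit[keep, , drop = FALSE], 1,
                                          function(h) paste(cts[h], collapse = ",")),
                    min_p = apply(pmat[keep, , drop = FALSE], 1, min,
                                  na.rm = TRUE),
                    stringsAsFactors = FALSE)
  for (ct in cts) out[[paste0("p_", ct)]] <- pmat[keep, ct]
  out <- out[order(out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage 2: mixed-model characterization of discovered DMPs
#'
#' Refits the discovered sites with the random-intercept mixed model
#' (interaction structure plus a random effect for multiple samples per
#' individual) and classifies each DMP: if the joint interaction
#' (heterogeneity) test is not significant at the Bonferroni-adjusted level
#' the effect is labelled "common" (explicitly a non-rejection - absence of
#' detected heterogeneity, not proof of a shared effect); if significant,
#' "cell_specific" with the affected cell types taken as those whose
#' per-cell-type case effect passes a nominal 0.05 check; non-converged
#' sites are "undetermined".
#'
#' @param beta beta matrix (all cell types).
#' @param sheet sample sheet.
#' @param dmps stage-1 output from [discover()] (may be empty).
#' @param config a [two_stage_config()].
#' @return an object of class `two_stage_report`.
#' @export
characterize <- function(beta, sheet, dmps, config = two_stage_config()) {
  sheet <- align_beta_sheet(beta, sheet)
  if (nrow(dmps) == 0) {
    return(new_two_stage_report(
      data.frame(site_id = character(0), discovered_in = character(0),
                 stage1_min_p = numeric(0), joint_int_p = numeric(0),
                 classification = character(0),
                 affected_cell_types = character(0),
                 stringsAsFactors = FALSE), config, sheet))
  }
  fit <- ewas_fit(beta, sheet, "mer", reference = config$reference,
                  sites = dmps$site_id)
  res <- fit$results
  cts <- fit$cell_types
  het_thr <- config$het_alpha / nrow(dmps)  # Bonferroni over discoveries
  het_p <- if (config$per_term) {
    int_p <- res[, grep("^int_.*_p$", names(res)), drop = FALSE]
    do.call(pmin, c(int_p, na.rm = TRUE)) * ncol(int_p)  # Bonferroni per site
  } else res$joint_int_p
  cls <- ifelse(!res$converged, "undetermined",
                ifelse(het_p < het_thr, "cell_specific", "common"))
  affected <- vapply(seq_len(nrow(res)), function(k) {
    if (cls[k] != "cell_specific") return(NA_character_)
    eff_p <- vapply(cts, function(ct) res[[paste0("eff_", ct, "_p")]][k],
                    numeric(1))
    paste(cts[!is.na(eff_p) & eff_p < 0.05], collapse = ",")
  }, character(1))
  report <- data.frame(site_id = res$site_id,
                       discovered_in = dmps$discovered_in[
                         match(res$site_id, dmps$site_id)],
                       stage1_min_p = dmps$min_p[
                         match(res$site_id, dmps$site_id)],
                       joint_int_p = res$joint_int_p,
                       classification = cls,
                       affected_cell_types = affected,
                       stringsAsFactors = FALSE)
  new_two_stage_report(report, config, sheet)
}

new_two_stage_report <- function(report, config, sheet) {
  structure(list(report = report, config = config,
                 n_samples = nrow(sheet),
                 cell_types = sort(unique(sheet$cell_type))),
            class = "two_stage_report")
}

#' Two-stage discovery and characterization pipeline
#'
#' The recommended analysis for cell-sorted EWAS: stage 1 discovers DMPs by
#' within-cell-type linear regression (well-calibrated false-positive
#' control); stage 2 characterizes the cell-type specificity of the
#' discovered DMPs with the random-intercept mixed model, whose inflated
#' discovery behaviour makes it unsuitable for stage 1 but whose
#' interaction structure is exactly what the characterization question
#' needs. Stage 2 never adds sites absent from stage 1.
#'
#' @inheritParams discover
#' @return an object of class `two_stage_report`.
#' @export
run_two_stage <- function(beta, sheet, config = two_stage_config()) {
  dmps <- discover(beta, sheet, config)
  out <- characterize(beta, sheet, dmps, config)
  out$provenance <- list(discovery_threshold = config$discovery_threshold,
                         het_alpha = config$het_alpha,
                         package_version = as.character(
                           utils::packageVersion("sortedmeth")))
  out
}

#' @export
print.two_stage_report <- function(x, ...) {
  cat("Two-stage cell-sorted EWAS report\n")
  cat(sprintf("  discovery threshold: %.3g; heterogeneity alpha: %g (Bonferroni)\n",
              x$config$discovery_threshold, x$config$het_alpha))
  r <- x$report
  cat(sprintf("  discovered DMPs: %d (common %d, cell-specific %d, undetermined %d)\n",
              nrow(r), sum(r$classification == "common"),
              sum(r$classification == "cell_specific"),
              sum(r$classification == "undetermined")))
  if (nrow(r)) print(head(r, 10), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.two_stage_report <- function(x, ...) x$report
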