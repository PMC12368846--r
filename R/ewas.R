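#' Fit a per-site EWAS regression framework
#'
#' Fits one of four per-site association frameworks for cell-sorted DNAm
#' data, vectorized across sites:
#'
#' \describe{
#'   \item{`ctlr`}{within-cell-type linear regression: per site,
#'     `beta ~ case + age + sex + brain_bank` on one cell type's samples
#'     (one per individual, so observations are independent). Classical t
#'     test on the case coefficient.}
#'   \item{`alllr`}{pooled linear regression over all cell types:
#'     `beta ~ case * cell_type + age + sex + brain_bank` with classical
#'     (non-robust) standard errors. With multiple samples per individual
#'     this is deliberately anticonservative; the bias is part of what the
#'     benchmark quantifies.}
#'   \item{`mer`}{the same fixed-effect structure plus a random intercept
#'     per individual, estimated per site by profiled REML over the variance
#'     ratio (fast dedicated solver; see Details). Wald tests with a normal
#'     reference.}
#'   \item{`crr`}{pooled OLS point estimates (identical to `alllr`) with
#'     cluster-robust sandwich standard errors, clustered on individual,
#'     CR1 small-sample scaling `G/(G-1) * (N-1)/(N-k)`, and a t reference
#'     with `G - 1` degrees of freedom.}
#' }
#'
#' Cell type enters with treatment coding; the reference level defaults to
#' the alphabetically first label and is configurable via `reference` (the
#' interpretation of the main effect and interactions depends on it: the
#' main case effect is the case-control contrast in the reference cell
#' type). Pooled results carry, per cell type, the implied case-effect
#' contrast (`eff_<ct>_*` columns) in addition to the raw main/interaction
#' terms and a joint interaction test.
#'
#' @details The mixed-model solver rotates each site's regression into the
#' eigenbasis of the cluster structure (computed once per design and reused
#' across all sites), profiles the REML criterion over the single variance
#' ratio on a log-spaced grid evaluated for all sites simultaneously, and
#' refines the per-site optimum either by quadratic interpolation on the
#' grid (default) or by Brent search (`refine = "brent"`, slower but exact).
#'
#' @param beta beta matrix (sites x samples).
#' @param sheet sample sheet with assigned phenotype.
#' @param framework one of "ctlr", "alllr", "mer", "crr".
#' @param cell_type for `ctlr`: which cell type to analyse (may be omitted
#'   if the sheet contains a single cell type).
#' @param reference reference level of the cell-type factor (pooled
#'   frameworks).
#' @param reml for `mer`: REML (default) or ML.
#' @param refine for `mer`: "quadratic" (default), "brent" or "none".
#' @param sites optional character vector restricting the fit to these
#'   site ids.
#' @return an object of class `ewas_fit`; its `results` data.frame has one
#'   row per site. For `ctlr`: `estimate`, `se`, `statistic`, `p`, `df`,
#'   `converged`. For pooled frameworks: `main_*`, `int_<ct>_*` per
#'   non-reference cell type, `joint_int_stat`/`joint_int_p`, `eff_<ct>_*`
#'   per cell type, `converged`.
#' @export
ewas_fit <- function(beta, sheet,
                     framework = c("ctlr", "alllr", "mer", "crr"),
                     cell_type = NULL, reference = NULL, reml = TRUE,
                     refine = c("quadratic", "brent", "none"),
                     sites = NULL) {
  framework <- match.arg(framework)
  refine <- match.arg(refine)
  sheet <- align_beta_sheet(beta, sheet)
  assert_sheet(sheet, need_phenotype = TRUE)
  if (!is.null(sites)) {
    missing <- setdiff(sites, rownames(beta))
    if (length(missing))
      stop("unknown site ids: ", paste(head(missing, 5), collapse = ", "))
    beta <- beta[sites, , drop = FALSE]
  }

  if (framework == "ctlr") {
    cts <- unique(sheet$cell_type)
    if (is.null(cell_type)) {
      if (length(cts) > 1)
        stop("ctlr analyses one cell type; pass `cell_type`")
      cell_type <- cts
    }
    keep <- sheet$cell_type == cell_type
    if (!any(keep)) stop("no samples of cell type ", cell_type)
    sheet <- sheet[keep, , drop = FALSE]
    beta <- beta[, sheet$sample_id, drop = FALSE]
    if (anyDuplicated(sheet$individual_id))
      stop("ctlr requires one sample per individual within the cell type")
    res <- fit_ctlr_impl(beta, sheet)
    return(new_ewas_fit(res, framework, cell_type = cell_type,
                        reference = NULL, sheet = sheet))
  }

  if (length(unique(sheet$cell_type)) < 2)
    stop("pooled frameworks require at least 2 cell types")
  reference <- reference %||% sort(unique(sheet$cell_type))[1]
  res <- switch(framework,
    alllr = fit_alllr_impl(beta, sheet, reference),
    crr = fit_crr_impl(beta, sheet, reference),
    mer = fit_mer_impl(beta, sheet, reference, reml = reml, refine = refine))
  new_ewas_fit(res, framework, cell_type = NULL, reference = reference,
               sheet = sheet)
}

new_ewas_fit <- function(results, framework, cell_type, reference, sheet) {
  structure(list(results = results, framework = framework,
                 cell_type = cell_type, reference = reference,
                 n_samples = nrow(sheet),
                 n_individuals = length(unique(sheet$individual_id)),
                 cell_types = sort(unique(sheet$cell_type))),
            class = "ewas_fit")
}

# ---- shared design machinery ------------------------------------------------

build_design <- function(sheet, with_celltype, reference = NULL) {
  dat <- data.frame(case = as.numeric(sheet$phenotype == "case"),
                    age = as.numeric(sheet$age),
                    sex = factor(sheet$sex),
                    brain_bank = factor(sheet$brain_bank))
  terms <- "case"
  if (with_celltype) {
    ct <- factor(sheet$cell_type)
    if (!is.null(reference)) ct <- stats::relevel(ct, ref = reference)
    dat$cell_type <- ct
    terms <- "case * cell_type"
  }
  if (length(unique(dat$age)) > 1) terms <- c(terms, "age")
  if (nlevels(dat$sex) > 1) terms <- c(terms, "sex")
  if (nlevels(dat$brain_bank) > 1) terms <- c(terms, "brain_bank")
  X <- model.matrix(stats::as.formula(paste("~", paste(terms, collapse = " + "))),
                    dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

# OLS across all sites at once; Y is samples x sites
fit_ols_multi <- function(X, Y) {
  if (nrow(X) <= ncol(X))
    stop("too few samples (", nrow(X), ") for ", ncol(X), " parameters")
  XtXinv <- chol2inv(chol(crossprod(X)))
  coef <- XtXinv %*% crossprod(X, Y)
  E <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(E^2) / df
  ok <- colVars_fast(Y) > .Machine$double.eps
  list(coef = coef, E = E, sigma2 = sigma2, XtXinv = XtXinv, df = df,
       converged = ok & is.finite(sigma2))
}

tstats <- function(est, se, df) {
  stat <- est / se
  list(stat = stat, p = 2 * pt(-abs(stat), df))
}

# ---- ctLR -------------------------------------------------------------------

fit_ctlr_impl <- function(beta, sheet) {
  X <- build_design(sheet, with_celltype = FALSE)
  if (nrow(X) <= ncol(X) + 2)
    stop("ctlr needs more samples (", nrow(X), ") than parameters (",
         ncol(X), ") plus 2")
  fit <- fit_ols_multi(X, t(beta))
  j <- which(colnames(X) == "case")
  est <- fit$coef[j, ]
  se <- sqrt(fit$sigma2 * fit$XtXinv[j, j])
  ts <- tstats(est, se, fit$df)
  out <- data.frame(site_id = rownames(beta), estimate = est, se = se,
                    statistic = ts$stat, p = ts$p, df = fit$df,
                    converged = fit$converged, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[!out$converged, c("estimate", "se", "statistic", "p")] <- NA_real_
  out
}

# ---- pooled frameworks ------------------------------------------------------

pooled_term_index <- function(X, sheet, reference) {
  cts <- levels(factor(sheet$cell_type, levels = c(
    reference, sort(setdiff(unique(sheet$cell_type), reference)))))
  main <- which(colnames(X) == "case")
  ints <- vapply(cts[-1], function(ct)
    which(colnames(X) == paste0("case:cell_type", ct)), integer(1))
  list(cts = cts, main = main, ints = ints, sel = c(main, ints))
}

# assemble the pooled result frame given per-coefficient stats and the
# (possibly per-site) covariance among (main, interactions)
pooled_results <- function(site_ids, info, est, se, stat, p,
                           joint_stat, joint_p, eff, converged) {
  out <- data.frame(site_id = site_ids,
                    main_beta = est[1, ], main_se = se[1, ],
                    main_stat = stat[1, ], main_p = p[1, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  for (k in seq_along(info$cts[-1])) {
    ct <- info$cts[-1][k]
    out[[paste0("int_", ct, "_beta")]] <- est[1 + k, ]
    out[[paste0("int_", ct, "_se")]] <- se[1 + k, ]
    out[[paste0("int_", ct, "_stat")]] <- stat[1 + k, ]
    out[[paste0("int_", ct, "_p")]] <- p[1 + k, ]
  }
  out$joint_int_stat <- joint_stat
  out$joint_int_p <- joint_p
  for (ct in info$cts) {
    out[[paste0("eff_", ct, "_beta")]] <- eff$beta[ct, ]
    out[[paste0("eff_", ct, "_se")]] <- eff$se[ct, ]
    out[[paste0("eff_", ct, "_p")]] <- eff$p[ct, ]
  }
  out$converged <- converged
  num <- setdiff(names(out), c("site_id", "converged"))
  out[!converged, num] <- NA_real_
  out
}

# per-cell-type case effects from main + interaction, given variances and
# main-interaction covariances (each a matrix coefficients x sites)
celltype_effects <- function(info, est, vcv, df_fun) {
  cts <- info$cts
  m <- length(cts)
  beta <- se <- p <- matrix(NA_real_, m, ncol(est), dimnames = list(cts, NULL))
  beta[1, ] <- est[1, ]
  se[1, ] <- sqrt(vcv[["11"]])
  for (k in seq_len(m - 1)) {
    beta[1 + k, ] <- est[1, ] + est[1 + k, ]
    se[1 + k, ] <- sqrt(vcv[["11"]] + vcv[[paste0(1 + k, 1 + k)]] +
                          2 * vcv[[paste0("1", 1 + k)]])
  }
  for (i in seq_len(m)) p[i, ] <- df_fun(beta[i, ] / se[i, ])
  list(beta = beta, se = se, p = p)
}

fit_alllr_impl <- function(beta, sheet, reference) {
  X <- build_design(sheet, with_celltype = TRUE, reference = reference)
  info <- pooled_term_index(X, sheet, reference)
  fit <- fit_ols_multi(X, t(beta))
  sel <- info$sel
  est <- fit$coef[sel, , drop = FALSE]
  Csub <- fit$XtXinv[sel, sel, drop = FALSE]
  se <- sqrt(outer(diag(Csub), fit$sigma2))
  ts <- tstats(est, se, fit$df)
  # joint Wald F over interaction terms (classical covariance)
  q <- length(info$ints)
  Cint_inv <- solve(fit$XtXinv[info$ints, info$ints, drop = FALSE])
  bint <- fit$coef[info$ints, , drop = FALSE]
  quad <- colSums(bint * (Cint_inv %*% bint))
  joint_stat <- quad / (q * fit$sigma2)
  joint_p <- pf(joint_stat, q, fit$df, lower.tail = FALSE)
  # covariance entries among (main, ints): sigma2 * Csub
  vcv <- list()
  for (i in seq_len(q + 1)) for (j in i:(q + 1))
    vcv[[paste0(i, j)]] <- Csub[i, j] * fit$sigma2
  names(vcv)[1] <- "11"
  eff <- celltype_effects(info, est, vcv,
                          function(z) 2 * pt(-abs(z), fit$df))
  pooled_results(rownames(beta), info, est, se, ts$stat, ts$p,
                 joint_stat, joint_p, eff, fit$converged)
}

fit_crr_impl <- function(beta, sheet, reference) {
  cluster <- factor(sheet$individual_id)
  G <- nlevels(cluster)
  if (G < 2) stop("cluster-robust regression requires at least 2 clusters")
  X <- build_design(sheet, with_celltype = TRUE, reference = reference)
  info <- pooled_term_index(X, sheet, reference)
  fit <- fit_ols_multi(X, t(beta))
  sel <- info$sel
  m <- length(sel)
  N <- nrow(X); k <- ncol(X)
  cr1 <- G / (G - 1) * (N - 1) / (N - k)
  # B rows map residuals to coefficient estimates: b_j = B[j, ] %*% y
  B <- fit$XtXinv %*% t(X)
  # per-cluster score contributions for each coefficient of interest
  Cg <- lapply(seq_len(m), function(i)
    rowsum(B[sel[i], ] * fit$E, cluster))
  vcv <- list()
  for (i in seq_len(m)) for (j in i:m)
    vcv[[paste0(i, j)]] <- cr1 * colSums(Cg[[i]] * Cg[[j]])
  names(vcv)[1] <- "11"
  est <- fit$coef[sel, , drop = FALSE]
  se <- do.call(rbind, lapply(seq_len(m), function(i)
    sqrt(vcv[[paste0(i, i)]])))
  df_t <- G - 1
  ts <- tstats(est, se, df_t)
  # joint Wald over interactions with the robust covariance
  q <- m - 1
  bint <- est[-1, , drop = FALSE]
  if (q == 1) {
    quad <- bint[1, ]^2 / vcv[["22"]]
  } else if (q == 2) {
    v22 <- vcv[["22"]]; v33 <- vcv[["33"]]; v23 <- vcv[["23"]]
    det <- v22 * v33 - v23^2
    quad <- (bint[1, ]^2 * v33 - 2 * bint[1, ] * bint[2, ] * v23 +
               bint[2, ]^2 * v22) / det
  } else {
    quad <- vapply(seq_len(ncol(bint)), function(s) {
      V <- matrix(0, q, q)
      for (i in seq_len(q)) for (j in i:q)
        V[i, j] <- V[j, i] <- vcv[[paste0(min(i + 1, j + 1),
                                          max(i + 1, j + 1))]][s]
      drop(crossprod(bint[, s], solve(V, bint[, s])))
    }, numeric(1))
  }
  joint_stat <- quad / q
  joint_p <- pf(joint_stat, q, df_t, lower.tail = FALSE)
  eff <- celltype_effects(info, est, vcv,
                          function(z) 2 * pt(-abs(z), df_t))
  pooled_results(rownames(beta), info, est, se, ts$stat, ts$p,
                 joint_stat, joint_p, eff, fit$converged)
}

#' Significance calls from an EWAS fit
#'
#' For `ctlr` fits, a site is called when the case-term p-value is below
#' the threshold. For pooled frameworks the default "any-term" policy calls
#' a site when the main effect or any interaction term is significant
#' (depending on which cell types a DMP affects, either may carry the
#' signal); "main-only" uses the main effect alone and "joint-test" the main
#' effect or the joint interaction test. Non-converged sites are never
#' called.
#'
#' @param fit an [ewas_fit()] result.
#' @param threshold p-value threshold in (0, 1).
#' @param policy term policy for pooled frameworks.
#' @return named logical vector over sites, with the policy as an attribute.
#' @export
call_significant <- function(fit, threshold = 9e-8,
                             policy = c("any-term", "main-only", "joint-test")) {
  policy <- match.arg(policy)
  if (threshold <= 0 || threshold >= 1)
    stop_config("threshold must lie in (0, 1)")
  res <- fit$results
  calls <- if (fit$framework == "ctlr") {
    res$p < threshold
  } else {
    int_p <- res[, grep("^int_.*_p$", names(res)), drop = FALSE]
    switch(policy,
      "any-term" = res$main_p < threshold |
        apply(int_p < threshold, 1, any),
      "main-only" = res$main_p < threshold,
      "joint-test" = res$main_p < threshold | res$joint_int_p < threshold)
  }
  calls[is.na(calls)] <- FALSE
  names(calls) <- res$site_id
  attr(calls, "policy") <- policy
  attr(calls, "threshold") <- threshold
  calls
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.ewas_fit <- function(x, ...) {
  cat(sprintf("EWAS fit: framework %s, %d sites\n",
              x$framework, nrow(x$results)))
  if (!is.null(x$cell_type))
    cat("  cell type:", x$cell_type, "\n")
  if (!is.null(x$reference))
    cat("  cell-type reference level:", x$reference, "\n")
  cat(sprintf("  %d samples, %d individuals; %d site(s) non-converged\n",
              x$n_samples, x$n_individuals, sum(!x$results$converged)))
  invisible(x)
}

#' @export
summary.ewas_fit <- function(object, threshold = 9e-8, ...) {
  res <- object$results
  pcol <- if (object$framework == "ctlr") "p" else "main_p"
  cat(sprintf("EWAS fit (%s): %d sites\n", object$framework, nrow(res)))
  cat(sprintf("  min %s: %.3g; sites with %s < %.3g: %d\n",
              pcol, suppressWarnings(min(res[[pcol]], na.rm = TRUE)), pcol,
              threshold, sum(res[[pcol]] < threshold, na.rm = TRUE)))
  if (object$framework != "ctlr") {
    cat(sprintf("  sites with joint interaction p < %.3g: %d\n", threshold,
                sum(res$joint_int_p < threshold, na.rm = TRUE)))
  }
  invisible(object)
}

#' @export
coef.ewas_fit <- function(object, ...) {
  res <- object$results
  cols <- if (object$framework == "ctlr") "estimate" else
    grep("^(main|int_.*)_beta$", names(res), value = TRUE)
  out <- as.matrix(res[, cols, drop = FALSE])
  rownames(out) <- res$site_id
  out
}

#' @export
as.data.frame.ewas_fit <- function(x, ...) x$results
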