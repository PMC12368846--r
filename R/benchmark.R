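#' Simulation benchmark configuration
#'
#' @param n_simulations number of simulated association studies.
#' @param thresholds significance thresholds at which calls are counted
#'   (must be sorted ascending); defaults to epigenome-wide significance
#'   9e-8 plus the three discovery thresholds 1e-7, 1e-6, 1e-5.
#' @param frameworks which frameworks to run.
#' @param n_dmps,prop_specific,delta spike settings (see [spike_dmps()]).
#' @param case_fraction individual-level case probability.
#' @param fwer_rate target family-wise error rate for threshold calibration.
#' @param policy term policy for pooled-framework calls.
#' @param reference cell-type reference level (NULL = alphabetical).
#' @param mer_sites for spiked benchmarks, fit the mixed model on "spiked"
#'   sites only (default; the framework's true-positive accounting needs no
#'   more) or on "all" sites.
#' @param master_seed master RNG seed; per-simulation seeds are derived
#'   deterministically from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_simulations = 100L,
                       thresholds = c(9e-8, 1e-7, 1e-6, 1e-5),
                       frameworks = c("ctlr", "crr"),
                       n_dmps = 1000L, prop_specific = 0.5, delta = 0.05,
                       case_fraction = 0.5, fwer_rate = 0.05,
                       policy = "any-term", reference = NULL,
                       mer_sites = c("spiked", "all"),
                       master_seed = 1L) {
  if (n_simulations < 1) stop_config("n_simulations must be at least 1")
  if (is.unsorted(thresholds))
    stop_config("thresholds must be sorted ascending")
  if (!all(frameworks %in% c("ctlr", "alllr", "mer", "crr")))
    stop_config("unknown framework in `frameworks`")
  structure(list(n_simulations = as.integer(n_simulations),
                 thresholds = thresholds, frameworks = frameworks,
                 n_dmps = as.integer(n_dmps), prop_specific = prop_specific,
                 delta = delta, case_fraction = case_fraction,
                 fwer_rate = fwer_rate, policy = policy,
                 reference = reference,
                 mer_sites = match.arg(mer_sites),
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

fit_all_frameworks <- function(beta, sheet, config, sites = NULL,
                               mer_only_sites = NULL) {
  fits <- list()
  for (fw in config$frameworks) {
    if (fw == "ctlr") {
      for (ct in sort(unique(sheet$cell_type))) {
        fits[[paste0("ctlr:", ct)]] <- ewas_fit(
          beta, sheet, "ctlr", cell_type = ct, sites = sites)
      }
    } else if (fw == "mer") {
      fits[["mer"]] <- ewas_fit(beta, sheet, "mer",
                                reference = config$reference,
                                sites = mer_only_sites %||% sites)
    } else {
      fits[[fw]] <- ewas_fit(beta, sheet, fw, reference = config$reference,
                             sites = sites)
    }
  }
  fits
}

# per-fit p-value vectors by term, used for counting and calibration
fit_term_p <- function(fit) {
  res <- fit$results
  if (fit$framework == "ctlr") return(list(case = res$p))
  int_p <- res[, grep("^int_.*_p$", names(res)), drop = FALSE]
  list(main = res$main_p,
       interaction = do.call(pmin, c(int_p, na.rm = TRUE)),
       any = pmin(res$main_p, do.call(pmin, c(int_p, na.rm = TRUE)),
                  na.rm = TRUE))
}

#' Null-simulation benchmark: false positives and calibration inputs
#'
#' Runs `n_simulations` null association studies on a fixed cohort: each
#' simulation freshly assigns case/control labels at the individual level
#' (seeds derived deterministically from the master seed), fits the
#' requested frameworks and counts significant calls per term and
#' threshold. Per-simulation minimum p-values are retained for family-wise
#' error calibration. Errors in individual fits are recorded and do not
#' abort the benchmark.
#'
#' @param cohort a [generate_cohort()] result (no spiked sites).
#' @param config a [sim_config()].
#' @return an object of class `null_benchmark` with elements `counts`
#'   (sim x framework x term x threshold false-positive counts), `min_p`,
#'   `errors` and `config`.
#' @export
run_null_benchmark <- function(cohort, config = sim_config()) {
  seeds <- derive_seeds(config$master_seed, config$n_simulations)
  counts <- list(); minp <- list(); errors <- character(0)
  for (i in seq_len(config$n_simulations)) {
    sheet_i <- assign_phenotype(cohort$sheet, config$case_fraction, seeds[i])
    fits <- tryCatch(
      fit_all_frameworks(cohort$beta, sheet_i, config),
      error = function(e) {
        errors <<- c(errors, sprintf("sim %d: %s", i, conditionMessage(e)))
        NULL
      })
    if (is.null(fits)) next
    for (nm in names(fits)) {
      fw <- sub(":.*", "", nm)
      ct <- if (grepl(":", nm)) sub(".*:", "", nm) else "pooled"
      for (term in names(pl <- fit_term_p(fits[[nm]]))) {
        p <- pl[[term]]
        counts[[length(counts) + 1L]] <- data.frame(
          sim = i, framework = fw, cell_type = ct, term = term,
          threshold = config$thresholds,
          fp = vapply(config$thresholds,
                      function(t) sum(p < t, na.rm = TRUE), numeric(1)),
          stringsAsFactors = FALSE)
        minp[[length(minp) + 1L]] <- data.frame(
          sim = i, framework = fw, cell_type = ct, term = term,
          min_p = suppressWarnings(min(p, na.rm = TRUE)),
          q_rate_p = unname(quantile(p, config$fwer_rate, na.rm = TRUE,
                                     type = 7)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 min_p = do.call(rbind, minp),
                 errors = errors, n_sites = nrow(cohort$beta),
                 config = config),
            class = "null_benchmark")
}

#' Spiked-simulation benchmark: true-positive rates
#'
#' Runs `n_simulations` spiked association studies: each simulation assigns
#' case/control labels, spikes `n_dmps` DMPs with mean difference `delta`
#' (a proportion `prop_specific` of them specific to one uniformly chosen
#' cell type, the rest common to all), fits the requested frameworks and
#' scores detections against the truth table.
#'
#' True-positive rates for `ctlr` in cell type c are computed over the DMPs
#' that affect c (a within-cell-type model cannot be expected to find a DMP
#' confined to a different fraction); pooled frameworks are scored over all
#' DMPs. Rates are additionally stratified into cell-specific and common
#' DMPs; empty strata are reported as `NA`, not zero. False positives are
#' counted on the non-spiked sites for every framework fitted genome-wide.
#'
#' @inheritParams run_null_benchmark
#' @return an object of class `spiked_benchmark` with elements `tpr`,
#'   `fp`, `errors`, `config`.
#' @export
run_spiked_benchmark <- function(cohort, config = sim_config()) {
  seeds <- derive_seeds(config$master_seed, 2L * config$n_simulations)
  tpr <- list(); fps <- list(); errors <- character(0)
  for (i in seq_len(config$n_simulations)) {
    sheet_i <- assign_phenotype(cohort$sheet, config$case_fraction,
                                seeds[2 * i - 1])
    sp <- spike_dmps(cohort$beta, sheet_i, config$n_dmps,
                     config$prop_specific, config$delta, seeds[2 * i])
    truth <- sp$truth
    is_specific <- !grepl(",", truth$affected_cell_types)
    mer_sites <- if (config$mer_sites == "spiked") truth$site_id else NULL
    fits <- tryCatch(
      fit_all_frameworks(sp$beta, sheet_i, config,
                         mer_only_sites = mer_sites),
      error = function(e) {
        errors <<- c(errors, sprintf("sim %d: %s", i, conditionMessage(e)))
        NULL
      })
    if (is.null(fits)) next
    for (nm in names(fits)) {
      fw <- sub(":.*", "", nm)
      ct <- if (grepl(":", nm)) sub(".*:", "", nm) else "pooled"
      fit <- fits[[nm]]
      in_scope <- if (fw == "ctlr") truth_affects(truth, ct)
                  else rep(TRUE, nrow(truth))
      for (thr in config$thresholds) {
        calls <- call_significant(fit, thr, config$policy)
        hit <- calls[truth$site_id]
        strata <- list(all = in_scope,
                       specific = in_scope & is_specific,
                       common = in_scope & !is_specific)
        tpr[[length(tpr) + 1L]] <- data.frame(
          sim = i, framework = fw, cell_type = ct, threshold = thr,
          stratum = names(strata),
          tpr = vapply(strata, function(s)
            if (any(s)) mean(hit[s]) else NA_real_, numeric(1)),
          n_in_scope = vapply(strata, sum, numeric(1)),
          stringsAsFactors = FALSE)
        null_sites <- setdiff(names(calls), truth$site_id)
        if (length(null_sites))
          fps[[length(fps) + 1L]] <- data.frame(
            sim = i, framework = fw, cell_type = ct, threshold = thr,
            fp = sum(calls[null_sites]), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(tpr = do.call(rbind, tpr), fp = do.call(rbind, fps),
                 errors = errors, config = config),
            class = "spiked_benchmark")
}

#' Family-wise error rate calibrated thresholds
#'
#' For each framework/term, the calibrated threshold is the empirical
#' `rate` quantile (linear interpolation, quantile type 7) of the
#' per-simulation minimum p-values from a null benchmark - the permutation
#' estimate of the p-value cutoff controlling the family-wise error rate at
#' `rate`. The alternative estimator `method = "mean-quantile"` averages the
#' per-simulation `rate`-quantiles of the full p-value distribution.
#'
#' @param null_benchmark a [run_null_benchmark()] result.
#' @param rate target family-wise error rate (default 0.05).
#' @param method estimator (see above).
#' @return data.frame with `framework`, `cell_type`, `term`, `threshold`.
#' @export
fwer_threshold <- function(null_benchmark, rate = 0.05,
                           method = c("min-p-quantile", "mean-quantile")) {
  method <- match.arg(method)
  mp <- null_benchmark$min_p
  if (length(unique(mp$sim)) < 20)
    stop("family-wise error calibration needs at least 20 null simulations")
  key <- interaction(mp$framework, mp$cell_type, mp$term, drop = TRUE)
  out <- do.call(rbind, lapply(split(mp, key), function(d) {
    thr <- if (method == "min-p-quantile")
      unname(quantile(d$min_p, rate, type = 7)) else mean(d$q_rate_p)
    data.frame(framework = d$framework[1], cell_type = d$cell_type[1],
               term = d$term[1], threshold = thr, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Summarize a benchmark into tidy mean/SD tables
#'
#' @param outcome a `null_benchmark` or `spiked_benchmark`.
#' @return long-format data.frame of means and SDs per framework x
#'   cell type x term/stratum x threshold (SD is `NA` with one simulation).
#' @export
summarize_benchmark <- function(outcome) {
  if (inherits(outcome, "null_benchmark")) {
    d <- outcome$counts
    d$group <- interaction(d$framework, d$cell_type, d$term, d$threshold,
                           drop = TRUE)
    val <- "fp"
  } else if (inherits(outcome, "spiked_benchmark")) {
    d <- outcome$tpr
    d$group <- interaction(d$framework, d$cell_type, d$stratum, d$threshold,
                           drop = TRUE)
    val <- "tpr"
  } else stop("not a benchmark outcome")
  out <- do.call(rbind, lapply(split(d, d$group), function(g) {
    v <- g[[val]][!is.na(g[[val]])]
    cbind(g[1, setdiff(names(g), c("sim", val, "group", "n_in_scope")),
            drop = FALSE],
          data.frame(mean = if (length(v)) mean(v) else NA_real_,
                     sd = if (length(v) > 1) sd(v) else NA_real_,
                     n_sims = length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.null_benchmark <- function(x, ...) {
  cat(sprintf("Null benchmark: %d simulations x %d sites\n",
              x$config$n_simulations, x$n_sites))
  s <- summarize_benchmark(x)
  print(s[s$term %in% c("case", "main", "any"), ], row.names = FALSE,
        digits = 3)
  if (length(x$errors)) cat(length(x$errors), "simulation errors\n")
  invisible(x)
}

#' @export
print.spiked_benchmark <- function(x, ...) {
  cat(sprintf("Spiked benchmark: %d simulations, %d DMPs, delta = %g\n",
              x$config$n_simulations, x$config$n_dmps, x$config$delta))
  s <- summarize_benchmark(x)
  print(s[s$stratum == "all" & s$threshold == min(s$threshold), ],
        row.names = FALSE, digits = 3)
  if (length(x$errors)) cat(length(x$errors), "simulation errors\n")
  invisible(x)
}
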