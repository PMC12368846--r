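#' Configuration for a synthetic cell-sorted DNAm cohort
#'
#' Describes the statistical structure of a synthetic cohort of sorted-nuclei
#' DNAm profiles: which cell fractions are available and in what numbers, the
#' per-cell-type distribution of site-wise standard deviations, and how much
#' of each site's variance is attributable to a shared individual intercept.
#' The defaults mirror a large brain FANS study: three analysed fractions
#' (NeuNPos, Sox10Pos, DoubleNeg) with 182/168/164 samples and site-SD
#' distributions with means 0.036/0.038/0.057 and SDs 0.023/0.024/0.033 on
#' the beta (proportion) scale.
#'
#' @param n_individuals number of donors; each contributes at most one sample
#'   per cell type.
#' @param cell_types ordered character vector of cell-type labels.
#' @param availability per-cell-type sample counts; each must be at most
#'   `n_individuals`.
#' @param n_sites number of CpG sites to simulate.
#' @param sd_moments named list, one `(mean, sd)` pair per cell type, giving
#'   the moments of the site-SD distribution. SDs are drawn from a log-normal
#'   matched to these moments (the empirical distributions are right-skewed).
#' @param individual_variance_share fraction of per-site variance carried by
#'   an individual-level intercept shared across that donor's fractions; must
#'   lie in [0, 1).
#' @param age_range numeric length-2, donor age range in years.
#' @param n_brain_banks number of brain-bank levels.
#' @param celltype_site_fraction fraction of autosomal sites given a
#'   cell-type-specific mean offset (what makes fractions separable in PC
#'   space).
#' @param covariate_effects logical; if TRUE, small age and sex effects are
#'   added at 1\% of sites (for confounding experiments). Default FALSE:
#'   covariates enter the models but have no effect on methylation.
#' @param n_imprinted,n_snp,n_x_linked numbers of special-class sites used by
#'   the normalization metrics (imprinted regions ~0.5 in everyone, SNP-like
#'   probes with three genotype bands, X-linked sites that separate the
#'   sexes).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 200L,
                          cell_types = c("NeuNPos", "Sox10Pos", "DoubleNeg"),
                          availability = c(182L, 168L, 164L),
                          n_sites = 10000L,
                          sd_moments = list(NeuNPos = c(0.036, 0.023),
                                            Sox10Pos = c(0.038, 0.024),
                                            DoubleNeg = c(0.057, 0.033)),
                          individual_variance_share = 0.2,
                          age_range = c(18, 100),
                          n_brain_banks = 8L,
                          celltype_site_fraction = 0.2,
                          covariate_effects = FALSE,
                          n_imprinted = 30L, n_snp = 30L, n_x_linked = 30L,
                          seed = 1L) {
  if (n_individuals < 1L) stop_config("n_individuals must be at least 1")
  if (n_sites < 1L) stop_config("n_sites must be at least 1")
  if (length(availability) != length(cell_types))
    stop_config("availability must have one count per cell type")
  if (any(availability > n_individuals))
    stop_config("availability counts cannot exceed n_individuals")
  if (any(availability < 1L))
    stop_config("each cell type needs at least one sample")
  if (!setequal(names(sd_moments), cell_types))
    stop_config("sd_moments must be named by cell type")
  if (any(unlist(sd_moments) <= 0))
    stop_config("sd_moments must be strictly positive")
  if (individual_variance_share < 0 || individual_variance_share >= 1)
    stop_config("individual_variance_share must lie in [0, 1)")
  n_special <- n_imprinted + n_snp + n_x_linked
  if (n_special >= n_sites) {
    # tiny cohorts: drop special sites rather than fail
    n_imprinted <- n_snp <- n_x_linked <- 0L
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 cell_types = cell_types,
                 availability = setNames(as.integer(availability), cell_types),
                 n_sites = as.integer(n_sites),
                 sd_moments = sd_moments[cell_types],
                 individual_variance_share = individual_variance_share,
                 age_range = age_range,
                 n_brain_banks = as.integer(n_brain_banks),
                 celltype_site_fraction = celltype_site_fraction,
                 covariate_effects = isTRUE(covariate_effects),
                 n_imprinted = as.integer(n_imprinted),
                 n_snp = as.integer(n_snp),
                 n_x_linked = as.integer(n_x_linked),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# log-normal parameters matched to a target mean and SD
lnorm_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Draw a moment-matched log-normal site-SD profile
#'
#' @param n_sites number of sites.
#' @param mean,sd target mean and SD of the site-SD distribution.
#' @param seed optional RNG seed.
#' @return numeric vector of per-site SDs.
#' @export
lognormal_sd_profile <- function(n_sites, mean, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- lnorm_params(mean, sd)
  rlnorm(n_sites, meanlog = p["meanlog"], sdlog = p["sdlog"])
}

#' Generate a synthetic cell-sorted DNAm cohort
#'
#' Simulates a beta matrix (sites x samples), a sample sheet and a site
#' annotation with the structure cell-sorted EWAS analyses assume: per-site
#' baseline means from a hypo/intermediate/hyper mixture with
#' cell-type-specific offsets at a subset of sites; per-site SDs from a
#' log-normal matched to the configured moments; and a donor-level intercept
#' shared across all of a donor's fractions, so that samples from the same
#' individual are correlated. Values are clamped to [0, 1].
#'
#' Per-site SDs are rank-coupled to the baseline means (sites near the 0/1
#' boundaries receive the smaller SD draws, with jitter), reproducing the
#' variance-mean relationship of bounded methylation data while leaving the
#' marginal SD distribution exactly the moment-matched log-normal.
#'
#' @param config a [cohort_config()].
#' @return an object of class `sorted_cohort`: a list with elements `beta`
#'   (matrix, sites x samples), `sheet` (data.frame sample sheet with
#'   phenotype "unassigned"), `annotation` (data.frame of site classes) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_config("config must be a cohort_config")
  set.seed(config$seed)
  cts <- config$cell_types
  nI <- config$n_individuals
  nS <- config$n_sites
  share <- config$individual_variance_share

  individuals <- sprintf("ind%03d", seq_len(nI))
  age <- round(runif(nI, config$age_range[1], config$age_range[2]))
  sex <- sample(c("F", "M"), nI, replace = TRUE)
  bank <- sample(sprintf("bank%d", seq_len(config$n_brain_banks)), nI,
                 replace = TRUE)

  sheet <- do.call(rbind, lapply(cts, function(ct) {
    idx <- sort(sample.int(nI, config$availability[[ct]]))
    data.frame(sample_id = paste(individuals[idx], ct, sep = "_"),
               individual_id = individuals[idx],
               cell_type = ct,
               age = age[idx], sex = sex[idx], brain_bank = bank[idx],
               phenotype = "unassigned",
               stringsAsFactors = FALSE)
  }))
  rownames(sheet) <- NULL

  site_ids <- sprintf("cg%07d", seq_len(nS))
  site_class <- rep("autosomal", nS)
  n_special <- config$n_imprinted + config$n_snp + config$n_x_linked
  if (n_special > 0) {
    special <- sample.int(nS, n_special)
    site_class[special[seq_len(config$n_imprinted)]] <- "imprinted_dmr"
    site_class[special[config$n_imprinted + seq_len(config$n_snp)]] <- "snp_probe"
    site_class[special[config$n_imprinted + config$n_snp +
                         seq_len(config$n_x_linked)]] <- "x_linked"
  }

  # baseline mean mixture: hypo / intermediate / hyper methylated sites
  comp <- sample.int(3L, nS, replace = TRUE, prob = c(0.35, 0.30, 0.35))
  base_m <- numeric(nS)
  base_m[comp == 1L] <- runif(sum(comp == 1L), 0.06, 0.16)
  base_m[comp == 2L] <- runif(sum(comp == 2L), 0.35, 0.65)
  base_m[comp == 3L] <- runif(sum(comp == 3L), 0.84, 0.94)

  # cell-type-specific offsets at a fraction of autosomal sites; the NeuN
  # analogue (first cell type) is the most distinct fraction, as in sorted
  # brain data where the primary axis separates NeuN+ from NeuN- nuclei
  m <- matrix(base_m, nS, length(cts), dimnames = list(site_ids, cts))
  structured <- which(site_class == "autosomal" &
                        runif(nS) < config$celltype_site_fraction)
  if (length(structured) && length(cts) > 1) {
    probs <- rep(0.4 / (length(cts) - 1), length(cts))
    probs[1] <- 0.6
    off_ct <- sample(seq_along(cts), length(structured), replace = TRUE,
                     prob = probs)
    # the NeuN analogue diverges most and hardest (the primary axis of
    # sorted brain DNAm separates NeuN+ from NeuN- nuclei, with large,
    # hypomethylation-biased neuronal differences), so its offsets are
    # bigger, commoner and directionally skewed - its marginal value
    # distribution, not just individual sites, is distinct
    dir <- ifelse(off_ct == 1L,
                  sample(c(-1, 1), length(structured), TRUE, prob = c(0.72, 0.28)),
                  sample(c(-1, 1), length(structured), TRUE))
    off <- dir * ifelse(off_ct == 1L, runif(length(structured), 0.20, 0.50),
                        runif(length(structured), 0.18, 0.40))
    m[cbind(structured, off_ct)] <-
      pmin(0.97, pmax(0.03, m[cbind(structured, off_ct)] + off))
  }

  # per-cell-type site SDs: log-normal draws, rank-coupled to mean extremity
  sigma <- matrix(0, nS, length(cts), dimnames = list(site_ids, cts))
  for (ct in cts) {
    p <- lnorm_params(config$sd_moments[[ct]][1], config$sd_moments[[ct]][2])
    draws <- sort(rlnorm(nS, p["meanlog"], p["sdlog"]))
    ext <- pmin(m[, ct], 1 - m[, ct])
    key <- ext + rnorm(nS, 0, 0.15 * sd(ext))
    sigma[order(key), ct] <- draws
  }
  # special classes carry their own tight noise scales
  sigma[site_class == "imprinted_dmr", ] <- 0.02
  sigma[site_class == "snp_probe", ] <- 0.015
  sigma[site_class == "x_linked", ] <- 0.03
  m[site_class == "imprinted_dmr", ] <- 0.5

  # SNP-like probes: individual-level genotype bands at {0.03, 0.5, 0.97}
  snp_rows <- which(site_class == "snp_probe")
  geno_centres <- c(0.03, 0.5, 0.97)
  geno <- NULL
  if (length(snp_rows))
    geno <- matrix(sample.int(3L, length(snp_rows) * nI, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)),
                   length(snp_rows), nI)

  # X-linked sites: X-inactivation pushes female values to ~0.5; a subset
  # is strongly sex-differential (males ~0.15), the rest near 0.5 in both
  # sexes, so that sex is a visible but not dominant axis of variation
  x_rows <- which(site_class == "x_linked")
  x_diff <- rep(FALSE, nS)
  x_diff[x_rows[seq_len(ceiling(length(x_rows) / 3))]] <- TRUE

  # optional small covariate effects at 1% of autosomal sites
  cov_rows <- integer(0)
  age_eff <- sex_eff <- NULL
  if (config$covariate_effects) {
    cov_rows <- which(site_class == "autosomal" & runif(nS) < 0.01)
    age_eff <- rnorm(length(cov_rows), 0, 0.0005)  # per year
    sex_eff <- rnorm(length(cov_rows), 0, 0.02)
  }

  z_ind <- matrix(rnorm(nS * nI), nS, nI)  # shared standardized donor factor

  beta <- matrix(NA_real_, nS, nrow(sheet),
                 dimnames = list(site_ids, sheet$sample_id))
  for (ct in cts) {
    cols <- which(sheet$cell_type == ct)
    idx <- match(sheet$individual_id[cols], individuals)
    sig <- sigma[, ct]
    vals <- m[, ct] +
      sqrt(share) * sig * z_ind[, idx, drop = FALSE] +
      sqrt(1 - share) * sig * matrix(rnorm(nS * length(cols)), nS)
    if (length(x_rows)) {
      is_m <- sheet$sex[cols] == "M"
      xmean <- matrix(0.5, length(x_rows), length(cols))
      xmean[x_diff[x_rows], is_m] <- 0.15
      vals[x_rows, ] <- xmean +
        sqrt(share) * 0.03 * z_ind[x_rows, idx, drop = FALSE] +
        sqrt(1 - share) * 0.03 * matrix(rnorm(length(x_rows) * length(cols)),
                                        length(x_rows))
    }
    if (length(snp_rows)) {
      vals[snp_rows, ] <- geno_centres[geno[, idx, drop = FALSE]] +
        matrix(rnorm(length(snp_rows) * length(cols), 0, 0.015),
               length(snp_rows))
    }
    if (length(cov_rows)) {
      vals[cov_rows, ] <- vals[cov_rows, ] +
        outer(age_eff, sheet$age[cols] - mean(config$age_range)) +
        outer(sex_eff, as.numeric(sheet$sex[cols] == "M"))
    }
    beta[, cols] <- vals
  }
  beta <- clamp01(beta)

  annotation <- data.frame(site_id = site_ids, site_class = site_class,
                           baseline_mean = base_m, stringsAsFactors = FALSE)
  structure(list(beta = beta, sheet = sheet, annotation = annotation,
                 config = config),
            class = "sorted_cohort")
}

#' @export
print.sorted_cohort <- function(x, ...) {
  cat("Synthetic cell-sorted DNAm cohort\n")
  cat(sprintf("  %d sites x %d samples (%d individuals)\n",
              nrow(x$beta), ncol(x$beta),
              length(unique(x$sheet$individual_id))))
  tab <- table(x$sheet$cell_type)[x$config$cell_types]
  cat("  samples per cell type: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  individual variance share: %.2f; seed: %d\n",
              x$config$individual_variance_share, x$config$seed))
  invisible(x)
}

#' Assign a case/control phenotype at the individual level
#'
#' All fractions belonging to the same donor receive the same label, so the
#' phenotype is constant within individual (a requirement for the clustered
#' analyses to be meaningful).
#'
#' @param sheet a sample sheet with phenotype "unassigned".
#' @param case_fraction probability that an individual is a case.
#' @param seed integer RNG seed.
#' @return the sheet with `phenotype` filled in ("case"/"control").
#' @export
assign_phenotype <- function(sheet, case_fraction = 0.5, seed = 1L) {
  assert_sheet(sheet)
  if (case_fraction < 0 || case_fraction > 1)
    stop_config("case_fraction must lie in [0, 1]")
  if (!all(sheet$phenotype == "unassigned"))
    stop("phenotype already assigned; start from an unassigned sheet")
  set.seed(as.integer(seed))
  inds <- unique(sheet$individual_id)
  is_case <- setNames(runif(length(inds)) < case_fraction, inds)
  sheet$phenotype <- ifelse(is_case[sheet$individual_id], "case", "control")
  sheet
}

#' Spike differentially methylated positions into a cohort
#'
#' Adds a fixed case-control mean difference `delta` at a random subset of
#' sites. A proportion `prop_specific` of the spiked DMPs affect a single,
#' uniformly chosen cell type; the remainder are common to all cell types.
#' `delta` is added to case samples of the affected cell types only, then
#' values are clamped to [0, 1].
#'
#' @param beta beta matrix (sites x samples).
#' @param sheet sample sheet with assigned phenotype.
#' @param n_dmps number of DMPs to introduce.
#' @param prop_specific proportion of DMPs specific to one cell type.
#' @param delta case-control difference on the proportion scale (> 0).
#' @param seed integer RNG seed.
#' @return list with `beta` (modified matrix) and `truth`, a data.frame with
#'   columns `site_id`, `affected_cell_types` (comma-separated) and `delta`.
#' @export
spike_dmps <- function(beta, sheet, n_dmps, prop_specific = 0.5,
                       delta = 0.05, seed = 1L) {
  sheet <- align_beta_sheet(beta, sheet)
  assert_sheet(sheet, need_phenotype = TRUE)
  if (delta <= 0 || delta > 1) stop_config("delta must lie in (0, 1]")
  if (n_dmps > nrow(beta)) stop_config("n_dmps cannot exceed the site count")
  truth <- data.frame(site_id = character(0), affected_cell_types = character(0),
                      delta = numeric(0), stringsAsFactors = FALSE)
  if (n_dmps == 0) return(list(beta = beta, truth = truth))
  set.seed(as.integer(seed))
  cts <- unique(sheet$cell_type)
  sites <- sample.int(nrow(beta), n_dmps)
  n_spec <- round(n_dmps * prop_specific)
  affected <- character(n_dmps)
  if (n_spec > 0)
    affected[seq_len(n_spec)] <- sample(cts, n_spec, replace = TRUE)
  if (n_spec < n_dmps)
    affected[(n_spec + 1):n_dmps] <- paste(cts, collapse = ",")
  case_cols <- sheet$phenotype == "case"
  for (k in seq_len(n_dmps)) {
    hit <- case_cols & sheet$cell_type %in% strsplit(affected[k], ",")[[1]]
    beta[sites[k], hit] <- clamp01(beta[sites[k], hit] + delta)
  }
  truth <- data.frame(site_id = rownames(beta)[sites],
                      affected_cell_types = affected,
                      delta = delta, stringsAsFactors = FALSE)
  list(beta = beta, truth = truth)
}

#' Does a spiked DMP affect a given cell type?
#'
#' @param truth truth table from [spike_dmps()].
#' @param cell_type cell-type label.
#' @return logical vector over truth rows.
#' @export
truth_affects <- function(truth, cell_type) {
  vapply(strsplit(truth$affected_cell_types, ","),
         function(x) cell_type %in% x, logical(1))
}

#' Inject sorting failures into a cohort
#'
#' Emulates the two failure modes of fluorescence-activated nuclei sorting
#' that quality control must catch: mislabelled samples (tube swaps - two
#' fractions of the same donor exchange their cell-type labels while the
#' values are untouched) and mixture samples (incomplete isolation - a
#' sample's values are replaced by a convex combination of its own profile
#' and the mean profile of a different cell type).
#'
#' @param beta beta matrix.
#' @param sheet sample sheet.
#' @param n_mislabelled number of mislabelled samples (rounded up to an even
#'   count, since labels are exchanged in within-donor pairs).
#' @param n_mixture number of mixture samples.
#' @param mix_fraction mixing fraction in (0, 1].
#' @param seed integer RNG seed.
#' @return list with `beta`, `sheet` and `truth` (data.frame: `sample_id`,
#'   `failure_kind`, `detail` = true cell type or mixing fraction).
#' @export
inject_sort_failures <- function(beta, sheet, n_mislabelled = 0L,
                                 n_mixture = 0L, mix_fraction = 0.5,
                                 seed = 1L) {
  sheet <- align_beta_sheet(beta, sheet)
  if (mix_fraction <= 0 || mix_fraction > 1)
    stop_config("mix_fraction must lie in (0, 1]")
  truth <- data.frame(sample_id = character(0), failure_kind = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  if (n_mislabelled == 0 && n_mixture == 0)
    return(list(beta = beta, sheet = sheet, truth = truth))
  set.seed(as.integer(seed))
  cts <- unique(sheet$cell_type)

  if (n_mislabelled > 0) {
    n_pairs <- ceiling(n_mislabelled / 2)
    multi <- names(which(table(sheet$individual_id) >= 2))
    if (length(multi) < n_pairs)
      stop_config("not enough multi-fraction individuals to mislabel")
    for (ind in sample(multi, n_pairs)) {
      rows <- which(sheet$individual_id == ind)
      pick <- sample(rows, 2)
      lab <- sheet$cell_type[pick]
      sheet$cell_type[pick] <- rev(lab)
      truth <- rbind(truth, data.frame(
        sample_id = sheet$sample_id[pick],
        failure_kind = "mislabelled", detail = lab,
        stringsAsFactors = FALSE))
    }
  }

  if (n_mixture > 0) {
    clean <- setdiff(sheet$sample_id, truth$sample_id)
    if (n_mixture > length(clean))
      stop_config("n_mixture exceeds available samples")
    ct_means <- sapply(cts, function(ct)
      rowMeans(beta[, sheet$sample_id[sheet$cell_type == ct], drop = FALSE]))
    for (sid in sample(clean, n_mixture)) {
      own_ct <- sheet$cell_type[sheet$sample_id == sid]
      other <- sample(setdiff(cts, own_ct), 1)
      beta[, sid] <- (1 - mix_fraction) * beta[, sid] +
        mix_fraction * ct_means[, other]
      truth <- rbind(truth, data.frame(
        sample_id = sid, failure_kind = "mixture",
        detail = sprintf("%s:%g", other, mix_fraction),
        stringsAsFactors = FALSE))
    }
  }
  rownames(truth) <- NULL
  list(beta = beta, sheet = sheet, truth = truth)
}
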