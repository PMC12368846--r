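test_that("degenerate configurations are rejected", {
  expect_config_error(cohort_config(n_sites = 0))
  expect_config_error(cohort_config(n_individuals = 0))
  expect_config_error(cohort_config(n_individuals = 100,
                                    availability = c(182, 168, 164)))
  expect_config_error(cohort_config(individual_variance_share = 1))
  expect_config_error(cohort_config(sd_moments = list(
    NeuNPos = c(0, 0.02), Sox10Pos = c(0.04, 0.02),
    DoubleNeg = c(0.04, 0.02))))
})

test_that("generation is deterministic given the seed", {
  a <- small_cohort(seed = 42)
  b <- small_cohort(seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sheet, b$sheet)
  expect_false(identical(a$beta, small_cohort(seed = 43)$beta))
})

test_that("site-SD distributions match the configured moments", {
  coh <- generate_cohort(cohort_config(n_sites = 5000, seed = 7))
  auto <- coh$annotation$site_class == "autosomal"
  targets <- coh$config$sd_moments
  for (ct in coh$config$cell_types) {
    sds <- apply(coh$beta[auto, coh$sheet$sample_id[coh$sheet$cell_type == ct]],
                 1, sd)
    expect_lt(abs(mean(sds) - targets[[ct]][1]), 0.1 * targets[[ct]][1])
    expect_lt(abs(sd(sds) - targets[[ct]][2]), 0.2 * targets[[ct]][2])
  }
})

test_that("clamping at the [0,1] boundary is rare under defaults", {
  coh <- generate_cohort(cohort_config(n_sites = 5000, seed = 7))
  expect_lt(mean(coh$beta == 0 | coh$beta == 1), 0.01)
  expect_true(all(coh$beta >= 0 & coh$beta <= 1))
  expect_false(anyNA(coh$beta))
})

test_that("sample sheet invariants hold", {
  coh <- study_cohort(n_sites = 50, seed = 3)
  sh <- coh$sheet
  expect_false(anyDuplicated(paste(sh$individual_id, sh$cell_type)) > 0)
  per_ind <- split(sh[, c("age", "sex", "brain_bank")], sh$individual_id)
  expect_true(all(vapply(per_ind, function(d) nrow(unique(d)) == 1,
                         logical(1))))
  expect_identical(colnames(coh$beta), sh$sample_id)
  expect_equal(unname(table(sh$cell_type)[coh$config$cell_types]),
               c(182L, 168L, 164L), ignore_attr = TRUE)
})

test_that("the shared individual intercept induces the configured cross-fraction correlation", {
  coh <- generate_cohort(cohort_config(n_sites = 1500, seed = 8))
  sh <- coh$sheet
  auto <- coh$annotation$site_class == "autosomal"
  b1 <- coh$beta[auto, sh$cell_type == "NeuNPos"]
  b2 <- coh$beta[auto, sh$cell_type == "Sox10Pos"]
  i1 <- sh$individual_id[sh$cell_type == "NeuNPos"]
  i2 <- sh$individual_id[sh$cell_type == "Sox10Pos"]
  both <- intersect(i1, i2)
  r1 <- b1[, match(both, i1)] - rowMeans(b1)
  r2 <- b2[, match(both, i2)] - rowMeans(b2)
  # mean over sites of the across-individual correlation of residuals
  rs <- sapply(seq_len(nrow(r1)), function(s) cor(r1[s, ], r2[s, ]))
  expect_lt(abs(mean(rs) - coh$config$individual_variance_share), 0.04)
})

test_that("phenotype assignment is individual-level with binomial case counts", {
  coh <- study_cohort(n_sites = 30, seed = 5)
  sh0 <- assign_phenotype(coh$sheet, 0, seed = 1)
  expect_true(all(sh0$phenotype == "control"))
  sh <- assign_phenotype(coh$sheet, 0.5, seed = 9)
  per_ind <- tapply(sh$phenotype, sh$individual_id,
                    function(x) length(unique(x)))
  expect_true(all(per_ind == 1))
  n_case <- sum(tapply(sh$phenotype, sh$individual_id, `[`, 1) == "case")
  n_ind <- length(unique(sh$individual_id))
  # binomial 99% interval oracle
  expect_gte(n_case, qbinom(0.005, n_ind, 0.5))
  expect_lte(n_case, qbinom(0.995, n_ind, 0.5))
  expect_config_error(assign_phenotype(coh$sheet, 1.5, 1))
  expect_error(assign_phenotype(sh, 0.5, 1), "already assigned")
})

test_that("spiked DMPs carry the requested effect structure", {
  coh <- study_cohort(n_sites = 800, seed = 11)
  sheet <- assign_phenotype(coh$sheet, 0.5, 2)
  none <- spike_dmps(coh$beta, sheet, 0, seed = 1)
  expect_identical(none$beta, coh$beta)
  expect_equal(nrow(none$truth), 0)

  sp1 <- spike_dmps(coh$beta, sheet, 50, prop_specific = 1, delta = 0.05,
                    seed = 3)
  expect_true(all(!grepl(",", sp1$truth$affected_cell_types)))
  expect_false(anyDuplicated(sp1$truth$site_id) > 0)

  expect_config_error(spike_dmps(coh$beta, sheet, 10, delta = 0))
  expect_config_error(spike_dmps(coh$beta, sheet, 10000, delta = 0.05))
  expect_error(spike_dmps(coh$beta, coh$sheet, 10, delta = 0.05),
               "phenotype")

  # group-mean oracle on common DMPs at mid-methylation sites (no clamping)
  sp <- spike_dmps(coh$beta, sheet, 120, prop_specific = 0, delta = 0.05,
                   seed = 4)
  mid <- coh$annotation$site_id[coh$annotation$site_class == "autosomal" &
                                  coh$annotation$baseline_mean > 0.3 &
                                  coh$annotation$baseline_mean < 0.7]
  use <- intersect(sp$truth$site_id, mid)
  diffs <- sapply(unique(sheet$cell_type), function(ct) {
    cols_case <- sheet$sample_id[sheet$cell_type == ct &
                                   sheet$phenotype == "case"]
    cols_ctrl <- sheet$sample_id[sheet$cell_type == ct &
                                   sheet$phenotype == "control"]
    mean(rowMeans(sp$beta[use, cols_case]) -
           rowMeans(sp$beta[use, cols_ctrl]))
  })
  expect_true(all(abs(diffs - 0.05) < 0.01))
})

test_that("per-cell-type OLS recovers the spiked effect with small bias", {
  coh <- study_cohort(n_sites = 800, seed = 21)
  sheet <- assign_phenotype(coh$sheet, 0.5, 6)
  sp <- spike_dmps(coh$beta, sheet, 150, prop_specific = 0, delta = 0.05,
                   seed = 7)
  for (ct in c("NeuNPos", "DoubleNeg")) {
    f <- ewas_fit(sp$beta, sheet, "ctlr", cell_type = ct,
                  sites = sp$truth$site_id)
    expect_lt(abs(mean(f$results$estimate) - 0.05), 0.005)
  }
})

test_that("sorting failures are injected as specified", {
  coh <- small_cohort(n_sites = 500, seed = 31)
  id0 <- inject_sort_failures(coh$beta, coh$sheet, 0, 0)
  expect_identical(id0$beta, coh$beta)
  expect_identical(id0$sheet, coh$sheet)

  inj <- inject_sort_failures(coh$beta, coh$sheet, n_mislabelled = 4,
                              n_mixture = 3, mix_fraction = 0.5, seed = 2)
  expect_config_error(inject_sort_failures(coh$beta, coh$sheet,
                                           n_mixture = 1, mix_fraction = 0))
  mixed <- inj$truth$sample_id[inj$truth$failure_kind == "mixture"]
  expect_true(all(inj$beta[, mixed] >= 0 & inj$beta[, mixed] <= 1))

  # mislabelled samples keep their original values: correlation to the TRUE
  # cell type's mean profile beats the labelled one
  mis <- inj$truth[inj$truth$failure_kind == "mislabelled", ]
  ct_means <- sapply(unique(coh$sheet$cell_type), function(ct)
    rowMeans(coh$beta[, coh$sheet$sample_id[coh$sheet$cell_type == ct]]))
  for (k in seq_len(nrow(mis))) {
    sid <- mis$sample_id[k]
    true_ct <- mis$detail[k]
    lab_ct <- inj$sheet$cell_type[inj$sheet$sample_id == sid]
    expect_gt(cor(inj$beta[, sid], ct_means[, true_ct]),
              cor(inj$beta[, sid], ct_means[, lab_ct]))
  }
})
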