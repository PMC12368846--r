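assigned_cohort <- function(n_sites = 300, seed = 1, pheno_seed = 2, ...) {
  coh <- study_cohort(n_sites = n_sites, seed = seed, ...)
  list(beta = coh$beta,
       sheet = assign_phenotype(coh$sheet, 0.5, pheno_seed),
       cohort = coh)
}

test_that("vectorized ctlr equals naive per-site lm", {
  ac <- assigned_cohort(40, seed = 3)
  f <- ewas_fit(ac$beta, ac$sheet, "ctlr", cell_type = "NeuNPos")
  sub <- ac$sheet[ac$sheet$cell_type == "NeuNPos", ]
  for (i in seq_len(20)) {
    m <- lm(ac$beta[i, sub$sample_id] ~ I(phenotype == "case") + age +
              sex + brain_bank, data = sub)
    co <- summary(m)$coefficients
    expect_equal(f$results$estimate[i], unname(co[2, 1]), tolerance = 1e-10)
    expect_equal(f$results$se[i], unname(co[2, 2]), tolerance = 1e-10)
    expect_equal(f$results$p[i], unname(co[2, 4]), tolerance = 1e-10)
  }
})

test_that("vectorized alllr equals naive per-site interaction lm", {
  ac <- assigned_cohort(25, seed = 4)
  f <- ewas_fit(ac$beta, ac$sheet, "alllr")
  d <- ac$sheet
  d$case <- as.numeric(d$phenotype == "case")
  d$cell_type <- factor(d$cell_type)  # DoubleNeg is the alphabetical reference
  for (i in c(1, 7, 19)) {
    m <- lm(ac$beta[i, d$sample_id] ~ case * cell_type + age + sex +
              brain_bank, data = d)
    co <- summary(m)$coefficients
    expect_equal(f$results$main_beta[i], unname(co["case", 1]),
                 tolerance = 1e-10)
    expect_equal(f$results$int_NeuNPos_p[i],
                 unname(co["case:cell_typeNeuNPos", 4]), tolerance = 1e-9)
    expect_equal(f$results$int_Sox10Pos_beta[i],
                 unname(co["case:cell_typeSox10Pos", 1]), tolerance = 1e-10)
  }
})

test_that("degenerate designs and sites are reported, not silently dropped", {
  ac <- assigned_cohort(30, seed = 5)
  beta <- ac$beta
  beta[3, ac$sheet$sample_id[ac$sheet$cell_type == "NeuNPos"]] <- 0.5
  f <- ewas_fit(beta, ac$sheet, "ctlr", cell_type = "NeuNPos")
  expect_false(f$results$converged[3])
  expect_true(is.na(f$results$p[3]))
  expect_equal(nrow(f$results), nrow(beta))  # row retained

  sheet2 <- ac$sheet
  sheet2$brain_bank <- sheet2$sex  # perfectly collinear with sex
  expect_error(ewas_fit(ac$beta, sheet2, "ctlr", cell_type = "NeuNPos"),
               "collinear")
})

test_that("ctlr is calibrated under the null and recovers spiked effects", {
  ac <- assigned_cohort(3000, seed = 6, pheno_seed = 7)
  f <- ewas_fit(ac$beta, ac$sheet, "ctlr", cell_type = "NeuNPos")
  expect_gt(stats::ks.test(f$results$p, "punif")$p.value, 0.001)

  sp <- spike_dmps(ac$beta, ac$sheet, 60, prop_specific = 0, delta = 0.05,
                   seed = 8)
  fs <- ewas_fit(sp$beta, ac$sheet, "ctlr", cell_type = "NeuNPos",
                 sites = sp$truth$site_id)
  ci_ok <- abs(fs$results$estimate - 0.05) <= 1.96 * fs$results$se
  expect_gt(mean(ci_ok), 0.9)
})

test_that("alllr main effect is calibrated without clustering or heteroskedasticity", {
  coh <- generate_cohort(cohort_config(n_sites = 3000,
                                       sd_moments = flat_moments(),
                                       individual_variance_share = 0,
                                       seed = 15))
  sheet <- assign_phenotype(coh$sheet, 0.5, 115)
  f <- ewas_fit(coh$beta, sheet, "alllr")
  expect_gt(stats::ks.test(f$results$main_p, "punif")$p.value, 0.001)
})

test_that("alllr inflates false positives on correlated cohorts relative to ctlr", {
  fp <- sapply(1:6, function(s) {
    coh <- generate_cohort(cohort_config(n_sites = 2500, seed = 400 + s))
    sheet <- assign_phenotype(coh$sheet, 0.5, 500 + s)
    p_ct <- unlist(lapply(unique(sheet$cell_type), function(ct)
      ewas_fit(coh$beta, sheet, "ctlr", cell_type = ct)$results$p))
    p_all <- ewas_fit(coh$beta, sheet, "alllr")$results$main_p
    c(ctlr = sum(p_ct < 1e-3) / 3, alllr = sum(p_all < 1e-3))
  })
  expect_gt(sum(fp["alllr", ]), sum(fp["ctlr", ]))
})

test_that("interaction terms recover cell-specific effects", {
  ac <- assigned_cohort(400, seed = 9, pheno_seed = 10)
  # spike only NeuNPos (non-reference under alphabetical coding)
  sheet <- ac$sheet
  sp_sites <- rownames(ac$beta)[1:40]
  beta <- ac$beta
  hit <- sheet$phenotype == "case" & sheet$cell_type == "NeuNPos"
  beta[sp_sites, hit] <- pmin(beta[sp_sites, hit] + 0.05, 1)
  f <- ewas_fit(beta, sheet, "alllr", sites = sp_sites)
  expect_lt(abs(mean(f$results$int_NeuNPos_beta) - 0.05), 0.01)
  expect_lt(abs(mean(f$results$main_beta)), 0.01)
  # per-cell-type effect contrasts agree
  expect_equal(f$results$eff_NeuNPos_beta,
               f$results$main_beta + f$results$int_NeuNPos_beta)
})

test_that("cluster-robust engine matches sandwich::vcovCL and degenerates to HC1", {
  ac <- assigned_cohort(12, seed = 11)
  f <- ewas_fit(ac$beta, ac$sheet, "crr")
  d <- ac$sheet
  d$case <- as.numeric(d$phenotype == "case")
  d$cell_type <- factor(d$cell_type)
  for (i in c(2, 9)) {
    m <- lm(ac$beta[i, d$sample_id] ~ case * cell_type + age + sex +
              brain_bank, data = d)
    V <- sandwich::vcovCL(m, cluster = d$individual_id, type = "HC1",
                          cadjust = TRUE)
    expect_equal(f$results$main_se[i], sqrt(V["case", "case"]),
                 tolerance = 1e-8)
    expect_equal(f$results$int_NeuNPos_se[i],
                 sqrt(V["case:cell_typeNeuNPos", "case:cell_typeNeuNPos"]),
                 tolerance = 1e-8)
  }
  expect_equal(f$results$main_beta,
               ewas_fit(ac$beta, ac$sheet, "alllr")$results$main_beta)

  # every sample its own cluster: CR1 collapses to HC1 heteroskedasticity SEs
  one_per <- ac$sheet[!duplicated(ac$sheet$individual_id), ]
  one_per$cell_type <- rep(c("A", "B"), length.out = nrow(one_per))
  one_per$individual_id <- one_per$sample_id  # singleton clusters
  bsub <- ac$beta[1:5, one_per$sample_id]
  fc <- ewas_fit(bsub, one_per, "crr")
  d2 <- one_per
  d2$case <- as.numeric(d2$phenotype == "case")
  d2$cell_type <- factor(d2$cell_type)
  m2 <- lm(bsub[1, ] ~ case * cell_type + age + sex + brain_bank, data = d2)
  V2 <- sandwich::vcovHC(m2, type = "HC1")
  expect_equal(fc$results$main_se[1], sqrt(V2["case", "case"]),
               tolerance = 1e-8)
})

test_that("mixed model collapses to OLS when the variance ratio is zero", {
  coh <- generate_cohort(cohort_config(n_sites = 40,
                                       individual_variance_share = 0,
                                       seed = 13))
  sheet <- assign_phenotype(coh$sheet, 0.5, 14)
  fa <- ewas_fit(coh$beta, sheet, "alllr")
  fm <- ewas_fit(coh$beta, sheet, "mer", refine = "brent")
  expect_true(all(fm$results$sigma_u2 >= 0))
  boundary <- fm$results$sigma_u2 == 0
  expect_gt(sum(boundary), 0)
  expect_equal(fm$results$main_beta[boundary],
               fa$results$main_beta[boundary], tolerance = 1e-6)
  # REML noise keeps the rest near, if not at, the OLS solution
  expect_lt(max(abs(fm$results$main_beta - fa$results$main_beta)), 1e-3)
})

test_that("mixed model recovers the individual variance component", {
  ac <- assigned_cohort(150, seed = 16, pheno_seed = 17)
  fm <- ewas_fit(ac$beta, ac$sheet, "mer")
  expect_true(all(fm$results$sigma_u2 >= 0))
  share_hat <- fm$results$sigma_u2 /
    (fm$results$sigma_u2 + fm$results$sigma_e2)
  expect_lt(abs(median(share_hat) - 0.2), 0.08)
})

test_that("significance calls respect the term policy", {
  ac <- assigned_cohort(200, seed = 18, pheno_seed = 19)
  sp <- spike_dmps(ac$beta, ac$sheet, 50, prop_specific = 0.5,
                   delta = 0.08, seed = 20)
  f <- ewas_fit(sp$beta, ac$sheet, "crr")
  any_t <- call_significant(f, 1e-4, "any-term")
  main_o <- call_significant(f, 1e-4, "main-only")
  joint <- call_significant(f, 1e-4, "joint-test")
  expect_true(all(names(any_t)[main_o] %in% names(any_t)[any_t]))
  expect_gte(sum(any_t), sum(main_o))
  expect_error(call_significant(f, 1e-4, "bogus"))
  expect_config_error(call_significant(f, 2))
  # all p = 1 can never be called
  f2 <- f
  f2$results[, grep("_p$", names(f2$results))] <- 1
  expect_equal(sum(call_significant(f2, 9e-8)), 0)
  # non-converged sites are never called
  f3 <- f
  f3$results$converged[1] <- FALSE
  f3$results$main_p[1] <- NA
  int_cols <- grep("^int_.*_p$", names(f3$results))
  f3$results[1, int_cols] <- NA
  expect_false(call_significant(f3, 0.999)[1])
})
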