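make_pcs <- function(scores, ids = sprintf("s%02d", seq_len(nrow(scores)))) {
  structure(list(sample_ids = ids, scores = scores,
                 explained_variance = rev(sort(apply(scores, 2, var))) /
                   sum(apply(scores, 2, var))),
            class = "pc_scores")
}

make_sheet <- function(ids, cts, inds = ids) {
  data.frame(sample_id = ids, individual_id = inds, cell_type = cts,
             age = 50, sex = "F", brain_bank = "b1",
             phenotype = "unassigned", stringsAsFactors = FALSE)
}

test_that("principal components have the contracted structure", {
  coh <- small_cohort(n_sites = 600, seed = 2)
  pcs <- compute_pcs(coh$beta, 5)
  expect_true(all(diff(pcs$explained_variance) <= 1e-12))
  expect_true(all(abs(colMeans(pcs$scores)) < 1e-8))
  expect_error(compute_pcs(matrix(0.5, 10, 4,
                                  dimnames = list(paste0("s", 1:10),
                                                  paste0("x", 1:4))), 2),
               "degenerate")
})

test_that("scores and distances are invariant to site/sample order and scaling", {
  coh <- small_cohort(n_sites = 300, seed = 3)
  beta <- coh$beta
  sheet <- coh$sheet
  z0 <- run_stage3(beta, sheet)$samples
  perm_sites <- sample(nrow(beta))
  perm_samp <- sample(ncol(beta))
  z1 <- run_stage3(beta[perm_sites, perm_samp], sheet)$samples
  z1 <- z1[match(z0$sample_id, z1$sample_id), ]
  expect_equal(abs(z0$z_pc1), abs(z1$z_pc1), tolerance = 1e-6)
  expect_equal(z0$retained, z1$retained)
  z2 <- run_stage3(beta * 0.5, sheet)$samples
  expect_equal(abs(z0$z_pc1), abs(z2$z_pc1), tolerance = 1e-6)
})

test_that("nearest-centroid assignment in PC space recovers cell-type labels", {
  coh <- study_cohort(n_sites = 1000, seed = 4)
  pcs <- compute_pcs(coh$beta, 2)
  ct <- coh$sheet$cell_type[match(pcs$sample_ids, coh$sheet$sample_id)]
  cts <- unique(ct)
  cen <- sapply(cts, function(c) colMeans(pcs$scores[ct == c, , drop = FALSE]))
  d <- sapply(seq_along(cts), function(k)
    rowSums(sweep(pcs$scores, 2, cen[, k])^2))
  expect_gte(mean(cts[max.col(-d)] == ct), 0.95)
})

test_that("isolation score is zero at the centroid and flags nobody", {
  sc <- rbind(matrix(c(0, 0), 4, 2, byrow = TRUE),
              matrix(c(5, 5), 4, 2, byrow = TRUE),
              matrix(c(-5, 0), 4, 2, byrow = TRUE))
  ids <- sprintf("s%02d", 1:12)
  pcs <- make_pcs(sc, ids)
  sheet <- make_sheet(ids, rep(c("A", "B", "C"), each = 4))
  sco <- isolation_efficiency_score(pcs, sheet, qc_config())
  expect_true(all(sco$score == 0))
  expect_false(any(sco$flagged))
})

test_that("isolation score requires 3 samples per cell type", {
  ids <- sprintf("s%02d", 1:5)
  pcs <- make_pcs(matrix(rnorm(10), 5, 2), ids)
  sheet <- make_sheet(ids, c("A", "A", "A", "B", "B"))
  expect_error(isolation_efficiency_score(pcs, sheet), "fewer than 3")
})

test_that("mixture samples raise the isolation score of their individuals", {
  coh <- study_cohort(n_sites = 800, seed = 6)
  inj <- inject_sort_failures(coh$beta, coh$sheet, n_mixture = 6,
                              mix_fraction = 0.5, seed = 3)
  pcs <- compute_pcs(inj$beta, 2)
  sco <- isolation_efficiency_score(pcs, inj$sheet, qc_config())
  bad <- unique(inj$sheet$individual_id[
    match(inj$truth$sample_id, inj$sheet$sample_id)])
  expect_gt(median(sco$score[sco$individual_id %in% bad]),
            median(sco$score[!sco$individual_id %in% bad]))
})

test_that("flagging sensitivity is non-decreasing in the mixing fraction", {
  coh <- study_cohort(n_sites = 800, seed = 6)
  med_bad <- sapply(c(0.1, 0.3, 0.5), function(f) {
    inj <- inject_sort_failures(coh$beta, coh$sheet, n_mixture = 8,
                                mix_fraction = f, seed = 4)
    sco <- isolation_efficiency_score(compute_pcs(inj$beta, 2), inj$sheet)
    bad <- unique(inj$sheet$individual_id[
      match(inj$truth$sample_id, inj$sheet$sample_id)])
    median(sco$score[sco$individual_id %in% bad])
  })
  expect_true(all(diff(med_bad) > 0))
})

test_that("clean cohorts flag no individuals at threshold 5 (10 seeds)", {
  flagged <- sapply(1:10, function(s) {
    coh <- small_cohort(n_sites = 500, seed = 200 + s)
    rep <- run_stage3(coh$beta, coh$sheet)
    rep$summary["n_flagged_individuals"]
  })
  expect_true(all(flagged == 0))
})

test_that("distance filter applies the per-PC 2-SD rule", {
  # clusters spread uniformly (max |z| < 2 by construction) + one outlier
  set.seed(9)
  sc <- cbind(runif(30, -1, 1), runif(30, -1, 1))
  sc[1:10, 1] <- sc[1:10, 1] + 10
  sc[11:20, 1] <- sc[11:20, 1] - 10
  ids <- sprintf("s%02d", 1:31)
  sc <- rbind(sc, c(10 + 25, 0))  # outlier in cluster A, far out on PC1
  pcs <- make_pcs(sc, ids)
  sheet <- make_sheet(ids, c(rep(c("A", "B", "C"), each = 10), "A"))
  filt <- celltype_distance_filter(pcs, sheet, qc_config())
  expect_identical(filt$sample_id[!filt$retained], "s31")

  # constructed sample far out on PC1, at centre on PC2 -> excluded even
  # though its own leverage inflates the single-pass SD
  set.seed(10)
  base <- cbind(runif(19, -1, 1), runif(19, -1, 1))
  sco <- make_pcs(rbind(base, c(10, 0)), sprintf("t%02d", 1:20))
  sh2 <- make_sheet(sprintf("t%02d", 1:20), rep("A", 20))
  f2 <- celltype_distance_filter(sco, sh2, qc_config())
  expect_false(f2$retained[20])
  expect_true(all(f2$retained[1:19]))
  # a sample exactly at the centroid is always retained
  at_centre <- which.min(rowSums(sweep(sco$scores, 2,
                                       colMeans(sco$scores))^2))
  expect_true(f2$retained[at_centre])
})

test_that("stage-3 report composes both metrics over a clean cohort", {
  coh <- study_cohort(n_sites = 600, seed = 8)
  rep <- run_stage3(coh$beta, coh$sheet)
  expect_equal(nrow(rep$samples), ncol(coh$beta))
  expect_equal(rep$summary[["n_flagged_individuals"]], 0)
  # per-PC 2-SD rule retains ~ 0.9545^2 of approximately normal scores
  expect_gt(rep$summary[["n_retained"]] / rep$summary[["n_samples"]], 0.85)
  expect_lte(rep$summary[["n_retained"]], rep$summary[["n_samples"]])
  expect_match(rep$stages[["stage1_array_quality"]], "not evaluated")
  df <- as.data.frame(rep)
  expect_true(all(c("retained", "isolation_score") %in% names(df)))
})

test_that("mislabelled fraction swaps fail the distance filter", {
  coh <- study_cohort(n_sites = 600, seed = 9)
  inj <- inject_sort_failures(coh$beta, coh$sheet, n_mislabelled = 2,
                              seed = 5)
  rep <- run_stage3(inj$beta, inj$sheet)
  swapped <- inj$truth$sample_id[inj$truth$failure_kind == "mislabelled"]
  expect_true(all(!rep$samples$retained[
    match(swapped, rep$samples$sample_id)]))
})
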