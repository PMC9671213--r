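test_that("vectorized metrics match naive loop oracles on random instances", {
  for (seed in 1:4) {
    inst <- random_metric_instance(20, 30, seed = seed,
                                   with_mask = seed %% 2 == 0)
    mk <- inst$mask
    expect_equal(as.numeric(concordance_rate(inst$truth, inst$calls, mk)),
                 oracle_cr(inst$truth, inst$calls, mk), tolerance = 1e-12)
    he <- hellinger_score(inst$truth, inst$posterior, mk)
    ho <- oracle_hellinger(inst$truth, inst$posterior, mk)
    expect_equal(he$mean, ho$mean, tolerance = 1e-12)
    expect_equal(he$min_mean, ho$min_mean, tolerance = 1e-12)
    expect_equal(unname(he$per_snp_mean), ho$per_snp_mean,
                 tolerance = 1e-12)
    se <- sen_score(inst$truth, inst$dosages, mk)
    so <- oracle_sen(inst$truth, inst$dosages, mk)
    expect_equal(se$mean, so$mean, tolerance = 1e-12)
    expect_equal(se$min_mean, so$min_mean, tolerance = 1e-12)
    iq <- iqs(inst$truth, inst$calls, mk)
    io <- oracle_iqs(inst$truth, inst$calls, mk)
    expect_equal(unname(iq$per_snp), io$per_snp, tolerance = 1e-12)
    expect_equal(iq$mean, io$mean, tolerance = 1e-12)
    pc <- pcc_dosage(inst$truth, inst$dosages, mk)
    po <- oracle_pcc(inst$truth, inst$dosages, mk)
    expect_equal(unname(pc$per_snp), po$per_snp, tolerance = 1e-12)
  }
})

test_that("perfect and maximally wrong predictions hit the metric bounds", {
  gm <- tiny_panel(10, 12, seed = 2)
  pm <- point_mass_posterior(gm)
  expect_equal(as.numeric(concordance_rate(gm, gm)), 1)
  he <- hellinger_score(gm, pm)
  expect_equal(he$mean, 1)
  expect_equal(he$min_mean, 1)
  se <- sen_score(gm, unclass(gm) * 1.0)
  expect_equal(se$mean, 1)
  expect_equal(unname(iqs(gm, gm)$per_snp[compute_maf(gm) > 0]),
               rep(1, sum(compute_maf(gm) > 0)))
  # point mass on a wrong genotype scores 0 (disjoint supports)
  wrong <- dcimpute:::gt_replace(gm, (unclass(gm) + 1L) %% 3L)
  he_w <- hellinger_score(gm, point_mass_posterior(wrong))
  expect_equal(he_w$mean, 0)
  # maximal dosage error scores 0
  gm0 <- dcimpute:::gt_replace(gm, matrix(0L, 10, 12))
  se_w <- sen_score(gm0, matrix(2, 10, 12))
  expect_equal(se_w$mean, 0)
})

test_that("CR follows the per-sample-then-mean aggregation order", {
  # sample A: 3/4 correct, sample B: 1/4 correct -> CR 0.5
  truth <- genotype_matrix(rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L)))
  calls <- genotype_matrix(rbind(c(0L, 0L, 0L, 1L), c(1L, 0L, 0L, 0L)))
  expect_equal(as.numeric(concordance_rate(truth, calls)), 0.5)
  # unequal in-scope counts: per-sample mean differs from pooled fraction
  mask <- rbind(c(TRUE, TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE, FALSE))
  cr <- as.numeric(concordance_rate(truth, calls, mask))
  expect_equal(cr, mean(c(3 / 4, 1)))
  pooled <- 4 / 5
  expect_false(isTRUE(all.equal(cr, pooled)))
})

test_that("Hellinger score matches its closed form at half mass", {
  truth <- genotype_matrix(matrix(0L, 1, 1))
  probs <- array(c(0, 0.5, 0.3, 0.2), c(1, 1, 4))
  post <- dcimpute:::new_posterior_tensor(probs, "diploid")
  expect_equal(hellinger_score(truth, post)$mean,
               1 - sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
  # cross-check the closed form against the generic two-distribution oracle
  expect_equal(1 - hellinger_dist(c(1, 0, 0), c(0.5, 0.3, 0.2)),
               1 - sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
})

test_that("SEN score is the scaled absolute dosage error", {
  truth <- genotype_matrix(matrix(2L, 1, 1))
  expect_equal(sen_score(truth, matrix(1.5, 1, 1))$mean, 0.75)
})

test_that("IQS corrects the agreement for chance", {
  # truth 8x class0 + 2x class1, calls all class0: Po = 0.8 = Pc -> IQS 0
  truth <- genotype_matrix(matrix(c(rep(0L, 8), rep(1L, 2)), ncol = 1))
  calls <- genotype_matrix(matrix(0L, 10, 1))
  expect_equal(unname(iqs(truth, calls)$per_snp), 0)
  # and the uncorrected CR is a misleading 0.8
  expect_equal(as.numeric(concordance_rate(truth, calls)), 0.8)
  # perfect agreement on a polymorphic SNP scores 1
  expect_equal(unname(iqs(truth, truth)$per_snp), 1)
  # degenerate Pc = 1 with perfect agreement scores 1, flagged
  mono <- genotype_matrix(matrix(0L, 6, 1))
  iq <- iqs(mono, mono)
  expect_equal(unname(iq$per_snp), 1)
  expect_identical(iq$n_degenerate, 1L)
})

test_that("IQS is invariant to sample permutation", {
  inst <- random_metric_instance(15, 10, seed = 9, with_mask = FALSE)
  perm <- sample(15)
  t2 <- dcimpute:::gt_subset(inst$truth, samples = perm)
  c2 <- dcimpute:::gt_subset(inst$calls, samples = perm)
  expect_equal(iqs(t2, c2)$per_snp, iqs(inst$truth, inst$calls)$per_snp)
})

test_that("dosage PCC hits the correlation bounds and excludes degenerates", {
  truth <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), ncol = 1))
  expect_equal(unname(pcc_dosage(truth, matrix(c(0, 1, 2, 1), ncol = 1))$per_snp), 1)
  expect_equal(unname(pcc_dosage(truth, matrix(c(2, 1, 0, 1), ncol = 1))$per_snp), -1)
  d <- matrix(c(0.1, 0.9, 1.8, 1.2), ncol = 1)
  expect_equal(unname(pcc_dosage(truth, d)$per_snp),
               cor(c(0, 1, 2, 1), c(0.1, 0.9, 1.8, 1.2)))
  mono <- genotype_matrix(matrix(0L, 4, 1))
  pc <- pcc_dosage(mono, matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1))
  expect_true(is.na(pc$per_snp))
  expect_identical(pc$n_excluded_snps, 1L)
})

test_that("scores are bounded and per-SNP min never exceeds per-SNP mean", {
  for (seed in 5:7) {
    inst <- random_metric_instance(12, 18, seed = seed)
    he <- hellinger_score(inst$truth, inst$posterior, inst$mask)
    se <- sen_score(inst$truth, inst$dosages, inst$mask)
    ok <- !is.na(he$per_snp_mean)
    expect_true(all(he$per_snp_mean[ok] >= 0 & he$per_snp_mean[ok] <= 1))
    expect_true(all(he$per_snp_min[ok] <= he$per_snp_mean[ok] + 1e-12))
    expect_true(all(se$per_snp_min[ok] <= se$per_snp_mean[ok] + 1e-12))
    cr <- as.numeric(concordance_rate(inst$truth, inst$calls, inst$mask))
    expect_true(cr >= 0 && cr <= 1)
    expect_true(all(iqs(inst$truth, inst$calls, inst$mask)$per_snp <= 1,
                    na.rm = TRUE))
  }
})

test_that("point-mass Hellinger reduces to per-sample concordance", {
  inst <- random_metric_instance(10, 14, seed = 3, with_mask = FALSE)
  pm <- point_mass_posterior(inst$calls)
  score_mat <- 1 * (unclass(inst$calls) == unclass(inst$truth))
  he <- hellinger_score(inst$truth, pm)
  expect_equal(he$per_snp_mean, colMeans(score_mat), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("full reports cover all metrics and recombine across MAF bins", {
  inst <- random_metric_instance(20, 24, seed = 10)
  gm <- inst$truth
  bins <- bin_by_maf(compute_maf(gm))
  rep <- full_report(gm, inst$posterior, inst$calls, dosages = inst$dosages,
                     mask = inst$mask, maf_bins = bins)
  expect_s3_class(rep, "metric_report")
  expect_identical(rep$scope[1], "masked-only")
  expect_true(all(c("cr", "hellinger_mean", "hellinger_min", "sen_mean",
                    "sen_min", "iqs", "pcc") %in% names(rep)))
  # per-sample numerators/denominators pooled across bins reproduce the
  # unbinned CR
  per_sample <- attr(rep, "per_sample")
  scope <- scope_of(gm, inst$mask)
  by_bin <- split(seq_len(ncol(gm)), bins[seq_len(ncol(gm))])
  num <- den <- numeric(nrow(gm))
  for (snps in by_bin) {
    if (!length(snps)) next
    sc <- scope[, snps, drop = FALSE]
    mt <- sc & (unclass(inst$calls)[, snps, drop = FALSE] ==
                unclass(gm)[, snps, drop = FALSE])
    num <- num + rowSums(mt, na.rm = TRUE)
    den <- den + rowSums(sc)
  }
  expect_equal(mean((num / den)[den > 0]), rep$cr[rep$bin == "all"],
               tolerance = 1e-12)
  # perfect imputation scores 1 in every bin
  pm <- point_mass_posterior(gm)
  perfect <- full_report(gm, pm, gm, dosages = unclass(gm) * 1.0,
                         mask = inst$mask, maf_bins = bins)
  expect_true(all(abs(perfect$cr - 1) < 1e-12))
  expect_true(all(abs(perfect$hellinger_mean - 1) < 1e-12))
  expect_true(all(abs(perfect$sen_mean - 1) < 1e-12))
  # determinism
  rep2 <- full_report(gm, inst$posterior, inst$calls, dosages = inst$dosages,
                      mask = inst$mask, maf_bins = bins)
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
})

test_that("empty evaluation scope raises an undefined-metric error", {
  gm <- tiny_panel(4, 6, seed = 1)
  empty_mask <- matrix(FALSE, 4, 6)
  expect_error(concordance_rate(gm, gm, empty_mask), "undefined")
})
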