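test_that("prevalence test flags only NC-skewed ASVs, with exact-test p-values", {
  # ASV1: 50/100 GU, 0/10 NC -> direction fails, never flagged
  # ASV2: 5/100 GU, 9/10 NC -> strongly NC-skewed, flagged
  cm <- make_qc_cm(presence_gu = c(50, 5), presence_nc = c(0, 9))
  res <- prevalence_contaminant_test(cm)
  expect_false(res$flag[res$asv_id == "ASV01"])
  expect_true(res$flag[res$asv_id == "ASV02"])
  # frozen from the hypergeometric enumeration oracle on [[5,95],[9,1]]
  expect_equal(res$p[res$asv_id == "ASV02"], 4.11946131847e-09,
               tolerance = 1e-6)
  expect_equal(res$p[res$asv_id == "ASV02"], oracle_fisher_p(5, 95, 9, 1),
               tolerance = 1e-12)
})

test_that("prevalence test matches exact/chi-square oracles on all small tables", {
  # every 2x2 presence table with margins <= 12; the implementation's two
  # branches are each checked against an independent oracle
  for (n_gu in c(3, 7, 12)) for (n_nc in c(2, 5, 12)) {
    for (a in 0:n_gu) for (c_ in 0:n_nc) {
      b <- n_gu - a; d <- n_nc - c_
      p <- urobiome:::.prev_test_p(a, b, c_, d)
      if ((a + c_) == 0 || (b + d) == 0) {
        expect_equal(p, 1)
        next
      }
      e_min <- min(outer(c(a + b, c_ + d), c(a + c_, b + d))) / (n_gu + n_nc)
      expected <- if (e_min >= 5) oracle_chisq_p(a, b, c_, d) else
        oracle_fisher_p(a, b, c_, d)
      expect_equal(p, expected, tolerance = 1e-9)
    }
  }
})

test_that("NC read-fraction rule uses the documented thresholds", {
  m <- matrix(0L, 12, 2, dimnames = list(
    c(sprintf("GU%02d", 1:10), "NC01", "NC02"), c("ASVA", "ASVB")))
  m[, 1] <- c(rep(9L, 10), 5L, 1L)   # NC reads 6 of 96 total -> 0.0625 > 0.05
  m[, 2] <- c(rep(10L, 10), 0L, 0L)  # no NC reads -> never flagged
  cm <- count_matrix(m, setNames(c(rep("GU", 10), "NC", "NC"), rownames(m)))
  res <- nc_read_fraction_filter(cm)
  expect_true(res$flag[res$asv_id == "ASVA"])
  expect_false(res$flag[res$asv_id == "ASVB"])
  expect_equal(res$nc_read_fraction[res$asv_id == "ASVA"], 6 / 96)
  # exactly 5% is not "more than 5%" (cohort large enough that the
  # NC-sample-count clause stays inert)
  m2 <- matrix(0L, 21, 2, dimnames = list(
    c(sprintf("GU%02d", 1:20), "NC01"), c("ASVX", "FILL")))
  m2[, "ASVX"] <- c(rep(5L, 19), 0L, 5L)    # 5 NC reads of 100 total
  m2[, "FILL"] <- 100L
  cm2 <- count_matrix(m2, setNames(c(rep("GU", 20), "NC"), rownames(m2)))
  expect_false(nc_read_fraction_filter(cm2)$flag[1])
})

test_that("cross-talk rule needs both low prevalence and low abundance", {
  # ASV in 2 GU samples at 0.1% and 0.3% of library -> flagged
  m <- matrix(0L, 5, 2, dimnames = list(
    c("GU1", "GU2", "GU3", "GU4", "NC1"), c("RARE", "COMMON")))
  m[, "COMMON"] <- c(999L, 2991L, 1000L, 1000L, 100L)
  m["GU1", "RARE"] <- 1L     # 1/1000 = 0.1%
  m["GU2", "RARE"] <- 9L     # 9/3000 = 0.3%
  cm <- count_matrix(m, setNames(c(rep("GU", 4), "NC"), rownames(m)))
  res <- crosstalk_filter(cm)
  expect_true(res$flag[res$asv_id == "RARE"])
  expect_false(res$flag[res$asv_id == "COMMON"])
  # same prevalence but one occurrence at 1% -> abundance condition fails
  m["GU2", "RARE"] <- 30L    # 30/3021 ~ 1%
  cm <- count_matrix(m, setNames(c(rep("GU", 4), "NC"), rownames(m)))
  expect_false(crosstalk_filter(cm)$flag[1])
})

test_that("apply_qc removes planted contaminants and keeps true ASVs", {
  sim <- simulate_cohort(default_paper_like_config("desk", seed = 42))
  qc <- apply_qc(sim$counts)
  planted <- c(sim$truth$contaminant_asvs, sim$truth$hop_artifact_asvs)
  removed <- qc$report$asv$asv_id[qc$report$asv$removed]
  tp <- length(intersect(planted, removed))
  f1 <- 2 * tp / (2 * tp + length(setdiff(removed, planted)) +
                    length(setdiff(planted, removed)))
  expect_gte(f1, 0.9)
  true_ids <- setdiff(colnames(sim$counts$counts), planted)
  expect_lte(length(intersect(removed, true_ids)) / length(true_ids), 0.05)
  # output holds GU samples only and no removed ASVs
  expect_true(all(qc$counts$sample_type == "GU"))
  expect_length(intersect(colnames(qc$counts$counts), removed), 0)
  # report invariant: removed <=> union of rules
  with(qc$report$asv, expect_identical(removed, rule1 | rule2 | rule3))
})

test_that("the retention rule drops samples at exactly the threshold", {
  # GU1 retains exactly 50% after removing CONT -> dropped (strictly-more-than)
  m <- matrix(c(50L, 50L,
                90L, 10L,
                0L, 60L), 3, 2, byrow = TRUE,
              dimnames = list(c("GU1", "GU2", "NC1"), c("KEEP", "CONT")))
  cm <- count_matrix(m, c(GU1 = "GU", GU2 = "GU", NC1 = "NC"))
  qc <- apply_qc(cm, alpha = 0.5)
  expect_true(qc$report$asv$removed[qc$report$asv$asv_id == "CONT"])
  smp <- qc$report$sample
  expect_false(smp$sample_kept[smp$sample_id == "GU1"])
  expect_true(smp$sample_kept[smp$sample_id == "GU2"])
})

test_that("QC without negative controls is an error", {
  sim <- simulate_cohort(default_paper_like_config("tiny", seed = 1))
  gu_only <- subset_count_matrix(sim$counts,
                                 samples = samples_of_type(sim$counts, "GU"))
  expect_error(apply_qc(gu_only), "negative controls")
})

test_that("a clean matrix passes QC unchanged", {
  m <- matrix(c(60L, 40L,
                30L, 70L,
                0L, 0L), 3, 2, byrow = TRUE,
              dimnames = list(c("GU1", "GU2", "NC1"), c("A", "B")))
  # NC present but empty for these ASVs; both ASVs abundant in >=2 GUs
  m[, 1] <- c(600L, 300L, 0L); m[, 2] <- c(400L, 700L, 0L)
  cm <- count_matrix(m, c(GU1 = "GU", GU2 = "GU", NC1 = "NC"))
  qc <- apply_qc(cm, min_gu_samples = 2L)
  expect_false(any(qc$report$asv$removed))
  expect_true(all(qc$report$sample$retained_fraction == 1))
  expect_identical(qc$counts$counts, cm$counts[c("GU1", "GU2"), ])
})

test_that("raising thresholds never shrinks a rule's removal set", {
  sim <- simulate_cohort(default_paper_like_config("tiny", seed = 9))
  cm <- sim$counts
  f1 <- prevalence_contaminant_test(cm, alpha = 0.2)$flag
  f2 <- prevalence_contaminant_test(cm, alpha = 0.7)$flag
  expect_true(all(f2[f1]))
  g1 <- nc_read_fraction_filter(cm, max_frac = 0.05)$flag
  g2 <- nc_read_fraction_filter(cm, max_frac = 0.02)$flag
  expect_true(all(g2[g1]))
  h1 <- crosstalk_filter(cm, min_gu_samples = 3)$flag
  h2 <- crosstalk_filter(cm, min_gu_samples = 5)$flag
  expect_true(all(h2[h1]))
})
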