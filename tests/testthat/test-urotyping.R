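make_profile_from_rel <- function(rel) {
  m <- matrix(as.integer(round(rel * 1e6)), nrow(rel), ncol(rel),
              dimnames = dimnames(rel))
  cm <- count_matrix(m, setNames(rep("GU", nrow(rel)), rownames(rel)))
  relative_abundance(cm, rank = "genus")
}

test_that("urotype matrix pools sub-cutoff genera into Others, conserving rows", {
  rel <- cbind(G1 = rep(0.5, 8), G2 = rep(0.3, 8),
               G3 = rep(0.001, 8), G4 = rep(0.199, 8))
  rownames(rel) <- sprintf("S%d", 1:8)
  prof <- make_profile_from_rel(rel)
  gm <- build_urotype_matrix(prof, mra_cutoff = 0.001)
  # G3 sits exactly at the cutoff: strict > means it is pooled
  expect_false("G3" %in% colnames(gm))
  expect_true(all(c("G1", "G2", "G4", "Others") %in% colnames(gm)))
  expect_equal(unname(rowSums(gm)), rep(1, 8), tolerance = 1e-12)
  expect_error(build_urotype_matrix(prof, mra_cutoff = 0.9), "no genus")
})

test_that("ward clustering separates two tight groups and validates input", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
             matrix(rnorm(20, 5, 0.05), 10, 2))
  rownames(x) <- sprintf("P%02d", 1:20)
  d <- as.matrix(dist(x))
  wc <- ward_cluster(d, k_range = 2:4)
  lab <- wc$labels[, "2"]
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(ward_cluster(bad, 2:3), "symmetric")
  expect_error(ward_cluster(d, k_range = 1:3), "k_range")
})

test_that("ward merge heights equal the Lance-Williams recomputation", {
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(rnorm(12), 6, 2)
    d <- dist(x)
    hc <- ward_cluster(as.matrix(d), 2:3)$hclust
    expect_equal(hc$height, oracle_ward_heights(d), tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))   # non-decreasing heights
  }
})

test_that("cluster partitions are invariant to sample order", {
  sim <- simulate_cohort(default_paper_like_config("tiny", seed = 19))
  qc <- apply_qc(sim$counts, max_nc_sample_frac = 0.5)
  rare <- suppressWarnings(rarefy(qc$counts, 2000, seed = 3))
  prof <- relative_abundance(collapse_taxonomy(rare, sim$taxonomy, "genus"),
                             "genus")
  gm <- build_urotype_matrix(prof)
  d <- bray_curtis(gm)
  lab1 <- ward_cluster(d, 2:4)$labels[, "3"]
  set.seed(4)
  perm <- sample(rownames(gm))
  lab2 <- ward_cluster(d[perm, perm], 2:4)$labels[, "3"]
  # same partition up to relabelling
  expect_equal(mclust::adjustedRandIndex(lab1[perm], lab2), 1)
})

test_that("CH and silhouette match direct-formula oracles on a 12-point toy", {
  set.seed(5)
  x <- rbind(matrix(rnorm(8, 0, 0.3), 4, 2),
             matrix(rnorm(8, 4, 0.3), 4, 2),
             matrix(rnorm(8, c(0, 8), 0.3), 4, 2))
  rownames(x) <- sprintf("P%02d", 1:12)
  d <- as.matrix(dist(x))
  labels <- rep(1:3, each = 4)
  expect_equal(calinski_harabasz(x, labels),
               oracle_calinski_harabasz(x, labels), tolerance = 1e-10)
  skip_if_not_installed("cluster")
  sil_ref <- mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
  expect_equal(mean_silhouette(d, labels), sil_ref, tolerance = 1e-10)
})

test_that("select_k picks the planted number for well-separated blobs", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 5, 0.2), 20, 2),
             matrix(rnorm(40, c(0, 9), 0.2), 20, 2))
  rownames(x) <- sprintf("P%02d", 1:60)
  d <- as.matrix(dist(x))
  wc <- ward_cluster(d, 2:6)
  sel <- select_k(d, wc$labels, x)
  expect_equal(sel$k, 3)
  expect_equal(which.max(sel$diagnostics$calinski_harabasz),
               which(sel$diagnostics$k == 3))
  # diagnostics are pure functions of their inputs
  sel2 <- select_k(d, wc$labels, x)
  expect_identical(sel$diagnostics, sel2$diagnostics)
})

test_that("dominant-genus labels respect the dominance threshold", {
  rel <- cbind(G1 = c(rep(0.60, 5), rep(0.10, 5)),
               G2 = c(rep(0.10, 5), rep(0.12, 5)))
  rel <- cbind(rel, Others = 1 - rowSums(rel))
  rownames(rel) <- sprintf("S%02d", 1:10)
  labels <- setNames(rep(1:2, each = 5), rownames(rel))
  info <- label_urotypes(labels, rel)
  expect_identical(info$dominant_genus[info$cluster == 1], "G1")
  expect_identical(info$dominant_genus[info$cluster == 2], "mixed")
})

test_that("modality classifier separates log-normal from mixed profiles", {
  set.seed(8)
  x <- exp(rnorm(500, -3, 1))
  expect_identical(modality_classify(x)$classification, "unimodal_lognormal")
  comp <- rbinom(500, 1, 0.4)
  y <- exp(rnorm(500, ifelse(comp == 1, -5.5, -2.5), 1))
  expect_identical(modality_classify(y)$classification, "multimodal")
  expect_identical(modality_classify(rep(0.2, 100))$classification,
                   "insufficient_data")
  expect_identical(modality_classify(exp(rnorm(20)))$classification,
                   "insufficient_data")
})

test_that("urotype prevalence comparison matches the chi-square oracle", {
  labels <- setNames(rep(c("U1", "U2"), c(100, 100)), sprintf("S%03d", 1:200))
  md <- data.frame(sample_id = sprintf("S%03d", 1:200),
                   gender = c(rep("female", 55), rep("male", 45),
                              rep("female", 34), rep("male", 66)),
                   stringsAsFactors = FALSE)
  res <- urotype_prevalence_compare(labels, md, "gender")
  expect_identical(res$test, "chi_square")
  # frozen from the textbook formula on [[55,45],[34,66]]
  expect_equal(res$p, 0.00280827212426, tolerance = 1e-6)
  expect_equal(res$p, oracle_chisq_p(55, 45, 34, 66), tolerance = 1e-9)
  md_single <- md; md_single$gender <- "female"
  expect_error(urotype_prevalence_compare(labels, md_single, "gender"),
               "two groups")
})

test_that("a urotype exclusive to one group is strongly significant", {
  labels <- setNames(rep(c("U1", "U2", "U3"), c(80, 80, 60)),
                     sprintf("S%03d", 1:220))
  md <- data.frame(sample_id = sprintf("S%03d", 1:220),
                   gender = c(rep("female", 160), rep("male", 60)),
                   stringsAsFactors = FALSE)
  res <- urotype_prevalence_compare(labels, md, "gender")
  expect_lt(res$p, 0.01)
})
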