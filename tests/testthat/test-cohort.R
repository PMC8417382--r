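test_that("age bins follow the T1-T4 convention", {
  md <- data.frame(sample_id = sprintf("S%d", 1:6),
                   age = c(54L, 55L, 74L, 75L, 86L, NA),
                   stringsAsFactors = FALSE)
  expect_warning(out <- assign_age_groups(md), "missing age")
  expect_identical(out$age_group,
                   c("T1", "T2", "T3", "T4", "T4"))
  md2 <- data.frame(sample_id = "S1", age = 44L, stringsAsFactors = FALSE)
  expect_warning(out2 <- assign_age_groups(md2), "out_of_range")
  expect_identical(out2$age_group, "out_of_range")
})

make_group_profile <- function(rel, groups) {
  m <- matrix(as.integer(round(rel * 1e6)), nrow(rel), ncol(rel),
              dimnames = dimnames(rel))
  cm <- count_matrix(m, setNames(rep("GU", nrow(rel)), rownames(rel)))
  list(profile = relative_abundance(cm, "genus"),
       metadata = data.frame(sample_id = rownames(rel), gender = groups,
                             stringsAsFactors = FALSE))
}

test_that("abundance comparison is symmetric in group order and finds shifts", {
  set.seed(11)
  n <- 60
  rel <- cbind(UP = c(rgamma(n / 2, 2), rgamma(n / 2, 8)),
               FLAT = rgamma(n, 4))
  rel <- rel / rowSums(rel)
  rel <- cbind(rel, REST = 1 - rowSums(rel) + 1)  # keep a filler column
  rel <- rel / rowSums(rel)
  rownames(rel) <- sprintf("S%02d", 1:n)
  gp <- make_group_profile(rel, rep(c("female", "male"), each = n / 2))
  res <- compare_abundance(gp$profile, gp$metadata, "gender")
  expect_true(res$significant[res$taxon == "UP"])
  # swapped group labels give identical p-values
  gp2 <- gp; gp2$metadata$gender <- ifelse(gp$metadata$gender == "female",
                                           "male", "female")
  res2 <- compare_abundance(gp2$profile, gp2$metadata, "gender")
  expect_equal(res$p, res2$p[match(paste(res$taxon), paste(res2$taxon))],
               tolerance = 1e-12)
})

test_that("wilcoxon p-values equal the rank-sum formula oracle under ties", {
  set.seed(12)
  for (i in 1:10) {
    x <- sample(seq(0, 0.3, by = 0.05), 15, replace = TRUE)
    y <- sample(seq(0.05, 0.4, by = 0.05), 18, replace = TRUE)
    got <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    expect_equal(got, oracle_wilcox_p(x, y), tolerance = 1e-9)
  }
})

test_that("prevalence comparison matches the exact-test oracle on small tables", {
  # 10 female (8 present), 8 male (1 present): small margins -> Fisher branch
  pres <- c(rep(1, 8), rep(0, 2), 1, rep(0, 7))
  rel <- cbind(TAX = pres * 0.2 + 1e-9, REST = 1)
  rel <- rel / rowSums(rel)
  rel[pres == 0, "TAX"] <- 0
  rel[, "REST"] <- 1 - rel[, "TAX"]
  rownames(rel) <- sprintf("S%02d", 1:18)
  gp <- make_group_profile(rel, rep(c("female", "male"), c(10, 8)))
  res <- compare_prevalence(gp$profile, gp$metadata, "gender")
  row <- res[res$taxon == "TAX", ]
  expect_identical(row$test, "fisher")
  expect_equal(row$p, oracle_fisher_p(8, 2, 1, 7), tolerance = 1e-9)
  expect_equal(row$prevalence1, 0.8)
})

test_that("a strong prevalence difference is significant", {
  set.seed(13)
  pres <- c(rbinom(100, 1, 0.98), rbinom(100, 1, 0.40))
  rel <- cbind(TAX = pres * 0.3, REST = 1 - pres * 0.3)
  rownames(rel) <- sprintf("S%03d", 1:200)
  gp <- make_group_profile(rel, rep(c("female", "male"), each = 100))
  res <- compare_prevalence(gp$profile, gp$metadata, "gender")
  expect_lt(res$p[res$taxon == "TAX"], 0.01)
})

test_that("exclusive taxa demand a strict zero in the other group", {
  pres_f <- c(5, 5, 0)  # females carrying taxon A, B, C
  pres_m <- c(0, 1, 6)
  rel <- matrix(0, 16, 3, dimnames = list(sprintf("S%02d", 1:16),
                                          c("A", "B", "C")))
  for (j in 1:3) {
    if (pres_f[j] > 0) rel[seq_len(pres_f[j]), j] <- 0.1
    if (pres_m[j] > 0) rel[10 + seq_len(pres_m[j]), j] <- 0.1
  }
  rel <- cbind(rel, REST = 1 - rowSums(rel))
  gp <- make_group_profile(rel, rep(c("female", "male"), c(10, 6)))
  ex <- exclusive_taxa(gp$profile, gp$metadata, "gender", min_samples = 5)
  expect_identical(ex$female_not_male, "A")       # B fails the zero rule
  expect_false("C" %in% ex$female_not_male)       # C: male-side only
  expect_false(any(ex$female_not_male %in% ex$male_not_female))
})

test_that("group tests hold their nominal type-I error on null data", {
  set.seed(14)
  reps <- 100; taxa <- 5; n <- 60
  wil_p <- chs_p <- c()
  genders <- rep(c("female", "male"), each = n / 2)
  for (r in seq_len(reps)) {
    pres <- matrix(rbinom(n * taxa, 1, 0.6), n, taxa)
    rel <- matrix(rgamma(n * taxa, 2), n, taxa) * pres
    rel <- cbind(rel, rgamma(n, 5))
    colnames(rel) <- c(sprintf("T%d", seq_len(taxa)), "REST")
    rownames(rel) <- sprintf("S%02d", seq_len(n))
    gp <- make_group_profile(rel / rowSums(rel), genders)
    wil_p <- c(wil_p, compare_abundance(gp$profile, gp$metadata, "gender")$p)
    res_p <- compare_prevalence(gp$profile, gp$metadata, "gender")
    chs_p <- c(chs_p, res_p$p[res_p$taxon != "REST"])
  }
  expect_gt(mean(wil_p < 0.05), 0.025)
  expect_lt(mean(wil_p < 0.05), 0.075)
  expect_gt(mean(chs_p < 0.05), 0.02)
  expect_lt(mean(chs_p < 0.05), 0.08)
})
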