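test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # step-up on (0.01, 0.02, 0.03, 0.04): every q collapses to 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.04), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    pv <- runif(15)
    q <- bh_adjust(pv)
    expect_equal(q, oracle_bh(pv), tolerance = 1e-12)
    o <- order(pv)
    expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("spearman machinery equals the rank-then-Pearson oracle with ties", {
  set.seed(3)
  for (i in 1:20) {
    x <- sample(0:5, 30, replace = TRUE)   # heavy ties
    y <- sample(0:5, 30, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    got <- urobiome:::.spearman_pairs(cbind(a = x, b = y))
    expect_equal(got$rho["a", "b"], oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("perfectly rank-correlated genera give a rho = 1 edge", {
  set.seed(4)
  base <- rgamma(30, 2)
  m <- cbind(G1 = base, G2 = base * 3, G3 = rgamma(30, 2))
  rownames(m) <- sprintf("S%02d", 1:30)
  net <- spearman_network(m, rho_min = 0.35, q_max = 0.05)
  e <- net$edges[net$edges$genus_a == "G1" & net$edges$genus_b == "G2", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$rho, 1)
})

test_that("the network is symmetric in its inputs and filters monotonically", {
  sim <- simulate_cohort(default_paper_like_config("desk", seed = 5))
  qc <- apply_qc(sim$counts)
  rare <- suppressWarnings(rarefy(qc$counts, 4000, seed = 5))
  prof <- relative_abundance(collapse_taxonomy(rare, sim$taxonomy, "genus"),
                             "genus")
  net <- spearman_network(prof)
  # edges stored once per unordered pair; no self edges
  expect_false(any(net$edges$genus_a == net$edges$genus_b))
  key <- paste(pmin(net$edges$genus_a, net$edges$genus_b),
               pmax(net$edges$genus_a, net$edges$genus_b))
  expect_identical(anyDuplicated(key), 0L)
  # all retained edges satisfy both thresholds
  expect_true(all(abs(net$edges$rho) > 0.35 & net$edges$q < 0.05))
  # stricter thresholds give an edge subset
  net2 <- spearman_network(prof, rho_min = 0.5, q_max = 0.01)
  key2 <- paste(pmin(net2$edges$genus_a, net2$edges$genus_b),
                pmax(net2$edges$genus_a, net2$edges$genus_b))
  expect_true(all(key2 %in% key))
  # node degree equals a brute-force incident-edge recount
  for (g in utils::head(net$nodes$genus[order(-net$nodes$degree)], 5)) {
    expect_equal(net$nodes$degree[net$nodes$genus == g],
                 sum(net$edges$genus_a == g) + sum(net$edges$genus_b == g))
  }
})

test_that("keystone ranking puts the hub of a star design first", {
  set.seed(6)
  z <- rnorm(80)
  m <- cbind(HUB = z + rnorm(80, 0, 0.3),
             A = z + rnorm(80, 0, 0.8), B = z + rnorm(80, 0, 0.8),
             C = z + rnorm(80, 0, 0.8), D = z + rnorm(80, 0, 0.8),
             E = rnorm(80), F = rnorm(80))
  m <- exp(m); rownames(m) <- sprintf("S%02d", 1:80)
  net <- spearman_network(m)
  ks <- detect_keystones(net, 3)
  expect_identical(ks$genus[1], "HUB")
  empty <- spearman_network(matrix(rnorm(30), 10, 3,
                                   dimnames = list(sprintf("S%d", 1:10),
                                                   c("X", "Y", "Z"))),
                            rho_min = 0.99)
  expect_warning(res <- detect_keystones(empty), "no edges")
  expect_equal(nrow(res), 0)
})

test_that("trio analysis validates input and detects planted structure", {
  sim <- simulate_cohort(default_paper_like_config("desk", seed = 7))
  qc <- apply_qc(sim$counts)
  rare <- suppressWarnings(rarefy(qc$counts, 4000, seed = 7))
  prof <- relative_abundance(collapse_taxonomy(rare, sim$taxonomy, "genus"),
                             "genus")
  div <- compute_diversity(rare, sim$tree)
  alpha <- setNames(div$alpha$shannon, div$alpha$sample_id)
  tr <- trio_analysis(prof, sim$truth$trio_genera, alpha)
  expect_true(all(tr$pairwise_rho[upper.tri(tr$pairwise_rho)] > 0.7))
  expect_gt(tr$shannon_assoc$r, 0.3)
  expect_lt(tr$shannon_assoc$p, 0.01)
  expect_error(trio_analysis(prof, c("NoSuchGenus", sim$truth$trio_genera[1:2]),
                             alpha), "absent")
  # shuffling the alpha values across samples decouples the association
  set.seed(8)
  shuffled <- setNames(sample(unname(alpha)), names(alpha))
  tr0 <- trio_analysis(prof, sim$truth$trio_genera, shuffled)
  expect_lt(abs(tr0$shannon_assoc$r), 0.15)
})

test_that("trio co-occurrence test is calibrated under independence", {
  set.seed(9)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    rel <- matrix(rbinom(3 * 150, 1, 0.5) * rgamma(3 * 150, 2), 150, 3,
                  dimnames = list(sprintf("S%03d", 1:150), c("A", "B", "C")))
    rel <- cbind(rel, D = rgamma(150, 5))
    prof <- structure(list(rank = "genus", rel_abund = rel / rowSums(rel),
                           mra = colMeans(rel / rowSums(rel)),
                           prevalence = colMeans(rel > 0),
                           rarefaction_depth = NA_real_),
                      class = "taxon_profile")
    tr <- trio_analysis(prof, c("A", "B", "C"), rnorm(150))
    if (tr$cooccurrence_p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.01)
  expect_lt(hits / reps, 0.10)
})
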