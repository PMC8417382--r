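# Brute-force / first-principles oracles, kept deliberately naive and
# independent of the package implementations they check.

oracle_shannon <- function(x, base = 2) {
  p <- x / sum(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base = base)
  h
}

# Faith PD by explicit root-to-tip path enumeration (ape::nodepath)
oracle_faith_pd <- function(present_tips, tree) {
  root <- length(tree$tip.label) + 1L
  edges_used <- integer()
  for (tip in present_tips) {
    np <- ape::nodepath(tree, root, which(tree$tip.label == tip))
    for (i in seq_len(length(np) - 1)) {
      e <- which(tree$edge[, 1] == np[i] & tree$edge[, 2] == np[i + 1])
      edges_used <- union(edges_used, e)
    }
  }
  sum(tree$edge.length[edges_used])
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  if (den == 0) 0 else num / den
}

# Unweighted UniFrac by per-edge shared/unique classification using
# ape::extract.clade to get each edge's descendant tips.
oracle_unifrac <- function(tips_a, tips_b, tree) {
  n_tip <- length(tree$tip.label)
  unique_len <- 0; total_len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    clade_tips <- if (child <= n_tip) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    in_a <- any(clade_tips %in% tips_a)
    in_b <- any(clade_tips %in% tips_b)
    if (in_a || in_b) total_len <- total_len + tree$edge.length[e]
    if (xor(in_a, in_b)) unique_len <- unique_len + tree$edge.length[e]
  }
  if (total_len == 0) 0 else unique_len / total_len
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

oracle_calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(x[idx, , drop = FALSE])
    B <- B + length(idx) * sum((cen - grand)^2)
    for (i in idx) W <- W + sum((x[i, ] - cen)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Fisher's exact two-sided p by hypergeometric enumeration
# (R's convention: sum tables whose probability <= observed, with slack)
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Pearson chi-square for a 2x2 table without continuity correction
oracle_chisq_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Wilcoxon rank-sum normal-approximation p with tie correction and
# continuity correction, from the published formulas.
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- W - n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
}

# Ward.D2 agglomeration by exhaustive Lance-Williams recomputation on the
# squared dissimilarities; returns the merge heights in order.
oracle_ward_heights <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestval <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (D2[i, j] < bestval - 1e-15) { bestval <- D2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestval))
    for (k in setdiff(active, c(i, j))) {
      upd <- ((size[i] + size[k]) * D2[i, k] +
                (size[j] + size[k]) * D2[j, k] -
                size[k] * D2[i, j]) / (size[i] + size[j] + size[k])
      D2[i, k] <- D2[k, i] <- upd
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}
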