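#' Shannon diversity of a single sample
#'
#' \eqn{H = -\sum p_i \log_b p_i} over taxa with positive abundance. Base 2
#' (bits) by default, following the QIIME q2-diversity convention.
#'
#' @param x non-negative counts or relative abundances, at least one positive
#' @param base logarithm base (2 = bits)
#' @return Shannon index (scalar)
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0) || !any(x > 0))
    stop("shannon needs non-negative abundances with at least one positive")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

## Per-edge leaf-descendant incidence: edges x tips logical matrix built by
## post-order accumulation; shared by faith_pd and unweighted_unifrac.
.edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  E <- matrix(FALSE, nrow(tree$edge), n_tip,
              dimnames = list(NULL, tree$tip.label))
  ## descendants[[v]] = tip indices under node v
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  ord <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  for (k in seq_len(nrow(tree$edge)))
    E[k, desc[[tree$edge[k, 2]]]] <- TRUE
  E
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree spanning the tree root
#' and all leaves present in the sample: an edge contributes whenever any
#' present leaf descends from it.
#'
#' @param x named abundance vector (names are tree leaves); presence is
#'   abundance > 0. A matrix/count_matrix input computes PD per sample.
#' @param tree rooted \code{ape::phylo} tree containing every observed taxon
#' @return PD in branch-length units (scalar, or named vector for a matrix)
#' @export
faith_pd <- function(x, tree) {
  if (inherits(x, "count_matrix")) x <- x$counts
  if (is.matrix(x)) {
    observed <- colnames(x)[colSums(x > 0) > 0]
    miss <- setdiff(observed, tree$tip.label)
    if (length(miss)) stop("taxa absent from tree: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    E <- .edge_tip_incidence(tree)
    common <- intersect(colnames(x), tree$tip.label)
    pres <- t(x[, common, drop = FALSE] > 0)          # taxa x samples
    hit <- (E[, common, drop = FALSE] %*% pres) > 0   # edges x samples
    return(stats::setNames(colSums(hit * tree$edge.length), rownames(x)))
  }
  if (is.null(names(x))) stop("sample abundances must be named by taxon")
  miss <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(miss)) stop("taxa absent from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  m <- matrix(x, 1, length(x), dimnames = list("s", names(x)))
  unname(faith_pd(m, tree))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over a common taxon
#' set, computed pairwise over all samples.
#'
#' @param x samples x taxa matrix of abundances (typically relative
#'   abundances from a \code{taxon_profile}), or a \code{taxon_profile}
#' @return symmetric \code{dist}-convertible matrix with zero diagonal
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "taxon_profile")) x <- x$rel_abund
  if (!is.matrix(x)) stop("bray_curtis needs a samples x taxa matrix")
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- rowSums(x)
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  den <- outer(tot, tot, "+")
  d <- ifelse(den > 0, num / den, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of branch length unique to one
#' sample's leaf set among the branch length observed in either, computed by
#' post-order accumulation over the shared rooted tree.
#'
#' @param x samples x taxa matrix (presence is abundance > 0); taxa must be
#'   a subset of the tree leaves; no sample may be empty
#' @param tree rooted \code{ape::phylo}
#' @return symmetric distance matrix with entries in [0, 1]
#' @export
unweighted_unifrac <- function(x, tree) {
  if (inherits(x, "count_matrix")) x <- x$counts
  if (!is.matrix(x)) stop("unweighted_unifrac needs a samples x taxa matrix")
  if (any(rowSums(x > 0) == 0))
    stop("empty sample(s): ",
         paste(rownames(x)[rowSums(x > 0) == 0], collapse = ", "))
  miss <- setdiff(colnames(x), tree$tip.label)
  if (length(miss)) stop("taxa absent from tree: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  E <- .edge_tip_incidence(tree)[, colnames(x), drop = FALSE]
  len <- tree$edge.length
  M <- (E %*% t(x > 0)) > 0            # edges x samples: edge observed
  Mw <- M * len
  a <- colSums(Mw)                     # branch length observed per sample
  C <- crossprod(Mw, M)                # shared observed length (i, j)
  num <- outer(a, a, "+") - 2 * C
  den <- outer(a, a, "+") - C
  d <- ifelse(den > 0, num / den, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Alpha and beta diversity of a cohort
#'
#' Computes per-sample Shannon (bits) and Faith's PD, plus Bray-Curtis (on
#' relative abundances) and unweighted UniFrac distance matrices.
#'
#' @param cm a rarefied \code{\link{count_matrix}} (ASV level)
#' @param tree rooted \code{ape::phylo} over the ASVs
#' @param base Shannon logarithm base
#' @return object of class \code{diversity_result}: list with \code{alpha}
#'   (data.frame sample_id, shannon, faith_pd) and \code{beta} (list of the
#'   two distance matrices)
#' @export
compute_diversity <- function(cm, tree, base = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  rel <- counts / rowSums(counts)
  sh <- apply(counts, 1, shannon, base = base)
  pd <- faith_pd(counts, tree)
  structure(list(
    alpha = data.frame(sample_id = rownames(counts), shannon = sh,
                       faith_pd = pd, row.names = NULL,
                       stringsAsFactors = FALSE),
    beta = list(bray_curtis = bray_curtis(rel),
                unweighted_unifrac = unweighted_unifrac(counts, tree))),
    class = "diversity_result")
}

#' Compare diversity between metadata groups
#'
#' Alpha diversity: per-group mean/median and pairwise Wilcoxon rank-sum
#' tests. Beta diversity: within-group pairwise distance distributions
#' compared pairwise between groups by Wilcoxon rank-sum on the distance
#' values (distances are not independent observations; p-values are
#' heuristic and flagged as such).
#'
#' @param result a \code{diversity_result}
#' @param metadata data.frame with \code{sample_id} and the grouping column
#' @param grouping metadata column name (e.g. \code{"gender"} or an age-group
#'   column from \code{\link{assign_age_groups}})
#' @return list with \code{alpha_summary}, \code{alpha_tests},
#'   \code{beta_tests}
#' @export
diversity_by_group <- function(result, metadata, grouping) {
  stopifnot(inherits(result, "diversity_result"))
  if (!grouping %in% names(metadata)) stop("unknown grouping column: ", grouping)
  alpha <- merge(result$alpha,
                 metadata[, c("sample_id", grouping)], by = "sample_id")
  alpha$group <- as.character(alpha[[grouping]])
  alpha <- alpha[!is.na(alpha$group), ]
  sizes <- table(alpha$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with <2 samples excluded: ", paste(small, collapse = ", "))
    alpha <- alpha[!alpha$group %in% small, ]
  }
  groups <- sort(unique(alpha$group))
  if (length(groups) < 2) stop("need at least two groups with >=2 samples")

  alpha_summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- alpha[alpha$group == g, ]
    data.frame(group = g, n = nrow(sub),
               mean_shannon = mean(sub$shannon),
               median_shannon = stats::median(sub$shannon),
               mean_faith_pd = mean(sub$faith_pd),
               median_faith_pd = stats::median(sub$faith_pd),
               stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  alpha_tests <- do.call(rbind, lapply(pairs, function(pr) {
    i <- alpha$group == pr[1]; j <- alpha$group == pr[2]
    data.frame(group1 = pr[1], group2 = pr[2], metric = c("shannon", "faith_pd"),
               p = c(stats::wilcox.test(alpha$shannon[i], alpha$shannon[j],
                                        exact = FALSE)$p.value,
                     stats::wilcox.test(alpha$faith_pd[i], alpha$faith_pd[j],
                                        exact = FALSE)$p.value),
               stringsAsFactors = FALSE)
  }))

  within_dist <- function(dmat, ids) {
    ids <- intersect(ids, rownames(dmat))
    if (length(ids) < 2) return(numeric())
    sub <- dmat[ids, ids]
    sub[lower.tri(sub)]
  }
  beta_tests <- do.call(rbind, lapply(names(result$beta), function(metric) {
    dmat <- result$beta[[metric]]
    do.call(rbind, lapply(pairs, function(pr) {
      d1 <- within_dist(dmat, alpha$sample_id[alpha$group == pr[1]])
      d2 <- within_dist(dmat, alpha$sample_id[alpha$group == pr[2]])
      data.frame(group1 = pr[1], group2 = pr[2], metric = metric,
                 median1 = stats::median(d1), median2 = stats::median(d2),
                 p = stats::wilcox.test(d1, d2, exact = FALSE)$p.value,
                 note = "within-group distances are non-independent",
                 stringsAsFactors = FALSE)
    }))
  }))

  list(alpha_summary = alpha_summary, alpha_tests = alpha_tests,
       beta_tests = beta_tests)
}
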