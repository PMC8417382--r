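#' Assign the standard age-group bins
#'
#' Bins ages into T1 (45-54), T2 (55-64), T3 (65-74) and T4 (>= 75 years).
#' Ages below 45 receive an \code{"out_of_range"} label with a warning;
#' samples with missing age are excluded with a warning.
#'
#' @param metadata data.frame with \code{sample_id} and \code{age}
#' @return the metadata with an added \code{age_group} column (rows with
#'   missing age dropped)
#' @export
assign_age_groups <- function(metadata) {
  miss <- is.na(metadata$age)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing age excluded")
    metadata <- metadata[!miss, ]
  }
  grp <- cut(metadata$age, breaks = c(45, 55, 65, 75, Inf), right = FALSE,
             labels = c("T1", "T2", "T3", "T4"))
  grp <- as.character(grp)
  below <- !is.na(metadata$age) & metadata$age < 45
  if (any(below)) {
    warning(sum(below), " sample(s) below the first age bin labelled out_of_range")
    grp[below] <- "out_of_range"
  }
  metadata$age_group <- grp
  metadata
}

.group_vector <- function(metadata, grouping, sample_ids) {
  if (!grouping %in% names(metadata)) stop("unknown grouping column: ", grouping)
  g <- as.character(metadata[[grouping]][match(sample_ids, metadata$sample_id)])
  g
}

#' Per-taxon abundance comparison between groups (Wilcoxon rank-sum)
#'
#' For every taxon, compares relative abundances between each pair of groups
#' with the Wilcoxon rank-sum test. Raw p-values are the primary output,
#' with a Benjamini-Hochberg adjusted column alongside (one family per group
#' pair).
#'
#' @param profile a \code{taxon_profile}
#' @param metadata data.frame with \code{sample_id} and the grouping column
#' @param grouping metadata column name
#' @param level significance level for the \code{significant} flag
#' @return data.frame: taxon, group1, group2, mean1, mean2, p, q, significant
#' @export
compare_abundance <- function(profile, metadata, grouping, level = 0.05) {
  stopifnot(inherits(profile, "taxon_profile"))
  rel <- profile$rel_abund
  g <- .group_vector(metadata, grouping, rownames(rel))
  keep <- !is.na(g)
  rel <- rel[keep, , drop = FALSE]; g <- g[keep]
  sizes <- table(g)
  groups <- sort(names(sizes)[sizes >= 2])
  if (length(groups) < 2) stop("need >= 2 groups with >= 2 samples each")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- g == pr[1]; j <- g == pr[2]
    res <- do.call(rbind, lapply(colnames(rel), function(tx) {
      xi <- rel[i, tx]; xj <- rel[j, tx]
      if (length(unique(c(xi, xj))) == 1) return(NULL)   # degenerate, skipped
      data.frame(taxon = tx, group1 = pr[1], group2 = pr[2],
                 mean1 = mean(xi), mean2 = mean(xj),
                 p = stats::wilcox.test(xi, xj, exact = FALSE)$p.value,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(res)) return(NULL)
    res$q <- bh_adjust(res$p)
    res
  }))
  out$significant <- out$p < level
  out
}

#' Per-taxon prevalence comparison between groups (chi-square / Fisher)
#'
#' For every taxon, tests presence/absence against group membership with a
#' chi-square test without continuity correction, falling back to Fisher's
#' exact test when any expected cell is below 5.
#'
#' @inheritParams compare_abundance
#' @return data.frame: taxon, group1, group2, prevalence1, prevalence2,
#'   test, p, q, significant
#' @export
compare_prevalence <- function(profile, metadata, grouping, level = 0.05) {
  stopifnot(inherits(profile, "taxon_profile"))
  pres <- profile$rel_abund > 0
  g <- .group_vector(metadata, grouping, rownames(pres))
  keep <- !is.na(g)
  pres <- pres[keep, , drop = FALSE]; g <- g[keep]
  sizes <- table(g)
  groups <- sort(names(sizes)[sizes >= 2])
  if (length(groups) < 2) stop("need >= 2 groups with >= 2 samples each")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    i <- g == pr[1]; j <- g == pr[2]
    res <- do.call(rbind, lapply(colnames(pres), function(tx) {
      a <- sum(pres[i, tx]); b <- sum(i) - a
      c_ <- sum(pres[j, tx]); d <- sum(j) - c_
      if (a + c_ == 0) return(NULL)        # absent everywhere, skipped
      tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5)) {
        p <- stats::fisher.test(tab)$p.value; test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chi_square"
      }
      data.frame(taxon = tx, group1 = pr[1], group2 = pr[2],
                 prevalence1 = a / sum(i), prevalence2 = c_ / sum(j),
                 test = test, p = p, stringsAsFactors = FALSE)
    }))
    if (is.null(res)) return(NULL)
    res$q <- bh_adjust(res$p)
    res
  }))
  out$significant <- out$p < level
  out
}

#' Taxa exclusive to one group
#'
#' Taxa present in at least \code{min_samples} samples of one group and in
#' zero samples of the other (strict-zero requirement), for every group pair.
#'
#' @inheritParams compare_abundance
#' @param min_samples minimum samples of the "own" group (default 5)
#' @return named list: for each ordered group pair \code{"<g1>_not_<g2>"},
#'   the character vector of exclusive taxa
#' @export
exclusive_taxa <- function(profile, metadata, grouping, min_samples = 5) {
  stopifnot(inherits(profile, "taxon_profile"))
  pres <- profile$rel_abund > 0
  g <- .group_vector(metadata, grouping, rownames(pres))
  keep <- !is.na(g)
  pres <- pres[keep, , drop = FALSE]; g <- g[keep]
  groups <- sort(unique(g))
  out <- list()
  for (g1 in groups) for (g2 in setdiff(groups, g1)) {
    n1 <- colSums(pres[g == g1, , drop = FALSE])
    n2 <- colSums(pres[g == g2, , drop = FALSE])
    out[[paste0(g1, "_not_", g2)]] <- colnames(pres)[n1 >= min_samples & n2 == 0]
  }
  out
}
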