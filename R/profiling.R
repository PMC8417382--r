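#' Rarefy a count matrix to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly \code{depth}
#' reads (hypergeometric subsampling via \code{vegan::rrarefy}). Samples whose
#' library size falls below \code{depth} are dropped with a warning rather
#' than scaled, keeping the subsampling semantics exact.
#'
#' @param cm a \code{\link{count_matrix}}
#' @param depth target depth in reads (default 4000)
#' @param seed optional integer seed for reproducible subsampling
#' @return a \code{count_matrix} in which every row sums to exactly \code{depth}
#' @export
rarefy <- function(cm, depth = 4000, seed = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (depth <= 0) stop("depth must be positive")
  lib <- library_sizes(cm)
  keep <- lib >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth ", depth)
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(names(lib)[!keep], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  kept <- cm$counts[keep, , drop = FALSE]
  ## vegan warns on any matrix whose smallest positive entry exceeds 1;
  ## counts are already validated as integers, so muffle that one warning
  sub <- withCallingHandlers(
    vegan::rrarefy(kept, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  sub <- matrix(as.integer(sub), nrow(kept), ncol(kept),
                dimnames = dimnames(kept))
  count_matrix(sub, cm$sample_type[rownames(sub)])
}

#' Collapse ASV counts to a taxonomic rank
#'
#' Sums counts over ASVs sharing the same label at \code{rank}; ASVs
#' unassigned at that rank (empty string) are pooled into a labelled
#' \code{"unassigned_<rank>"} taxon. Total reads are preserved exactly.
#'
#' @param cm a \code{\link{count_matrix}} at ASV level
#' @param taxonomy taxonomy data.frame (see \code{\link{read_taxonomy}})
#'   covering every ASV of \code{cm}
#' @param rank one of phylum, class, order, family, genus
#' @return a \code{count_matrix} with taxa at \code{rank} as columns
#' @export
collapse_taxonomy <- function(cm, taxonomy, rank = "genus") {
  stopifnot(inherits(cm, "count_matrix"))
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  idx <- match(colnames(cm$counts), taxonomy$asv_id)
  if (anyNA(idx))
    stop("ASV(s) missing from taxonomy: ",
         paste(utils::head(colnames(cm$counts)[is.na(idx)], 5), collapse = ", "))
  labels <- taxonomy[[rank]][idx]
  labels[is.na(labels) | labels == ""] <- paste0("unassigned_", rank)
  collapsed <- t(rowsum(t(cm$counts), group = labels))
  count_matrix(collapsed, cm$sample_type)
}

#' Relative-abundance taxon profile with MRA and prevalence
#'
#' Converts counts to per-sample relative abundances and summarizes each
#' taxon by its mean relative abundance (MRA; the per-sample mean with zeros
#' included) and its prevalence (fraction of samples where it is present).
#'
#' @param cm a \code{\link{count_matrix}} (typically rarefied and collapsed
#'   to a rank)
#' @param rank label recorded in the profile (informational)
#' @return object of class \code{taxon_profile}: list with \code{rank},
#'   \code{rel_abund} (samples x taxa, rows summing to 1), \code{mra},
#'   \code{prevalence}, \code{rarefaction_depth} (the common row sum if the
#'   input is rarefied, otherwise NA)
#' @export
relative_abundance <- function(cm, rank = "asv") {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) == 0 || nrow(cm$counts) == 0)
    stop("empty count matrix")
  lib <- library_sizes(cm)
  if (any(lib == 0)) stop("sample(s) with zero reads: ",
                          paste(names(lib)[lib == 0], collapse = ", "))
  rel <- cm$counts / lib
  depth <- if (length(unique(lib)) == 1) unique(lib) else NA_real_
  structure(list(rank = rank, rel_abund = rel,
                 mra = colMeans(rel), prevalence = colMeans(rel > 0),
                 rarefaction_depth = depth),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("taxon_profile (%s): %d samples x %d taxa%s\n", x$rank,
              nrow(x$rel_abund), ncol(x$rel_abund),
              if (!is.na(x$rarefaction_depth))
                sprintf(", rarefied to %d reads", as.integer(x$rarefaction_depth))
              else ""))
  top <- sort(x$mra, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top taxa by MRA:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Stratify taxa into dominant / low-abundance / below-core by MRA
#'
#' Partition convention: dominant taxa have MRA strictly above
#' \code{dominant_min}; low-abundance (core) taxa lie in the closed-open
#' interval [\code{core_min}, \code{dominant_min}]; everything below
#' \code{core_min} is below-core. Defaults follow the field convention of
#' 5\% and 0.01\%.
#'
#' @param profile a \code{taxon_profile}
#' @param dominant_min MRA threshold for the dominant stratum (strict >)
#' @param core_min MRA threshold for core membership (closed lower bound)
#' @return list with character vectors \code{dominant}, \code{low_abundance},
#'   \code{below_core}; every taxon appears in exactly one stratum
#' @export
core_taxa <- function(profile, dominant_min = 0.05, core_min = 1e-4) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (core_min >= dominant_min) stop("strata must be non-overlapping")
  mra <- profile$mra
  if (!length(mra)) stop("empty profile")
  list(dominant = names(mra)[mra > dominant_min],
       low_abundance = names(mra)[mra >= core_min & mra <= dominant_min],
       below_core = names(mra)[mra < core_min])
}
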