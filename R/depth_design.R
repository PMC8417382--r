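#' Bin samples by raw sequencing depth
#'
#' Half-open bins \code{[b_i, b_{i+1})} with open-ended first and last bins,
#' labelled G1..Gk. Defaults reproduce the conventional 20k..80k grid (eight
#' bins: below 20,000 up to 80,000 and above).
#'
#' @param cm a \code{\link{count_matrix}} (raw, pre-rarefaction)
#' @param boundaries strictly increasing depth boundaries
#' @return factor of bin labels named by sample id
#' @export
bin_by_depth <- function(cm, boundaries = seq(20000, 80000, by = 10000)) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  lib <- library_sizes(cm)
  breaks <- c(-Inf, boundaries, Inf)
  labels <- paste0("G", seq_len(length(boundaries) + 1))
  stats::setNames(cut(lib, breaks = breaks, labels = labels, right = FALSE),
                  names(lib))
}

#' ASV detection sensitivity along a sequencing-depth grid
#'
#' For each depth d, every sample is subsampled without replacement to
#' min(d, library size) reads (replicated), ASVs are re-detected across the
#' cohort, and sensitivity is the fraction of the reference ASV set (those
#' detected at full depth) recovered. Capping at the library size keeps every
#' sample in play at every depth, so the curve is monotone and reaches 1 at
#' the maximum library size.
#'
#' @param cm a \code{\link{count_matrix}}
#' @param depth_grid increasing depths to evaluate (each <= max library size)
#' @param replicates Monte-Carlo replicates per grid point
#' @param seed integer seed
#' @param min_count detection threshold after subsampling (default 1 read)
#' @return object of class \code{sensitivity_curve}: data.frame with columns
#'   \code{value} (depth), \code{sensitivity} (mean), \code{sd}; attributes
#'   \code{axis}, \code{reference_asv_count}, \code{replicates}
#' @export
depth_sensitivity <- function(cm, depth_grid, replicates = 10, seed = 1,
                              min_count = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- library_sizes(cm)
  if (any(depth_grid > max(lib)))
    stop("depth grid value(s) exceed the largest library (", max(lib), ")")
  set.seed(seed)
  reference <- colnames(cm$counts)[colSums(cm$counts >= min_count) > 0]
  res <- lapply(sort(depth_grid), function(d) {
    sens <- vapply(seq_len(replicates), function(r) {
      target <- pmin(d, lib)
      sub <- vegan::rrarefy(cm$counts, target)
      detected <- colnames(sub)[colSums(sub >= min_count) > 0]
      length(intersect(detected, reference)) / length(reference)
    }, numeric(1))
    c(mean = mean(sens), sd = stats::sd(sens))
  })
  out <- data.frame(value = sort(depth_grid),
                    sensitivity = vapply(res, `[[`, numeric(1), "mean"),
                    sd = vapply(res, `[[`, numeric(1), "sd"))
  structure(out, axis = "depth", reference_asv_count = length(reference),
            replicates = replicates, class = c("sensitivity_curve",
                                               "data.frame"))
}

#' ASV detection sensitivity along a cohort-size grid
#'
#' For each n, draws n samples without replacement (replicated); sensitivity
#' is the fraction of the full-cohort ASV set detected within the subset.
#'
#' @param cm a \code{\link{count_matrix}}
#' @param n_grid increasing cohort sizes (each <= number of samples)
#' @param replicates Monte-Carlo replicates per grid point
#' @param seed integer seed
#' @param min_count detection threshold (default 1 read)
#' @return a \code{sensitivity_curve} (axis \code{"n_samples"})
#' @export
samplesize_sensitivity <- function(cm, n_grid, replicates = 10, seed = 1,
                                   min_count = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- nrow(cm$counts)
  if (any(n_grid > n)) stop("n grid value(s) exceed the cohort size (", n, ")")
  set.seed(seed)
  reference <- colnames(cm$counts)[colSums(cm$counts >= min_count) > 0]
  res <- lapply(sort(n_grid), function(k) {
    sens <- vapply(seq_len(replicates), function(r) {
      idx <- sample.int(n, k)
      detected <- colSums(cm$counts[idx, , drop = FALSE] >= min_count) > 0
      sum(colnames(cm$counts)[detected] %in% reference) / length(reference)
    }, numeric(1))
    c(mean = mean(sens), sd = stats::sd(sens))
  })
  out <- data.frame(value = sort(n_grid),
                    sensitivity = vapply(res, `[[`, numeric(1), "mean"),
                    sd = vapply(res, `[[`, numeric(1), "sd"))
  structure(out, axis = "n_samples", reference_asv_count = length(reference),
            replicates = replicates, class = c("sensitivity_curve",
                                               "data.frame"))
}

#' Recommend minimal sequencing depth and cohort size for a target sensitivity
#'
#' Scans each curve for the smallest grid value whose mean sensitivity
#' reaches the target; when the target is crossed between grid points the
#' linearly interpolated value is returned and flagged.
#'
#' @param depth_curve a depth \code{sensitivity_curve} (or NULL)
#' @param n_curve a cohort-size \code{sensitivity_curve} (or NULL)
#' @param target_sensitivity target detection sensitivity (default 0.90)
#' @return list with \code{min_depth}, \code{min_n} (each a list of
#'   \code{value}, \code{interpolated}, \code{attained})
#' @export
recommend_design <- function(depth_curve = NULL, n_curve = NULL,
                             target_sensitivity = 0.90) {
  scan <- function(curve) {
    if (is.null(curve)) return(NULL)
    s <- curve$sensitivity; v <- curve$value
    hit <- which(s >= target_sensitivity)
    if (!length(hit))
      return(list(value = NA_real_, interpolated = FALSE, attained = FALSE))
    i <- hit[1]
    if (i == 1 || s[i - 1] >= target_sensitivity)
      return(list(value = v[i], interpolated = FALSE, attained = TRUE))
    frac <- (target_sensitivity - s[i - 1]) / (s[i] - s[i - 1])
    list(value = v[i - 1] + frac * (v[i] - v[i - 1]),
         interpolated = TRUE, attained = TRUE)
  }
  list(min_depth = scan(depth_curve), min_n = scan(n_curve),
       target_sensitivity = target_sensitivity)
}
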