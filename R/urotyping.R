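#' Build the genus matrix used for urotype clustering
#'
#' Keeps genera with MRA strictly above \code{mra_cutoff} (default 0.1\%) as
#' columns and pools everything else into a single \code{"Others"} column, so
#' rows still sum to 1.
#'
#' @param profile a genus-rank \code{taxon_profile}
#' @param mra_cutoff MRA inclusion threshold (strict >)
#' @return samples x (rich genera + Others) relative-abundance matrix
#' @export
build_urotype_matrix <- function(profile, mra_cutoff = 0.001) {
  stopifnot(inherits(profile, "taxon_profile"))
  keep <- names(profile$mra)[profile$mra > mra_cutoff]
  keep <- setdiff(keep, "Others")
  if (!length(keep)) stop("no genus passes the MRA cutoff ", mra_cutoff)
  rest <- setdiff(colnames(profile$rel_abund), keep)
  m <- profile$rel_abund[, keep, drop = FALSE]
  others <- rowSums(profile$rel_abund[, rest, drop = FALSE])
  cbind(m, Others = others)
}

#' Ward.D2 hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with the Ward.D2 criterion (squared-dissimilarity
#' Lance-Williams update), via \code{stats::hclust}, plus flat cluster labels
#' for every k in \code{k_range}. Deterministic given input order.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist})
#' @param k_range integer vector of candidate cluster counts, within [2, n-1]
#' @return list with \code{hclust} (the merge tree) and \code{labels}
#'   (samples x length(k_range) integer matrix, columns named by k)
#' @export
ward_cluster <- function(d, k_range = 2:10) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
      stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  k_range <- as.integer(k_range)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("k_range must lie within [2, n-1]")
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- sapply(k_range, function(k) stats::cutree(hc, k))
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = length(k_range))
  colnames(labels) <- as.character(k_range)
  rownames(labels) <- hc$labels
  list(hclust = hc, labels = labels)
}

#' Mean silhouette width of a flat clustering
#'
#' Computed directly from the dissimilarity matrix: for each point,
#' \eqn{s = (b - a) / max(a, b)} with \eqn{a} the mean within-cluster
#' dissimilarity (excluding self) and \eqn{b} the smallest mean dissimilarity
#' to another cluster. Points in singleton clusters score 0.
#'
#' @param d symmetric dissimilarity matrix
#' @param labels integer cluster labels
#' @return mean silhouette width in [-1, 1]
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  ks <- unique(labels)
  if (length(ks) < 2) stop("silhouette needs at least two clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }    # singleton: undefined, scored 0
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(ks, labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Calinski-Harabasz index of a flat clustering
#'
#' Ratio of between- to within-cluster dispersion on a feature matrix:
#' \eqn{[B/(k-1)] / [W/(n-k)]} with B and W the between/within sums of
#' squared Euclidean distances to centroids.
#'
#' @param x samples x features matrix
#' @param labels integer cluster labels (k >= 2 distinct values)
#' @return CH index (larger = better separated)
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    sub <- x[labels == g, , drop = FALSE]
    cen <- colMeans(sub)
    B <- B + nrow(sub) * sum((cen - grand)^2)
    W <- W + sum(sweep(sub, 2, cen)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of urotype clusters
#'
#' Scores every candidate k by the Calinski-Harabasz index (on the feature
#' matrix) and the mean silhouette width (on the dissimilarity matrix) and
#' returns the k maximizing mean silhouette; the CH curve is reported
#' alongside. Ties go to the smaller k.
#'
#' @param d symmetric dissimilarity matrix
#' @param labels_per_k samples x k-candidates label matrix (columns named by
#'   k), as produced by \code{\link{ward_cluster}}
#' @param x feature matrix used for the CH index (e.g. the urotype genus
#'   matrix)
#' @return list with \code{k} (chosen), \code{diagnostics} (data.frame k,
#'   calinski_harabasz, mean_silhouette)
#' @export
select_k <- function(d, labels_per_k, x) {
  ks <- as.integer(colnames(labels_per_k))
  if (length(ks) < 2) stop("need at least two candidate k values")
  diag_df <- data.frame(
    k = ks,
    calinski_harabasz = vapply(seq_along(ks), function(j)
      calinski_harabasz(x, labels_per_k[, j]), numeric(1)),
    mean_silhouette = vapply(seq_along(ks), function(j)
      mean_silhouette(d, labels_per_k[, j]), numeric(1)))
  best <- which.max(diag_df$mean_silhouette)
  list(k = ks[best], diagnostics = diag_df)
}

#' Label clusters by their dominant genus
#'
#' Per cluster, the genus with the highest within-cluster mean relative
#' abundance; clusters whose top genus stays below the dominance threshold
#' are labelled \code{"mixed"}. The pooled \code{"Others"} column never
#' serves as a dominant label.
#'
#' @param labels integer cluster labels named by sample id
#' @param genus_matrix samples x genera relative-abundance matrix (may
#'   include an \code{Others} column)
#' @param dominance_min within-cluster MRA required to name the cluster
#'   after its top genus (default 25\%)
#' @return data.frame: cluster, dominant_genus, dominant_mra, n_samples
#' @export
label_urotypes <- function(labels, genus_matrix, dominance_min = 0.25) {
  if (is.null(names(labels))) names(labels) <- rownames(genus_matrix)
  gm <- genus_matrix[, setdiff(colnames(genus_matrix), "Others"), drop = FALSE]
  do.call(rbind, lapply(sort(unique(labels)), function(g) {
    sub <- gm[names(labels)[labels == g], , drop = FALSE]
    mu <- colMeans(sub)
    top <- which.max(mu)
    data.frame(cluster = g,
               dominant_genus = if (mu[top] < dominance_min) "mixed" else
                 colnames(gm)[top],
               dominant_mra = unname(mu[top]), n_samples = nrow(sub),
               stringsAsFactors = FALSE)
  }))
}

#' Classify the abundance distribution of a genus as log-normal or multimodal
#'
#' Fits 1- and 2-component Gaussian mixtures (unequal variances) to the log
#' of the positive abundances. The genus is called \code{"multimodal"} when
#' the 2-component fit wins by a BIC margin greater than \code{bic_margin}
#' AND the component means are separated by more than \code{sep_sd} pooled
#' standard deviations; otherwise \code{"unimodal_lognormal"}. Fewer than
#' \code{min_n} positive observations (or a degenerate constant input) give
#' an \code{"insufficient_data"} outcome rather than an error.
#'
#' @param abund abundance vector (zeros are excluded and counted)
#' @param min_n minimum positive observations (default 50)
#' @param bic_margin required BIC advantage of the 2-component fit
#' @param sep_sd required mean separation in pooled-SD units
#' @return list with \code{classification}, \code{n_positive},
#'   \code{delta_bic}, \code{separation_sd}, \code{fit} (mclust model or NULL)
#' @export
modality_classify <- function(abund, min_n = 50, bic_margin = 10, sep_sd = 1) {
  pos <- abund[!is.na(abund) & abund > 0]
  out <- list(classification = "insufficient_data",
              n_positive = length(pos), delta_bic = NA_real_,
              separation_sd = NA_real_, fit = NULL)
  if (length(pos) < min_n) return(out)
  x <- log(pos)
  if (stats::sd(x) < 1e-10) return(out)
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 1:2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  bics <- fit$BIC[, "V"]                      # mclust BIC: higher is better
  if (anyNA(bics)) return(out)
  delta <- unname(bics["2"] - bics["1"])
  fit2 <- suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                          verbose = FALSE))
  sep <- NA_real_
  if (!is.null(fit2)) {
    mu <- fit2$parameters$mean
    va <- fit2$parameters$variance$sigmasq
    pro <- fit2$parameters$pro
    pooled_sd <- sqrt(sum(pro * va))
    sep <- abs(diff(mu)) / pooled_sd
  }
  out$delta_bic <- delta
  out$separation_sd <- sep
  out$fit <- fit
  out$classification <-
    if (!is.na(delta) && delta > bic_margin && !is.na(sep) && sep > sep_sd)
      "multimodal" else "unimodal_lognormal"
  out
}

#' Compare urotype prevalence between metadata groups
#'
#' Builds the urotype x group contingency table and tests it by chi-square
#' (without continuity correction), falling back to Fisher's exact test when
#' any expected cell is below 5.
#'
#' @param labels cluster/urotype labels named by sample id
#' @param metadata data.frame with \code{sample_id} and the grouping column
#' @param grouping metadata column name
#' @return list with \code{table} (urotype x group counts),
#'   \code{prevalence} (per-group urotype fractions), \code{p},
#'   \code{test} ("chi_square" or "fisher")
#' @export
urotype_prevalence_compare <- function(labels, metadata, grouping) {
  if (!grouping %in% names(metadata)) stop("unknown grouping column: ", grouping)
  grp <- metadata[[grouping]][match(names(labels), metadata$sample_id)]
  keep <- !is.na(grp)
  tab <- table(urotype = labels[keep], group = as.character(grp[keep]))
  if (ncol(tab) < 2) stop("need at least two groups to compare")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                            B = 1e4)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chi_square"
  }
  list(table = tab, prevalence = prop.table(tab, margin = 2), p = p,
       test = test)
}

#' Full urotype discovery on a genus profile
#'
#' Convenience wrapper: builds the rich-genus matrix, clusters it with
#' Ward.D2 on Bray-Curtis, selects k by mean silhouette, labels the clusters
#' by dominant genus, and classifies the modality of every dominant genus's
#' abundance distribution.
#'
#' @param profile genus-rank \code{taxon_profile}
#' @param k_range candidate cluster counts
#' @param mra_cutoff genus inclusion threshold for the clustering matrix
#' @param dominance_min dominant-genus labelling threshold
#' @return object of class \code{urotype_result}: list with \code{labels}
#'   (chosen-k labels named by sample), \code{k}, \code{hclust},
#'   \code{diagnostics}, \code{cluster_info}, \code{modality}
#' @export
find_urotypes <- function(profile, k_range = 2:10, mra_cutoff = 0.001,
                          dominance_min = 0.25) {
  gm <- build_urotype_matrix(profile, mra_cutoff)
  d <- bray_curtis(gm)
  wc <- ward_cluster(d, k_range)
  sel <- select_k(d, wc$labels, gm)
  labels <- wc$labels[, as.character(sel$k)]
  info <- label_urotypes(labels, gm, dominance_min)
  ## modality is of interest for the dominant genera (MRA > 5%)
  dom <- intersect(names(profile$mra)[profile$mra > 0.05], colnames(gm))
  modality <- lapply(stats::setNames(dom, dom), function(g)
    modality_classify(profile$rel_abund[, g]))
  structure(list(labels = labels, k = sel$k, hclust = wc$hclust,
                 diagnostics = sel$diagnostics, cluster_info = info,
                 modality = modality, genus_matrix = gm),
            class = "urotype_result")
}

#' @export
print.urotype_result <- function(x, ...) {
  cat(sprintf("urotype_result: k = %d over %d samples\n", x$k,
              length(x$labels)))
  print(x$cluster_info, row.names = FALSE)
  invisible(x)
}
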