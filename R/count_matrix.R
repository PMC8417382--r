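#' Sample-by-ASV count matrix with sample-type labels
#'
#' The universal currency of the pipeline: an integer read-count matrix with
#' samples as rows and amplicon sequence variants (ASVs) as columns, plus a
#' per-sample type label distinguishing genitourinary specimens (\code{"GU"}),
#' sterile-water negative controls (\code{"NC"}) and positive controls
#' (\code{"PC"}).
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples as rows and ASVs as columns, both fully named.
#' @param sample_type character vector of types in \code{GU}/\code{NC}/\code{PC}
#'   (case-insensitive), either named by sample id or in row order.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (integer matrix) and \code{sample_type} (named character).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("ASV1", "ASV2")))
#' cm <- count_matrix(m, c(S1 = "GU", S2 = "NC"))
#' library_sizes(cm)
#' @export
count_matrix <- function(counts, sample_type) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample row names and ASV column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate ASV ids in count matrix")
  if (!is.numeric(counts)) stop("counts must be numeric read counts")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers (read counts); found fractional values")
  storage.mode(counts) <- "integer"

  st <- .normalize_sample_type(sample_type, rownames(counts))
  structure(list(counts = counts, sample_type = st), class = "count_matrix")
}

.normalize_sample_type <- function(sample_type, sample_ids) {
  st <- toupper(as.character(sample_type))
  if (!is.null(names(sample_type))) {
    missing <- setdiff(sample_ids, names(sample_type))
    if (length(missing))
      stop("missing sample-type label for: ", paste(missing, collapse = ", "))
    st <- st[match(sample_ids, names(sample_type))]
  } else if (length(st) != length(sample_ids)) {
    stop("sample_type must be named or match the number of samples")
  }
  bad <- setdiff(unique(st), c("GU", "NC", "PC"))
  if (length(bad))
    stop("unknown sample type(s): ", paste(bad, collapse = ", "),
         " (expected GU, NC or PC)")
  names(st) <- sample_ids
  st
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(factor(x$sample_type, levels = c("GU", "NC", "PC")))
  cat(sprintf("count_matrix: %d samples x %d ASVs (GU %d, NC %d, PC %d)\n",
              nrow(x$counts), ncol(x$counts), tab["GU"], tab["NC"], tab["PC"]))
  cat(sprintf("  library sizes: median %s [%s-%s]\n",
              format(stats::median(library_sizes(x))),
              format(min(library_sizes(x))), format(max(library_sizes(x)))))
  invisible(x)
}

#' Per-sample library sizes (total reads)
#' @param cm a \code{count_matrix}
#' @return named numeric vector of row sums
#' @export
library_sizes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  rowSums(cm$counts)
}

#' Sample ids of a given type
#' @param cm a \code{count_matrix}
#' @param type one or more of \code{"GU"}, \code{"NC"}, \code{"PC"}
#' @return character vector of sample ids
#' @export
samples_of_type <- function(cm, type) {
  stopifnot(inherits(cm, "count_matrix"))
  names(cm$sample_type)[cm$sample_type %in% toupper(type)]
}

#' Subset a count matrix by samples and/or ASVs
#'
#' @param cm a \code{count_matrix}
#' @param samples sample ids (or logical/integer index) to keep; default all
#' @param asvs ASV ids (or logical/integer index) to keep; default all
#' @return a \code{count_matrix}
#' @export
subset_count_matrix <- function(cm, samples = NULL, asvs = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(asvs)) counts <- counts[, asvs, drop = FALSE]
  count_matrix(counts, cm$sample_type[rownames(counts)])
}
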