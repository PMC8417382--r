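#' Read a tab-delimited ASV count table
#'
#' Reads a TSV count table (ASVs as rows and samples as columns by default,
#' the common amplicon convention; set \code{orientation} for the transpose)
#' and returns a validated \code{\link{count_matrix}} with samples as rows in
#' memory.
#'
#' @param path TSV file; first column holds row ids, header holds column ids.
#' @param sample_type named character vector mapping sample id to
#'   GU/NC/PC (case-insensitive), or the path of a two-column TSV
#'   (\code{sample_id}, \code{sample_type}) with header.
#' @param orientation \code{"asvs_as_rows"} (default) or \code{"samples_as_rows"}.
#' @return a \code{count_matrix}
#' @export
read_count_table <- function(path, sample_type,
                             orientation = c("asvs_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, row.names = NULL,
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2) stop("count table needs an id column plus data columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table ", path)
  rownames(m) <- ids
  if (orientation == "asvs_as_rows") m <- t(m)
  if (is.character(sample_type) && length(sample_type) == 1 &&
      is.null(names(sample_type)) && file.exists(sample_type)) {
    sample_type <- read_sample_types(sample_type)
  }
  count_matrix(m, sample_type)
}

#' Read a sample-type mapping file
#' @param path two-column TSV (\code{sample_id}, \code{sample_type}) with header
#' @return named character vector of GU/NC/PC labels
#' @export
read_sample_types <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2) stop("sample-type file needs two columns")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write a count matrix (and optionally its sample types) to TSV
#'
#' Files are written ASVs-as-rows, tab-delimited, UTF-8.
#'
#' @param cm a \code{count_matrix}
#' @param path output TSV path
#' @param types_path optional path for the sample-type mapping TSV
#' @return \code{path}, invisibly
#' @export
write_count_table <- function(cm, path, types_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- t(cm$counts)
  df <- data.frame(asv_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(types_path)) {
    utils::write.table(
      data.frame(sample_id = names(cm$sample_type),
                 sample_type = unname(cm$sample_type)),
      types_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read / write an ASV taxonomy table
#'
#' A taxonomy table maps each ASV to an ordered lineage
#' (kingdom, phylum, class, order, family, genus); an empty string marks an
#' unassigned rank.
#'
#' @param path TSV with columns \code{asv_id}, then the six ranks
#' @return data.frame with character columns \code{asv_id} + the six ranks
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("asv_id", .tax_ranks)
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  tab[is.na(tab)] <- ""
  if (anyDuplicated(tab$asv_id)) stop("duplicate asv_id in taxonomy table")
  tab
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame as returned by \code{read_taxonomy}
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted phylogenetic tree over ASVs from newick
#'
#' Wraps \code{ape::read.tree} with the validation the pipeline needs:
#' the tree must parse, be rooted, and have unique leaf labels; missing branch
#' lengths default to 0 with a warning; negative branch lengths are rejected.
#'
#' @param path newick file
#' @return an \code{ape::phylo} tree
#' @export
read_tree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("could not parse newick tree from ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' @rdname read_tree
#' @param tree an \code{ape::phylo} tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read per-sample participant metadata
#'
#' @param path TSV with header and columns \code{sample_id}, \code{gender}
#'   (\code{female}/\code{male}), \code{age} (integer years), \code{region}.
#' @param age_range plausible age bounds (inclusive); ages outside are rejected.
#' @return data.frame with columns sample_id, gender, age, region
#' @export
read_metadata <- function(path, age_range = c(18, 120)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "gender", "age", "region")
  if (!all(need %in% names(tab)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  validate_metadata(tab, age_range)
}

#' Validate a metadata data.frame against the declared constraints
#' @param metadata data.frame with sample_id, gender, age, region
#' @param age_range plausible age bounds (inclusive)
#' @return the validated data.frame (gender lower-cased, age integer)
#' @export
validate_metadata <- function(metadata, age_range = c(18, 120)) {
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  g <- tolower(as.character(metadata$gender))
  bad <- setdiff(unique(g[!is.na(g)]), c("female", "male"))
  if (length(bad))
    stop("unknown gender label(s): ", paste(bad, collapse = ", "))
  age <- suppressWarnings(as.integer(metadata$age))
  out_of_range <- !is.na(age) & (age < age_range[1] | age > age_range[2])
  if (any(out_of_range))
    stop("age outside plausible range [", age_range[1], ", ", age_range[2],
         "] for: ", paste(metadata$sample_id[out_of_range], collapse = ", "))
  metadata$gender <- g
  metadata$age <- age
  metadata
}

#' @rdname read_metadata
#' @param metadata metadata data.frame
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize / restore an analysis report
#'
#' Reports (e.g. the \code{contaminant_report} from \code{\link{apply_qc}})
#' are written as JSON carrying the report class, so a round-trip restores
#' the object including every rule flag.
#'
#' @param report a report object (list-like, with a class attribute)
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
write_report <- function(report, path) {
  payload <- list(class = class(report)[1], data = unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$data
  for (nm in intersect(c("asv", "sample"), names(out)))
    if (is.list(out[[nm]]) && !is.data.frame(out[[nm]]))
      out[[nm]] <- as.data.frame(out[[nm]], stringsAsFactors = FALSE)
  class(out) <- payload$class
  out
}
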