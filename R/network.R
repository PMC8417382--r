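#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to \code{stats::p.adjust(method = "BH")} after validating the
#' input range).
#'
#' @param p p-values in [0, 1]
#' @return q-values, same length/order as \code{p}
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

## Spearman rho via midranks + Pearson, with large-sample t p-values.
.spearman_pairs <- function(x) {
  n <- nrow(x)
  r <- apply(x, 2, rank)                 # midranks handle ties
  rho <- stats::cor(r)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Genus co-occurrence network from Spearman correlations
#'
#' Computes all pairwise Spearman correlations between genera (midranks for
#' ties; p-values by the large-sample t approximation), adjusts them jointly
#' by Benjamini-Hochberg, and keeps edges with \code{|rho| > rho_min} and
#' \code{q < q_max}. Constant genus columns have undefined correlations;
#' their pairs are skipped with a message.
#'
#' @param profile a genus-rank \code{taxon_profile} (or samples x genera
#'   abundance matrix); needs >= 3 samples and >= 2 genera
#' @param rho_min absolute-correlation threshold (default 0.35)
#' @param q_max q-value threshold (default 0.05)
#' @return object of class \code{cooc_network}: list with \code{edges}
#'   (data.frame genus_a, genus_b, rho, q), \code{nodes} (data.frame genus,
#'   mra, degree), \code{thresholds}, \code{n_pairs_tested}
#' @export
spearman_network <- function(profile, rho_min = 0.35, q_max = 0.05) {
  x <- if (inherits(profile, "taxon_profile")) profile$rel_abund else profile
  mra <- if (inherits(profile, "taxon_profile")) profile$mra else colMeans(x)
  x <- x[, setdiff(colnames(x), "Others"), drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (ncol(x) < 2) stop("need at least 2 genera")
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    message("skipping constant genus column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  sp <- .spearman_pairs(x)
  ut <- upper.tri(sp$rho)
  pairs <- which(ut, arr.ind = TRUE)
  pv <- sp$p[ut]
  qv <- bh_adjust(pv)
  rhov <- sp$rho[ut]
  keep <- abs(rhov) > rho_min & qv < q_max
  edges <- data.frame(
    genus_a = colnames(x)[pairs[keep, 1]],
    genus_b = colnames(x)[pairs[keep, 2]],
    rho = rhov[keep], q = qv[keep], stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(ncol(x)), colnames(x))
  strength <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (nrow(edges)) {
    tb <- table(c(edges$genus_a, edges$genus_b))
    degree[names(tb)] <- as.integer(tb)
    for (i in seq_len(nrow(edges))) {
      strength[edges$genus_a[i]] <- strength[edges$genus_a[i]] + abs(edges$rho[i])
      strength[edges$genus_b[i]] <- strength[edges$genus_b[i]] + abs(edges$rho[i])
    }
  }
  nodes <- data.frame(genus = colnames(x),
                      mra = unname(mra[colnames(x)]),
                      degree = unname(degree),
                      strength = unname(strength),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 n_pairs_tested = sum(ut)),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (|rho| > %.2f, q < %.2f; %d pairs tested)\n",
              nrow(x$nodes), nrow(x$edges), x$thresholds["rho_min"],
              x$thresholds["q_max"], x$n_pairs_tested))
  invisible(x)
}

#' Rank keystone genera by network connectivity
#'
#' Genera ranked by degree (incident significant edges), ties broken by the
#' summed absolute correlation of incident edges.
#'
#' @param network a \code{cooc_network}
#' @param top_n how many genera to return
#' @return data.frame genus, degree, strength, ordered by rank; empty (with
#'   a warning) for an edgeless network
#' @export
detect_keystones <- function(network, top_n = 10) {
  stopifnot(inherits(network, "cooc_network"))
  if (!nrow(network$edges)) {
    warning("network has no edges; no keystones")
    return(network$nodes[0, c("genus", "degree", "strength")])
  }
  nd <- network$nodes[order(-network$nodes$degree, -network$nodes$strength), ]
  utils::head(nd[, c("genus", "degree", "strength")], top_n)
}

#' Trio co-occurrence, co-abundance, and diversity association
#'
#' For three focal genera: the joint-presence count with a chi-square test of
#' mutual independence of their presence indicators (2x2x2 table, 4 df),
#' pairwise Spearman correlations of their abundances, and the Pearson
#' correlation of the summed trio abundance with per-sample Shannon
#' diversity.
#'
#' @param profile genus-rank \code{taxon_profile}
#' @param trio_genera three genus names present in the profile
#' @param alpha_values per-sample Shannon values named by (or ordered as)
#'   the profile's samples
#' @return list: \code{joint_presence_count}, \code{cooccurrence_p},
#'   \code{pairwise_rho} (3x3), \code{shannon_assoc} (r, p)
#' @export
trio_analysis <- function(profile, trio_genera, alpha_values) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (length(trio_genera) != 3) stop("trio_genera must name three genera")
  miss <- setdiff(trio_genera, colnames(profile$rel_abund))
  if (length(miss)) stop("genus absent from profile: ",
                         paste(miss, collapse = ", "))
  x <- profile$rel_abund[, trio_genera]
  pres <- x > 0
  joint <- sum(rowSums(pres) == 3)

  ## mutual-independence chi-square on the 2x2x2 presence table
  n <- nrow(pres)
  ph <- colMeans(pres)
  cells <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                       c = c(TRUE, FALSE))
  obs <- apply(cells, 1, function(cc)
    sum(pres[, 1] == cc[1] & pres[, 2] == cc[2] & pres[, 3] == cc[3]))
  expd <- apply(cells, 1, function(cc)
    n * prod(ifelse(unlist(cc), ph, 1 - ph)))
  valid <- expd > 0
  stat <- sum((obs[valid] - expd[valid])^2 / expd[valid])
  coocc_p <- stats::pchisq(stat, df = 4, lower.tail = FALSE)

  rho <- stats::cor(apply(x, 2, rank))

  if (!is.null(names(alpha_values)))
    alpha_values <- alpha_values[rownames(profile$rel_abund)]
  ct <- stats::cor.test(rowSums(x), alpha_values, method = "pearson")

  list(joint_presence_count = joint, cooccurrence_p = coocc_p,
       pairwise_rho = rho,
       shannon_assoc = list(r = unname(ct$estimate), p = ct$p.value))
}
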