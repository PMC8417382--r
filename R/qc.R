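#' Prevalence-based contaminant test against negative controls
#'
#' For every ASV, compares its presence/absence prevalence between
#' genitourinary samples and negative controls in a 2x2 table and flags it as
#' a likely reagent contaminant when the test p-value falls below \code{alpha}
#' AND the NC prevalence fraction strictly exceeds the GU prevalence fraction.
#' The test is a chi-square test of independence without continuity
#' correction, falling back to Fisher's exact test whenever any expected cell
#' is below 5. ASVs absent from all NCs are never flagged. The permissive
#' default \code{alpha = 0.5} reflects the screening (rather than confirmatory)
#' role of this rule in low-biomass decontamination.
#'
#' @param cm a \code{\link{count_matrix}} containing at least one GU and one
#'   NC sample
#' @param alpha flagging threshold on the p-value, in (0, 1]
#' @param presence_min minimum count for an ASV to be called present
#' @return data.frame with one row per ASV: \code{asv_id},
#'   \code{prevalence_gu}, \code{prevalence_nc} (fractions), \code{p},
#'   \code{flag}
#' @export
prevalence_contaminant_test <- function(cm, alpha = 0.5, presence_min = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  gu <- samples_of_type(cm, "GU"); nc <- samples_of_type(cm, "NC")
  if (length(nc) == 0)
    stop("prevalence contaminant test needs negative controls (no NC samples)")
  if (length(gu) == 0) stop("no GU samples")
  pres <- cm$counts >= presence_min
  a <- colSums(pres[gu, , drop = FALSE])        # GU present
  c_ <- colSums(pres[nc, , drop = FALSE])       # NC present
  n_gu <- length(gu); n_nc <- length(nc)
  p <- .prev_test_p(a, n_gu - a, c_, n_nc - c_)
  prev_gu <- a / n_gu; prev_nc <- c_ / n_nc
  flag <- !is.na(p) & p < alpha & prev_nc > prev_gu & c_ > 0
  data.frame(asv_id = colnames(cm$counts),
             prevalence_gu = prev_gu, prevalence_nc = prev_nc,
             p = p, flag = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

## Vectorized 2x2 independence p-values: chi-square (no continuity
## correction) where all expected cells >= 5, Fisher's exact otherwise.
.prev_test_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  p <- rep(NA_real_, length(a))
  degenerate <- c1 == 0 | c2 == 0 | r1 == 0 | r2 == 0
  e_min <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  use_chisq <- !degenerate & e_min >= 5
  if (any(use_chisq)) {
    i <- which(use_chisq)
    stat <- n[i] * (a[i] * d[i] - b[i] * c_[i])^2 /
      (r1[i] * r2[i] * c1[i] * c2[i])
    p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  fish <- which(!degenerate & !use_chisq)
  for (i in fish) {
    p[i] <- stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2, 2,
                                      byrow = TRUE))$p.value
  }
  p[degenerate] <- 1
  p
}

#' Negative-control read-fraction filter
#'
#' Flags an ASV when the reads attributed to it in negative controls exceed
#' \code{max_frac} of that ASV's total reads, or when the number of NC samples
#' containing it exceeds \code{max_nc_sample_frac} of all samples.
#'
#' @param cm a \code{\link{count_matrix}}
#' @param max_frac threshold on NC reads / total reads per ASV (default 5\%)
#' @param max_nc_sample_frac threshold on (NC samples containing the ASV) /
#'   (total samples) (default 6\%)
#' @return data.frame per ASV: \code{asv_id}, \code{nc_read_fraction},
#'   \code{nc_sample_count}, \code{flag}
#' @export
nc_read_fraction_filter <- function(cm, max_frac = 0.05,
                                    max_nc_sample_frac = 0.06) {
  stopifnot(inherits(cm, "count_matrix"))
  nc <- samples_of_type(cm, "NC")
  total <- colSums(cm$counts)
  nc_reads <- if (length(nc)) colSums(cm$counts[nc, , drop = FALSE]) else
    numeric(ncol(cm$counts))
  frac <- ifelse(total > 0, nc_reads / total, 0)
  nc_n <- if (length(nc)) colSums(cm$counts[nc, , drop = FALSE] > 0) else
    integer(ncol(cm$counts))
  flag <- (total > 0 & frac > max_frac) |
    (nc_n > max_nc_sample_frac * nrow(cm$counts))
  data.frame(asv_id = colnames(cm$counts), nc_read_fraction = frac,
             nc_sample_count = as.integer(nc_n), flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-talk (index hopping) filter
#'
#' Flags ASVs present in fewer than \code{min_gu_samples} GU samples whose
#' relative abundance stays below \code{max_rel_abund} (default 5 per mille)
#' in every sample where they occur -- the signature of reads randomly
#' misassigned between multiplexed samples.
#'
#' @param cm a \code{\link{count_matrix}}
#' @param min_gu_samples GU-prevalence threshold (strictly fewer flags)
#' @param max_rel_abund per-sample relative-abundance ceiling (strictly below)
#' @param abund_stat how per-ASV abundance is summarized over the samples
#'   where it occurs: \code{"max"} (default; most conservative retention) or
#'   \code{"mean"}
#' @return data.frame per ASV: \code{asv_id}, \code{gu_prevalence_count},
#'   \code{abund_summary}, \code{flag}
#' @export
crosstalk_filter <- function(cm, min_gu_samples = 3L, max_rel_abund = 0.005,
                             abund_stat = c("max", "mean")) {
  stopifnot(inherits(cm, "count_matrix"))
  abund_stat <- match.arg(abund_stat)
  gu <- samples_of_type(cm, "GU")
  gcounts <- cm$counts[gu, , drop = FALSE]
  lib <- rowSums(gcounts)
  rel <- gcounts / ifelse(lib > 0, lib, 1)
  prev_n <- colSums(gcounts > 0)
  summ <- apply(rel, 2, function(col) {
    pos <- col[col > 0]
    if (!length(pos)) return(0)
    if (abund_stat == "max") max(pos) else mean(pos)
  })
  flag <- prev_n < min_gu_samples & summ < max_rel_abund
  data.frame(asv_id = colnames(cm$counts),
             gu_prevalence_count = as.integer(prev_n),
             abund_summary = summ, flag = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Apply the full four-rule contaminant-removal procedure
#'
#' Computes the three ASV-level rule flags on the unfiltered matrix
#' (prevalence test against NCs, NC read fraction, cross-talk signature),
#' removes the union of flagged ASVs, then drops GU samples whose retained
#' read fraction does not exceed the retention threshold (strictly more than
#' 50\% by default). Control samples are excluded from the output matrix but
#' summarized in the report.
#'
#' @param cm a \code{\link{count_matrix}} with at least one NC sample
#' @param alpha rule-1 p-value threshold (default 0.5)
#' @param max_frac,max_nc_sample_frac rule-2 thresholds (defaults 5\%, 6\%)
#' @param min_gu_samples,max_rel_abund rule-3 thresholds (defaults 3, 5 per mille)
#' @param retention rule-4 retained-read-fraction threshold (default 0.5;
#'   samples at exactly the threshold are dropped)
#' @param retention_mode \code{"per_sample"} (retained fraction of the
#'   sample's own pre-filter reads, default) or \code{"cohort_average"}
#'   (retained reads compared against the cohort-average pre-filter library)
#' @return list with \code{counts} (filtered GU-only \code{count_matrix}) and
#'   \code{report} (a \code{contaminant_report}: per-ASV flags and scores,
#'   per-sample retention, overall summary)
#' @export
apply_qc <- function(cm, alpha = 0.5, max_frac = 0.05,
                     max_nc_sample_frac = 0.06, min_gu_samples = 3L,
                     max_rel_abund = 0.005, retention = 0.5,
                     retention_mode = c("per_sample", "cohort_average")) {
  stopifnot(inherits(cm, "count_matrix"))
  retention_mode <- match.arg(retention_mode)
  r1 <- prevalence_contaminant_test(cm, alpha = alpha)
  r2 <- nc_read_fraction_filter(cm, max_frac = max_frac,
                                max_nc_sample_frac = max_nc_sample_frac)
  r3 <- crosstalk_filter(cm, min_gu_samples = min_gu_samples,
                         max_rel_abund = max_rel_abund)
  removed <- r1$flag | r2$flag | r3$flag

  asv_report <- data.frame(
    asv_id = r1$asv_id,
    prevalence_gu = r1$prevalence_gu, prevalence_nc = r1$prevalence_nc,
    prevalence_p = r1$p, nc_read_fraction = r2$nc_read_fraction,
    rule1 = r1$flag, rule2 = r2$flag, rule3 = r3$flag, removed = removed,
    stringsAsFactors = FALSE)

  gu <- samples_of_type(cm, "GU")
  gcounts <- cm$counts[gu, , drop = FALSE]
  before <- rowSums(gcounts)
  after <- rowSums(gcounts[, !removed, drop = FALSE])
  retained_frac <- ifelse(before > 0, after / before, 0)
  kept <- if (retention_mode == "per_sample") retained_frac > retention else
    after > retention * mean(before)
  if (!any(kept))
    stop("all GU samples dropped by the retention rule (threshold ",
         retention, ", mode ", retention_mode, "): check contamination load")

  sample_report <- data.frame(
    sample_id = gu, reads_before = before, reads_after = after,
    retained_fraction = retained_frac, sample_kept = kept,
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    asv = asv_report, sample = sample_report,
    summary = list(
      n_asvs_before = ncol(cm$counts),
      n_asvs_removed = sum(removed),
      n_removed_rule1 = sum(r1$flag), n_removed_rule2 = sum(r2$flag),
      n_removed_rule3 = sum(r3$flag),
      n_gu_before = length(gu), n_gu_kept = sum(kept),
      reads_retained_overall = sum(after[kept]) / sum(before[kept]))),
    class = "contaminant_report")

  filtered <- subset_count_matrix(cm, samples = gu[kept],
                                  asvs = which(!removed))
  list(counts = filtered, report = report)
}

#' @export
print.contaminant_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "contaminant_report: %d/%d ASVs removed (rule1 %d, rule2 %d, rule3 %d)\n",
    "  GU samples kept: %d/%d; reads retained overall: %.2f%%\n"),
    s$n_asvs_removed, s$n_asvs_before, s$n_removed_rule1, s$n_removed_rule2,
    s$n_removed_rule3, s$n_gu_kept, s$n_gu_before,
    100 * s$reads_retained_overall))
  invisible(x)
}
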