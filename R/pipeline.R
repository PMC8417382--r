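#' Assemble a pipeline configuration
#'
#' A plain list of stage parameters, either built here or loaded from a YAML
#' file (values in the file override the defaults; anything omitted keeps its
#' default). The seed is mandatory and feeds every stochastic stage through
#' per-stage offsets.
#'
#' @param yaml_path optional YAML file of overrides
#' @param ... named overrides applied after the YAML
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    scale = "desk", seed = 1L,
    qc = list(alpha = 0.5, max_frac = 0.05, max_nc_sample_frac = 0.06,
              min_gu_samples = 3, max_rel_abund = 0.005, retention = 0.5,
              retention_mode = "per_sample"),
    rarefaction_depth = 4000,
    rank = "genus",
    urotype = list(k_range = 2:10, mra_cutoff = 0.001, dominance_min = 0.25),
    network = list(rho_min = 0.35, q_max = 0.05),
    compare_group = "gender",
    depth_design = list(depth_grid = c(1000, 2000, 4000, 8000, 16000, 32000,
                                       64000),
                        n_grid = c(10, 25, 50, 75, 100, 150, 200, 300),
                        replicates = 5, target = 0.90))
  if (!is.null(yaml_path)) {
    over <- yaml::read_yaml(yaml_path)
    cfg <- utils::modifyList(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (is.null(cfg$seed)) stop("a seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> qc -> rarefy/profile -> diversity -> urotype ->
#' network -> cohort comparison -> depth design, writing every stage's
#' outputs under \code{out_dir} plus a run manifest (\code{manifest.json})
#' recording the effective configuration, the seeds, and an MD5 checksum of
#' every output file. Identical config + seed produces byte-identical
#' outputs and therefore identical manifest checksums.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, paste0(...))
  stage <- "simulate"
  manifest <- list(config = unclass(config), stages = character(), files = list())
  on.exit(if (!is.null(stage))
    writeLines(paste("FAILED at stage:", stage), p("FAILED")), add = TRUE)

  ## simulate
  sim_cfg <- default_paper_like_config(config$scale, seed = config$seed)
  sim <- simulate_cohort(sim_cfg)
  write_count_table(sim$counts, p("counts_raw.tsv"), p("sample_types.tsv"))
  write_taxonomy(sim$taxonomy, p("taxonomy.tsv"))
  write_tree(sim$tree, p("tree.nwk"))
  write_metadata(sim$metadata, p("metadata.tsv"))
  jsonlite::write_json(unclass(sim$truth), p("truth.json"), auto_unbox = TRUE,
                       digits = NA)

  ## qc
  stage <- "qc"
  if (length(samples_of_type(sim$counts, "NC")) == 0)
    stop("qc stage requires negative controls; none present")
  qc <- do.call(apply_qc, c(list(cm = sim$counts), config$qc))
  write_count_table(qc$counts, p("counts_qc.tsv"))
  write_report(qc$report, p("qc_report.json"))

  ## profile
  stage <- "profile"
  rare <- rarefy(qc$counts, depth = config$rarefaction_depth,
                 seed = config$seed + 1L)
  genus_cm <- collapse_taxonomy(rare, sim$taxonomy, config$rank)
  profile <- relative_abundance(genus_cm, rank = config$rank)
  core <- core_taxa(profile)
  utils::write.table(
    data.frame(taxon = names(profile$mra), mra = profile$mra,
               prevalence = profile$prevalence, row.names = NULL),
    p("profile_genus.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(core, p("core_taxa.json"), auto_unbox = FALSE)

  ## diversity
  stage <- "diversity"
  div <- compute_diversity(rare, sim$tree)
  utils::write.table(div$alpha, p("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## urotype
  stage <- "urotype"
  uro <- find_urotypes(profile, k_range = config$urotype$k_range,
                       mra_cutoff = config$urotype$mra_cutoff,
                       dominance_min = config$urotype$dominance_min)
  utils::write.table(
    data.frame(sample_id = names(uro$labels), urotype = uro$labels,
               row.names = NULL),
    p("urotype_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(uro$diagnostics, p("urotype_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(uro$cluster_info, p("urotype_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## network
  stage <- "network"
  net <- spearman_network(profile, rho_min = config$network$rho_min,
                          q_max = config$network$q_max)
  utils::write.table(net$edges, p("network_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, p("network_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  keystones <- detect_keystones(net, top_n = 10)
  utils::write.table(keystones, p("keystones.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  alpha_named <- stats::setNames(div$alpha$shannon, div$alpha$sample_id)
  trio <- trio_analysis(profile, sim$truth$trio_genera, alpha_named)
  jsonlite::write_json(
    list(joint_presence_count = trio$joint_presence_count,
         cooccurrence_p = trio$cooccurrence_p,
         shannon_assoc = trio$shannon_assoc),
    p("trio_stats.json"), auto_unbox = TRUE, digits = NA)

  ## cohort comparison
  stage <- "compare"
  meta <- assign_age_groups(sim$metadata)
  comp_ab <- compare_abundance(profile, meta, config$compare_group)
  comp_prev <- compare_prevalence(profile, meta, config$compare_group)
  utils::write.table(comp_ab, p("compare_abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comp_prev, p("compare_prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## depth design
  stage <- "depth_design"
  dd <- config$depth_design
  grid_ok <- dd$depth_grid[dd$depth_grid <= max(library_sizes(qc$counts))]
  n_ok <- dd$n_grid[dd$n_grid <= nrow(qc$counts$counts)]
  dcurve <- depth_sensitivity(qc$counts, grid_ok, replicates = dd$replicates,
                              seed = config$seed + 2L)
  ncurve <- samplesize_sensitivity(qc$counts, n_ok,
                                   replicates = dd$replicates,
                                   seed = config$seed + 3L)
  rec <- recommend_design(dcurve, ncurve, dd$target)
  utils::write.table(as.data.frame(dcurve), p("depth_curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(ncurve), p("samplesize_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rec, p("design_recommendation.json"),
                       auto_unbox = TRUE, digits = NA)

  ## manifest
  stage <- NULL
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest$stages <- c("simulate", "qc", "profile", "diversity", "urotype",
                       "network", "compare", "depth_design")
  manifest$files <- as.list(checksums)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
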