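#' Configuration for the synthetic genitourinary cohort generator
#'
#' Builds a validated configuration for \code{\link{simulate_cohort}}. The
#' defaults encode the statistical structure of a middle-aged/elderly urine
#' 16S survey: six dominant genera plus a long log-normal tail of low-abundance
#' genera, urotype structure driven by one boosted genus per cluster (with the
#' Prevotella-analog remaining close to a single log-normal and the other
#' dominants bimodal), a strongly co-abundant three-genus trio coupled to
#' community evenness, reagent contaminants that dominate the tiny
#' negative-control libraries, and rare cross-talk (index-hopping) artifacts.
#'
#' @param n_gu number of genitourinary samples
#' @param n_nc number of sterile-water negative controls
#' @param n_genera total number of true community genera (six dominants and the
#'   three trio genera are always included; the remainder form the tail)
#' @param n_true_asvs total ASVs across true genera (each genus owns 1-10 ASVs)
#' @param n_contaminant_asvs number of planted reagent-contaminant ASVs
#' @param n_hop_asvs number of planted index-hopping artifact ASVs
#' @param urotype_spec data.frame with columns \code{dominant_genus},
#'   \code{weight} (mixing proportions summing to 1) and \code{boost}
#'   (multiplicative abundance boost of the dominant genus within the urotype)
#' @param trio_spec list with \code{genera} (three genus names) and \code{rho}
#'   (Gaussian-copula correlation of their log abundances, in (0,1))
#' @param depth_distribution \code{c(meanlog, sdlog)} of the log-normal GU
#'   library-size distribution (reads)
#' @param nc_depth_distribution \code{c(meanlog, sdlog)} for NC library sizes;
#'   negative controls carry far less DNA, hence much smaller libraries
#' @param hop_rate fraction of each library's reads subject to cross-sample
#'   reassignment (index hopping); must be in [0, 0.01); 0 disables artifacts
#' @param contaminant_nc_load expected fraction of NC reads that are
#'   reagent contaminants (the remainder is trace carry-over of true taxa)
#' @param contaminant_gu_load typical fraction of a GU library made of
#'   reagent contaminants (log-normal median)
#' @param gender_effects named numeric vector of multiplicative abundance
#'   shifts applied to male samples, per genus
#' @param age_effects named numeric vector of per-year log-abundance slopes
#'   (centred at age 65), per genus
#' @param female_fraction probability a participant is female
#' @param age_range inclusive integer age range sampled uniformly
#' @param seed integer seed; all randomness flows from this single stream
#' @return object of class \code{simulation_config}
#' @export
simulation_config <- function(n_gu = 300,
                              n_nc = 10,
                              n_genera = 140,
                              n_true_asvs = 700,
                              n_contaminant_asvs = 30,
                              n_hop_asvs = 50,
                              urotype_spec = default_urotype_spec(),
                              trio_spec = list(
                                genera = c("Peptoniphilus", "Ezakiella",
                                           "Porphyromonas"),
                                rho = 0.8),
                              depth_distribution = c(meanlog = log(40000) - 0.08,
                                                     sdlog = 0.4),
                              nc_depth_distribution = c(meanlog = log(2000) - 0.125,
                                                        sdlog = 0.5),
                              hop_rate = 0.0005,
                              contaminant_nc_load = 0.8,
                              contaminant_gu_load = 0.004,
                              gender_effects = c(Prevotella = 0.6,
                                                 Lactobacillus = 0.6,
                                                 Streptococcus = 1.6,
                                                 Veillonella = 1.5,
                                                 Ezakiella = 1.4),
                              age_effects = c(Gardnerella = -0.04,
                                              Lactobacillus = -0.03,
                                              `Escherichia-Shigella` = 0.02),
                              female_fraction = 0.637,
                              age_range = c(45, 86),
                              seed = 1L) {
  cfg <- list(n_gu = as.integer(n_gu), n_nc = as.integer(n_nc),
              n_genera = as.integer(n_genera),
              n_true_asvs = as.integer(n_true_asvs),
              n_contaminant_asvs = as.integer(n_contaminant_asvs),
              n_hop_asvs = as.integer(n_hop_asvs),
              urotype_spec = urotype_spec, trio_spec = trio_spec,
              depth_distribution = depth_distribution,
              nc_depth_distribution = nc_depth_distribution,
              hop_rate = hop_rate,
              contaminant_nc_load = contaminant_nc_load,
              contaminant_gu_load = contaminant_gu_load,
              gender_effects = gender_effects, age_effects = age_effects,
              female_fraction = female_fraction, age_range = age_range,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default urotype specification (six clusters, one dominant genus each)
#'
#' The Prevotella-analog urotype is the commonest and carries only a mild
#' boost (its marginal abundance stays close to a single log-normal); the
#' other dominants get strong boosts, making their marginals bimodal.
#' @return data.frame with columns dominant_genus, weight, boost
#' @export
default_urotype_spec <- function() {
  data.frame(
    dominant_genus = c("Prevotella", "Streptococcus", "Lactobacillus",
                       "Gardnerella", "Escherichia-Shigella", "Veillonella"),
    weight = c(0.40, 0.14, 0.12, 0.10, 0.12, 0.12),
    boost = c(1.7, 40, 40, 40, 40, 40),
    stringsAsFactors = FALSE)
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_gu < 1 || n_nc < 0 || n_genera < 1 || n_true_asvs < 1 ||
        n_contaminant_asvs < 0 || n_hop_asvs < 0)
      stop("all counts in a simulation_config must be positive")
    if (n_genera < 9)
      stop("n_genera must be at least 9 (six dominants plus the trio)")
    if (nrow(urotype_spec) > n_genera)
      stop("infeasible config: more urotypes than genera")
    if (abs(sum(urotype_spec$weight) - 1) > 1e-8)
      stop("urotype mixing weights must sum to 1")
    if (any(urotype_spec$weight <= 0) || any(urotype_spec$boost <= 0))
      stop("urotype weights and boosts must be positive")
    if (hop_rate < 0 || hop_rate >= 0.01)
      stop("hop_rate must be in [0, 0.01)")
    if (trio_spec$rho <= 0 || trio_spec$rho >= 1)
      stop("trio copula correlation must be in (0, 1)")
    if (length(trio_spec$genera) != 3)
      stop("trio_spec$genera must name exactly three genera")
    if (contaminant_nc_load <= 0 || contaminant_nc_load >= 1)
      stop("contaminant_nc_load must be in (0, 1)")
    if (n_true_asvs < n_genera || n_true_asvs > 10L * n_genera)
      stop("n_true_asvs must allow 1-10 ASVs per genus")
  })
  invisible(cfg)
}

#' Paper-like default configurations at three scales
#'
#' \code{tiny} (30 GU + 5 NC) runs end-to-end in seconds and is meant for
#' smoke tests; \code{desk} (300 GU + 10 NC) is the working scale used by the
#' package's own validation; \code{full} mirrors the cohort shape of a large
#' survey (1,165 GU samples, 63.7\% female, ages 45-86, mean library size
#' about 40,000 reads).
#'
#' @param scale one of \code{"tiny"}, \code{"desk"}, \code{"full"}
#' @param seed integer seed stored in the config
#' @return a \code{simulation_config}
#' @export
default_paper_like_config <- function(scale = c("desk", "tiny", "full"),
                                      seed = 1L) {
  scale <- match.arg(scale)
  switch(scale,
    tiny = simulation_config(n_gu = 30, n_nc = 5, n_genera = 40,
                             n_true_asvs = 120, n_contaminant_asvs = 10,
                             n_hop_asvs = 10, seed = seed),
    desk = simulation_config(seed = seed),
    full = simulation_config(n_gu = 1165, n_nc = 35, seed = seed))
}

#' Simulate a genitourinary cohort with planted ground truth
#'
#' Generates GU and NC samples jointly: per-sample genus abundances on a log
#' scale (urotype dominant boosted; trio genera driven by a shared latent
#' factor with copula correlation \code{rho}; the same factor lifts the whole
#' low-abundance tail, coupling trio abundance to community evenness and hence
#' alpha diversity), multinomial ASV counts at log-normal library sizes,
#' compositional reagent contamination concentrated in the tiny NC libraries,
#' and index-hopping artifacts present in at most two GU samples at <5 per
#' mille relative abundance.
#'
#' @param config a \code{\link{simulation_config}}
#' @return list with elements \code{counts} (\code{count_matrix} of GU+NC),
#'   \code{taxonomy} (data.frame), \code{tree} (\code{ape::phylo} over all
#'   ASVs, genus-monophyletic), \code{metadata} (GU participants), and
#'   \code{truth} (\code{simulation_truth}: contaminant and artifact ASV sets,
#'   per-sample urotype labels, trio genera, genus-of-ASV map).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  cfg <- config

  ## ---- genus panel -------------------------------------------------------
  dominants <- cfg$urotype_spec$dominant_genus
  trio <- cfg$trio_spec$genera
  named <- unique(c(dominants, trio))
  n_tail <- cfg$n_genera - length(named)
  if (n_tail < 0) stop("n_genera too small for the named genera")
  tail_genera <- sprintf("Genus%03d", seq_len(n_tail))
  genera <- c(named, tail_genera)

  ## baseline genus weights (unnormalized, log-normal tail)
  base <- numeric(length(genera)); names(base) <- genera
  base[dominants] <- 0.012
  base["Prevotella"] <- 0.16
  base[trio] <- 0.022
  base[tail_genera] <- exp(stats::rnorm(n_tail, log(0.0012), 1.0))

  sigma <- rep(1.0, length(genera)); names(sigma) <- genera
  sigma[dominants] <- 0.45
  sigma["Prevotella"] <- 0.5
  sigma[trio] <- 0.7

  ## ---- participants ------------------------------------------------------
  n_gu <- cfg$n_gu; n_nc <- cfg$n_nc
  gu_ids <- sprintf("GU%04d", seq_len(n_gu))
  nc_ids <- if (n_nc > 0) sprintf("NC%03d", seq_len(n_nc)) else character()
  gender <- ifelse(stats::runif(n_gu) < cfg$female_fraction, "female", "male")
  age <- sample(cfg$age_range[1]:cfg$age_range[2], n_gu, replace = TRUE)
  region <- sample(c("Anqing", "Lianyungang", "Wuyuan"), n_gu, replace = TRUE)

  ## ---- per-sample genus abundances --------------------------------------
  n_uro <- nrow(cfg$urotype_spec)
  urotype <- sample.int(n_uro, n_gu, replace = TRUE,
                        prob = cfg$urotype_spec$weight)
  rho <- cfg$trio_spec$rho
  in_prev_uro <- cfg$urotype_spec$dominant_genus[urotype] == "Prevotella"
  ## latent trio/diversity factor; mildly higher in the urotype whose
  ## dominant is the Prevotella-analog (trio pattern typical of that urotype)
  z_shift <- ifelse(in_prev_uro, 0.8, -0.2)
  sd_z <- 0.7     # within-urotype spread of the latent factor
  z <- z_shift + stats::rnorm(n_gu, sd = sd_z)
  b_tail <- 0.6   # tail loading on z: trio-diversity coupling
  b_prev <- 0.5   # Prevotella-analog loading on z: it co-occurs with the trio
  ## direct trio enrichment in the Prevotella-analog urotype: the trio
  ## co-occurrence/co-abundance pattern is a defining feature of that urotype
  trio_shift <- ifelse(in_prev_uro, 1.8, -0.6)

  logw <- matrix(rep(log(base), each = n_gu), n_gu, length(genera),
                 dimnames = list(gu_ids, genera))
  ## urotype dominant boost
  boost <- cfg$urotype_spec$boost[urotype]
  logw[cbind(seq_len(n_gu),
             match(cfg$urotype_spec$dominant_genus[urotype], genera))] <-
    logw[cbind(seq_len(n_gu),
               match(cfg$urotype_spec$dominant_genus[urotype], genera))] +
    log(boost)
  ## stochastic parts
  for (g in genera) {
    if (g %in% trio) {
      eps <- stats::rnorm(n_gu)
      logw[, g] <- logw[, g] + trio_shift +
        sigma[g] * (sqrt(rho) * (z - z_shift) / sd_z + sqrt(1 - rho) * eps)
    } else if (g %in% tail_genera) {
      logw[, g] <- logw[, g] + b_tail * z + sigma[g] * stats::rnorm(n_gu)
    } else if (g == "Prevotella") {
      logw[, g] <- logw[, g] + b_prev * z + sigma[g] * stats::rnorm(n_gu)
    } else {
      logw[, g] <- logw[, g] + sigma[g] * stats::rnorm(n_gu)
    }
  }
  ## gender / age covariate shifts
  ge <- cfg$gender_effects
  for (g in intersect(names(ge), genera))
    logw[gender == "male", g] <- logw[gender == "male", g] + log(ge[[g]])
  ae <- cfg$age_effects
  for (g in intersect(names(ae), genera))
    logw[, g] <- logw[, g] + ae[[g]] * (age - 65)

  w <- exp(logw)
  p_genus <- w / rowSums(w)

  ## ---- genus -> ASV split ------------------------------------------------
  n_per_genus <- rep(1L, cfg$n_genera)
  extra <- cfg$n_true_asvs - cfg$n_genera
  while (extra > 0) {
    room <- which(n_per_genus < 10L)
    take <- sample(room, min(extra, length(room)),
                   replace = length(room) < extra)
    add <- tabulate(take, nbins = cfg$n_genera)
    add <- pmin(add, 10L - n_per_genus)
    n_per_genus <- n_per_genus + add
    extra <- cfg$n_true_asvs - sum(n_per_genus)
  }
  genus_of_asv <- rep(genera, times = n_per_genus)
  true_asv_ids <- sprintf("ASV%04d", seq_along(genus_of_asv))
  names(genus_of_asv) <- true_asv_ids
  split <- unlist(lapply(n_per_genus, function(k) {
    gkt <- stats::rgamma(k, 1); gkt / sum(gkt)
  }))
  p_asv <- p_genus[, genus_of_asv, drop = FALSE] *
    rep(split, each = n_gu)
  colnames(p_asv) <- true_asv_ids

  ## ---- contaminants ------------------------------------------------------
  n_cont <- cfg$n_contaminant_asvs
  cont_ids <- if (n_cont > 0) sprintf("ASVC%03d", seq_len(n_cont)) else character()
  w_cont <- if (n_cont > 0) {
    gk <- stats::rgamma(n_cont, 1); gk / sum(gk)
  } else numeric()

  ## GU counts: mixture of true composition and contaminant profile
  gu_cont_frac <- pmin(exp(stats::rnorm(n_gu, log(cfg$contaminant_gu_load), 0.5)),
                       0.05)
  depth_gu <- pmax(1000L, as.integer(round(stats::rlnorm(
    n_gu, cfg$depth_distribution[[1]], cfg$depth_distribution[[2]]))))
  all_ids <- c(true_asv_ids, cont_ids)
  counts_gu <- matrix(0L, n_gu, length(all_ids),
                      dimnames = list(gu_ids, all_ids))
  for (i in seq_len(n_gu)) {
    p <- c(p_asv[i, ] * (1 - gu_cont_frac[i]), w_cont * gu_cont_frac[i])
    counts_gu[i, ] <- stats::rmultinom(1, depth_gu[i], p)[, 1]
  }

  ## NC counts: mostly contaminants plus trace of the mean true composition
  counts_nc <- NULL
  if (n_nc > 0) {
    depth_nc <- pmax(200L, as.integer(round(stats::rlnorm(
      n_nc, cfg$nc_depth_distribution[[1]], cfg$nc_depth_distribution[[2]]))))
    mean_true <- colMeans(p_asv); mean_true <- mean_true / sum(mean_true)
    p_nc <- c(mean_true * (1 - cfg$contaminant_nc_load),
              w_cont * cfg$contaminant_nc_load)
    counts_nc <- matrix(0L, n_nc, length(all_ids),
                        dimnames = list(nc_ids, all_ids))
    for (j in seq_len(n_nc))
      counts_nc[j, ] <- stats::rmultinom(1, depth_nc[j], p_nc)[, 1]
  }

  counts <- rbind(counts_gu, if (!is.null(counts_nc)) counts_nc)

  ## ---- index-hopping artifacts ------------------------------------------
  hop_ids <- character()
  if (cfg$hop_rate > 0 && cfg$n_hop_asvs > 0) {
    hop_ids <- sprintf("ASVH%03d", seq_len(cfg$n_hop_asvs))
    hop <- matrix(0L, nrow(counts), cfg$n_hop_asvs,
                  dimnames = list(rownames(counts), hop_ids))
    mean_depth <- mean(depth_gu)
    for (h in seq_len(cfg$n_hop_asvs)) {
      n_s <- sample(1:2, 1)
      targets <- sample(seq_len(n_gu), n_s)
      for (i in targets) {
        reads <- 1L + stats::rpois(1, mean_depth * cfg$hop_rate)
        cap <- max(1L, as.integer(floor(0.004 * depth_gu[i])))
        hop[i, h] <- min(reads, cap)
      }
    }
    counts <- cbind(counts, hop)
  }

  sample_type <- stats::setNames(
    c(rep("GU", n_gu), rep("NC", n_nc)), c(gu_ids, nc_ids))
  cm <- count_matrix(counts, sample_type)

  ## ---- taxonomy ----------------------------------------------------------
  phyla <- c(Prevotella = "Bacteroidota", Porphyromonas = "Bacteroidota",
             Streptococcus = "Firmicutes", Lactobacillus = "Firmicutes",
             Veillonella = "Firmicutes", Peptoniphilus = "Firmicutes",
             Ezakiella = "Firmicutes", Gardnerella = "Actinobacteriota",
             `Escherichia-Shigella` = "Proteobacteria")
  pool <- c("Firmicutes", "Bacteroidota", "Actinobacteriota",
            "Proteobacteria", "Fusobacteriota")
  genus_phylum <- stats::setNames(
    c(phyla[named], sample(pool, n_tail, replace = TRUE)), genera)
  cont_genera <- if (n_cont > 0)
    stats::setNames(sprintf("ReagentGenus%02d", seq_len(n_cont)), cont_ids)
  else stats::setNames(character(), character())
  hop_genera <- stats::setNames(sprintf("HopGenus%02d", seq_along(hop_ids)),
                                hop_ids)
  asv_ids <- colnames(counts)
  genus_all <- c(genus_of_asv, cont_genera, hop_genera)[asv_ids]
  phylum_all <- ifelse(names(genus_all) %in% true_asv_ids,
                       genus_phylum[genus_all],
                       "Proteobacteria")
  taxonomy <- data.frame(
    asv_id = asv_ids,
    kingdom = "Bacteria",
    phylum = unname(phylum_all),
    class = paste0(unname(phylum_all), "_c"),
    order = paste0(unname(genus_all), "_o"),
    family = paste0(unname(genus_all), "_f"),
    genus = unname(genus_all),
    stringsAsFactors = FALSE)

  ## ---- tree: random coalescent with genus-level monophyly ----------------
  tree <- .simulate_tree(split(asv_ids, genus_all[asv_ids]))

  metadata <- data.frame(sample_id = gu_ids, gender = gender, age = age,
                         region = region, stringsAsFactors = FALSE)

  truth <- structure(list(
    contaminant_asvs = cont_ids,
    hop_artifact_asvs = hop_ids,
    urotype_label = stats::setNames(
      cfg$urotype_spec$dominant_genus[urotype], gu_ids),
    trio_genera = trio,
    genus_of_asv = stats::setNames(unname(genus_all), asv_ids)),
    class = "simulation_truth")

  list(counts = cm, taxonomy = taxonomy, tree = tree, metadata = metadata,
       truth = truth)
}

## Build a rooted tree whose leaves are ASV ids, monophyletic per genus:
## a random coalescent over genera, each genus tip replaced by a random
## coalescent subtree over its ASVs.
.simulate_tree <- function(asvs_by_genus) {
  k <- length(asvs_by_genus)
  tokens <- sprintf("GTOK%04d", seq_len(k))
  if (k >= 2) {
    top <- ape::rcoal(k, tip.label = tokens)
    nwk <- ape::write.tree(top)
  } else {
    nwk <- paste0(tokens, ":1;")
  }
  for (i in seq_len(k)) {
    asvs <- asvs_by_genus[[i]]
    rep_str <- if (length(asvs) == 1) asvs else {
      sub <- ape::rcoal(length(asvs), tip.label = asvs)
      sub$edge.length <- sub$edge.length * 0.1   # shallow within-genus splits
      sub("; *$", "", ape::write.tree(sub))
    }
    nwk <- sub(tokens[i], rep_str, nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}
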