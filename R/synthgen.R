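# Synthetic COSMIC-shaped mutation cohorts with planted cluster structure.
#
# Each synthetic cluster is defined by (i) a power-law gene-propensity
# profile with a partially shared top-gene backbone and cluster-unique top
# genes, (ii) a 12-category substitution-bias vector (one C>T/G>A-heavy
# transition-dominated cluster, one flatter cluster with elevated G>T),
# (iii) a per-chromosome rate profile, and (iv) a mutation-burden scale.
# Cohorts draw a Dirichlet-perturbed copy of their cluster's substitution
# bias, so within-cluster variation is controlled by a single
# concentration knob, and every mutation is emitted as a valid record that
# passes the package's own filters.

default_substitution_bias <- function() {
  b1 <- c(0.03, 0.07, 0.03, 0.05, 0.04, 0.26, 0.26, 0.04, 0.05, 0.03, 0.11, 0.03)
  b2 <- c(0.06, 0.08, 0.06, 0.07, 0.06, 0.14, 0.14, 0.06, 0.12, 0.06, 0.09, 0.06)
  m <- rbind(b1, b2)
  colnames(m) <- substitution_labels()
  rownames(m) <- NULL
  m
}

default_chrom_profile <- function() {
  lens <- grch38_chrom_lengths()
  base <- lens / sum(lens)
  p1 <- base
  p1["19"] <- p1["19"] * 3
  p1[c("1", "7", "9")] <- p1[c("1", "7", "9")] * 1.5
  p1 <- p1 / sum(p1)
  m <- rbind(p1, base / sum(base))
  rownames(m) <- NULL
  m
}

default_gene_propensity <- function(n_genes = 500L, n_top = 25L,
                                    shared_frac = 0.6, exponent = 1.1) {
  n_shared <- round(shared_frac * n_top)
  n_unique <- n_top - n_shared
  w <- (seq_len(n_genes))^(-exponent)
  build <- function(unique_block) {
    top <- c(seq_len(n_shared), unique_block)
    rest <- setdiff(seq_len(n_genes), top)
    ord <- c(top, rest)              # ord[r] = gene occupying rank r
    p <- numeric(n_genes)
    p[ord] <- w
    p / sum(p)
  }
  u1 <- seq(n_genes - 2 * n_unique + 1, n_genes - n_unique)
  u2 <- seq(n_genes - n_unique + 1, n_genes)
  rbind(build(u1), build(u2))
}

#' Configuration of the synthetic mutation-cohort generator
#'
#' Defaults emulate a two-cluster pan-cancer design: cluster 1 has a higher
#' mutation burden, C>T/G>A-dominated spectra and elevated load on a few
#' chromosomes; cluster 2 is lighter and flatter with relatively more G>T.
#' About 60% of each cluster's top-propensity genes are shared between
#' clusters, the rest are cluster-specific.
#'
#' @param n_cohorts Number of cohorts (default 40).
#' @param n_clusters Number of planted clusters (default 2; defaults for
#'   the profile matrices exist only for 2).
#' @param proportions Cluster mixing proportions (default equal).
#' @param n_genes Gene vocabulary size (default 500).
#' @param shared_frac Fraction of top-gene slots shared across clusters
#'   (default 0.6).
#' @param gene_exponent Power-law exponent of gene propensities (default 1.1).
#' @param burden Mean mutations per cohort, one per cluster
#'   (default c(30000, 10000), matching the scale of pooled per-cancer-type
#'   coding-SNV extracts and a 3:1 load contrast between clusters).
#' @param substitution_bias `n_clusters x 12` probability matrix.
#' @param chrom_profile `n_clusters x 24` probability matrix.
#' @param gene_propensity Optional `n_clusters x n_genes` probability
#'   matrix; built from the power-law defaults when NULL.
#' @param dirichlet_concentration Within-cluster concentration of the
#'   per-cohort substitution bias (larger = more homogeneous; default 1e4,
#'   i.e. cluster membership essentially determines a cohort's substitution
#'   mixture and residual within-cluster variation is dominated by
#'   sampling noise).
#' @param n_samples_per_cohort Synthetic tumor samples per cohort
#'   (default 50).
#' @param seed RNG seed (default 42).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cohorts = 40L, n_clusters = 2L,
                         proportions = NULL, n_genes = 500L,
                         shared_frac = 0.6, gene_exponent = 1.1,
                         burden = c(30000, 10000),
                         substitution_bias = default_substitution_bias(),
                         chrom_profile = default_chrom_profile(),
                         gene_propensity = NULL,
                         dirichlet_concentration = 1e4,
                         n_samples_per_cohort = 50L,
                         seed = 42L) {
  if (is.null(proportions)) proportions <- rep(1 / n_clusters, n_clusters)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (is.null(gene_propensity))
    gene_propensity <- default_gene_propensity(n_genes, 25L, shared_frac,
                                               gene_exponent)
  check_prob <- function(m, what) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-6))
      stop(what, " rows must be probability vectors")
  }
  check_prob(substitution_bias, "substitution_bias")
  check_prob(chrom_profile, "chrom_profile")
  check_prob(gene_propensity, "gene_propensity")
  stopifnot(nrow(substitution_bias) == n_clusters,
            nrow(chrom_profile) == n_clusters,
            nrow(gene_propensity) == n_clusters,
            length(burden) == n_clusters, all(burden > 0))
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_clusters = as.integer(n_clusters),
                 proportions = proportions, n_genes = as.integer(n_genes),
                 burden = burden, substitution_bias = substitution_bias,
                 chrom_profile = chrom_profile,
                 gene_propensity = gene_propensity,
                 dirichlet_concentration = dirichlet_concentration,
                 n_samples_per_cohort = as.integer(n_samples_per_cohort),
                 seed = as.integer(seed)),
            class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a synthetic mutation dataset with planted cluster labels
#'
#' Fully seeded: identical configs yield identical tables. Every emitted
#' record passes [filter_records()] (canonical chromosomes, single-base
#' ref != alt, coding).
#'
#' @param cfg A [synth_config()].
#' @return A `synth_dataset`: list with `records` (mutation table),
#'   `true_labels` (named integer vector, cohort -> cluster in 1..k), and
#'   `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  k <- cfg$n_clusters
  counts <- floor(cfg$proportions * cfg$n_cohorts)
  while (sum(counts) < cfg$n_cohorts)
    counts[which.max(cfg$proportions * cfg$n_cohorts - counts)] <-
      counts[which.max(cfg$proportions * cfg$n_cohorts - counts)] + 1
  labels <- rep(seq_len(k), counts)
  cohorts <- sprintf("COH%03d", seq_len(cfg$n_cohorts))
  names(labels) <- cohorts
  if (length(unique(labels)) < k) stop("every cluster needs at least one cohort")

  genes <- sprintf("SG%04d", seq_len(cfg$n_genes))
  chroms <- chromosome_labels()
  lens <- grch38_chrom_lengths()
  subs <- substitution_labels()
  ref_of <- substr(subs, 1, 1); alt_of <- substr(subs, 3, 3)

  per <- vector("list", cfg$n_cohorts)
  for (i in seq_len(cfg$n_cohorts)) {
    cl <- labels[i]
    m <- max(1L, stats::rpois(1, cfg$burden[cl]))
    bias <- rdirichlet1(cfg$dirichlet_concentration * cfg$substitution_bias[cl, ])
    gi <- sample.int(cfg$n_genes, m, replace = TRUE,
                     prob = cfg$gene_propensity[cl, ])
    ci <- sample.int(24L, m, replace = TRUE, prob = cfg$chrom_profile[cl, ])
    si <- sample.int(12L, m, replace = TRUE, prob = bias)
    pos <- 1L + as.integer(floor(stats::runif(m) * (lens[ci] - 1)))
    per[[i]] <- data.frame(
      cohort = cohorts[i],
      sample_id = paste0(cohorts[i], "_S",
                         sprintf("%03d", sample.int(cfg$n_samples_per_cohort,
                                                    m, replace = TRUE))),
      gene = genes[gi],
      chromosome = chroms[ci],
      position = pos,
      ref = ref_of[si],
      alt = alt_of[si],
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, per)
  records$coding_flag <- TRUE
  rownames(records) <- NULL
  structure(list(records = records, true_labels = labels, config = cfg),
            class = "synth_dataset")
}

#' Interpolate planted cluster separation
#'
#' Moves every cluster-level profile (gene propensities, substitution bias,
#' chromosome profile, burden) toward the across-cluster mean:
#' `level = 0` collapses all clusters onto one shared profile (null
#' configuration), `level = 1` returns the config unchanged.
#'
#' @param cfg A [synth_config()].
#' @param level Real in \[0, 1\].
#' @return A new `synth_config`.
#' @export
separation_dial <- function(cfg, level) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.numeric(level) || level < 0 || level > 1)
    stop("level must be in [0, 1]")
  blend <- function(M) {
    mu <- colMeans(M)
    t(apply(M, 1, function(r) mu + level * (r - mu)))
  }
  cfg$substitution_bias <- blend(cfg$substitution_bias)
  cfg$chrom_profile <- blend(cfg$chrom_profile)
  cfg$gene_propensity <- blend(cfg$gene_propensity)
  mb <- mean(cfg$burden)
  cfg$burden <- mb + level * (cfg$burden - mb)
  cfg
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard mutation TSV consumed by [read_mutation_table()] plus
#' `true_labels.csv`.
#'
#' @param ds A `synth_dataset`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- file.path(dir, "mutations.tsv")
  pl <- file.path(dir, "true_labels.csv")
  write_mutation_table(ds$records, pm)
  data.table::fwrite(data.frame(cohort = names(ds$true_labels),
                                cluster = as.integer(ds$true_labels)), pl)
  invisible(c(pm, pl))
}
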