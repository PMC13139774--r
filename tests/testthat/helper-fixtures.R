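# Shared fixtures and oracles. Everything is generated in code; heavy
# end-to-end runs are memoized so several test files can share them.

toy_records <- function(cohort = "LUNG",
                        gene = c("TP53", "TP53", "TP53", "TP53", "KRAS", "KRAS"),
                        chromosome = c("17", "17", "17", "17", "12", "12"),
                        ref = c("C", "C", "C", "G", "A", "A"),
                        alt = c("T", "T", "T", "A", "T", "T"),
                        position = seq(1000, by = 100, length.out = length(gene))) {
  data.frame(cohort = cohort,
             sample_id = paste0("S", seq_along(gene)),
             gene = gene, chromosome = chromosome, position = position,
             ref = ref, alt = alt, coding_flag = TRUE,
             stringsAsFactors = FALSE)
}

random_records <- function(n, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  data.frame(
    cohort = sample(c("A", "B", "C"), n, replace = TRUE),
    sample_id = paste0("S", sample(50, n, replace = TRUE)),
    gene = sample(c("TP53", "KRAS", "BRAF", "WEIRD_ENST0001", "EGFR"), n, TRUE),
    chromosome = sample(c(chromosome_labels(), "MT", "chr1_KI270706v1"), n, TRUE),
    position = sample(c(1:100000, -1L, NA_integer_), n, TRUE),
    ref = sample(c(bases, "AT", "N"), n, TRUE),
    alt = sample(c(bases, ""), n, TRUE),
    coding_flag = sample(c(TRUE, TRUE, TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
}

# small but trainable feature views (12 cohorts, 2 planted clusters)
tiny_views <- function(seed = 7, n_cohorts = 12, burden = c(2000, 800)) {
  cfg <- synth_config(n_cohorts = n_cohorts, burden = burden, seed = seed)
  ds <- generate_dataset(cfg)
  fl <- filter_records(ds$records)
  by_cohort <- split(fl$records, fl$records$cohort)
  views <- assemble_feature_views(lapply(by_cohort, build_gene_signature),
                                  lapply(by_cohort, build_chromosome_signature))
  list(views = views, truth = ds$true_labels[views$cohorts], dataset = ds)
}

views_from_dataset <- function(ds) {
  fl <- filter_records(ds$records)
  by_cohort <- split(fl$records, fl$records$cohort)
  list(
    gene_sigs = lapply(by_cohort, build_gene_signature),
    chrom_sigs = lapply(by_cohort, build_chromosome_signature),
    views = assemble_feature_views(lapply(by_cohort, build_gene_signature),
                                   lapply(by_cohort, build_chromosome_signature))
  )
}

# memoized full-scale end-to-end run (40 cohorts, 100 epochs) used by the
# acceptance and ablation tests; one entry per (seed, separation level)
.e2e_cache <- new.env(parent = emptyenv())

e2e_run <- function(seed, level = 1) {
  key <- sprintf("s%d_l%g", seed, level)
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  cfg <- separation_dial(synth_config(seed = seed), level)
  ds <- generate_dataset(cfg)
  fl <- filter_records(ds$records)
  by_cohort <- split(fl$records, fl$records$cohort)
  views <- assemble_feature_views(lapply(by_cohort, build_gene_signature),
                                  lapply(by_cohort, build_chromosome_signature))
  fit <- train_ms_contab(views, cfg = train_config(seed = seed))
  cl <- kmeans_cluster(fit$embedding$Z_fused, 2, seed = seed)
  truth <- ds$true_labels[views$cohorts]
  res <- list(
    views = views, fit = fit, cluster = cl, truth = truth,
    ari = mclust::adjustedRandIndex(cl$labels, truth),
    metrics = internal_metrics(fit$embedding$Z_fused, cl$labels)
  )
  .e2e_cache[[key]] <- res
  res
}

# brute-force NT-Xent oracle: plain double loop over anchors and negatives
ntxent_bruteforce <- function(Zg, Zc, tau, denominator = "exclude_anchor") {
  Z <- rbind(Zg, Zc)
  Z <- Z / sqrt(rowSums(Z^2))
  n2 <- nrow(Z)
  N <- n2 / 2
  partner <- function(i) if (i <= N) i + N else i - N
  losses <- numeric(n2)
  for (i in seq_len(n2)) {
    j <- partner(i)
    den <- 0
    for (k in seq_len(n2)) {
      skip <- if (denominator == "exclude_anchor") k == i else k == j
      if (!skip) den <- den + exp(sum(Z[i, ] * Z[k, ]) / tau)
    }
    losses[i] <- -log(exp(sum(Z[i, ] * Z[j, ]) / tau) / den)
  }
  list(anchor_losses = losses, loss = mean(losses))
}

# external reference for the three internal validity indices
sklearn_metrics <- function(Z, labels) {
  fz <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  fo <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".py")
  on.exit(unlink(c(fz, fl, fo, fs)))
  write.table(Z, fz, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(as.integer(factor(labels)), fl, sep = ",",
              row.names = FALSE, col.names = FALSE)
  writeLines(sprintf(paste0(
    "import numpy as np\n",
    "from sklearn import metrics\n",
    "X = np.loadtxt(%s, delimiter=','); y = np.loadtxt(%s)\n",
    "if X.ndim == 1: X = X.reshape(-1, 1)\n",
    "out = [metrics.silhouette_score(X, y), metrics.davies_bouldin_score(X, y),\n",
    "       metrics.calinski_harabasz_score(X, y)]\n",
    "np.savetxt(%s, np.array(out), delimiter=',', fmt='%%.17g')\n"),
    deparse(fz), deparse(fl), deparse(fo)), fs)
  status <- system2("python", fs, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python sklearn oracle unavailable")
  v <- scan(fo, quiet = TRUE)
  list(silhouette = v[1], davies_bouldin = v[2], calinski_harabasz = v[3])
}

# KKT certificate that s is the Euclidean projection of v onto the simplex
sparsemax_kkt_ok <- function(v, s, tol = 1e-8) {
  if (abs(sum(s) - 1) > tol || any(s < -tol)) return(FALSE)
  supp <- s > tol
  if (!any(supp)) return(FALSE)
  # on the support s_i = v_i - tau, so tau is recoverable from any active
  # coordinate; off-support optimality requires v_j <= tau
  tau <- mean(v[supp] - s[supp])
  ok_supp <- all(abs(s[supp] - (v[supp] - tau)) < 1e-6)
  ok_off <- all(v[!supp] <= tau + 1e-6)
  ok_supp && ok_off
}
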