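# End-to-end orchestration: filter -> featurize -> train -> fuse ->
# cluster -> evaluate -> report, driven by a single validated config.

#' Default pipeline configuration
#'
#' @return Nested list of all pipeline settings (paths, filter rules,
#'   signature options, encoder and training hyperparameters, clustering
#'   and projection options). Every seed lives under the stage that uses
#'   it and defaults to 42.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(input_table = NULL, chrom_lengths = NULL, output_dir = "mscontab_out"),
    filter = list(rules = FILTER_RULES, transcript_marker = "_ENST", dedup = "none"),
    signatures = list(top_k = 25L, restrict_to_top_genes = FALSE,
                      scaling = "log1p_center"),
    encoder = list(n_steps = 3L, n_d = 64L, n_a = 64L, gamma = 1.3),
    train = list(epochs = 100L, learning_rate = 1e-3, batch_size = 8L,
                 temperature = 0.5, seed = 42L,
                 fusion_mode = "mean_normalized", denominator = "exclude_anchor"),
    clustering = list(k = 2L, n_init = 10L, seed = 42L),
    projection = list(method = "pca", seed = 42L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults))
      stop("unknown config key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and validate a pipeline config file
#'
#' YAML file whose keys must be a subset of [default_pipeline_config()];
#' unknown keys raise an error naming the offending key.
#'
#' @param path YAML config path.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user %||% list())
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes filter -> featurize -> train -> fuse -> cluster -> evaluate and
#' writes every artifact plus a manifest (file, md5 checksum, producing
#' stage) into the output directory. Deterministic given the seeds in the
#' config; rerunning with the same config reproduces identical checksums
#' for all deterministic artifacts.
#'
#' @param cfg Config list from [read_pipeline_config()] /
#'   [default_pipeline_config()], or a path to a YAML config.
#' @return Invisibly, a list with the in-memory results and the manifest
#'   `data.frame`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (is.null(cfg$paths$input_table)) stop("config paths.input_table is required")
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  add <- function(stage, paths) {
    for (p in paths) artifacts[[length(artifacts) + 1]] <<-
      data.frame(file = basename(p), path = p, stage = stage,
                 stringsAsFactors = FALSE)
  }

  stage_log("filter", "reading ", cfg$paths$input_table)
  recs <- read_mutation_table(cfg$paths$input_table)
  fl <- filter_records(recs, rules = cfg$filter$rules,
                       transcript_marker = cfg$filter$transcript_marker,
                       dedup = cfg$filter$dedup)
  p_filt <- file.path(out, "filtered.tsv")
  write_mutation_table(fl$records, p_filt)
  p_rep <- file.path(out, "filter_report.json")
  write_filter_report(fl$report, p_rep)
  add("filter", c(p_filt, p_rep))
  stage_log("filter", fl$report$n_retained, "/", fl$report$n_input, " records retained")

  stage_log("featurize", "building signatures")
  lengths <- if (!is.null(cfg$paths$chrom_lengths))
    read_chrom_lengths(cfg$paths$chrom_lengths) else grch38_chrom_lengths()
  by_cohort <- split(fl$records, fl$records$cohort)
  gene_sigs <- lapply(by_cohort, build_gene_signature,
                      top_k = cfg$signatures$top_k)
  chrom_sigs <- lapply(by_cohort, build_chromosome_signature,
                       lengths = lengths,
                       restrict_to_top_genes = cfg$signatures$restrict_to_top_genes,
                       top_k = cfg$signatures$top_k)
  views <- assemble_feature_views(gene_sigs, chrom_sigs,
                                  scaling = cfg$signatures$scaling)
  add("featurize", write_feature_views(views, out))

  stage_log("train", "contrastive training (", cfg$train$epochs, " epochs)")
  tc <- train_config(epochs = cfg$train$epochs,
                     learning_rate = cfg$train$learning_rate,
                     batch_size = cfg$train$batch_size,
                     temperature = cfg$train$temperature,
                     seed = cfg$train$seed,
                     fusion_mode = cfg$train$fusion_mode,
                     denominator = cfg$train$denominator)
  ep_g <- encoder_params(ncol(views$Xg), cfg$encoder$n_steps, cfg$encoder$n_d,
                         cfg$encoder$n_a, cfg$encoder$gamma)
  ep_c <- encoder_params(ncol(views$Xc), cfg$encoder$n_steps, cfg$encoder$n_d,
                         cfg$encoder$n_a, cfg$encoder$gamma)
  fit <- train_ms_contab(views, ep_g, ep_c, cfg = tc)
  add("train", write_embeddings(fit, out))

  stage_log("cluster", "k-means, k = ", cfg$clustering$k)
  Z <- fit$embedding$Z_fused
  cl <- kmeans_cluster(Z, cfg$clustering$k, seed = cfg$clustering$seed,
                       n_init = cfg$clustering$n_init)
  p_cl <- file.path(out, "clusters.csv")
  data.table::fwrite(data.frame(cohort = cl$cohorts, cluster = cl$labels, row.names = NULL), p_cl)
  add("cluster", p_cl)

  stage_log("evaluate", "metrics and downstream summaries")
  metrics <- internal_metrics(Z, cl$labels)
  metrics_all <- list(original = unclass(metrics))
  proj <- tryCatch(project_2d(Z, method = cfg$projection$method,
                              seed = cfg$projection$seed),
                   error = function(e) {
                     stage_log("evaluate", "2-D projection skipped: ",
                               conditionMessage(e))
                     NULL
                   })
  if (!is.null(proj))
    metrics_all$projected_2d <-
      unclass(internal_metrics(proj, cl$labels, space_tag = "projected_2d"))
  p_met <- file.path(out, "metrics.json")
  jsonlite::write_json(metrics_all, p_met, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  M <- cosine_matrix(Z, labels = cl$labels)
  p_sim <- file.path(out, "similarity_matrix.csv")
  data.table::fwrite(data.frame(cohort = rownames(M), M, check.names = FALSE, row.names = NULL), p_sim)
  nn <- nearest_neighbors(Z, m = min(3L, nrow(Z) - 1L))
  p_nn <- file.path(out, "neighbors.csv")
  data.table::fwrite(nn, p_nn)
  spectra <- cluster_spectra(gene_sigs, chrom_sigs, cl$labels)
  p_sp <- file.path(out, "spectra.csv")
  sp_df <- rbind(
    data.frame(cluster = rownames(spectra$substitution), type = "substitution",
               feature = rep(colnames(spectra$substitution),
                             each = nrow(spectra$substitution)),
               value = as.vector(spectra$substitution)),
    data.frame(cluster = rownames(spectra$chromosome_load), type = "chromosome_load",
               feature = rep(colnames(spectra$chromosome_load),
                             each = nrow(spectra$chromosome_load)),
               value = as.vector(spectra$chromosome_load))
  )
  data.table::fwrite(sp_df, p_sp)
  overlap <- gene_set_overlap(gene_sigs, cl$labels)
  p_ov <- file.path(out, "gene_overlap.json")
  jsonlite::write_json(overlap, p_ov, auto_unbox = TRUE, pretty = TRUE)
  add("evaluate", c(p_met, p_sim, p_nn, p_sp, p_ov))

  manifest <- do.call(rbind, artifacts)
  manifest$md5 <- unname(tools::md5sum(manifest$path))
  p_man <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest[, c("file", "stage", "md5")], p_man,
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log("done", nrow(manifest), " artifacts in ", out)
  invisible(list(filter = fl, views = views, fit = fit, cluster = cl,
                 metrics = metrics_all, manifest = manifest))
}
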