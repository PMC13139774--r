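#' The 12 ordered single-nucleotide substitution categories
#'
#' Strand-specific ordered pairs over \{A,C,G,T\} in fixed lexicographic
#' order: A>C, A>G, A>T, C>A, C>G, C>T, G>A, G>C, G>T, T>A, T>C, T>G.
#' Complementary substitutions (e.g. C>T and G>A) are kept separate; they
#' carry distinct biological signal and are not collapsed to the 6
#' pyrimidine-centric classes.
#'
#' @return Character vector of length 12, e.g. `"C>T"`.
#' @export
substitution_labels <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (r in bases) for (a in bases) if (r != a) out <- c(out, paste0(r, ">", a))
  out
}

#' Index of a substitution in the fixed 12-category order
#'
#' @param ref,alt Single bases in \{A,C,G,T\}; vectors are recycled
#'   elementwise.
#' @return Integer vector of 0-based indices in 0..11.
#' @export
substitution_index <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases))
    stop("ref and alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref must differ from alt (not a substitution)")
  labs <- substitution_labels()
  match(paste0(ref, ">", alt), labs) - 1L
}

#' GRCh38 primary-assembly chromosome lengths
#'
#' Lengths in base pairs of the 24 canonical human chromosomes
#' (GRCh38/hg38 primary assembly), used to normalize per-chromosome
#' mutation counts into loads (mutations per bp).
#'
#' @return Named numeric vector over "1".."22","X","Y".
#' @export
grch38_chrom_lengths <- function() {
  stats::setNames(c(
    248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
    159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
    114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
    58617616, 64444167, 46709983, 50818468, 156040895, 57227415
  ), chromosome_labels())
}

#' Read a chromosome-length table
#'
#' @param path 2-column TSV (chromosome, length_bp), with or without header.
#' @return Named numeric vector covering the 24 canonical chromosomes.
#' @export
read_chrom_lengths <- function(path) {
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  lens <- stats::setNames(as.numeric(dt[[2]]), normalize_chromosome(dt[[1]]))
  missing <- setdiff(chromosome_labels(), names(lens))
  if (length(missing)) stop("chromosome length table missing: ",
                            paste(missing, collapse = ", "))
  if (any(lens <= 0)) stop("chromosome lengths must be positive")
  lens[chromosome_labels()]
}

#' Gene-level mutation signature of one cohort
#'
#' Ranks the cohort's genes by total mutation count (ties broken
#' alphabetically), keeps the top `top_k`, and tallies each retained gene's
#' mutations over the 12 substitution categories. The `top_k x 12` count
#' matrix is zero-padded when fewer than `top_k` genes are mutated and
#' flattened row-major (gene-rank major) to a fixed-length vector, 300-dim
#' at the default `top_k = 25`.
#'
#' @param records Filtered mutation records from a single cohort.
#' @param top_k Number of gene rows (default 25).
#' @param cohort Cohort label; inferred from the records when omitted.
#' @return A `gene_signature`: list with `cohort`, `genes` (ranked, length
#'   <= top_k), `matrix` (top_k x 12 integer counts), `x_g` (length
#'   `12 * top_k`).
#' @export
build_gene_signature <- function(records, top_k = 25L, cohort = NULL) {
  subs <- substitution_labels()
  if (is.null(cohort)) {
    cohort <- if (nrow(records) > 0) records$cohort[1] else NA_character_
  }
  if (nrow(records) > 0 && length(unique(records$cohort)) > 1)
    stop("records from more than one cohort")
  mat <- matrix(0L, nrow = top_k, ncol = 12L,
                dimnames = list(NULL, subs))
  genes <- character(0)
  if (nrow(records) == 0) {
    warning("empty record set: returning all-zero gene signature")
  } else {
    tot <- table(records$gene)
    ord <- order(-as.integer(tot), names(tot), method = "radix")
    genes <- head(names(tot)[ord], top_k)
    idx <- substitution_index(records$ref, records$alt) + 1L
    sel <- records$gene %in% genes
    tab <- table(factor(records$gene[sel], levels = genes),
                 factor(idx[sel], levels = 1:12))
    mat[seq_along(genes), ] <- as.integer(tab)
    rownames(mat) <- c(genes, rep("", top_k - length(genes)))
  }
  structure(list(cohort = cohort, genes = genes, matrix = mat,
                 x_g = as.vector(t(mat)), top_k = top_k),
            class = "gene_signature")
}

#' Chromosome-level mutation signature of one cohort
#'
#' Counts substitutions per (chromosome, substitution category) and divides
#' each chromosome's row by its length in bp, yielding a 24 x 12 matrix of
#' length-normalized loads, flattened row-major (chromosome-major,
#' order 1..22, X, Y) to a 288-dim vector.
#'
#' @param records Filtered records from a single cohort.
#' @param lengths Named chromosome-length vector; default GRCh38.
#' @param restrict_to_top_genes If TRUE, only mutations in the cohort's
#'   top-`top_k` genes are counted (default FALSE: all retained coding
#'   SNVs contribute).
#' @param top_k Gene cut used when `restrict_to_top_genes` is TRUE.
#' @param cohort Cohort label; inferred when omitted.
#' @return A `chromosome_signature`: list with `cohort`, `matrix`
#'   (24 x 12 rates), `x_c` (length 288).
#' @export
build_chromosome_signature <- function(records, lengths = grch38_chrom_lengths(),
                                       restrict_to_top_genes = FALSE,
                                       top_k = 25L, cohort = NULL) {
  chroms <- chromosome_labels()
  subs <- substitution_labels()
  if (is.null(cohort)) {
    cohort <- if (nrow(records) > 0) records$cohort[1] else NA_character_
  }
  missing <- setdiff(chroms, names(lengths))
  if (length(missing)) stop("length table missing chromosomes: ",
                            paste(missing, collapse = ", "))
  if (nrow(records) > 0 && !all(records$chromosome %in% chroms))
    stop("records contain non-canonical chromosomes; filter first")
  if (restrict_to_top_genes && nrow(records) > 0) {
    gs <- build_gene_signature(records, top_k = top_k, cohort = cohort)
    records <- records[records$gene %in% gs$genes, , drop = FALSE]
  }
  counts <- matrix(0, nrow = 24, ncol = 12, dimnames = list(chroms, subs))
  if (nrow(records) > 0) {
    idx <- substitution_index(records$ref, records$alt) + 1L
    tab <- table(factor(records$chromosome, levels = chroms),
                 factor(idx, levels = 1:12))
    counts[] <- as.numeric(tab)
  }
  rates <- counts / as.numeric(lengths[chroms])
  structure(list(cohort = cohort, matrix = rates, x_c = as.vector(t(rates))),
            class = "chromosome_signature")
}

#' Assemble per-cohort signatures into scaled feature views
#'
#' Stacks gene-level and chromosome-level signature vectors into two
#' matrices with one aligned row per cohort and applies the train-time
#' feature scaling (default: `log1p`, per-feature centering, one pooled
#' scale per view; features constant across cohorts map to 0). Scaling
#' parameters are stored so the transform is reusable and invertible.
#'
#' @param gene_sigs List of `gene_signature` objects.
#' @param chrom_sigs List of `chromosome_signature` objects (same cohorts).
#' @param scaling `"log1p_center"` (default): `log1p`, center each feature,
#'   then divide the whole view by one pooled scale factor (the root mean
#'   feature variance), preserving the relative variance of features within
#'   a view so that low-variance noise features are not amplified.
#'   `"log1p_zscore"`: classical per-feature standardization (constant
#'   features map to 0). `"none"`: raw counts/rates.
#' @return A `feature_views`: list with `cohorts`, `Xg` (n x 300), `Xc`
#'   (n x 288), `Xg_raw`, `Xc_raw` (pre-scaling), and `scaling` metadata.
#' @export
assemble_feature_views <- function(gene_sigs, chrom_sigs,
                                   scaling = c("log1p_center", "log1p_zscore",
                                               "none")) {
  scaling <- match.arg(scaling)
  gc_names <- vapply(gene_sigs, function(s) s$cohort, character(1))
  cc_names <- vapply(chrom_sigs, function(s) s$cohort, character(1))
  if (!setequal(gc_names, cc_names))
    stop("cohorts differ between gene and chromosome views: ",
         paste(union(setdiff(gc_names, cc_names), setdiff(cc_names, gc_names)),
               collapse = ", "))
  cohorts <- sort(gc_names)
  gi <- match(cohorts, gc_names); ci <- match(cohorts, cc_names)
  Xg_raw <- do.call(rbind, lapply(gene_sigs[gi], function(s) s$x_g))
  Xc_raw <- do.call(rbind, lapply(chrom_sigs[ci], function(s) s$x_c))
  rownames(Xg_raw) <- rownames(Xc_raw) <- cohorts
  top_k <- gene_sigs[[1]]$top_k
  colnames(Xg_raw) <- paste0("gene_rank", sprintf("%02d", rep(seq_len(top_k), each = 12)),
                             "|", rep(substitution_labels(), top_k))
  colnames(Xc_raw) <- paste0("chr", rep(chromosome_labels(), each = 12),
                             "|", rep(substitution_labels(), 24))

  fit_scale <- function(X) {
    if (scaling == "none")
      return(list(X = X, mu = rep(0, ncol(X)), sd = rep(1, ncol(X))))
    L <- log1p(X)
    mu <- colMeans(L)
    sdv <- apply(L, 2, stats::sd)
    sdv[!is.finite(sdv)] <- 0
    Z <- sweep(L, 2, mu, "-")
    if (scaling == "log1p_zscore") {
      nz <- sdv > 0
      Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sdv[nz], "/")
      Z[, !nz] <- 0
      return(list(X = Z, mu = mu, sd = sdv))
    }
    # log1p_center: one pooled scale per view keeps the features'
    # relative variances (noise features stay small)
    pooled <- sqrt(mean(sdv^2))
    if (pooled == 0) pooled <- 1
    list(X = Z / pooled, mu = mu, sd = rep(pooled, ncol(X)))
  }
  sg <- fit_scale(Xg_raw); sc <- fit_scale(Xc_raw)
  structure(list(cohorts = cohorts, Xg = sg$X, Xc = sc$X,
                 Xg_raw = Xg_raw, Xc_raw = Xc_raw,
                 scaling = list(method = scaling,
                                gene = list(mu = sg$mu, sd = sg$sd),
                                chrom = list(mu = sc$mu, sd = sc$sd))),
            class = "feature_views")
}

#' Apply stored feature-view scaling to new raw matrices
#' @param views A `feature_views` (supplies the scaling parameters).
#' @param X_raw Raw (pre-scaling) matrix.
#' @param which `"gene"` or `"chrom"`.
#' @return Scaled matrix.
#' @export
scale_view <- function(views, X_raw, which = c("gene", "chrom")) {
  which <- match.arg(which)
  if (views$scaling$method == "none") return(X_raw)
  p <- views$scaling[[which]]
  L <- log1p(X_raw)
  Z <- sweep(L, 2, p$mu, "-")
  nz <- p$sd > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, p$sd[nz], "/")
  Z[, !nz] <- 0
  Z
}

#' Invert the feature-view scaling
#' @inheritParams scale_view
#' @param X_scaled Scaled matrix.
#' @return Raw-scale matrix (columns with zero variance return the stored
#'   constant value).
#' @export
unscale_view <- function(views, X_scaled, which = c("gene", "chrom")) {
  which <- match.arg(which)
  if (views$scaling$method == "none") return(X_scaled)
  p <- views$scaling[[which]]
  L <- X_scaled
  nz <- p$sd > 0
  L[, nz] <- sweep(L[, nz, drop = FALSE], 2, p$sd[nz], "*")
  L[, !nz] <- 0
  L <- sweep(L, 2, p$mu, "+")
  expm1(L)
}

#' Export feature views as wide CSVs
#' @param views A `feature_views`.
#' @param dir Output directory.
#' @param raw Write the raw (pre-scaling) matrices instead of scaled ones.
#' @return Paths of the two files, invisibly.
#' @export
write_feature_views <- function(views, dir, raw = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Xg <- if (raw) views$Xg_raw else views$Xg
  Xc <- if (raw) views$Xc_raw else views$Xc
  pg <- file.path(dir, "gene_view.csv"); pc <- file.path(dir, "chromosome_view.csv")
  data.table::fwrite(data.frame(cohort = views$cohorts, Xg, check.names = FALSE, row.names = NULL), pg)
  data.table::fwrite(data.frame(cohort = views$cohorts, Xc, check.names = FALSE, row.names = NULL), pc)
  invisible(c(pg, pc))
}
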