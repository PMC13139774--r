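# Downstream evaluation of the learned cohort embeddings: k-means
# clustering, internal validity indices, similarity structure, prototypes,
# neighbors, cluster-level mutation spectra, and top-gene set overlap.

#' K-means clustering of cohort embeddings
#'
#' Best of `n_init` seeded restarts by total within-cluster sum of squares
#' (Hartigan–Wong). Cluster ids are canonicalized to 0..k-1 in order of
#' first appearance so relabeling is stable across platforms.
#'
#' @param Z Embedding matrix (rownames = cohort labels).
#' @param k Number of clusters (2 <= k <= n).
#' @param seed RNG seed (default 42).
#' @param n_init Number of restarts (default 10).
#' @return A `cluster_result`: list with `cohorts`, `labels` (0-based,
#'   named), `k`, `centroids`, `seed`.
#' @export
kmeans_cluster <- function(Z, k, seed = 42L, n_init = 10L) {
  n <- nrow(Z)
  if (k > n) stop("k = ", k, " exceeds number of points n = ", n)
  if (k < 1) stop("k must be >= 1")
  set.seed(seed)
  if (k == n) {
    # degenerate: every point is its own cluster (zero within-SS)
    km <- list(cluster = seq_len(n), centers = Z)
  } else {
    km <- stats::kmeans(Z, centers = k, nstart = n_init, iter.max = 100L)
  }
  raw <- km$cluster
  first <- unique(raw)
  labels <- match(raw, first) - 1L
  centroids <- km$centers[first, , drop = FALSE]
  rownames(centroids) <- NULL
  cohorts <- rownames(Z) %||% as.character(seq_len(n))
  names(labels) <- cohorts
  structure(list(cohorts = cohorts, labels = labels, k = as.integer(k),
                 centroids = centroids, seed = as.integer(seed)),
            class = "cluster_result")
}

#' Internal cluster-validity indices
#'
#' Euclidean-metric versions of the three standard label-free indices:
#' \itemize{
#' \item Silhouette: mean over points of `(b - a)/max(a, b)`, `a` the mean
#'   distance to co-members, `b` the smallest mean distance to another
#'   cluster; the term for a point in a singleton cluster is defined as 0.
#' \item Davies–Bouldin: mean over clusters of the worst pairwise
#'   `(S_i + S_j)/M_ij`, with `S` the mean member-to-centroid distance and
#'   `M` the centroid separation (lower is better).
#' \item Calinski–Harabasz: `[BSS/(k-1)] / [WSS/(n-k)]` (higher is better).
#' }
#'
#' @param Z Embedding matrix.
#' @param labels Integer cluster labels (any coding), one per row.
#' @param space_tag `"original"` or `"projected_2d"`; recorded, never mixed.
#' @return A `metric_bundle`: list with `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`, `space_tag`, `k`, `n`.
#' @export
internal_metrics <- function(Z, labels, space_tag = c("original", "projected_2d")) {
  space_tag <- match.arg(space_tag)
  labels <- as.integer(factor(labels))
  n <- nrow(Z); k <- length(unique(labels))
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("every cluster must be non-empty")
  D <- as.matrix(stats::dist(Z))

  sil_terms <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { sil_terms[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    sil_terms[i] <- (b - a) / max(a, b)
  }
  silhouette <- mean(sil_terms)

  cents <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(Z[labels == cl, , drop = FALSE])))
  S <- vapply(seq_len(k), function(cl) {
    M <- Z[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums(sweep(M, 2, cents[cl, ], "-")^2)))
  }, numeric(1))
  Mc <- as.matrix(stats::dist(cents))
  db_terms <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (S[i] + S[j]) / Mc[i, j],
               numeric(1)))
  }, numeric(1))
  davies_bouldin <- mean(db_terms)

  grand <- colMeans(Z)
  sizes <- tabulate(labels, k)
  bss <- sum(sizes * rowSums(sweep(cents, 2, grand, "-")^2))
  wss <- sum(vapply(seq_len(k), function(cl) {
    M <- Z[labels == cl, , drop = FALSE]
    sum(sweep(M, 2, cents[cl, ], "-")^2)
  }, numeric(1)))
  ch <- if (wss == 0) Inf else (bss / (k - 1)) / (wss / (n - k))

  structure(list(silhouette = silhouette, davies_bouldin = davies_bouldin,
                 calinski_harabasz = ch, space_tag = space_tag,
                 k = k, n = n),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("cluster metrics [%s space, k=%d, n=%d]\n", x$space_tag, x$k, x$n))
  cat(sprintf("  silhouette:        %.4f\n", x$silhouette))
  cat(sprintf("  Davies-Bouldin:    %.4f\n", x$davies_bouldin))
  cat(sprintf("  Calinski-Harabasz: %.2f\n", x$calinski_harabasz))
  invisible(x)
}

#' Pairwise cosine-similarity matrix of cohort embeddings
#'
#' @param Z Embedding matrix with non-zero rows (rownames = cohorts).
#' @param labels Optional cluster labels; when given, rows/columns are
#'   ordered by (cluster, cohort label) so within-cluster blocks are
#'   contiguous.
#' @return Symmetric matrix with unit diagonal.
#' @export
cosine_matrix <- function(Z, labels = NULL) {
  if (any(rowSums(Z^2) == 0)) stop("zero row in embedding matrix")
  Zn <- l2_normalize_rows(Z)
  M <- Zn %*% t(Zn)
  diag(M) <- 1
  if (!is.null(labels)) {
    nm <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
    ord <- order(labels, nm)
    M <- M[ord, ord]
  }
  M
}

#' Mean within- and between-cluster cosine similarity
#' @param Z Embedding matrix.
#' @param labels Cluster labels.
#' @return List with per-cluster `within` means and the `between` mean over
#'   all cross-cluster pairs.
#' @export
cosine_cluster_summary <- function(Z, labels) {
  M <- cosine_matrix(Z)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  within <- stats::setNames(vapply(ks, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2) return(NA_real_)
    sub <- M[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1)), paste0("cluster", ks - 1L))
  between <- if (length(ks) >= 2) {
    vals <- c()
    for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j)
      vals <- c(vals, as.vector(M[labels == ks[i], labels == ks[j]]))
    mean(vals)
  } else NA_real_
  list(within = within, between = between)
}

#' Cluster prototypes by mean cosine similarity
#'
#' The prototype of a cluster is the member with maximal mean cosine
#' similarity to its co-members (ties broken alphabetically); a singleton
#' cluster's prototype is its only member.
#'
#' @param Z Embedding matrix (rownames = cohorts).
#' @param labels Cluster labels.
#' @return Named character vector, one cohort per cluster.
#' @export
cluster_prototypes <- function(Z, labels) {
  nm <- rownames(Z) %||% as.character(seq_len(nrow(Z)))
  labels <- as.integer(factor(labels))
  M <- cosine_matrix(Z)
  ks <- sort(unique(labels))
  out <- character(length(ks))
  for (ii in seq_along(ks)) {
    idx <- which(labels == ks[ii])
    if (length(idx) == 1) { out[ii] <- nm[idx]; next }
    sims <- vapply(idx, function(i) mean(M[i, setdiff(idx, i)]), numeric(1))
    best <- sims == max(sims)
    cand <- sort(nm[idx][best])
    out[ii] <- cand[1]
  }
  stats::setNames(out, paste0("cluster", ks - 1L))
}

#' Nearest-neighbor table by cosine similarity
#'
#' @param Z Embedding matrix (rownames = cohorts).
#' @param m Neighbors per cohort (default 3); requires `n > m`.
#' @return `data.frame` with columns `cohort`, `rank`, `neighbor`, `score`,
#'   scores descending within each cohort, ties broken alphabetically,
#'   self excluded.
#' @export
nearest_neighbors <- function(Z, m = 3L) {
  n <- nrow(Z)
  if (n <= m) stop("need more than m = ", m, " cohorts")
  nm <- rownames(Z) %||% as.character(seq_len(n))
  M <- cosine_matrix(Z)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-M[i, others], nm[others])]
    top <- ord[seq_len(m)]
    rows[[i]] <- data.frame(cohort = nm[i], rank = seq_len(m),
                            neighbor = nm[top], score = unname(M[i, top]),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster-level mutation spectra
#'
#' For each cluster: the unweighted mean (each cohort counts once) of the
#' 12 substitution-category totals from the raw gene-signature counts, and
#' the mean per-chromosome length-normalized load (24 values).
#'
#' @param gene_sigs,chrom_sigs Lists of per-cohort signatures.
#' @param labels Named cluster labels (names = cohorts) covering every
#'   signature's cohort.
#' @return A `spectrum_profile`: list with `substitution` (clusters x 12)
#'   and `chromosome_load` (clusters x 24) matrices.
#' @export
cluster_spectra <- function(gene_sigs, chrom_sigs, labels) {
  g_names <- vapply(gene_sigs, function(s) s$cohort, character(1))
  c_names <- vapply(chrom_sigs, function(s) s$cohort, character(1))
  if (!all(g_names %in% names(labels)) || !all(c_names %in% names(labels)))
    stop("labels missing for some cohorts with signatures")
  labels <- as.integer(factor(labels[g_names]))
  ks <- sort(unique(labels))
  sub_tot <- t(vapply(gene_sigs, function(s) colSums(s$matrix), numeric(12)))
  load_tot <- t(vapply(chrom_sigs[match(g_names, c_names)],
                       function(s) rowSums(s$matrix), numeric(24)))
  subs <- t(vapply(ks, function(cl)
    colMeans(sub_tot[labels == cl, , drop = FALSE]), numeric(12)))
  loads <- t(vapply(ks, function(cl)
    colMeans(load_tot[labels == cl, , drop = FALSE]), numeric(24)))
  dimnames(subs) <- list(paste0("cluster", ks - 1L), substitution_labels())
  dimnames(loads) <- list(paste0("cluster", ks - 1L), chromosome_labels())
  structure(list(substitution = subs, chromosome_load = loads),
            class = "spectrum_profile")
}

#' Overlap of cluster top-gene sets
#'
#' Each cluster's gene set is the union of its member cohorts' ranked
#' top-gene lists; for two clusters the result is a Venn-style summary.
#' With more clusters, pairwise summaries are returned.
#'
#' @param gene_sigs List of per-cohort `gene_signature`s.
#' @param labels Named cluster labels (names = cohorts).
#' @return For two clusters: list with `shared`, `unique` (per cluster) and
#'   `counts`. Otherwise a list of pairwise results.
#' @export
gene_set_overlap <- function(gene_sigs, labels) {
  g_names <- vapply(gene_sigs, function(s) s$cohort, character(1))
  labels <- as.integer(factor(labels[g_names]))
  ks <- sort(unique(labels))
  sets <- lapply(ks, function(cl) {
    s <- sort(unique(unlist(lapply(gene_sigs[labels == cl], function(g) g$genes))))
    if (length(s) == 0) warning("cluster ", cl - 1L, " has an empty gene set")
    s
  })
  names(sets) <- paste0("cluster", ks - 1L)
  pair_overlap <- function(a, b, na, nb) {
    shared <- intersect(a, b)
    ua <- setdiff(a, b); ub <- setdiff(b, a)
    out <- list(shared = shared)
    out[[paste0("unique_", na)]] <- ua
    out[[paste0("unique_", nb)]] <- ub
    out$counts <- stats::setNames(
      c(length(shared), length(ua), length(ub)),
      c("shared", paste0("unique_", na), paste0("unique_", nb)))
    out
  }
  if (length(sets) == 2)
    return(pair_overlap(sets[[1]], sets[[2]], names(sets)[1], names(sets)[2]))
  res <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i < j) {
    res[[paste(names(sets)[i], names(sets)[j], sep = "_vs_")]] <-
      pair_overlap(sets[[i]], sets[[j]], names(sets)[i], names(sets)[j])
  }
  res
}

#' Project embeddings to 2-D for visualization
#'
#' t-SNE and UMAP are treated as an external projection contract
#' (deterministic given `seed`) and are delegated to the installed Python
#' scientific stack (`sklearn.manifold.TSNE`, `umap-learn`) through a
#' subprocess; `"pca"` runs in-process via [stats::prcomp()]. Cluster
#' metrics recomputed on the output should carry
#' `space_tag = "projected_2d"`.
#'
#' @param Z Embedding matrix, `n >= 4` rows.
#' @param method `"tsne"`, `"umap"`, or `"pca"`.
#' @param seed Projection seed.
#' @param python Python executable used for tsne/umap.
#' @return `n x 2` coordinate matrix (rownames preserved).
#' @export
project_2d <- function(Z, method = c("tsne", "umap", "pca"), seed = 42L,
                       python = "python") {
  method <- match.arg(method)
  n <- nrow(Z)
  if (n < 4) stop("need at least 4 points for a 2-D projection")
  if (method == "pca") {
    P <- stats::prcomp(Z, center = TRUE, scale. = FALSE)$x
    if (ncol(P) < 2) P <- cbind(P, 0)
    coords <- P[, 1:2, drop = FALSE]
    colnames(coords) <- c("dim1", "dim2")
    return(coords)
  }
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(Z, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- if (method == "tsne") sprintf(
    "import numpy as np\nfrom sklearn.manifold import TSNE\nX=np.loadtxt(%s,delimiter=',')\nperp=max(2,min(30,(X.shape[0]-1)//3))\nY=TSNE(n_components=2,perplexity=perp,random_state=%d,init='pca').fit_transform(X)\nnp.savetxt(%s,Y,delimiter=',')\n",
    deparse(fin), as.integer(seed), deparse(fout)
  ) else sprintf(
    "import numpy as np, umap\nX=np.loadtxt(%s,delimiter=',')\nnn=max(2,min(15,X.shape[0]-1))\nY=umap.UMAP(n_components=2,n_neighbors=nn,random_state=%d).fit_transform(X)\nnp.savetxt(%s,Y,delimiter=',')\n",
    deparse(fin), as.integer(seed), deparse(fout)
  )
  sf <- tempfile(fileext = ".py")
  on.exit(unlink(sf), add = TRUE)
  writeLines(script, sf)
  status <- system2(python, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop(method, " projection failed: could not run '", python,
         "' with ", method, " available; use method = 'pca' for a ",
         "dependency-free projection")
  coords <- as.matrix(utils::read.table(fout, sep = ","))
  dimnames(coords) <- list(rownames(Z), c("dim1", "dim2"))
  coords
}
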