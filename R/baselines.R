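# Comparison embeddings and ablation grid, all funneled through the same
# downstream clustering pipeline (kmeans_cluster + internal_metrics) as the
# full model.

#' Non-negative matrix factorization (Frobenius, multiplicative updates)
#'
#' Lee–Seung multiplicative updates minimizing `||X - W H||_F`, seeded
#' uniform initialization.
#'
#' @param X Non-negative matrix (n x p).
#' @param rank Factorization rank.
#' @param n_iter Maximum update iterations (default 500).
#' @param tol Relative change in reconstruction error for early stop.
#' @param seed RNG seed.
#' @return List with `W` (n x rank factor scores), `H` (rank x p),
#'   `rel_err` (final relative Frobenius error).
#' @export
nmf_fit <- function(X, rank, n_iter = 500L, tol = 1e-9, seed = 42L) {
  if (any(X < 0)) stop("NMF requires non-negative input")
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * p, 0.1, 1), rank, p)
  eps <- 1e-12
  nx <- sqrt(sum(X^2))
  prev <- Inf
  for (it in seq_len(n_iter)) {
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
    if (it %% 10 == 0 || it == n_iter) {
      err <- sqrt(sum((X - W %*% H)^2)) / nx
      if (is.finite(prev) && abs(prev - err) < tol * max(err, eps)) break
      prev <- err
    }
  }
  list(W = W, H = H, rel_err = sqrt(sum((X - W %*% H)^2)) / nx)
}

#' Baseline embedding specification
#'
#' @param method One of `"nmf"`, `"hierarchical_ward"`, `"autoencoder"`,
#'   `"simclr_mlp"`, `"deepcluster"`.
#' @param k Clusters for the downstream k-means (default 2).
#' @param seed RNG seed (default 42).
#' @param rank NMF rank (default 8).
#' @param epochs Training epochs for the neural baselines (default 100).
#' @param batch_size Mini-batch size (default 8).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param hidden Encoder hidden width (default 128).
#' @param code_dim Embedding width (default 64).
#' @param dropout_p,jitter_sd SimCLR augmentation knobs: feature-dropout
#'   probability (default 0.1) and Gaussian jitter SD (default 0.1).
#' @param rounds DeepCluster alternations (default 15).
#' @param temperature NT-Xent temperature for the SimCLR baseline.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(method = c("nmf", "hierarchical_ward", "autoencoder",
                                     "simclr_mlp", "deepcluster"),
                          k = 2L, seed = 42L, rank = 8L, epochs = 100L,
                          batch_size = 8L, learning_rate = 1e-3,
                          hidden = 128L, code_dim = 64L,
                          dropout_p = 0.1, jitter_sd = 0.1, rounds = 15L,
                          temperature = 0.5) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "baseline_spec")
}

baseline_input <- function(views, raw = FALSE) {
  if (raw) cbind(views$Xg_raw, views$Xc_raw) else cbind(views$Xg, views$Xc)
}

minibatches <- function(n, bs) {
  perm <- sample.int(n)
  starts <- seq(1, n, by = bs)
  lapply(starts, function(s) perm[s:min(s + bs - 1, n)])
}

train_autoencoder <- function(X, spec) {
  set.seed(spec$seed)
  p <- ncol(X)
  params <- list(enc = mlp_init(p, spec$hidden, spec$code_dim),
                 dec = mlp_init(spec$code_dim, spec$hidden, p))
  opt <- adam_init(params)
  for (epoch in seq_len(spec$epochs)) {
    for (idx in minibatches(nrow(X), spec$batch_size)) {
      Xb <- X[idx, , drop = FALSE]
      fe <- mlp_forward(params$enc, Xb)
      fd <- mlp_forward(params$dec, fe$out)
      dRec <- 2 * (fd$out - Xb) / length(Xb)
      bd <- mlp_backward(params$dec, fd$cache, dRec)
      be <- mlp_backward(params$enc, fe$cache, bd$dX)
      res <- adam_step(params, list(enc = be$grads, dec = bd$grads), opt,
                       lr = spec$learning_rate)
      params <- res$params; opt <- res$state
    }
  }
  mlp_forward(params$enc, X)$out
}

augment <- function(X, dropout_p, jitter_sd) {
  keep <- matrix(stats::runif(length(X)) >= dropout_p, nrow(X))
  X * keep + matrix(stats::rnorm(length(X), sd = jitter_sd), nrow(X))
}

train_simclr_mlp <- function(X, spec) {
  set.seed(spec$seed)
  p <- ncol(X)
  params <- list(enc = mlp_init(p, spec$hidden, spec$code_dim),
                 head = mlp_init(spec$code_dim, spec$code_dim, spec$code_dim))
  opt <- adam_init(params)
  for (epoch in seq_len(spec$epochs)) {
    chunks <- minibatches(nrow(X), spec$batch_size)
    for (idx in chunks) {
      if (length(idx) < 2) next
      Xb <- X[idx, , drop = FALSE]
      X1 <- augment(Xb, spec$dropout_p, spec$jitter_sd)
      X2 <- augment(Xb, spec$dropout_p, spec$jitter_sd)
      f1 <- mlp_forward(params$enc, X1); f2 <- mlp_forward(params$enc, X2)
      h1 <- mlp_forward(params$head, f1$out); h2 <- mlp_forward(params$head, f2$out)
      Z1 <- l2_normalize_rows(h1$out); Z2 <- l2_normalize_rows(h2$out)
      N <- length(idx)
      core <- nt_xent_core(rbind(Z1, Z2), c((N + 1):(2 * N), 1:N),
                           spec$temperature, "exclude_anchor")
      d1 <- l2_normalize_rows_backward(h1$out, core$dZn[1:N, , drop = FALSE])
      d2 <- l2_normalize_rows_backward(h2$out, core$dZn[(N + 1):(2 * N), , drop = FALSE])
      bh1 <- mlp_backward(params$head, h1$cache, d1)
      bh2 <- mlp_backward(params$head, h2$cache, d2)
      be1 <- mlp_backward(params$enc, f1$cache, bh1$dX)
      be2 <- mlp_backward(params$enc, f2$cache, bh2$dX)
      grads <- list(enc = tree_add(be1$grads, be2$grads),
                    head = tree_add(bh1$grads, bh2$grads))
      res <- adam_step(params, grads, opt, lr = spec$learning_rate)
      params <- res$params; opt <- res$state
    }
  }
  mlp_forward(params$enc, X)$out
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

train_deepcluster <- function(X, spec) {
  set.seed(spec$seed)
  p <- ncol(X)
  params <- list(enc = mlp_init(p, spec$hidden, spec$code_dim),
                 clf = linear_init(spec$code_dim, spec$k))
  opt <- adam_init(params)
  for (round in seq_len(spec$rounds)) {
    E <- mlp_forward(params$enc, X)$out
    km <- stats::kmeans(E, centers = spec$k, nstart = 5, iter.max = 50)
    y <- km$cluster
    for (idx in minibatches(nrow(X), spec$batch_size)) {
      Xb <- X[idx, , drop = FALSE]
      fe <- mlp_forward(params$enc, Xb)
      lc <- linear_forward(params$clf, fe$out)
      P <- softmax_rows(lc$out)
      Y <- matrix(0, length(idx), spec$k)
      Y[cbind(seq_along(idx), y[idx])] <- 1
      dL <- (P - Y) / length(idx)
      bc <- linear_backward(params$clf, lc, dL)
      be <- mlp_backward(params$enc, fe$cache, bc$dX)
      res <- adam_step(params, list(enc = be$grads, clf = bc$grads), opt,
                       lr = spec$learning_rate)
      params <- res$params; opt <- res$state
    }
  }
  mlp_forward(params$enc, X)$out
}

#' Run a baseline embedding method through the standard pipeline
#'
#' All methods consume the concatenated gene + chromosome views (588
#' features; the NMF path uses the raw non-negative counts/rates, the rest
#' the scaled features) and are scored with the identical
#' [kmeans_cluster()] + [internal_metrics()] downstream used by the full
#' model. Ward hierarchical clustering produces labels directly (cut at
#' `k`); its metrics are computed on the concatenated features.
#'
#' @param spec A [baseline_spec()].
#' @param views A `feature_views`.
#' @return List with `method`, `embedding`, `cluster` (a `cluster_result`,
#'   or NULL for Ward), `labels`, and `metrics` (a `metric_bundle`).
#' @export
run_baseline <- function(spec, views) {
  stopifnot(inherits(spec, "baseline_spec"))
  cohorts <- views$cohorts
  if (spec$method == "hierarchical_ward") {
    X <- baseline_input(views)
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    labels <- stats::cutree(hc, k = spec$k) - 1L
    names(labels) <- cohorts
    metrics <- internal_metrics(X, labels)
    return(list(method = spec$method, embedding = X, cluster = NULL,
                labels = labels, metrics = metrics))
  }
  E <- switch(spec$method,
    nmf = {
      fit <- nmf_fit(baseline_input(views, raw = TRUE), spec$rank,
                     seed = spec$seed)
      fit$W
    },
    autoencoder = train_autoencoder(baseline_input(views), spec),
    simclr_mlp = train_simclr_mlp(baseline_input(views), spec),
    deepcluster = train_deepcluster(baseline_input(views), spec)
  )
  rownames(E) <- cohorts
  cl <- kmeans_cluster(E, spec$k, seed = spec$seed)
  metrics <- internal_metrics(E, cl$labels)
  list(method = spec$method, embedding = E, cluster = cl,
       labels = cl$labels, metrics = metrics)
}

ABLATION_MODES <- c("no_gene_tabenc", "no_chrom_tabenc", "no_both_tabenc",
                    "no_contrastive")

#' Ablation specification
#'
#' The four modes mirror the component-removal grid: replace the gene-view
#' TabNet, the chromosome-view TabNet, or both with 2-layer MLP encoders of
#' matched output width, or keep both TabNets but train with a
#' non-contrastive objective (mean squared distance between paired
#' normalized projections).
#'
#' @param mode One of `"no_gene_tabenc"`, `"no_chrom_tabenc"`,
#'   `"no_both_tabenc"`, `"no_contrastive"`.
#' @param cfg A [train_config()].
#' @param k Downstream k-means clusters (default 2).
#' @param no_contrastive_variant How the contrastive loss is "removed":
#'   `"untrained"` (default) keeps both TabNet encoders at their seeded
#'   initialization, so the embedding space is shaped by no training signal
#'   at all; `"mse_align"` instead trains with the mean squared distance
#'   between paired normalized projections. The MSE variant drives the two
#'   views toward a collapsed embedding, and collapse trivially inflates
#'   internal validity indices (silhouette ~ 1 for near-duplicate points),
#'   so it is not the default comparison.
#' @return An `ablation_spec` list.
#' @export
ablation_spec <- function(mode = ABLATION_MODES, cfg = train_config(), k = 2L,
                          no_contrastive_variant = c("untrained", "mse_align")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, cfg = cfg, k = as.integer(k),
                 no_contrastive_variant = match.arg(no_contrastive_variant)),
            class = "ablation_spec")
}

#' Run an ablated model end-to-end
#'
#' Trains the ablated architecture/objective on the views and pushes the
#' fused embedding through the identical [kmeans_cluster()] +
#' [internal_metrics()] downstream.
#'
#' @param spec An [ablation_spec()].
#' @param views A `feature_views`.
#' @return List with `mode`, `fit`, `cluster`, `labels`, `metrics`.
#' @export
run_ablation <- function(spec, views) {
  stopifnot(inherits(spec, "ablation_spec"))
  gene_type <- if (spec$mode %in% c("no_gene_tabenc", "no_both_tabenc")) "mlp" else "tabnet"
  chrom_type <- if (spec$mode %in% c("no_chrom_tabenc", "no_both_tabenc")) "mlp" else "tabnet"
  loss <- "ntxent"
  if (spec$mode == "no_contrastive") {
    loss <- if (spec$no_contrastive_variant == "untrained") "none" else "mse_align"
  }
  fit <- train_dual(views$Xg, views$Xc, views$cohorts,
                    encoder_spec(gene_type, ncol(views$Xg)),
                    encoder_spec(chrom_type, ncol(views$Xc)),
                    projection_head_params(), spec$cfg, loss = loss)
  Z <- fit$embedding$Z_fused
  cl <- kmeans_cluster(Z, spec$k, seed = spec$cfg$seed)
  metrics <- internal_metrics(Z, cl$labels)
  list(mode = spec$mode, fit = fit, cluster = cl, labels = cl$labels,
       metrics = metrics)
}
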