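# Two-view NT-Xent contrastive training of the dual encoders. The gene-view
# and chromosome-view encoders each feed a 2-layer projection head; the two
# L2-normalized projections of the same cohort form a positive pair, all
# other projections in the mini-batch act as negatives.

#' Cosine similarity between two vectors
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return `a . b / (||a|| ||b||)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Training configuration for contrastive alignment
#'
#' @param epochs Number of passes over the cohorts (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Cohorts per mini-batch (default 8; must be >= 2 so each
#'   anchor has at least one negative).
#' @param temperature NT-Xent temperature tau > 0 (default 0.5).
#' @param seed Integer seed controlling weight init and batch shuffling
#'   (default 42).
#' @param fusion_mode `"mean_normalized"` (average of the two unit-norm view
#'   projections, re-normalized; keeps d = 64) or `"concat"` (d = 128).
#' @param denominator `"exclude_anchor"` (standard SimCLR convention: the
#'   anchor's self-similarity is excluded from the softmax denominator) or
#'   `"exclude_positive"` (the positive is excluded instead; in that variant
#'   the anchor's own `exp(1/tau)` term enters its denominator).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3, batch_size = 8L,
                         temperature = 0.5, seed = 42L,
                         fusion_mode = c("mean_normalized", "concat"),
                         denominator = c("exclude_anchor", "exclude_positive")) {
  stopifnot(temperature > 0, batch_size >= 2, epochs >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), temperature = temperature,
                 seed = as.integer(seed), fusion_mode = match.arg(fusion_mode),
                 denominator = match.arg(denominator)),
            class = "train_config")
}

#' Projection-head configuration
#' @param in_dim,hidden_dim,out_dim Layer widths (defaults 64/64/64).
#' @return List of widths.
#' @export
projection_head_params <- function(in_dim = 64L, hidden_dim = 64L, out_dim = 64L) {
  list(in_dim = in_dim, hidden_dim = hidden_dim, out_dim = out_dim)
}

# loss and gradient of NT-Xent on an already-L2-normalized 2N x d matrix.
# pairs[i] is the row index of anchor i's positive.
nt_xent_core <- function(Zn, pairs, tau, denominator = "exclude_anchor") {
  if (tau <= 0) stop("temperature must be positive")
  n2 <- nrow(Zn)
  S <- (Zn %*% t(Zn)) / tau
  excl <- if (denominator == "exclude_anchor") seq_len(n2) else pairs
  A <- matrix(TRUE, n2, n2)
  A[cbind(seq_len(n2), excl)] <- FALSE
  Sm <- S; Sm[!A] <- -Inf
  mx <- apply(Sm, 1, max)
  E <- exp(Sm - mx)
  den <- rowSums(E)
  lse <- mx + log(den)
  pos <- S[cbind(seq_len(n2), pairs)]
  losses <- lse - pos
  W <- E / den                       # softmax over allowed entries, 0 elsewhere
  G <- W
  G[cbind(seq_len(n2), pairs)] <- G[cbind(seq_len(n2), pairs)] - 1
  G <- G / n2
  dZn <- ((G + t(G)) %*% Zn) / tau
  list(loss = mean(losses), anchor_losses = losses, dZn = dZn)
}

#' NT-Xent loss of a single anchor
#'
#' The batch is the row-stack of the two views' projections: rows `1..N`
#' are view one, rows `N+1..2N` view two, and row `i`'s positive is its
#' same-cohort row in the other view.
#'
#' @param i Anchor row index in `1..2N`.
#' @param batch `2N x d` matrix of projections (rows are normalized
#'   internally).
#' @param tau Temperature > 0.
#' @param denominator See [train_config()].
#' @return Non-negative anchor loss `L_i`.
#' @export
nt_xent_anchor_loss <- function(i, batch, tau = 0.5,
                                denominator = c("exclude_anchor", "exclude_positive")) {
  denominator <- match.arg(denominator)
  n2 <- nrow(batch)
  if (n2 %% 2 != 0) stop("batch must stack two equally sized views")
  N <- n2 / 2
  pairs <- c((N + 1):(2 * N), 1:N)
  Zn <- l2_normalize_rows(batch)
  nt_xent_core(Zn, pairs, tau, denominator)$anchor_losses[i]
}

#' NT-Xent batch loss over two aligned views
#'
#' Mean of the `2N` anchor losses (both directions: view one anchored
#' against view two and vice versa).
#'
#' @param Zg_batch,Zc_batch `N x d` projection matrices with aligned rows.
#' @param tau Temperature > 0.
#' @param denominator See [train_config()].
#' @return Scalar batch loss.
#' @export
nt_xent_batch_loss <- function(Zg_batch, Zc_batch, tau = 0.5,
                               denominator = c("exclude_anchor", "exclude_positive")) {
  denominator <- match.arg(denominator)
  if (nrow(Zg_batch) != nrow(Zc_batch)) stop("view batches must have equal rows")
  N <- nrow(Zg_batch)
  Zn <- l2_normalize_rows(rbind(Zg_batch, Zc_batch))
  pairs <- c((N + 1):(2 * N), 1:N)
  nt_xent_core(Zn, pairs, tau, denominator)$loss
}

#' Fuse the two view embeddings into one cohort embedding
#'
#' @param Zg,Zc Aligned `n x 64` view projections.
#' @param mode `"mean_normalized"`: rows of each view are L2-normalized,
#'   averaged, and the result re-normalized (output width 64).
#'   `"concat"`: column-bind (width 128).
#' @return Fused embedding matrix.
#' @export
fuse_embeddings <- function(Zg, Zc, mode = c("mean_normalized", "concat")) {
  mode <- match.arg(mode)
  if (nrow(Zg) != nrow(Zc)) stop("view embeddings must have aligned rows")
  if (mode == "concat") return(cbind(Zg, Zc))
  l2_normalize_rows((l2_normalize_rows(Zg) + l2_normalize_rows(Zc)) / 2)
}

## ---- encoder dispatch (TabNet or MLP replacement) ----

encoder_spec <- function(type = c("tabnet", "mlp"), input_dim,
                         n_steps = 3L, n_d = 64L, n_a = 64L, gamma = 1.3,
                         hidden = 128L) {
  type <- match.arg(type)
  if (type == "tabnet") {
    list(type = "tabnet", params = encoder_params(input_dim, n_steps, n_d, n_a, gamma))
  } else {
    list(type = "mlp", params = list(input_dim = input_dim, hidden = hidden, out = n_d))
  }
}

encoder_init_weights <- function(spec) {
  if (spec$type == "tabnet") tabnet_init(spec$params)
  else mlp_init(spec$params$input_dim, spec$params$hidden, spec$params$out)
}

encoder_fwd <- function(spec, weights, X) {
  if (spec$type == "tabnet") {
    f <- tabnet_forward(weights, spec$params, X)
    list(out = f$h, cache = f)
  } else {
    f <- mlp_forward(weights, X)
    list(out = f$out, cache = f$cache)
  }
}

encoder_bwd <- function(spec, weights, cache, dOut) {
  if (spec$type == "tabnet") tabnet_backward(weights, spec$params, cache, dOut)$grads
  else mlp_backward(weights, cache, dOut)$grads
}

# Shared dual-encoder training loop. `loss` is "ntxent" (contrastive),
# "mse_align" (mean squared distance between paired normalized projections),
# or "none" (no training at all: the seeded initialization is evaluated
# directly; used by the default no-contrastive ablation).
train_dual <- function(Xg, Xc, cohorts, spec_g, spec_c, head_par, cfg,
                       loss = c("ntxent", "mse_align", "none")) {
  loss <- match.arg(loss)
  n <- nrow(Xg)
  if (n < 3) stop("need at least 3 cohorts to train")
  set.seed(cfg$seed)
  params <- list(
    enc_g = encoder_init_weights(spec_g),
    enc_c = encoder_init_weights(spec_c),
    head_g = mlp_init(head_par$in_dim, head_par$hidden_dim, head_par$out_dim),
    head_c = mlp_init(head_par$in_dim, head_par$hidden_dim, head_par$out_dim)
  )
  opt <- adam_init(params)
  loss_history <- if (loss == "none") numeric(0) else numeric(cfg$epochs)

  batch_indices <- function(n, bs) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = bs)
    chunks <- lapply(starts, function(s) perm[s:min(s + bs - 1, n)])
    k <- length(chunks)
    if (k > 1 && length(chunks[[k]]) < 2) {
      chunks[[k - 1]] <- c(chunks[[k - 1]], chunks[[k]])
      chunks[[k]] <- NULL
    }
    chunks
  }

  step_batch <- function(idx) {
    Xgb <- Xg[idx, , drop = FALSE]; Xcb <- Xc[idx, , drop = FALSE]
    fg <- encoder_fwd(spec_g, params$enc_g, Xgb)
    fc <- encoder_fwd(spec_c, params$enc_c, Xcb)
    hg <- mlp_forward(params$head_g, fg$out)
    hc <- mlp_forward(params$head_c, fc$out)
    Zg <- l2_normalize_rows(hg$out); Zc <- l2_normalize_rows(hc$out)
    N <- length(idx)
    if (loss == "ntxent") {
      pairs <- c((N + 1):(2 * N), 1:N)
      core <- nt_xent_core(rbind(Zg, Zc), pairs, cfg$temperature, cfg$denominator)
      l <- core$loss
      dZg <- core$dZn[1:N, , drop = FALSE]
      dZc <- core$dZn[(N + 1):(2 * N), , drop = FALSE]
    } else {
      D <- Zg - Zc
      l <- mean(D^2)
      sc <- 2 / length(D)
      dZg <- sc * D; dZc <- -sc * D
    }
    dHg <- l2_normalize_rows_backward(hg$out, dZg)
    dHc <- l2_normalize_rows_backward(hc$out, dZc)
    bg <- mlp_backward(params$head_g, hg$cache, dHg)
    bc <- mlp_backward(params$head_c, hc$cache, dHc)
    grads <- list(
      enc_g = encoder_bwd(spec_g, params$enc_g, fg$cache, bg$dX),
      enc_c = encoder_bwd(spec_c, params$enc_c, fc$cache, bc$dX),
      head_g = bg$grads, head_c = bc$grads
    )
    list(loss = l, grads = grads)
  }

  for (epoch in if (loss == "none") integer(0) else seq_len(cfg$epochs)) {
    chunks <- batch_indices(n, cfg$batch_size)
    ep_losses <- numeric(length(chunks))
    for (b in seq_along(chunks)) {
      sb <- step_batch(chunks[[b]])
      if (!is.finite(sb$loss))
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " — check input scaling / learning rate")
      res <- adam_step(params, sb$grads, opt, lr = cfg$learning_rate)
      params <- res$params; opt <- res$state
      ep_losses[b] <- sb$loss
    }
    loss_history[epoch] <- mean(ep_losses)
  }

  # evaluation pass: full-batch, deterministic
  fg <- encoder_fwd(spec_g, params$enc_g, Xg)
  fc <- encoder_fwd(spec_c, params$enc_c, Xc)
  Zg <- l2_normalize_rows(mlp_forward(params$head_g, fg$out)$out)
  Zc <- l2_normalize_rows(mlp_forward(params$head_c, fc$out)$out)
  rownames(Zg) <- rownames(Zc) <- cohorts
  Zf <- fuse_embeddings(Zg, Zc, cfg$fusion_mode)
  rownames(Zf) <- cohorts
  structure(list(
    weights = params, spec_g = spec_g, spec_c = spec_c,
    head_params = head_par, cfg = cfg, loss = loss,
    embedding = list(cohorts = cohorts, Zg = Zg, Zc = Zc, Z_fused = Zf,
                     loss_history = loss_history)
  ), class = "mscontab_fit")
}

#' Train the full multi-scale contrastive model
#'
#' Jointly trains the gene-view and chromosome-view TabNet encoders and
#' their projection heads with the NT-Xent objective, then runs a final
#' full-batch evaluation pass and fuses the two view projections into the
#' per-cohort embedding used for clustering. Fully reproducible given
#' `cfg$seed`.
#'
#' @param views A `feature_views` from [assemble_feature_views()].
#' @param enc_params_g,enc_params_c Optional [encoder_params()] for the two
#'   views (defaults: 3 decision steps, n_d = n_a = 64, gamma = 1.3).
#' @param head_par [projection_head_params()].
#' @param cfg [train_config()].
#' @return An `mscontab_fit` with `weights` and `embedding` (`Zg`, `Zc`,
#'   `Z_fused`, per-epoch `loss_history`).
#' @export
train_ms_contab <- function(views, enc_params_g = NULL, enc_params_c = NULL,
                            head_par = projection_head_params(),
                            cfg = train_config()) {
  spec_g <- if (is.null(enc_params_g)) encoder_spec("tabnet", ncol(views$Xg))
            else list(type = "tabnet", params = enc_params_g)
  spec_c <- if (is.null(enc_params_c)) encoder_spec("tabnet", ncol(views$Xc))
            else list(type = "tabnet", params = enc_params_c)
  train_dual(views$Xg, views$Xc, views$cohorts, spec_g, spec_c, head_par, cfg,
             loss = "ntxent")
}

#' @export
print.mscontab_fit <- function(x, ...) {
  emb <- x$embedding
  cat("mscontab fit:", length(emb$cohorts), "cohorts\n")
  cat("  encoders:", x$spec_g$type, "/", x$spec_c$type, "; loss:", x$loss, "\n")
  cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              emb$loss_history[1], emb$loss_history[length(emb$loss_history)],
              length(emb$loss_history)))
  cat("  fused embedding:", nrow(emb$Z_fused), "x", ncol(emb$Z_fused), "\n")
  invisible(x)
}

#' Export embeddings and loss history as CSV
#' @param fit An `mscontab_fit`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_embeddings <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- fit$embedding
  pe <- file.path(dir, "embeddings.csv")
  pl <- file.path(dir, "loss_history.csv")
  df <- data.frame(cohort = emb$cohorts, emb$Z_fused, check.names = FALSE, row.names = NULL)
  colnames(df) <- c("cohort", paste0("z", seq_len(ncol(emb$Z_fused))))
  data.table::fwrite(df, pe)
  data.table::fwrite(data.frame(epoch = seq_along(emb$loss_history),
                                mean_loss = emb$loss_history), pl)
  invisible(c(pe, pl))
}

#' Save / load a trained model checkpoint
#'
#' Serializes the weights of both encoders and projection heads together
#' with their architecture specs and training config into a single file
#' (RDS, a binary runtime artifact).
#'
#' @param fit An `mscontab_fit`.
#' @param path Checkpoint file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mscontab_fit"))
  saveRDS(fit[c("weights", "spec_g", "spec_c", "head_params", "cfg", "loss")],
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return `read_checkpoint` returns the checkpoint contents (weights,
#'   specs, config); combine with [encode()] or [mask_traces()] for
#'   inference on new feature views.
#' @export
read_checkpoint <- function(path) {
  readRDS(path)
}

#' Per-cohort attention-mask importances of a trained model
#'
#' Runs the trained TabNet encoders over the feature views and aggregates
#' each cohort's per-step sparsemax masks into normalized per-feature
#' importances (see [feature_importance()]), one matrix per view. Views
#' whose encoder is an MLP (ablations) are skipped.
#'
#' @param fit An `mscontab_fit` (or checkpoint contents).
#' @param views The `feature_views` the model was trained on.
#' @param dir Optional directory; when given, writes
#'   `mask_trace_gene.csv` / `mask_trace_chromosome.csv` (cohort x feature).
#' @return List with `gene` and `chromosome` importance matrices (NULL for
#'   MLP-encoded views).
#' @export
mask_traces <- function(fit, views, dir = NULL) {
  one <- function(spec, w, X) {
    if (spec$type != "tabnet") return(NULL)
    enc <- encode(X, spec$params, w)
    imp <- feature_importance(enc$trace, feature_names = colnames(X),
                              aggregate = FALSE)
    rownames(imp) <- rownames(X)
    imp
  }
  out <- list(gene = one(fit$spec_g, fit$weights$enc_g, views$Xg),
              chromosome = one(fit$spec_c, fit$weights$enc_c, views$Xc))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (is.null(out[[nm]])) next
      data.table::fwrite(data.frame(cohort = rownames(out[[nm]]), out[[nm]],
                                    check.names = FALSE, row.names = NULL),
                         file.path(dir, paste0("mask_trace_", nm, ".csv")))
    }
  }
  out
}
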