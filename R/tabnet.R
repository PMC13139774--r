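# TabNet-style sparse attentive encoder for tabular mutation signatures.
#
# Architecture (per view): at each of n_steps decision steps an attentive
# transformer maps the previous step's attention features through a linear
# layer, multiplies by a running prior and applies sparsemax, producing a
# sparse mask over input features. Masked features pass through a feature
# transformer (two GLU blocks shared across steps + two step-specific GLU
# blocks, residual connections scaled by sqrt(0.5)), and the rectified
# decision outputs are summed across steps into the latent representation.
# The prior is updated multiplicatively by (gamma - mask), discouraging
# re-use of already-attended features. Forward and backward passes are
# written out explicitly; gradients flow through masks, priors, and all
# GLU blocks.

#' TabNet encoder hyperparameters
#'
#' @param input_dim Width of the input view (300 for the gene view, 288 for
#'   the chromosome view).
#' @param n_steps Number of decision steps (default 3).
#' @param n_d Decision (latent output) width; the encoder emits `n_d`
#'   features (default 64).
#' @param n_a Attention width fed to the next step's attentive transformer
#'   (default 64).
#' @param gamma Prior relaxation >= 1 (default 1.3): 1 forces each feature
#'   to be used in at most one step; larger values allow re-use.
#' @return An `encoder_params` list.
#' @export
encoder_params <- function(input_dim, n_steps = 3L, n_d = 64L, n_a = 64L,
                           gamma = 1.3) {
  stopifnot(input_dim >= 1, n_steps >= 1, n_d >= 1, n_a >= 1, gamma >= 1)
  structure(list(input_dim = as.integer(input_dim), n_steps = as.integer(n_steps),
                 n_d = as.integer(n_d), n_a = as.integer(n_a), gamma = gamma),
            class = "encoder_params")
}

#' Initialize TabNet encoder weights
#'
#' Glorot-uniform initialization drawn from R's RNG; seed the session (or
#' rely on the training config seed) for reproducibility.
#'
#' @param params An [encoder_params()].
#' @return Nested list of weight matrices.
#' @export
tabnet_init <- function(params) {
  H <- params$n_d + params$n_a
  steps <- lapply(seq_len(params$n_steps + 1L), function(i) {
    list(g1 = linear_init(H, 2 * H), g2 = linear_init(H, 2 * H))
  })
  att <- lapply(seq_len(params$n_steps), function(i) {
    linear_init(params$n_a, params$input_dim)
  })
  list(shared = list(g1 = linear_init(params$input_dim, 2 * H),
                     g2 = linear_init(H, 2 * H)),
       steps = steps, att = att)
}

RESID_SCALE <- sqrt(0.5)

ft_forward <- function(shared, step, Xin) {
  l1 <- linear_forward(shared$g1, Xin); g1 <- glu_forward(l1$out)
  z1 <- g1$out
  l2 <- linear_forward(shared$g2, z1); g2 <- glu_forward(l2$out)
  z2 <- (z1 + g2$out) * RESID_SCALE
  l3 <- linear_forward(step$g1, z2); g3 <- glu_forward(l3$out)
  z3 <- (z2 + g3$out) * RESID_SCALE
  l4 <- linear_forward(step$g2, z3); g4 <- glu_forward(l4$out)
  z4 <- (z3 + g4$out) * RESID_SCALE
  list(out = z4, l1 = l1, g1 = g1, l2 = l2, g2 = g2,
       l3 = l3, g3 = g3, l4 = l4, g4 = g4)
}

ft_backward <- function(shared, step, cache, dZ4) {
  s <- RESID_SCALE
  dz3 <- dZ4 * s
  b4 <- linear_backward(step$g2, cache$l4, glu_backward(cache$g4, dZ4 * s))
  dz3 <- dz3 + b4$dX
  dz2 <- dz3 * s
  b3 <- linear_backward(step$g1, cache$l3, glu_backward(cache$g3, dz3 * s))
  dz2 <- dz2 + b3$dX
  dz1 <- dz2 * s
  b2 <- linear_backward(shared$g2, cache$l2, glu_backward(cache$g2, dz2 * s))
  dz1 <- dz1 + b2$dX
  b1 <- linear_backward(shared$g1, cache$l1, glu_backward(cache$g1, dz1))
  list(dXin = b1$dX,
       shared = list(g1 = b1$grads, g2 = b2$grads),
       step = list(g1 = b3$grads, g2 = b4$grads))
}

# Full forward pass over a batch X (B x input_dim). Returns the latent h
# (B x n_d), per-step masks, and the cache needed for the backward pass.
tabnet_forward <- function(weights, params, X) {
  if (ncol(X) != params$input_dim)
    stop("input has ", ncol(X), " features; encoder expects ", params$input_dim)
  B <- nrow(X)
  nd <- params$n_d; H <- params$n_d + params$n_a
  ft0 <- ft_forward(weights$shared, weights$steps[[1]], X)
  a <- ft0$out[, (nd + 1):H, drop = FALSE]
  prior <- matrix(1, B, params$input_dim)
  h <- matrix(0, B, nd)
  steps <- vector("list", params$n_steps)
  for (i in seq_len(params$n_steps)) {
    la <- linear_forward(weights$att[[i]], a)
    mp <- prior * la$out
    M <- sparsemax_rows(mp)
    Xm <- M * X
    ft <- ft_forward(weights$shared, weights$steps[[i + 1]], Xm)
    d <- ft$out[, 1:nd, drop = FALSE]
    a <- ft$out[, (nd + 1):H, drop = FALSE]
    h <- h + relu(d)
    steps[[i]] <- list(la = la, pre = la$out, prior = prior, M = M,
                       Xm = Xm, ft = ft, d = d)
    prior <- prior * (params$gamma - M)
  }
  list(h = h, masks = lapply(steps, `[[`, "M"),
       d_steps = lapply(steps, `[[`, "d"),
       cache = list(X = X, ft0 = ft0, steps = steps))
}

# Backward pass: dh is the gradient w.r.t. the latent output. Gradients
# flow through decision outputs, masks, the sparsemax, the running prior
# chain, and the attentive inputs of later steps.
tabnet_backward <- function(weights, params, fwd, dh) {
  cache <- fwd$cache
  X <- cache$X
  nd <- params$n_d; H <- params$n_d + params$n_a
  B <- nrow(X)
  grads <- tree_zero_like(weights)
  da <- matrix(0, B, params$n_a)              # grad w.r.t. a_i (none after last step)
  dprior <- matrix(0, B, params$input_dim)    # grad w.r.t. prior_{i+1}
  dX <- matrix(0, B, params$input_dim)
  for (i in rev(seq_len(params$n_steps))) {
    st <- cache$steps[[i]]
    dd <- dh * (st$d > 0)
    dZ4 <- cbind(dd, da)
    fb <- ft_backward(weights$shared, weights$steps[[i + 1]], st$ft, dZ4)
    grads$shared <- tree_add(grads$shared, fb$shared)
    grads$steps[[i + 1]] <- tree_add(grads$steps[[i + 1]], fb$step)
    dXm <- fb$dXin
    dM <- dXm * X
    dX <- dX + dXm * st$M
    # prior chain: prior_{i+1} = prior_i * (gamma - M_i)
    dM <- dM - dprior * st$prior
    dprior_i <- dprior * (params$gamma - st$M)
    dmp <- sparsemax_rows_backward(st$M, dM)
    dprior_i <- dprior_i + dmp * st$pre
    dpre <- dmp * st$prior
    ab <- linear_backward(weights$att[[i]], st$la, dpre)
    grads$att[[i]] <- tree_add(grads$att[[i]], ab$grads)
    da <- ab$dX
    dprior <- dprior_i
  }
  dZ4_0 <- cbind(matrix(0, B, nd), da)
  fb0 <- ft_backward(weights$shared, weights$steps[[1]], cache$ft0, dZ4_0)
  grads$shared <- tree_add(grads$shared, fb0$shared)
  grads$steps[[1]] <- tree_add(grads$steps[[1]], fb0$step)
  dX <- dX + fb0$dXin
  list(dX = dX, grads = grads)
}

#' Encode feature vectors with a TabNet encoder
#'
#' @param x Numeric vector of length `params$input_dim`, or a matrix with
#'   one row per observation.
#' @param params An [encoder_params()].
#' @param weights Weights from [tabnet_init()] (or a trained model).
#' @return List with `h` (latent matrix, `n_d` columns; a vector input
#'   yields one row) and `trace`, an attention-mask trace: `masks` (list of
#'   `n_steps` simplex-row matrices) and `d_steps` (per-step decision
#'   outputs, used to weight masks in [feature_importance()]).
#' @export
encode <- function(x, params, weights) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  fwd <- tabnet_forward(weights, params, x)
  list(h = fwd$h, trace = list(masks = fwd$masks, d_steps = fwd$d_steps))
}

#' Aggregate attention masks into per-feature importances
#'
#' Each step's mask is weighted by that step's total rectified decision
#' output (its contribution to the latent representation), summed across
#' steps, and normalized so every row sums to 1.
#'
#' @param trace Trace from [encode()].
#' @param feature_names Optional column names for the result.
#' @param aggregate If TRUE (default) also average over rows into a single
#'   normalized importance vector.
#' @return Matrix of per-observation importances, or a vector when
#'   `aggregate = TRUE`.
#' @export
feature_importance <- function(trace, feature_names = NULL, aggregate = TRUE) {
  if (length(trace$masks) == 0) stop("empty attention trace")
  imp <- 0
  for (i in seq_along(trace$masks)) {
    eta <- rowSums(relu(trace$d_steps[[i]]))
    imp <- imp + trace$masks[[i]] * eta
  }
  rs <- rowSums(imp)
  imp <- imp / ifelse(rs > 0, rs, 1)
  if (!is.null(feature_names)) colnames(imp) <- feature_names
  if (aggregate) {
    v <- colMeans(imp)
    s <- sum(v)
    if (s > 0) v <- v / s
    return(v)
  }
  imp
}
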