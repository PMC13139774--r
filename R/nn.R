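# Minimal vectorized neural-network primitives with hand-written backward
# passes. Parameters live in nested named lists of matrices/vectors; the
# Adam optimizer walks the same tree. All randomness goes through R's RNG
# so a single set.seed() makes every fit bit-reproducible.

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

linear_init <- function(n_in, n_out) {
  list(W = glorot_init(n_in, n_out), b = rep(0, n_out))
}

linear_forward <- function(p, X) {
  list(out = sweep(X %*% p$W, 2, p$b, "+"), X = X)
}

linear_backward <- function(p, cache, dY) {
  list(dX = tcrossprod(dY, p$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Gated linear unit on a pre-activation matrix with 2H columns:
# out = U[,1:H] * sigmoid(U[,H+1:2H]).
glu_forward <- function(U) {
  H <- ncol(U) / 2
  A <- U[, 1:H, drop = FALSE]
  S <- sigmoid(U[, H + (1:H), drop = FALSE])
  list(out = A * S, A = A, S = S)
}

glu_backward <- function(cache, dOut) {
  dA <- dOut * cache$S
  dPre <- dOut * cache$A * cache$S * (1 - cache$S)
  cbind(dA, dPre)
}

relu <- function(x) pmax(x, 0)

l2_normalize_rows <- function(X, eps = 1e-12) {
  nr <- sqrt(rowSums(X^2))
  X / pmax(nr, eps)
}

# Backward of row L2 normalization: given Y = X / ||X||, dX = (dY - Y * <Y, dY>)/||X||.
l2_normalize_rows_backward <- function(X, dY, eps = 1e-12) {
  nr <- pmax(sqrt(rowSums(X^2)), eps)
  Y <- X / nr
  (dY - Y * rowSums(Y * dY)) / nr
}

## ---- two-layer MLP (projection head; ablation/baseline encoder) ----

mlp_init <- function(n_in, n_hidden, n_out) {
  list(fc1 = linear_init(n_in, n_hidden), fc2 = linear_init(n_hidden, n_out))
}

mlp_forward <- function(p, X) {
  l1 <- linear_forward(p$fc1, X)
  A <- relu(l1$out)
  l2 <- linear_forward(p$fc2, A)
  list(out = l2$out, cache = list(l1 = l1, A = A, l2 = l2))
}

mlp_backward <- function(p, cache, dY) {
  b2 <- linear_backward(p$fc2, cache$l2, dY)
  dA <- b2$dX * (cache$A > 0)
  b1 <- linear_backward(p$fc1, cache$l1, dA)
  list(dX = b1$dX, grads = list(fc1 = b1$grads, fc2 = b2$grads))
}

## ---- parameter-tree utilities ----

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zero_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_flatten <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  do.call(c, lapply(tree, tree_flatten))
}

## ---- Adam optimizer ----

# State holds the two moment trees. Leaf vectors of params/m/v are owned
# exclusively by the optimizer loop: the C++ kernel updates them in place
# (both Adam bias corrections folded into the step size), so adam_step
# callers must treat the params tree they passed in as consumed and use the
# returned one.
adam_init <- function(params) {
  list(m = tree_zero_like(params), v = tree_zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  adam_update_tree_cpp(tree_flatten(params), tree_flatten(grads),
                       tree_flatten(state$m), tree_flatten(state$v),
                       state$t, lr, beta1, beta2, eps)
  list(params = params, state = state)
}
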