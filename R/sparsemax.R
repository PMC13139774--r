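#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Computes `argmin_p ||p - v||^2` subject to `p >= 0, sum(p) = 1` via the
#' sorted-threshold algorithm. Unlike softmax, the result can contain exact
#' zeros, which is what makes the TabNet attention masks sparse and
#' interpretable.
#'
#' @param v Numeric vector (finite), length >= 1.
#' @return Vector on the simplex: entries >= 0 summing to 1.
#' @export
sparsemax <- function(v) {
  if (length(v) == 0) stop("sparsemax: empty vector")
  if (any(!is.finite(v))) stop("sparsemax: non-finite input")
  z <- sort(v, decreasing = TRUE)
  css <- cumsum(z)
  k <- seq_along(z)
  supp <- z + 1 / k * (1 - css) > 0
  kz <- max(k[supp])
  tau <- (css[kz] - 1) / kz
  pmax(v - tau, 0)
}

# Row-wise sparsemax for a matrix (each row projected independently).
sparsemax_rows <- function(V) {
  t(apply(V, 1, sparsemax))
}

# Backward pass of row-wise sparsemax.
# Jacobian at output s with support S: dv = (ds - mean_S(ds)) on S, 0 off S.
sparsemax_rows_backward <- function(S_out, dS) {
  supp <- S_out > 0
  ns <- rowSums(supp)
  masked <- dS * supp
  mean_supp <- rowSums(masked) / pmax(ns, 1)
  (masked - supp * mean_supp)
}
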