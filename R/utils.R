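# small numerical helpers shared across the package

# floor used inside every logarithm; matches the pseudocount floor applied to
# otherwise-zero initial-state counts
LOG_FLOOR <- exp(-16)

#' Numerically safe natural logarithm
#'
#' Logarithm with its argument floored at `exp(-16)`, the package-wide
#' convention for handling structural zeros in probability arrays.
#'
#' @param x numeric vector/array of nonnegative values.
#' @return `log(pmax(x, exp(-16)))`.
#' @keywords internal
#' @export
safe_log <- function(x) log(pmax(x, LOG_FLOOR))

#' Softmax (normalized exponential)
#'
#' @param x numeric vector of log-scale scores.
#' @return probability vector proportional to `exp(x)`.
#' @export
softmax <- function(x) {
  y <- exp(x - max(x))
  y / sum(y)
}

# Shannon entropy of a probability vector (nats); 0 * log 0 := 0
entropy_nats <- function(q) {
  -sum(ifelse(q > 0, q * log(q), 0))
}

# KL divergence KL(q || p) in nats, with p floored
kl_nats <- function(q, p) {
  sum(ifelse(q > 0, q * (log(q) - safe_log(p)), 0))
}

# cross entropy -E_q[ln p] in nats
cross_entropy_nats <- function(q, p) {
  -sum(ifelse(q > 0, q * safe_log(p), 0))
}

is_prob_vector <- function(q, tol = 1e-9) {
  is.numeric(q) && all(q >= -tol) && abs(sum(q) - 1) < tol
}

# flatten joint distribution over factors from per-factor marginals, in
# column-major order with factor 1 varying fastest
joint_weights <- function(qlist) {
  w <- qlist[[1]]
  if (length(qlist) > 1) {
    for (f in 2:length(qlist)) w <- as.vector(outer(w, qlist[[f]]))
  }
  w
}
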