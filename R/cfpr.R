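#' Convert a Saaty-scale ratio judgment to a fuzzy preference
#'
#' Maps a multiplicative preference ratio r in \[1/9, 9\] to an additive
#' fuzzy preference in \[0, 1\] via
#' \deqn{f(r) = \tfrac{1}{2}\,(1 + \log_9 r).}
#' Indifference (r = 1) maps to 0.5, the strongest preference (r = 9) to 1,
#' and reciprocal ratios to complements: f(1/r) = 1 - f(r).
#'
#' @param r numeric vector of ratios in \[1/9, 9\].
#' @return fuzzy preferences in \[0, 1\].
#' @export
#' @examples
#' ratio_to_fuzzy(c(1, 3, 9))  # 0.50 0.75 1.00
ratio_to_fuzzy <- function(r) {
  check_numeric(r, "ratio judgment")
  if (any(r < 1 / 9 - 1e-12 | r > 9 + 1e-12)) {
    stop_input("ratio judgment outside [1/9, 9]: ",
               paste(r[r < 1 / 9 - 1e-12 | r > 9 + 1e-12], collapse = ", "))
  }
  0.5 * (1 + log(r, base = 9))
}

new_cfpr_matrix <- function(p, shift = 0, rescaled = FALSE) {
  structure(p, shift = shift, rescaled = rescaled, class = "cfpr_matrix")
}

#' Complete a preference matrix from a chain of adjacent comparisons
#'
#' Given the k-1 elicited fuzzy preferences p(i, i+1) between consecutive
#' attributes, the remaining entries of the k x k relation are determined
#' by additive transitivity
#' \deqn{p_{ij} + p_{jl} - 0.5 = p_{il},}
#' i.e. for j > i, p(i, j) is the sum of the consecutive chain values minus
#' (j - i - 1)/2; the diagonal is 0.5 and the lower triangle follows from
#' additive reciprocity p(j, i) = 1 - p(i, j).  The completed matrix
#' satisfies transitivity for every triple, not just adjacent ones, but its
#' entries may fall outside \[0, 1\]; see [rescale_matrix()].
#'
#' @param chain numeric vector of k-1 fuzzy preferences in \[0, 1\]
#'   (elicitation order = instrument order); `numeric(0)` for k = 1.
#' @param k group size; defaults to `length(chain) + 1`.
#' @return A `cfpr_matrix`: the k x k relation with attributes `shift`
#'   (rescale constant, 0 here) and `rescaled` (`FALSE` here).
#' @export
#' @examples
#' complete_matrix(c(0.7, 0.7))  # p13 = 0.7 + 0.7 - 0.5 = 0.9
complete_matrix <- function(chain, k = length(chain) + 1L) {
  check_numeric(chain, "chain")
  if (length(chain) != k - 1L) {
    stop_input("chain length ", length(chain), " does not match k - 1 = ", k - 1L)
  }
  if (any(chain < 0 | chain > 1)) {
    stop_input("chain values must lie in [0, 1] (convert Saaty ratios first)")
  }
  # cumulative chain sums give p(i, j) = S[j] - S[i] - (j - i - 1)/2 for j > i
  s <- cumsum(c(0, chain))
  p <- outer(seq_len(k), seq_len(k),
             function(i, j) (s[pmax(i, j)] - s[pmin(i, j)]) - (abs(j - i) - 1) / 2)
  p[lower.tri(p)] <- 1 - p[lower.tri(p)]
  diag(p) <- 0.5
  new_cfpr_matrix(p)
}

#' Rescale a completed preference matrix into \[0, 1\]
#'
#' Additive-transitivity completion can push entries outside the unit
#' interval (into \[-a, 1 + a\]).  The order-preserving transform
#' \deqn{f(x) = (x + a) / (1 + 2a), \qquad a = \max(0,\ \max_{ij} p_{ij} - 1),}
#' maps them back while preserving the 0.5 diagonal, additive reciprocity
#' and additive transitivity.  A matrix already inside \[0, 1\] is returned
#' unchanged with a = 0.
#'
#' @param m a `cfpr_matrix` (or plain numeric matrix) satisfying
#'   reciprocity and transitivity.
#' @return A `cfpr_matrix` with all entries in \[0, 1\]; attribute `shift`
#'   records the constant a applied and `rescaled` whether f was applied.
#' @export
rescale_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_input("expected a square matrix")
  a <- max(0, max(m) - 1)
  if (a == 0) return(new_cfpr_matrix(unclass(m)[, , drop = FALSE], shift = 0, rescaled = FALSE))
  new_cfpr_matrix((unclass(m) + a) / (1 + 2 * a), shift = a, rescaled = TRUE)
}

#' Derive attribute weights from a preference matrix
#'
#' Uses the normalized row-sum rule
#' \deqn{w_i = \sum_j p_{ij} \Big/ \sum_{i}\sum_{j} p_{ij},}
#' where by additive reciprocity the denominator equals k^2 / 2.  Weights
#' are positive, sum to one, and preserve the ordering of row sums.
#'
#' @param m a `cfpr_matrix` with entries in \[0, 1\] (see
#'   [rescale_matrix()]).
#' @return numeric weight vector of length k summing to 1.
#' @export
weights_from_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_input("expected a square matrix")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9) {
    stop_input("matrix entries outside [0, 1]; apply rescale_matrix() first")
  }
  rs <- rowSums(m)
  as.numeric(rs / sum(rs))
}

#' Weights from an adjacent-comparison chain
#'
#' The composition [complete_matrix()] -> [rescale_matrix()] ->
#' [weights_from_matrix()]: the full elicitation-to-weights step for one
#' comparison group of one respondent.  A single-attribute group (empty
#' chain) has weight 1.
#'
#' @inheritParams complete_matrix
#' @return numeric weight vector of length k summing to 1.
#' @export
#' @examples
#' chain_weights(c(0.7, 0.7))  # 0.4667 0.3333 0.2000
chain_weights <- function(chain, k = length(chain) + 1L) {
  if (k == 1L) {
    if (length(chain)) stop_input("k = 1 group takes an empty chain")
    return(1)
  }
  weights_from_matrix(rescale_matrix(complete_matrix(chain, k)))
}

#' @export
print.cfpr_matrix <- function(x, ...) {
  cat("<cfpr_matrix> k = ", nrow(x),
      if (attr(x, "rescaled")) paste0(", rescaled (a = ", signif(attr(x, "shift"), 6), ")")
      else ", raw", "\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}
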