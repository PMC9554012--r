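# Independent oracles, deliberately implemented by different routes than
# the package: the completion oracle solves the additive-transitivity
# equations for all upper-triangular entries as a linear system instead of
# accumulating chain sums.

oracle_complete <- function(chain, k = length(chain) + 1) {
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  idx <- function(i, j) which(pairs[, 1] == i & pairs[, 2] == j)
  m <- nrow(pairs)
  A <- NULL; b <- NULL
  for (i in seq_len(k - 1)) {           # elicited adjacent values
    row <- numeric(m); row[idx(i, i + 1)] <- 1
    A <- rbind(A, row); b <- c(b, chain[i])
  }
  for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
    if (i < j && j < l) {               # p_il - p_ij - p_jl = -0.5
      row <- numeric(m)
      row[idx(i, l)] <- 1; row[idx(i, j)] <- -1; row[idx(j, l)] <- -1
      A <- rbind(A, row); b <- c(b, -0.5)
    }
  }
  x <- qr.solve(A, b)
  p <- matrix(0.5, k, k)
  for (q in seq_len(m)) {
    p[pairs[q, 1], pairs[q, 2]] <- x[q]
    p[pairs[q, 2], pairs[q, 1]] <- 1 - x[q]
  }
  p
}

oracle_chain_weights <- function(chain, k = length(chain) + 1) {
  if (k == 1) return(1)
  p <- oracle_complete(chain, k)
  a <- max(0, max(p) - 1)
  p <- (p + a) / (1 + 2 * a)
  rowSums(p) / sum(p)
}

# straightforward two-pass recomputation of the leave-one-out confidence
# level, driven by the oracle completion path
oracle_global_weights <- function(panel, rows) {
  instrument <- panel$instrument
  resp <- panel$respondents[rows]
  jd <- panel$judgments
  gw <- function(g) {
    ids <- if (identical(g, "DIMS")) dimension_ids(instrument)
           else criterion_ids(instrument, g)
    k <- length(ids)
    if (k == 1) return(setNames(1, ids))
    per <- sapply(resp, function(r) {
      jr <- jd[jd$respondent_id == r & jd$group_id == g, ]
      chain <- jr$fuzzy_value[match(ids[-k], jr$left_id)]
      oracle_chain_weights(chain, k)
    })
    setNames(rowMeans(per), ids)
  }
  dims <- gw("DIMS")
  unlist(lapply(names(dims), function(d) dims[[d]] * gw(d)))
}

oracle_confidence <- function(panel) {
  n <- panel$n
  w_full <- oracle_global_weights(panel, seq_len(n))
  w_loo <- oracle_global_weights(panel, seq_len(n - 1))
  mean(abs(w_full - w_loo) / w_full) * 100
}
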