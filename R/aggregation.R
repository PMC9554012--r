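#' Elicit per-respondent weights for every comparison group
#'
#' Runs [chain_weights()] for each respondent on the dimension chain
#' (`"DIMS"`) and on each dimension's criteria chain, using judgments on
#' the fuzzy \[0, 1\] scale (Saaty ratios were converted at load time).
#'
#' @param panel a `respondent_panel`.
#' @return list with `respondents` (character), `dims` (n x D matrix of
#'   dimension weights, rows = respondents in file order) and `crit` (named
#'   list per dimension of n x k local weight matrices).
#' @export
elicit_weights <- function(panel) {
  stopifnot(inherits(panel, "respondent_panel"))
  instrument <- panel$instrument
  resp <- panel$respondents
  jd <- panel$judgments

  group_w <- function(group_id) {
    members <- group_members(instrument, group_id)
    k <- length(members)
    w <- matrix(NA_real_, nrow = length(resp), ncol = k,
                dimnames = list(resp, members))
    jg <- jd[jd$group_id == group_id, ]
    for (r in resp) {
      jr <- jg[jg$respondent_id == r, ]
      pos <- match(jr$left_id, members)
      chain <- numeric(k - 1L)
      chain[pos] <- jr$fuzzy_value
      w[r, ] <- chain_weights(chain, k)
    }
    w
  }

  dims <- group_w("DIMS")
  crit <- lapply(dimension_ids(instrument), group_w)
  names(crit) <- dimension_ids(instrument)
  list(respondents = resp, dims = dims, crit = crit)
}

#' Aggregate expert weight vectors by arithmetic mean
#'
#' Group weights are the element-wise mean of the respondents' normalized
#' weight vectors; since each vector sums to one, so does the mean.
#'
#' @param w matrix with one weight vector per row, or list of equal-length
#'   numeric vectors.
#' @return numeric mean weight vector (names preserved).
#' @export
aggregate_expert_weights <- function(w) {
  if (is.list(w)) {
    if (length(w) == 0L) stop_input("no weight vectors to aggregate")
    len <- lengths(w)
    if (any(len != len[1])) stop_input("weight vectors have unequal lengths")
    w <- do.call(rbind, w)
  }
  if (!is.matrix(w) || nrow(w) == 0L) stop_input("no weight vectors to aggregate")
  sums <- rowSums(w)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_input("weight vector(s) do not sum to 1 (row ",
               which(abs(sums - 1) > 1e-6)[1], ")")
  }
  colMeans(w)
}

#' Competition ranks, largest first
#'
#' Rank 1 is the largest value; ties share the smallest (best) tied rank
#' and keep input (instrument) order for presentation.
#'
#' @param x numeric vector.
#' @return integer ranks.
#' @export
#' @examples
#' rank_weights(c(0.3, 0.3, 0.4))  # 2 2 1
rank_weights <- function(x) {
  check_numeric(x, "weights")
  if (!length(x)) stop_input("cannot rank an empty vector")
  as.integer(rank(-x, ties.method = "min"))
}

#' Compose dimension and criterion weights into a hierarchical weight table
#'
#' The global weight of criterion c in dimension d is the product
#' w(d) x w(c | d); global weights therefore sum to one whenever the input
#' levels each sum to one.  Ranks are competition ranks computed from the
#' full-precision weights at each level: dimensions among dimensions,
#' criteria within their dimension, and all criteria globally.
#'
#' Inputs are accepted if each level sums to 1 within `tol`; the loose
#' default accommodates recomposition from 4-decimal printed weights.
#'
#' @param dim_weights named numeric vector of dimension weights.
#' @param crit_weights named list (one element per dimension, same order)
#'   of named local criterion weight vectors.
#' @param tol allowed deviation of each level's sum from 1.
#' @return A `weight_table` data frame with columns `dimension, dim_weight,
#'   dim_rank, criterion, crit_weight, crit_rank, global_weight,
#'   global_rank`, one row per criterion.
#' @export
compute_global_weights <- function(dim_weights, crit_weights, tol = 1e-3) {
  if (is.null(names(dim_weights)) || is.null(names(crit_weights))) {
    stop_input("dim_weights and crit_weights must be named")
  }
  if (!identical(names(dim_weights), names(crit_weights))) {
    stop_input("dimension names of dim_weights and crit_weights disagree")
  }
  if (abs(sum(dim_weights) - 1) > tol) {
    stop_input("dimension weights sum to ", sum(dim_weights), ", not 1")
  }
  dim_rank <- rank_weights(dim_weights)
  rows <- lapply(seq_along(dim_weights), function(i) {
    lw <- crit_weights[[i]]
    if (is.null(names(lw))) stop_input("local weights for dimension '",
                                       names(dim_weights)[i], "' must be named")
    if (abs(sum(lw) - 1) > tol) {
      stop_input("local weights for dimension '", names(dim_weights)[i],
                 "' sum to ", sum(lw), ", not 1")
    }
    data.frame(dimension = names(dim_weights)[i],
               dim_weight = unname(dim_weights[i]),
               dim_rank = dim_rank[i],
               criterion = names(lw),
               crit_weight = unname(lw),
               crit_rank = rank_weights(lw),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$global_weight <- tab$dim_weight * tab$crit_weight
  tab$global_rank <- rank_weights(tab$global_weight)
  rownames(tab) <- NULL
  class(tab) <- c("weight_table", "data.frame")
  tab
}

#' Leave-one-respondent-out confidence level of the aggregated weights
#'
#' Stability statistic for the group weights: with w^(n) the weights
#' aggregated over all n respondents and w^(n-1) the weights aggregated
#' with one respondent removed,
#' \deqn{CL = \frac{1}{k} \sum_{i=1}^{k}
#'   \frac{|w_i^{(n)} - w_i^{(n-1)}|}{w_i^{(n)}} \times 100\%.}
#' A CL below the threshold (default 5\%) indicates the panel is large
#' enough that no single respondent moves the weights materially.
#'
#' @param panel a `respondent_panel` with n >= 2.
#' @param target which weight set to assess: the 30 global criterion
#'   weights (default) or the dimension weights.
#' @param drop `"last"` removes the final respondent in file order;
#'   `"all"` computes CL for every possible single removal and reports the
#'   mean and maximum.
#' @param threshold pass/fail threshold in percent.
#' @return An object of class `confidence_stat`: list with `n`, `k`,
#'   `value` (percent; for `drop = "all"` the mean over drops), `max_value`
#'   (drop = "all" only), `per_drop`, `threshold`, `pass`, `target`,
#'   `drop`.
#' @export
confidence_level <- function(panel, target = c("global", "dimensions"),
                             drop = c("last", "all"), threshold = 5) {
  stopifnot(inherits(panel, "respondent_panel"))
  target <- match.arg(target)
  drop <- match.arg(drop)
  if (panel$n < 2L) stop_input("confidence level requires at least 2 respondents")

  ew <- elicit_weights(panel)
  target_weights <- function(rows) {
    dw <- aggregate_expert_weights(ew$dims[rows, , drop = FALSE])
    if (target == "dimensions") return(dw)
    cw <- lapply(ew$crit, function(m) aggregate_expert_weights(m[rows, , drop = FALSE]))
    tab <- compute_global_weights(dw, cw, tol = 1e-9)
    setNames(tab$global_weight, tab$criterion)
  }

  n <- panel$n
  w_full <- target_weights(seq_len(n))
  cl_one <- function(omit) {
    w_loo <- target_weights(setdiff(seq_len(n), omit))
    mean(abs(w_full - w_loo) / w_full) * 100
  }
  if (drop == "last") {
    per_drop <- setNames(cl_one(n), ew$respondents[n])
    value <- unname(per_drop)
    max_value <- NULL
  } else {
    per_drop <- setNames(vapply(seq_len(n), cl_one, 0), ew$respondents)
    value <- mean(per_drop)
    max_value <- max(per_drop)
  }
  structure(list(n = n, k = length(w_full), value = value,
                 max_value = max_value, per_drop = per_drop,
                 threshold = threshold, pass = value < threshold,
                 target = target, drop = drop),
            class = "confidence_stat")
}

#' @export
print.confidence_stat <- function(x, ...) {
  cat(sprintf("<confidence_stat> CL = %.4g%% (%s weights, n = %d, drop = %s): %s %g%%\n",
              x$value, x$target, x$n, x$drop,
              if (x$pass) "below threshold" else "NOT below threshold",
              x$threshold))
  if (!is.null(x$max_value)) {
    cat(sprintf("  max over single drops: %.4g%%\n", x$max_value))
  }
  invisible(x)
}
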