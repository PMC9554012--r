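#' Consistent preference matrix with a prescribed weight vector
#'
#' Inverse of [weights_from_matrix()]: the relation
#' \deqn{p_{ij} = 0.5 + k\,(w_i - w_j)/2}
#' satisfies additive reciprocity and additive transitivity and has
#' normalized row sums exactly equal to `w`.  Entries stay inside \[0, 1\]
#' only if the weights are not too spread out:
#' max_ij k |w_i - w_j| / 2 <= 0.5.  Wider targets are rejected rather
#' than rescaled, because rescaling would change the recovered weights;
#' see [compress_weights()].
#'
#' @param w numeric weight vector summing to 1.
#' @return a `cfpr_matrix` with entries in \[0, 1\].
#' @export
consistent_matrix_from_weights <- function(w) {
  check_numeric(w, "weights")
  k <- length(w)
  if (abs(sum(w) - 1) > 1e-8) stop_input("weights must sum to 1 (got ", sum(w), ")")
  spread <- k * (max(w) - min(w)) / 2
  if (spread > 0.5 + 1e-12) {
    stop_input("weight spread too large for a consistent matrix in [0, 1] ",
               "(k * (max - min) / 2 = ", signif(spread, 4),
               " > 0.5); compress the target weights toward uniform, ",
               "e.g. with compress_weights()")
  }
  p <- 0.5 + k * outer(w, w, "-") / 2
  dimnames(p) <- list(names(w), names(w))
  new_cfpr_matrix(p)
}

#' Adjacent-comparison chain that encodes a weight vector
#'
#' The k-1 consecutive entries p(i, i+1) of
#' [consistent_matrix_from_weights()]; feeding the chain back through
#' [chain_weights()] recovers `w` exactly (no rescale is triggered).
#'
#' @inheritParams consistent_matrix_from_weights
#' @return numeric vector of length k-1 in \[0, 1\] (`numeric(0)` for
#'   k = 1).
#' @export
chain_from_weights <- function(w) {
  k <- length(w)
  if (k == 1L) {
    if (abs(w - 1) > 1e-8) stop_input("a single weight must equal 1")
    return(numeric(0))
  }
  m <- consistent_matrix_from_weights(w)
  m[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)]
}

#' Shrink a weight vector toward uniform to satisfy the spread constraint
#'
#' Linearly interpolates between `w` and the uniform vector just enough
#' that `consistent_matrix_from_weights()` stays inside \[0, 1\], with a
#' small safety margin.  Already-feasible vectors are returned unchanged.
#' Shrinking preserves the sum, the ordering and the ranking of the
#' weights, but not their ratios.
#'
#' @param w numeric weight vector summing to 1.
#' @param margin fraction of the feasible spread to use (default 0.98).
#' @return feasible weight vector summing to 1.
#' @export
compress_weights <- function(w, margin = 0.98) {
  check_numeric(w, "weights")
  if (abs(sum(w) - 1) > 1e-8) stop_input("weights must sum to 1")
  k <- length(w)
  spread <- k * (max(w) - min(w)) / 2
  limit <- margin * 0.5
  if (spread <= limit) return(w)
  lambda <- limit / spread
  1 / k + lambda * (w - 1 / k)
}

#' Default ground-truth weights for an instrument
#'
#' For the bundled HHNJS instrument the targets are the reference study's
#' local weights ([hhnjs_reference_weights()]), renormalized to sum
#' exactly to 1 per group and compressed toward uniform where a group's
#' spread exceeds what a consistent matrix in \[0, 1\] can encode (only
#' the "relationship with peer" group needs this).  For any other
#' instrument the targets are uniform per group.
#'
#' @param instrument an `instrument`.
#' @return named list: `dims` (named dimension weight vector) and `crit`
#'   (named list of named local weight vectors).
#' @export
default_true_weights <- function(instrument) {
  dims <- dimension_ids(instrument)
  ref <- hhnjs_reference_weights()
  is_hhnjs <- setequal(dims, unique(ref$dimension)) &&
    setequal(criterion_ids(instrument), ref$criterion)
  norm <- function(x) x / sum(x)
  if (is_hhnjs) {
    dw <- vapply(dims, function(d) ref$dim_weight[ref$dimension == d][1], 0)
    cw <- lapply(dims, function(d) {
      rows <- ref[ref$dimension == d, ]
      compress_weights(norm(setNames(rows$crit_weight, rows$criterion)))
    })
    names(cw) <- dims
    list(dims = compress_weights(norm(dw)), crit = cw)
  } else {
    cw <- lapply(dims, function(d) {
      ids <- criterion_ids(instrument, d)
      setNames(rep(1 / length(ids), length(ids)), ids)
    })
    names(cw) <- dims
    list(dims = setNames(rep(1 / length(dims), length(dims)), dims),
         crit = cw)
  }
}

#' Configuration for the synthetic respondent generator
#'
#' Defines the study conditions a generated panel emulates.  The defaults
#' mirror a 31-respondent survey on the HHNJS with ground-truth weights
#' taken from the reference study and true item means from its reported
#' performance column.
#'
#' @param instrument an `instrument` (default: the bundled HHNJS).
#' @param true_weights list with `dims` and `crit` as in
#'   [default_true_weights()]; each vector must sum to 1 and satisfy the
#'   spread constraint.
#' @param true_performance named per-criterion true mean satisfaction in
#'   \[1, 5\]; default: the reference study's performance means for the
#'   HHNJS, else 3.5 for every item.
#' @param judgment_noise standard deviation of the additive Gaussian noise
#'   applied to each fuzzy chain value (on the \[0, 1\] scale), then
#'   clipped back to \[0, 1\].  Default 0.05: respondents agree on the
#'   broad preference ordering but differ in degree.
#' @param rating_noise standard deviation of the latent Gaussian rating
#'   around the true mean before clipping to \[1, 5\] and rounding to the
#'   Likert categories.  Default 0.7, a typical single-item spread on a
#'   5-point scale.
#' @param n number of respondents (default 31).
#' @param seed integer RNG seed (default 1).
#' @return a `generator_config` list.
#' @export
generator_config <- function(instrument = load_hhnjs(),
                             true_weights = default_true_weights(instrument),
                             true_performance = NULL,
                             judgment_noise = 0.05,
                             rating_noise = 0.7,
                             n = 31L, seed = 1L) {
  stopifnot(inherits(instrument, "instrument"))
  crit <- criterion_ids(instrument)
  if (is.null(true_performance)) {
    ref <- hhnjs_reference_ipa()
    true_performance <- if (setequal(crit, ref$criterion)) {
      setNames(ref$performance[match(crit, ref$criterion)], crit)
    } else {
      setNames(rep(3.5, length(crit)), crit)
    }
  }
  if (!setequal(names(true_performance), crit)) {
    stop_input("true_performance must be named by the instrument's criterion ids")
  }
  true_performance <- true_performance[crit]
  if (any(true_performance < 1 | true_performance > 5)) {
    stop_input("true_performance means must lie in [1, 5]")
  }
  if (judgment_noise < 0 || rating_noise < 0) stop_input("noise sd must be >= 0")
  if (n < 1L) stop_input("n must be >= 1")

  dims <- dimension_ids(instrument)
  if (!identical(names(true_weights$dims), dims) ||
      !identical(names(true_weights$crit), dims)) {
    stop_input("true_weights must be named by the instrument's dimension ids, in order")
  }
  # fail fast on any spread-infeasible target group
  consistent_matrix_from_weights(true_weights$dims)
  for (d in dims) {
    lw <- true_weights$crit[[d]]
    if (!identical(names(lw), criterion_ids(instrument, d))) {
      stop_input("true_weights$crit[['", d, "']] must be named by that ",
                 "dimension's criterion ids, in order")
    }
    if (length(lw) > 1L) consistent_matrix_from_weights(lw)
  }

  structure(list(instrument = instrument, true_weights = true_weights,
                 true_performance = true_performance,
                 judgment_noise = judgment_noise, rating_noise = rating_noise,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic respondent panel
#'
#' Per respondent and comparison group, the ideal chain encoding the true
#' weights ([chain_from_weights()]) is perturbed with independent
#' N(0, judgment_noise^2) noise per chain value and clipped to \[0, 1\];
#' ratings are `round(clip(N(mu_c, rating_noise^2), 1, 5))` per criterion.
#' The panel is fully reproducible from `config$seed` and always passes
#' [as_panel()] validation.  The ground truth is attached as attribute
#' `"truth"`.
#'
#' @param config a `generator_config`.
#' @return a `respondent_panel` with attribute `truth` (list: `weights`,
#'   `performance`, `global_weights`, `config`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  instrument <- config$instrument
  set.seed(config$seed)

  resp <- sprintf("R%02d", seq_len(config$n))
  groups <- group_ids(instrument)
  ideal <- lapply(groups, function(g) {
    w <- if (identical(g, "DIMS")) config$true_weights$dims
         else config$true_weights$crit[[g]]
    chain_from_weights(w)
  })
  names(ideal) <- groups

  jrows <- list()
  for (r in resp) {
    for (g in groups) {
      chain <- ideal[[g]]
      if (!length(chain)) next
      members <- group_members(instrument, g)
      noisy <- pmin(pmax(chain + rnorm(length(chain), 0, config$judgment_noise), 0), 1)
      jrows[[length(jrows) + 1L]] <- data.frame(
        respondent_id = r, group_id = g,
        left_id = members[-length(members)], right_id = members[-1],
        value = noisy, scale = "fuzzy", stringsAsFactors = FALSE)
    }
  }
  judgments <- do.call(rbind, jrows)

  crit <- criterion_ids(instrument)
  mu <- config$true_performance[crit]
  rrows <- lapply(resp, function(r) {
    latent <- rnorm(length(crit), mu, config$rating_noise)
    data.frame(respondent_id = r, criterion_id = crit,
               rating = as.integer(round(pmin(pmax(latent, 1), 5))),
               stringsAsFactors = FALSE)
  })
  ratings <- do.call(rbind, rrows)

  panel <- as_panel(instrument, judgments, ratings)
  truth_tab <- compute_global_weights(config$true_weights$dims,
                                      config$true_weights$crit, tol = 1e-9)
  attr(panel, "truth") <- list(
    weights = config$true_weights,
    performance = mu,
    global_weights = setNames(truth_tab$global_weight, truth_tab$criterion),
    config = config)
  panel
}

#' Generate a panel and write it to disk
#'
#' Writes `judgments.csv` and `ratings.csv` (the [load_panel()] schemas)
#' plus `truth.json` holding the ground-truth weights, item means and
#' generator settings, for use by test harnesses.
#'
#' @param config a `generator_config`.
#' @param dir output directory (created if needed).
#' @return the generated `respondent_panel`, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  panel <- generate_panel(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(panel, dir)
  truth <- attr(panel, "truth")
  jsonlite::write_json(
    list(true_dim_weights = as.list(truth$weights$dims),
         true_local_weights = lapply(truth$weights$crit, as.list),
         true_global_weights = as.list(truth$global_weights),
         true_performance = as.list(truth$performance),
         judgment_noise = config$judgment_noise,
         rating_noise = config$rating_noise,
         n = config$n, seed = config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(panel)
}
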