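#' Mean Likert performance per criterion
#'
#' Performance of a criterion is the arithmetic mean of the respondents'
#' 1-5 ratings.  Negatively worded items are averaged as-is by default;
#' `reverse_code = TRUE` recodes flagged items as 6 - x before averaging,
#' so that higher always means more satisfied.
#'
#' @param panel a `respondent_panel`.
#' @param reverse_code recode reverse-worded items before averaging?
#' @return named numeric vector of means in \[1, 5\], in instrument order.
#' @export
mean_performance <- function(panel, reverse_code = FALSE) {
  stopifnot(inherits(panel, "respondent_panel"))
  ratings <- panel$ratings
  if (reverse_code) {
    flip <- ratings$criterion_id %in% reverse_worded_ids(panel$instrument)
    ratings$rating[flip] <- 6 - ratings$rating[flip]
  }
  crit <- criterion_ids(panel$instrument)
  means <- tapply(ratings$rating, ratings$criterion_id, mean)
  setNames(as.numeric(means[crit]), crit)
}

#' Quadrant thresholds for importance-performance analysis
#'
#' The two axis thresholds that split the importance-performance plane
#' into quadrants:
#' * `grand_mean` (default): mean of each axis across criteria;
#' * `median`: median of each axis;
#' * `scale_midpoint`: performance threshold 3 (midpoint of the 1-5 Likert
#'   scale) and importance threshold 1/m for m criteria (the uniform
#'   global weight);
#' * `fixed`: user-supplied values via `tau_importance` / `tau_performance`.
#'
#' @param importance numeric vector of global weights.
#' @param performance numeric vector of mean Likert scores, same length.
#' @param strategy threshold strategy (see above).
#' @param tau_importance,tau_performance fixed threshold values (required
#'   for, and only used by, `strategy = "fixed"`).
#' @return An `ipa_thresholds` list: `strategy`, `tau_importance`,
#'   `tau_performance`.
#' @export
compute_thresholds <- function(importance, performance,
                               strategy = c("grand_mean", "median",
                                            "scale_midpoint", "fixed"),
                               tau_importance = NULL, tau_performance = NULL) {
  strategy <- match.arg(strategy)
  check_numeric(importance, "importance")
  check_numeric(performance, "performance")
  if (!length(importance) || length(importance) != length(performance)) {
    stop_input("importance and performance must be non-empty and equal length")
  }
  th <- switch(strategy,
    grand_mean = list(ti = mean(importance), tp = mean(performance)),
    median = list(ti = median(importance), tp = median(performance)),
    scale_midpoint = list(ti = 1 / length(importance), tp = 3),
    fixed = {
      if (is.null(tau_importance) || is.null(tau_performance)) {
        stop_input("strategy 'fixed' requires both tau_importance and tau_performance")
      }
      list(ti = tau_importance, tp = tau_performance)
    })
  if (th$ti <= 0) stop_input("importance threshold must be positive")
  structure(list(strategy = strategy, tau_importance = th$ti,
                 tau_performance = th$tp),
            class = "ipa_thresholds")
}

#' Classify criteria into importance-performance quadrants
#'
#' "High" on an axis means value >= threshold.  Quadrants follow the
#' keep-up / overkill / low-priority / concentrate layout:
#' * I  "keep up the good work": high importance, high performance;
#' * II "possible overkill": low importance, high performance;
#' * III "low priority": low importance, low performance;
#' * IV "concentrate here": high importance, low performance.
#'
#' @param importance named numeric vector of global weights (names =
#'   criterion ids).
#' @param performance numeric vector of mean Likert scores, same length
#'   and order.
#' @param thresholds an `ipa_thresholds` object (see
#'   [compute_thresholds()]).
#' @return An `ipa_result` data frame with columns `criterion`,
#'   `importance`, `performance`, `quadrant` (factor I/II/III/IV), and the
#'   thresholds stored in attribute `"thresholds"`.
#' @export
classify_quadrants <- function(importance, performance, thresholds) {
  stopifnot(inherits(thresholds, "ipa_thresholds"))
  check_numeric(importance, "importance")
  check_numeric(performance, "performance")
  if (length(importance) != length(performance)) {
    stop_input("importance and performance must be equal length")
  }
  hi_i <- importance >= thresholds$tau_importance
  hi_p <- performance >= thresholds$tau_performance
  quadrant <- ifelse(hi_i, ifelse(hi_p, "I", "IV"), ifelse(hi_p, "II", "III"))
  res <- data.frame(
    criterion = names(importance) %||% as.character(seq_along(importance)),
    importance = unname(importance),
    performance = unname(performance),
    quadrant = factor(quadrant, levels = c("I", "II", "III", "IV")),
    stringsAsFactors = FALSE)
  attr(res, "thresholds") <- thresholds
  class(res) <- c("ipa_result", "data.frame")
  res
}

#' Quadrant scatter of an IPA result
#'
#' Importance (x) against performance (y) with the threshold cross-hairs;
#' points labelled by criterion id.
#'
#' @param x an `ipa_result`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ipa_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  plot(x$importance, x$performance, pch = 19,
       xlab = "Importance (global weight)", ylab = "Performance (mean rating)",
       ...)
  graphics::abline(v = th$tau_importance, h = th$tau_performance, lty = 2)
  graphics::text(x$importance, x$performance, labels = x$criterion,
                 pos = 3, cex = 0.7)
  invisible(x)
}
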