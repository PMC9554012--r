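#' Pipeline configuration
#'
#' Bundles the tunable choices of [run_pipeline()].
#'
#' @param threshold_strategy IPA threshold strategy, see
#'   [compute_thresholds()].
#' @param tau_importance,tau_performance fixed thresholds (only for
#'   `threshold_strategy = "fixed"`).
#' @param reverse_code recode reverse-worded items (6 - x) before
#'   computing performance means?  Default `FALSE`: raw means.
#' @param confidence_target weight set for the confidence statistic
#'   (`"global"` or `"dimensions"`).
#' @param confidence_drop `"last"` or `"all"`, see [confidence_level()].
#' @param confidence_threshold pass threshold for the confidence level, in
#'   percent.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_strategy = "grand_mean",
                            tau_importance = NULL, tau_performance = NULL,
                            reverse_code = FALSE,
                            confidence_target = "global",
                            confidence_drop = "last",
                            confidence_threshold = 5) {
  structure(list(threshold_strategy = threshold_strategy,
                 tau_importance = tau_importance,
                 tau_performance = tau_performance,
                 reverse_code = isTRUE(reverse_code),
                 confidence_target = confidence_target,
                 confidence_drop = confidence_drop,
                 confidence_threshold = confidence_threshold),
            class = "pipeline_config")
}

#' Run the full weighting and importance-performance pipeline
#'
#' Executes, in order: per-respondent weight elicitation
#' ([elicit_weights()]), arithmetic-mean aggregation across respondents,
#' hierarchical global-weight composition with ranks
#' ([compute_global_weights()]), mean Likert performance
#' ([mean_performance()]), IPA thresholding and quadrant classification
#' ([classify_quadrants()]), and — when the panel has at least two
#' respondents — the leave-one-out confidence level
#' ([confidence_level()]).  No respondent is ever dropped silently;
#' validation failures upstream abort the run.
#'
#' @param panel a `respondent_panel`.
#' @param config a `pipeline_config`.
#' @param out_dir optional directory; when given, `weights.tsv` and
#'   `ipa.tsv` are written there via [write_weight_table()] and
#'   [write_ipa_table()].
#' @param verbose log panel size, group sizes, rescale shifts and
#'   thresholds to the console?
#' @return An `mcdm_result` list: `weights` (a `weight_table`), `ipa` (an
#'   `ipa_result`), `confidence` (a `confidence_stat`, or `NULL` for a
#'   single-respondent panel), `config`.
#' @export
run_pipeline <- function(panel, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(panel, "respondent_panel"),
            inherits(config, "pipeline_config"))
  instrument <- panel$instrument
  say <- function(...) if (verbose) message(...)
  say("pipeline: n = ", panel$n, " respondents, groups k = ",
      paste(vapply(group_ids(instrument),
                   function(g) length(group_members(instrument, g)), 0L),
            collapse = "/"))

  ew <- elicit_weights(panel)
  dim_w <- aggregate_expert_weights(ew$dims)
  crit_w <- lapply(ew$crit, aggregate_expert_weights)
  weights <- compute_global_weights(dim_w, crit_w, tol = 1e-9)

  performance <- mean_performance(panel, reverse_code = config$reverse_code)
  importance <- setNames(weights$global_weight, weights$criterion)[names(performance)]
  thresholds <- compute_thresholds(importance, performance,
                                   strategy = config$threshold_strategy,
                                   tau_importance = config$tau_importance,
                                   tau_performance = config$tau_performance)
  say("pipeline: thresholds tau_importance = ",
      signif(thresholds$tau_importance, 6), ", tau_performance = ",
      signif(thresholds$tau_performance, 6),
      " (", thresholds$strategy, ")")
  ipa <- classify_quadrants(importance, performance, thresholds)

  confidence <- NULL
  if (panel$n >= 2L) {
    confidence <- confidence_level(panel, target = config$confidence_target,
                                   drop = config$confidence_drop,
                                   threshold = config$confidence_threshold)
    say(sprintf("pipeline: confidence level %.4g%% (threshold %g%%)",
                confidence$value, confidence$threshold))
  } else {
    say("pipeline: single respondent, confidence level skipped")
  }

  res <- structure(list(weights = weights, ipa = ipa, confidence = confidence,
                        config = config),
                   class = "mcdm_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_weight_table(weights, file.path(out_dir, "weights.tsv"),
                       confidence = confidence)
    write_ipa_table(ipa, file.path(out_dir, "ipa.tsv"))
  }
  res
}

#' Write a weight table as TSV
#'
#' Columns `dimension, dim_weight, dim_rank, criterion, crit_weight,
#' crit_rank, global_weight, global_rank`; weights printed to 4 decimals
#' (round half up).  When a confidence statistic is supplied it is
#' appended as a `#`-prefixed footer line.
#'
#' @param table a `weight_table`.
#' @param path output path.
#' @param confidence optional `confidence_stat` to append as a footer.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(table, path, confidence = NULL) {
  stopifnot(inherits(table, "weight_table"))
  out <- table
  for (col in c("dim_weight", "crit_weight", "global_weight")) {
    out[[col]] <- fmt_dec(out[[col]], 4)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(confidence)) {
    cat(sprintf("# confidence_level\t%.4f\t%%\tthreshold\t%g\t%%\tpass\t%s\n",
                confidence$value, confidence$threshold, confidence$pass),
        file = path, append = TRUE)
  }
  invisible(path)
}

#' Write an IPA table as TSV
#'
#' Columns `criterion, importance, performance, quadrant`, values printed
#' to 4 decimals (round half up), quadrants as I/II/III/IV.
#'
#' @param result an `ipa_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ipa_table <- function(result, path) {
  stopifnot(inherits(result, "ipa_result"))
  out <- data.frame(criterion = result$criterion,
                    importance = fmt_dec(result$importance, 4),
                    performance = fmt_dec(result$performance, 4),
                    quadrant = as.character(result$quadrant),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.mcdm_result <- function(x, ...) {
  cat("<mcdm_result>\n")
  cat("Weights (top 5 by global rank):\n")
  w <- x$weights[order(x$weights$global_rank), ]
  print(utils::head(data.frame(criterion = w$criterion,
                               global_weight = round(w$global_weight, 4),
                               rank = w$global_rank), 5), row.names = FALSE)
  cat("Quadrant counts: ",
      paste(names(table(x$ipa$quadrant)), table(x$ipa$quadrant),
            sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$confidence)) print(x$confidence)
  invisible(x)
}
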