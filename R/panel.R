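#' Load a respondent panel from long-format CSV files
#'
#' A panel couples the pairwise-comparison judgments and the Likert ratings
#' of a set of respondents to one instrument.  Both files are long format,
#' one record per row.
#'
#' `judgments_path` columns: `respondent_id, group_id, left_id, right_id,
#' value, scale`.  `group_id` is `"DIMS"` for the chain over dimensions or a
#' dimension id for that dimension's criteria chain.  `(left_id, right_id)`
#' must be an adjacent pair in the group's instrument order.  `scale` is
#' `"fuzzy"` (value in \[0, 1\], 0.5 = indifference) or `"saaty"` (ratio in
#' \[1/9, 9\], 1 = indifference); Saaty ratios are converted on load via
#' [ratio_to_fuzzy()].
#'
#' `ratings_path` columns: `respondent_id, criterion_id, rating` with rating
#' an integer in 1..5.
#'
#' Validation is strict and performs no imputation: every respondent must
#' supply exactly k-1 judgments per group of size k and exactly one rating
#' per criterion; violations are reported with the respondent and field.
#'
#' @param instrument an `instrument`.
#' @param judgments_path,ratings_path CSV file paths.
#' @return An object of class `respondent_panel`: list with `instrument`,
#'   `n`, `respondents`, `judgments` (data frame, with an added
#'   `fuzzy_value` column on the \[0, 1\] scale), `ratings` (data frame).
#' @export
load_panel <- function(instrument, judgments_path, ratings_path) {
  for (p in c(judgments_path, ratings_path)) {
    if (!file.exists(p)) stop_input("panel file not found: ", p)
  }
  judgments <- read.csv(judgments_path, stringsAsFactors = FALSE)
  ratings <- read.csv(ratings_path, stringsAsFactors = FALSE)
  as_panel(instrument, judgments, ratings)
}

#' Assemble and validate a respondent panel from data frames
#'
#' @param instrument an `instrument`.
#' @param judgments data frame with columns `respondent_id, group_id,
#'   left_id, right_id, value, scale`.
#' @param ratings data frame with columns `respondent_id, criterion_id,
#'   rating`.
#' @return validated `respondent_panel` (see [load_panel()]).
#' @export
as_panel <- function(instrument, judgments, ratings) {
  stopifnot(inherits(instrument, "instrument"))
  need_j <- c("respondent_id", "group_id", "left_id", "right_id", "value", "scale")
  need_r <- c("respondent_id", "criterion_id", "rating")
  if (!all(need_j %in% names(judgments))) {
    stop_input("judgments: missing column(s): ",
               paste(setdiff(need_j, names(judgments)), collapse = ", "))
  }
  if (!all(need_r %in% names(ratings))) {
    stop_input("ratings: missing column(s): ",
               paste(setdiff(need_r, names(ratings)), collapse = ", "))
  }
  judgments$respondent_id <- as.character(judgments$respondent_id)
  ratings$respondent_id <- as.character(ratings$respondent_id)

  respondents <- unique(c(judgments$respondent_id, ratings$respondent_id))
  if (length(respondents) == 0L) stop_input("panel: no respondents found")
  groups_needing_judgments <- Filter(
    function(g) length(group_members(instrument, g)) > 1L,
    group_ids(instrument))
  if (length(groups_needing_judgments) &&
      !setequal(unique(judgments$respondent_id), unique(ratings$respondent_id))) {
    stop_input("panel: respondent ids differ between judgments and ratings: ",
               paste(union(setdiff(judgments$respondent_id, ratings$respondent_id),
                           setdiff(ratings$respondent_id, judgments$respondent_id)),
                     collapse = ", "))
  }

  ## --- judgments ---
  groups <- group_ids(instrument)
  bad_grp <- setdiff(unique(judgments$group_id), groups)
  if (length(bad_grp)) stop_input("judgments: unknown group_id: ",
                                  paste(bad_grp, collapse = ", "))
  if (!all(judgments$scale %in% c("fuzzy", "saaty"))) {
    stop_input("judgments: scale must be 'fuzzy' or 'saaty'")
  }
  check_numeric(judgments$value, "judgments: value")
  fz <- judgments$scale == "fuzzy"
  if (any(fz & (judgments$value < 0 | judgments$value > 1))) {
    bad <- judgments[fz & (judgments$value < 0 | judgments$value > 1), ][1, ]
    stop_input("judgments: fuzzy value out of [0,1] for respondent ",
               bad$respondent_id, ", pair (", bad$left_id, ", ", bad$right_id, ")")
  }
  if (any(!fz & (judgments$value < 1 / 9 - 1e-12 | judgments$value > 9 + 1e-12))) {
    bad <- judgments[!fz & (judgments$value < 1 / 9 - 1e-12 | judgments$value > 9 + 1e-12), ][1, ]
    stop_input("judgments: saaty value out of [1/9,9] for respondent ",
               bad$respondent_id, ", pair (", bad$left_id, ", ", bad$right_id, ")")
  }
  judgments$fuzzy_value <- ifelse(fz, judgments$value,
                                  ratio_to_fuzzy(pmin(pmax(judgments$value, 1 / 9), 9)))

  # adjacency and per-respondent completeness, group by group
  member_list <- lapply(groups, function(g) group_members(instrument, g))
  names(member_list) <- groups
  for (g in groups) {
    members <- member_list[[g]]
    k <- length(members)
    jg <- judgments[judgments$group_id == g, ]
    if (k <= 1L) {
      if (nrow(jg)) stop_input("judgments: group '", g,
                               "' has a single member and takes no judgments")
      next
    }
    li <- match(jg$left_id, members)
    ri <- match(jg$right_id, members)
    bad <- which(is.na(li) | is.na(ri) | ri != li + 1L)
    if (length(bad)) {
      b <- jg[bad[1], ]
      stop_input("judgments: non-adjacent pair (", b$left_id, ", ", b$right_id,
                 ") in group '", g, "' for respondent ", b$respondent_id,
                 " (expected consecutive ids in instrument order)")
    }
    for (r in respondents) {
      pos <- sort(li[jg$respondent_id == r])
      if (!identical(pos, seq_len(k - 1L))) {
        missing <- setdiff(seq_len(k - 1L), pos)
        if (length(missing)) {
          stop_input("judgments: respondent ", r, " is missing pair (",
                     members[missing[1]], ", ", members[missing[1] + 1L],
                     ") in group '", g, "'")
        }
        stop_input("judgments: respondent ", r, " has duplicate pairs in group '", g, "'")
      }
    }
  }

  ## --- ratings ---
  crit <- criterion_ids(instrument)
  bad_cr <- setdiff(unique(ratings$criterion_id), crit)
  if (length(bad_cr)) stop_input("ratings: unknown criterion_id: ",
                                 paste(bad_cr, collapse = ", "))
  if (!is.numeric(ratings$rating) || anyNA(ratings$rating) ||
      any(ratings$rating != as.integer(ratings$rating)) ||
      any(ratings$rating < 1 | ratings$rating > 5)) {
    stop_input("ratings: rating must be an integer in 1..5")
  }
  for (r in respondents) {
    have <- ratings$criterion_id[ratings$respondent_id == r]
    missing <- setdiff(crit, have)
    if (length(missing)) {
      stop_input("ratings: respondent ", r, " is missing rating(s) for: ",
                 paste(missing, collapse = ", "))
    }
    if (anyDuplicated(have)) {
      stop_input("ratings: respondent ", r, " has duplicate rating(s) for: ",
                 paste(unique(have[duplicated(have)]), collapse = ", "))
    }
  }

  structure(list(instrument = instrument, n = length(respondents),
                 respondents = respondents, judgments = judgments,
                 ratings = ratings),
            class = "respondent_panel")
}

#' Write a panel back to long-format CSV files
#'
#' Emits `judgments.csv` and `ratings.csv` in the schemas read by
#' [load_panel()].
#'
#' @param panel a `respondent_panel`.
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "respondent_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, "judgments.csv")
  rp <- file.path(dir, "ratings.csv")
  jd <- panel$judgments[c("respondent_id", "group_id", "left_id", "right_id",
                          "value", "scale")]
  write.csv(jd, jp, row.names = FALSE, quote = FALSE)
  write.csv(panel$ratings[c("respondent_id", "criterion_id", "rating")],
            rp, row.names = FALSE, quote = FALSE)
  invisible(c(judgments = jp, ratings = rp))
}

#' @export
print.respondent_panel <- function(x, ...) {
  cat("<respondent_panel> ", x$n, " respondents on '", x$instrument$name, "'\n",
      sep = "")
  cat("  ", nrow(x$judgments), " judgments, ", nrow(x$ratings), " ratings\n",
      sep = "")
  invisible(x)
}
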