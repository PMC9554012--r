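# small instruments and panels built in code

toy_instrument <- function() {
  as_instrument(list(
    name = "toy",
    dimensions = list(
      list(id = "D1", label = "first", criteria = list(
        list(id = "D11", label = "a"),
        list(id = "D12", label = "b", reverse_worded = TRUE),
        list(id = "D13", label = "c"))),
      list(id = "D2", label = "second", criteria = list(
        list(id = "D21", label = "d"),
        list(id = "D22", label = "e"))))))
}

single_instrument <- function() {
  as_instrument(list(
    name = "single",
    dimensions = list(
      list(id = "S1", label = "only", criteria = list(
        list(id = "S11", label = "only item"))))))
}

# judgments data frame for one respondent from fuzzy chains named by group
judgment_rows <- function(instrument, respondent, chains) {
  rows <- lapply(names(chains), function(g) {
    ids <- if (identical(g, "DIMS")) dimension_ids(instrument)
           else criterion_ids(instrument, g)
    v <- chains[[g]]
    if (!length(v)) return(NULL)
    data.frame(respondent_id = respondent, group_id = g,
               left_id = ids[-length(ids)], right_id = ids[-1],
               value = v, scale = "fuzzy", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

rating_rows <- function(instrument, respondent, ratings) {
  crit <- criterion_ids(instrument)
  stopifnot(length(ratings) == length(crit))
  data.frame(respondent_id = respondent, criterion_id = crit,
             rating = as.integer(ratings), stringsAsFactors = FALSE)
}

# panel whose respondents all encode the given per-group weight targets
panel_from_weights <- function(instrument, weights, n = 2, ratings = NULL) {
  chains <- lapply(seq_along(weights), function(i) chain_from_weights(weights[[i]]))
  names(chains) <- names(weights)
  crit <- criterion_ids(instrument)
  if (is.null(ratings)) ratings <- rep(3L, length(crit))
  jd <- do.call(rbind, lapply(seq_len(n), function(i) {
    judgment_rows(instrument, sprintf("P%02d", i), chains)
  }))
  rt <- do.call(rbind, lapply(seq_len(n), function(i) {
    rating_rows(instrument, sprintf("P%02d", i), ratings)
  }))
  as_panel(instrument, jd, rt)
}

toy_weights <- function() {
  list(DIMS = c(D1 = 0.6, D2 = 0.4),
       D1 = c(D11 = 0.5, D12 = 0.3, D13 = 0.2),
       D2 = c(D21 = 0.7, D22 = 0.3))
}

random_chain <- function(k, lo = 0.3, hi = 0.7) runif(k - 1, lo, hi)
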