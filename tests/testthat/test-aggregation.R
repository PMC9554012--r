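test_that("arithmetic-mean aggregation behaves like a mean", {
  expect_equal(aggregate_expert_weights(matrix(c(0.3, 0.7), 1)), c(0.3, 0.7))
  expect_equal(aggregate_expert_weights(list(c(0.6, 0.4), c(0.4, 0.6))),
               c(0.5, 0.5))
  set.seed(5)
  m <- t(replicate(31, { x <- runif(4); x / sum(x) }))
  expect_equal(aggregate_expert_weights(m), colSums(m) / 31)  # brute-force mean
  expect_equal(sum(aggregate_expert_weights(m)), 1)
  expect_error(aggregate_expert_weights(list()), "no weight vectors")
  expect_error(aggregate_expert_weights(list(c(0.5, 0.5), c(1))), "unequal")
  expect_error(aggregate_expert_weights(matrix(c(0.5, 0.4), 1)), "sum to 1")
})

test_that("competition ranks are largest-first with ties sharing the best rank", {
  expect_equal(rank_weights(c(0.0662, 0.0134)), c(1L, 2L))
  expect_equal(rank_weights(c(0.3, 0.3, 0.4)), c(2L, 2L, 1L))
  expect_equal(rank_weights(c(1, 1, 1)), c(1L, 1L, 1L))
  expect_error(rank_weights(numeric(0)), "empty")
})

test_that("global weights are dimension x local products with hierarchical ranks", {
  tab <- compute_global_weights(
    c(A = 0.6, B = 0.4),
    list(A = c(A1 = 0.5, A2 = 0.5), B = c(B1 = 1)))
  expect_s3_class(tab, "weight_table")
  expect_equal(tab$global_weight, c(0.3, 0.3, 0.4))
  expect_equal(tab$global_rank, c(2L, 2L, 1L))
  expect_equal(sum(tab$global_weight), 1)

  # a single dimension of weight 1: globals equal locals
  tab1 <- compute_global_weights(c(A = 1), list(A = c(A1 = 0.7, A2 = 0.3)))
  expect_equal(tab1$global_weight, tab1$crit_weight)

  expect_error(compute_global_weights(c(A = 0.6, B = 0.4),
                                      list(B = c(B1 = 1), A = c(A1 = 1))),
               "disagree")
  expect_error(compute_global_weights(c(A = 0.9, B = 0.4),
                                      list(A = c(A1 = 1), B = c(B1 = 1)),
                                      tol = 1e-9),
               "sum to")
})

test_that("aggregation commutes with global composition when dimension weights are shared", {
  set.seed(9)
  dims <- c(A = 0.55, B = 0.45)
  locals <- replicate(6, list(A = {x <- runif(3); setNames(x / sum(x), c("A1", "A2", "A3"))},
                              B = {x <- runif(2); setNames(x / sum(x), c("B1", "B2"))}),
                      simplify = FALSE)
  # compose per respondent, then average the globals
  per <- sapply(locals, function(l) compute_global_weights(dims, l)$global_weight)
  # average the locals, then compose
  mean_loc <- list(A = rowMeans(sapply(locals, `[[`, "A")),
                   B = rowMeans(sapply(locals, `[[`, "B")))
  tab <- compute_global_weights(dims, mean_loc)
  expect_equal(tab$global_weight, rowMeans(per), tolerance = 1e-12)
})

test_that("confidence level is 0 for identical respondents and reads off a constructed 10% case", {
  inst <- toy_instrument()
  panel <- panel_from_weights(inst, toy_weights(), n = 4)
  cl <- confidence_level(panel)
  expect_s3_class(cl, "confidence_stat")
  expect_equal(cl$value, 0)
  expect_true(cl$pass)

  # two respondents engineered so dropping the 2nd shifts both dimension
  # weights by exactly 10% of the full-panel weight: CL = 10%
  inst2 <- as_instrument(list(name = "two", dimensions = list(
    list(id = "A", criteria = list(list(id = "A1"))),
    list(id = "B", criteria = list(list(id = "B1"))))))
  jd <- rbind(
    data.frame(respondent_id = "r1", group_id = "DIMS", left_id = "A",
               right_id = "B", value = chain_from_weights(c(0.55, 0.45)),
               scale = "fuzzy"),
    data.frame(respondent_id = "r2", group_id = "DIMS", left_id = "A",
               right_id = "B", value = chain_from_weights(c(0.45, 0.55)),
               scale = "fuzzy"))
  rt <- rbind(rating_rows(inst2, "r1", c(3, 3)), rating_rows(inst2, "r2", c(3, 3)))
  panel2 <- as_panel(inst2, jd, rt)
  cl2 <- confidence_level(panel2, target = "dimensions")
  expect_equal(cl2$value, 10, tolerance = 1e-9)

  expect_error(confidence_level(panel_from_weights(inst, toy_weights(), n = 1)),
               "at least 2")
})

test_that("confidence level matches a two-pass brute-force recomputation on a noisy panel", {
  inst <- toy_instrument()
  w <- toy_weights()
  cfg <- generator_config(inst,
                          true_weights = list(dims = w$DIMS, crit = w[c("D1", "D2")]),
                          true_performance = setNames(c(4, 3, 3.5, 2.5, 4.2),
                                                      criterion_ids(inst)),
                          judgment_noise = 0.05, n = 12, seed = 99)
  panel <- generate_panel(cfg)
  cl <- confidence_level(panel, drop = "last")
  expect_equal(cl$value, oracle_confidence(panel), tolerance = 1e-10)
})

test_that("all-leave-one-out variant reports mean and max over drops", {
  set.seed(3)
  cfg <- generator_config(judgment_noise = 0.05, n = 6, seed = 8)
  panel <- generate_panel(cfg)
  cl <- confidence_level(panel, drop = "all")
  expect_length(cl$per_drop, 6)
  expect_equal(cl$value, mean(cl$per_drop))
  expect_equal(cl$max_value, max(cl$per_drop))
  expect_gte(cl$max_value, cl$value)
})
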