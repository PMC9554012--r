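test_that("the consistent matrix inverts the row-sum weight rule exactly", {
  w <- c(0.4667, 0.3333, 0.2)
  w <- w / sum(w)
  m <- consistent_matrix_from_weights(w)
  expect_equal(weights_from_matrix(m), w, tolerance = 1e-14)
  expect_equal(unclass(m) + t(unclass(m)), matrix(1, 3, 3), ignore_attr = TRUE)
  # uniform weights give the indifference matrix
  expect_equal(unclass(consistent_matrix_from_weights(rep(0.25, 4))),
               matrix(0.5, 4, 4), ignore_attr = TRUE)
  # k = 2 example pairs with the cfpr side
  expect_equal(consistent_matrix_from_weights(c(0.625, 0.375))[1, 2], 0.75)
  # spread violation is rejected with advice, not rescaled
  expect_error(consistent_matrix_from_weights(c(0.7, 0.2, 0.1)),
               "compress")
})

test_that("chains encode weights and round-trip through the elicitation path", {
  w3 <- c(0.4667, 0.3333, 0.2); w3 <- w3 / sum(w3)
  expect_equal(chain_from_weights(w3), c(0.7, 0.7), tolerance = 2e-4)
  expect_equal(chain_from_weights(rep(1 / 5, 5)), rep(0.5, 4))
  expect_equal(chain_from_weights(1), numeric(0))
  set.seed(53)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    w <- compress_weights({ x <- runif(k); x / sum(x) })
    expect_equal(chain_weights(chain_from_weights(w), k), unname(w),
                 tolerance = 1e-12)
  }
})

test_that("compress_weights enforces the spread constraint and preserves order and sum", {
  w <- c(0.0935, 0.2021, 0.3253, 0.3791)
  w <- w / sum(w)
  expect_error(consistent_matrix_from_weights(w), "compress")
  cw <- compress_weights(w)
  expect_equal(sum(cw), 1)
  expect_equal(order(cw), order(w))
  expect_s3_class(consistent_matrix_from_weights(cw), "cfpr_matrix")
  # feasible vectors pass through untouched
  feasible <- c(0.3, 0.4, 0.3)
  expect_identical(compress_weights(feasible), feasible)
})

test_that("generation is reproducible: same seed gives byte-identical CSVs", {
  cfg <- generator_config(n = 5, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  for (f in c("judgments.csv", "ratings.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the panel
  simulate_to_dir(generator_config(n = 5, seed = 124), d2)
  expect_false(identical(readLines(file.path(d1, "judgments.csv")),
                         readLines(file.path(d2, "judgments.csv"))))
})

test_that("generated panels always pass interface validation and reload cleanly", {
  set.seed(61)
  for (s in c(0, 0.05, 0.2)) {
    cfg <- generator_config(n = 4, judgment_noise = s, seed = 100 + s * 100)
    panel <- generate_panel(cfg)   # as_panel() validation runs inside
    expect_s3_class(panel, "respondent_panel")
    dir <- withr::local_tempdir()
    write_panel(panel, dir)
    reloaded <- load_panel(cfg$instrument, file.path(dir, "judgments.csv"),
                           file.path(dir, "ratings.csv"))
    expect_equal(reloaded$n, 4)
    expect_equal(reloaded$judgments$fuzzy_value, panel$judgments$fuzzy_value,
                 tolerance = 1e-12)
  }
})

test_that("a noiseless panel recovers every true weight vector exactly and ratings are rounded means", {
  cfg <- generator_config(judgment_noise = 0, rating_noise = 0, n = 3, seed = 2)
  panel <- generate_panel(cfg)
  truth <- attr(panel, "truth")
  ew <- elicit_weights(panel)
  for (i in seq_len(3)) {
    expect_equal(unname(ew$dims[i, ]), unname(truth$weights$dims),
                 tolerance = 1e-12)
    for (d in names(truth$weights$crit)) {
      expect_equal(unname(ew$crit[[d]][i, ]), unname(truth$weights$crit[[d]]),
                   tolerance = 1e-12)
    }
  }
  # with zero rating noise each rating equals the rounded true mean
  perf <- mean_performance(panel)
  expect_equal(unname(perf), unname(round(truth$performance)))
})

test_that("generator config rejects invalid study conditions", {
  inst <- toy_instrument()
  w <- toy_weights()
  tw <- list(dims = w$DIMS, crit = w[c("D1", "D2")])
  expect_error(generator_config(inst, true_weights = tw,
                                true_performance = setNames(c(6, 3, 3, 3, 3),
                                                            criterion_ids(inst))),
               "\\[1, 5\\]")
  expect_error(generator_config(inst, true_weights = tw, judgment_noise = -1),
               ">= 0")
  expect_error(generator_config(inst, true_weights = tw, n = 0), "n must be")
  bad <- tw; bad$dims <- c(D1 = 0.95, D2 = 0.05)
  expect_error(generator_config(inst, true_weights = bad), "compress")
})
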