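test_that("oversplit features with close m/z and RT are merged with summed abundance", {
  ab <- matrix(c(10, 20,
                 1,  2), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("S1", "S2")))
  q <- make_quant(ab, mz = c(301.1412, 301.1415), rt = c(3.50, 3.52))
  res <- repetitive_mz_filter(q, mz_tol = 0.01, rt_tol = 0.1,
                              max_occurrences = 8)
  expect_equal(nrow(res$quant$abundance), 1)
  expect_equal(unname(res$quant$abundance[1, ]), c(11, 22))
  expect_equal(res$report$n_removed_repetitive, 1)
})

test_that("features without a near-m/z partner pass through unchanged", {
  ab <- matrix(c(5, 6, 7, 8), 2, 2, dimnames = list(NULL, c("S1", "S2")))
  q <- make_quant(ab, mz = c(200.0, 355.5), rt = c(1.0, 5.0))
  res <- repetitive_mz_filter(q)
  expect_equal(res$quant$abundance, q$abundance)
  expect_equal(res$report$n_removed_repetitive, 0)
})

test_that("planted background ladders are removed exactly", {
  cfg <- synth_config(n_extracts = 15, n_scaffolds = 30,
                      n_background_ladders = 5, ladder_length = 12, seed = 6)
  g <- synth_generate(cfg, dir = withr::local_tempdir())
  q <- read_quant_table(g$paths$quant)
  res <- repetitive_mz_filter(q, max_occurrences = 8)
  removed <- setdiff(q$features$feature_id, res$quant$features$feature_id)
  expect_setequal(removed, g$truth$ladder_ids)
})

test_that("fivefold blank removal: threshold, boundary and zero-blank cases", {
  ab <- matrix(c(10, 55, 65,    # sample mean 60 >= 5*10: retained
                 10, 35, 45,    # sample mean 40 <  5*10: removed
                 0,  1,  1,     # absent from blanks: always retained
                 10, 45, 55),   # sample mean 50 == 5*10: retained (>=)
               4, 3, byrow = TRUE,
               dimnames = list(NULL, c("BlankA", "S1", "S2")))
  q <- make_quant(ab, blanks = "BlankA")
  res <- blank_filter(q, fold = 5)
  expect_equal(res$quant$features$feature_id, c(1L, 3L, 4L))
  expect_equal(res$report$n_removed_blank, 1)
  expect_error(blank_filter(make_quant(ab[, 2:3])), class = "sp_config_error")
})

test_that("TIC normalization rescales each sample column to unit total", {
  ab <- matrix(c(2, 4,
                 3, 6,
                 5, 10), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("S1", "S2")))
  q <- make_quant(ab)
  norm <- tic_normalize(q)
  expect_equal(unname(norm$abundance[, "S1"]), c(0.2, 0.3, 0.5))
  expect_true(all(abs(colSums(norm$abundance) - 1) < 1e-12))

  set.seed(11)
  big <- matrix(rlnorm(200), 20, 10, dimnames = list(NULL, sprintf("S%02d", 1:10)))
  nb <- tic_normalize(make_quant(big))
  expect_true(all(abs(colSums(nb$abundance) - 1) < 1e-12))
  # normalization preserves within-extract feature ranking
  for (j in 1:10)
    expect_equal(order(nb$abundance[, j]), order(big[, j]))

  zero <- make_quant(matrix(0, 2, 2, dimnames = list(NULL, c("S1", "S2"))))
  expect_error(tic_normalize(zero), "S1")
})

test_that("presence filter uses an inclusive boundary on sample columns", {
  ab <- matrix(0, 3, 10, dimnames = list(NULL, sprintf("S%02d", 1:10)))
  ab[1, 1:2] <- 1   # present in 2: removed at min 3
  ab[2, 1:3] <- 1   # present in 3: retained (boundary inclusive)
  ab[3, ] <- 1
  q <- make_quant(ab)
  res <- presence_filter(q, min_extracts = 3)
  expect_equal(res$quant$features$feature_id, c(2L, 3L))
  expect_equal(res$report$n_removed_presence, 1)
  # min_extracts = 1 is the identity when no feature is all-zero
  res1 <- presence_filter(q, min_extracts = 1)
  expect_equal(res1$quant$abundance, q$abundance)
})

test_that("blank and presence filters are idempotent", {
  set.seed(21)
  ab <- matrix(rlnorm(60) * rbinom(60, 1, 0.6), 6, 10,
               dimnames = list(NULL, c("Blank1", sprintf("S%02d", 1:9))))
  q <- make_quant(ab, blanks = "Blank1")
  b1 <- blank_filter(q)
  b2 <- blank_filter(b1$quant)
  expect_equal(b2$quant$abundance, b1$quant$abundance)
  expect_equal(b2$report$n_removed_blank, 0)
  p1 <- presence_filter(b1$quant)
  p2 <- presence_filter(p1$quant)
  expect_equal(p2$quant$abundance, p1$quant$abundance)
  expect_equal(p2$report$n_removed_presence, 0)
})

test_that("pipeline filter report reconciles exactly", {
  g <- synth_generate(synth_config(n_extracts = 25, n_scaffolds = 60, seed = 14),
                      dir = withr::local_tempdir())
  q <- read_quant_table(g$paths$quant)
  res <- quant_pipeline(q)
  r <- res$report
  expect_equal(r$n_input_features, nrow(q$abundance))
  expect_equal(r$n_input_features,
               r$n_removed_repetitive + r$n_removed_blank +
                 r$n_removed_presence + r$n_retained)
  expect_equal(r$n_retained, nrow(res$quant$abundance))
  expect_true(all(abs(colSums(res$quant$abundance) - 1) < 1e-12))
})
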