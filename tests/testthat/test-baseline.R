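test_that("identical extracts reach full coverage at the first pick", {
  m <- make_membership(list(A = 1:5, B = 1:5, C = 1:5))
  rb <- random_coverage(m, n_iter = 25, seed = 9, thresholds = 1.0)
  expect_true(all(rb$coverage$mean == 1))
  expect_equal(unname(rb$mean_extracts_to_fraction), 1)
})

test_that("mean extracts-to-full-coverage matches exhaustive permutation enumeration", {
  sets <- list(A = 1:3, B = 2:3, C = 4L)
  m <- make_membership(sets)
  # enumerate all 3! equally likely draw orders; coverage completes at the
  # first position where both A and C have appeared
  P <- all_perms(3)
  ids <- names(sets)
  first_complete <- apply(P, 1, function(idx) {
    covered <- integer(0)
    for (k in seq_along(idx)) {
      covered <- union(covered, sets[[ids[idx[k]]]])
      if (length(covered) == 4) return(k)
    }
  })
  analytic <- mean(first_complete)  # = 8/3
  expect_equal(analytic, 8 / 3)

  rb <- random_coverage(m, n_iter = 4000, seed = 5, thresholds = 1.0)
  emp <- rb$extracts_to_fraction[, "1"]
  se <- stats::sd(emp) / sqrt(length(emp))
  expect_lt(abs(mean(emp) - analytic), 3 * se)
})

test_that("Monte-Carlo mean coverage matches the hypergeometric closed form", {
  set.seed(77)
  sets <- random_instance(20, 40)
  m <- make_membership(sets)
  rb <- random_coverage(m, n_iter = 2000, seed = 13, thresholds = 1.0,
                        keep_iterations = TRUE)
  expected <- hypergeom_coverage(sets, k = seq_along(sets))
  # also cross-check the package's own closed form against the helper's
  expect_equal(expected_random_coverage(m), expected, tolerance = 1e-12)
  for (k in c(1, 3, 7, 12)) {
    se <- stats::sd(rb$iterations[, k]) / sqrt(rb$n_iter)
    expect_lt(abs(rb$coverage$mean[k] - expected[k]), 3 * se + 1e-9)
  }
  expect_equal(rb$coverage$mean[20], expected[20])  # both exactly 1 at k = n
})

test_that("random baselines are reproducible from the seed and monotone", {
  set.seed(3)
  m <- make_membership(random_instance(12, 30))
  a <- random_coverage(m, n_iter = 200, seed = 21)
  b <- random_coverage(m, n_iter = 200, seed = 21)
  expect_identical(a, b)
  expect_true(all(diff(a$coverage$mean) >= 0))
  expect_equal(a$coverage$mean[12], 1)  # all extracts = full coverage
})

test_that("greedy dominates the mean random curve on redundant libraries", {
  g <- synth_generate(synth_config(n_extracts = 60, n_scaffolds = 120, seed = 8))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(g$tables$node, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- build_membership(read_node_table(f))
  cv <- diversity_curve(m)
  rb <- random_coverage(m, n_iter = 300, seed = 2)
  expect_true(all(cv$fraction >= rb$coverage$mean[seq_len(nrow(cv))] - 1e-12))
})

test_that("hit-rate quartiles: degenerate and hypergeometric-calibrated cases", {
  ids <- sprintf("E%03d", 1:100)
  all_hits <- make_activity(ids, hit = TRUE)
  q <- random_hit_rate_quartiles(all_hits, ids, 10, n_iter = 50, seed = 1)
  expect_equal(c(q$lower_quartile, q$upper_quartile), c(100, 100))
  no_hits <- make_activity(ids, hit = FALSE)
  q0 <- random_hit_rate_quartiles(no_hits, ids, 10, n_iter = 50, seed = 1)
  expect_equal(c(q0$lower_quartile, q0$upper_quartile), c(0, 0))
  expect_error(random_hit_rate_quartiles(all_hits, ids, 200, 10, 1),
               class = "sp_arg_error")

  # population mimicking the evaluation library: 1,439 extracts, 11.26% hits
  n_pop <- 1439; n_hit <- 162
  ids <- sprintf("E%04d", seq_len(n_pop))
  act <- make_activity(ids, hit = rep(c(TRUE, FALSE), c(n_hit, n_pop - n_hit)))
  qq <- random_hit_rate_quartiles(act, ids, subset_size = 50,
                                  n_iter = 1000, seed = 4)
  lo_exact <- 100 * stats::qhyper(0.25, n_hit, n_pop - n_hit, 50) / 50
  hi_exact <- 100 * stats::qhyper(0.75, n_hit, n_pop - n_hit, 50) / 50
  expect_lt(abs(qq$lower_quartile - lo_exact), 2.01)  # within one extract
  expect_lt(abs(qq$upper_quartile - hi_exact), 2.01)
  expect_lte(qq$lower_quartile, qq$upper_quartile)
})
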