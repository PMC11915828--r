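test_that("perfect monotone and anti-monotone relationships give rho = +/-1", {
  ab <- matrix(1:5, 1, 5, dimnames = list(NULL, paste0("S", 1:5)))
  q <- make_quant(ab)
  act <- make_activity(paste0("S", 1:5), activity = c(10, 20, 30, 40, 50))
  res <- correlate_features(q, act)
  expect_equal(res$rho, 1.0)
  expect_equal(res$n_pairs, 5L)

  ab3 <- matrix(1:3, 1, 3, dimnames = list(NULL, paste0("S", 1:3)))
  act3 <- make_activity(paste0("S", 1:3), activity = c(3, 2, 1))
  expect_equal(correlate_features(make_quant(ab3), act3)$rho, -1.0)
})

test_that("fewer than three shared extracts is an error", {
  ab <- matrix(1:2, 1, 2, dimnames = list(NULL, c("S1", "S2")))
  act <- make_activity(c("S1", "S2", "S3"), activity = 1:3)
  expect_error(correlate_features(make_quant(ab), act), "3")
})

test_that("constant features get rho = NA and are excluded from the FDR family", {
  set.seed(31)
  ab <- rbind(matrix(rlnorm(30), 3, 10),
              rep(2, 10))  # constant abundance: correlation undefined
  colnames(ab) <- sprintf("S%02d", 1:10)
  q <- make_quant(ab)
  act <- make_activity(colnames(ab), activity = rnorm(10))
  res <- correlate_features(q, act)
  expect_true(is.na(res$rho[4]))
  expect_true(is.na(res$p_adj[4]))
  expect_false(res$significant[4])
  # BH family size is the 3 scored features, not 4
  expect_equal(res$p_adj[1:3], bh_manual(res$p_raw[1:3]))
})

test_that("Spearman rho and p match independent oracles on random vectors", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:7, 1)
    x <- rlnorm(n)
    y <- rnorm(n)
    ab <- matrix(x, 1, n, dimnames = list(NULL, paste0("S", 1:n)))
    res <- correlate_features(make_quant(ab), make_activity(paste0("S", 1:n),
                                                            activity = y))
    expect_equal(res$rho, spearman_rho_oracle(x, y), tolerance = 1e-12)
    # the t-approximation tracks the exact permutation null at these n
    expect_lt(abs(res$p_raw - spearman_p_exact(x, y)), 0.09)
  }
  # at larger n the p value must agree with the standard t-based test
  n <- 30
  x <- rlnorm(n); y <- rnorm(n)
  ab <- matrix(x, 1, n, dimnames = list(NULL, sprintf("S%02d", 1:n)))
  res <- correlate_features(make_quant(ab),
                            make_activity(sprintf("S%02d", 1:n), activity = y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  tt <- res$rho * sqrt((n - 2) / (1 - res$rho^2))
  expect_equal(res$p_raw, 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(51)
  n <- 12
  x <- rlnorm(n); y <- rnorm(n)
  ids <- sprintf("S%02d", 1:n)
  rho0 <- correlate_features(make_quant(matrix(x, 1, dimnames = list(NULL, ids))),
                             make_activity(ids, activity = y))$rho
  rho1 <- correlate_features(make_quant(matrix(log(x), 1,
                                               dimnames = list(NULL, ids))),
                             make_activity(ids, activity = exp(y)))$rho
  expect_equal(rho0, rho1, tolerance = 1e-12)
})

test_that("the Pearson path covers binary (point-biserial) activity", {
  set.seed(61)
  n <- 20
  hit <- rep(c(TRUE, FALSE), each = n / 2)
  x <- rnorm(n, mean = ifelse(hit, 5, 1))
  ids <- sprintf("S%02d", 1:n)
  q <- make_quant(matrix(x, 1, dimnames = list(NULL, ids)))
  res <- correlate_features(q, make_activity(ids, hit = hit),
                            method = "pearson")
  ref <- stats::cor.test(x, as.numeric(hit))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.03, 6)), rep(0.03, 6))
  set.seed(71)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_manual(p))
    # adjusted values are monotone in the raw values
    expect_true(all(diff(benjamini_hochberg(p)[order(p)]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), class = "sp_arg_error")
})

test_that("hit_rate arithmetic and error on missing calls", {
  ids <- sprintf("E%02d", 1:50)
  act <- make_activity(ids, hit = rep(c(TRUE, FALSE), c(11, 39)))
  expect_equal(hit_rate(ids, act), 22)
  expect_equal(hit_rate(ids[12:50], act), 0)
  expect_equal(hit_rate(ids[1:11], act), 100)
  expect_error(hit_rate(c(ids, "E99"), act), "E99")
})

test_that("retention scans abundance presence in selected extracts", {
  ab <- rbind(c(0, 0, 3, 0), c(1, 0, 0, 0), c(0, 2, 0, 4))
  colnames(ab) <- c("E1", "E2", "E7", "E9")
  q <- make_quant(ab)
  corr <- structure(data.frame(feature_id = 1:3, method = "spearman",
                               rho = c(0.9, 0.8, 0.1), p_raw = 0.001,
                               p_adj = 0.004, n_pairs = 4,
                               significant = c(TRUE, TRUE, FALSE)),
                    class = c("correlation_result", "data.frame"))
  ret <- retention(corr, q, list(small = c("E7"), big = c("E7", "E2")))
  expect_equal(ret$n_significant_full, 2)
  expect_equal(unname(ret$n_retained), c(1L, 1L))   # feature 2 only in E1
  expect_equal(ret$retained_ids$small, 1L)
  expect_error(retention(corr, q, list(bad = "E99")), "E99")
})

test_that("retention on synthetic data matches an independent matrix scan and is monotone", {
  g <- synth_generate(synth_config(n_extracts = 50, n_scaffolds = 100, seed = 19),
                      dir = withr::local_tempdir())
  mem <- build_membership(read_node_table(g$paths$node))
  act <- read_activity_table(g$paths$activity)
  qp <- quant_pipeline(read_quant_table(g$paths$quant))
  corr <- correlate_features(qp$quant, act)
  sels <- list("80%" = greedy_select(mem, 0.8),
               "95%" = greedy_select(mem, 0.95),
               "100%" = greedy_select(mem, 1.0))
  ret <- retention(corr, qp$quant, sels)
  # independent scan: loop feature by feature, extract by extract
  sig <- corr$feature_id[corr$significant]
  for (lib in names(sels)) {
    ids <- sels[[lib]]$extract_id
    manual <- sum(vapply(sig, function(fi) {
      any(vapply(ids, function(e)
        qp$quant$abundance[match(as.character(fi),
                                 rownames(qp$quant$abundance)), e] > 0,
        logical(1)))
    }, logical(1)))
    expect_equal(unname(ret$n_retained[lib]), manual)
  }
  # nested libraries retain monotonically
  expect_true(ret$n_retained["80%"] <= ret$n_retained["95%"])
  expect_true(ret$n_retained["95%"] <= ret$n_retained["100%"])
})
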