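test_that("a table with no column effect gives statistic 0 and p 1", {
  x <- matrix(rep(c(3, 1, 4), each = 4), 4)
  expect_warning(ft <- friedman_test(t(x)), "tied")
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)
})

test_that("the statistic matches independent references", {
  set.seed(51)
  # tie-free tables: closed-form oracle and stats::friedman.test
  for (i in 1:5) {
    x <- matrix(rnorm(6 * 4), 6)
    ft <- friedman_test(x)
    expect_equal(ft$statistic, friedman_stat_oracle(x), tolerance = 1e-12)
    expect_equal(ft$statistic, unname(stats::friedman.test(x)$statistic))
    expect_equal(ft$p.value, unname(stats::friedman.test(x)$p.value))
  }
  # tied tables: tie-corrected statistic still matches stats::friedman.test
  for (i in 1:5) {
    x <- matrix(sample(1:3, 18, TRUE), 6)
    expect_equal(suppressWarnings(friedman_test(x)$statistic),
                 unname(stats::friedman.test(x)$statistic))
  }
})

test_that("exact permutation p agrees with full enumeration", {
  set.seed(53)
  x <- matrix(rnorm(4 * 3), 4)  # (3!)^4 = 1296 orderings
  ft <- friedman_test(x, exact = TRUE)
  expect_equal(ft$p.exact, friedman_exact_oracle(x), tolerance = 1e-12)

  # dominant column: n = 6, k = 3 ((3!)^6 = 46656 orderings)
  x2 <- cbind(rnorm(6), rnorm(6), rnorm(6) + 10)
  ft2 <- friedman_test(x2, exact = TRUE)
  expect_equal(ft2$statistic, friedman_stat_oracle(x2))
  expect_equal(ft2$p.exact, friedman_exact_oracle(x2), tolerance = 1e-12)
  expect_error(friedman_test(matrix(rnorm(100 * 6), 100), exact = TRUE),
               "infeasible")
})

test_that("the test is invariant to column permutation and monotone maps", {
  set.seed(57)
  x <- matrix(rnorm(8 * 5), 8)
  base <- friedman_test(x)$statistic
  expect_equal(friedman_test(x[, c(4, 1, 5, 3, 2)])$statistic, base)
  expect_equal(friedman_test(t(apply(x, 1, function(v) exp(v))))$statistic,
               base)
})

test_that("input validation and missing-row handling", {
  expect_error(friedman_test(matrix(rnorm(4), 1)), "2 complete rows")
  expect_error(friedman_test(matrix(rnorm(8), 4)), "3 conditions")
  x <- matrix(rnorm(15), 5)
  x[2, 1] <- NA
  expect_warning(ft <- friedman_test(x), "dropped")
  expect_equal(ft$n, 4)
})

test_that("Dunn post hoc z, adjustment and stars behave as specified", {
  set.seed(61)
  x <- matrix(rnorm(22 * 6), 22)
  colnames(x) <- c("preS", paste0("S", 1:4), "postS")
  res <- dunn_posthoc(x)
  expect_equal(nrow(res), 15)
  expect_equal(res$p_adj, pmin(1, res$p * 15))           # factor = n pairs
  expect_true(all(res$p_adj >= res$p))
  # z formula on mean ranks
  ft <- friedman_test(x)
  se <- sqrt(6 * 7 / (6 * 22))
  expect_equal(res$z[1],
               unname(ft$mean_ranks["preS"] - ft$mean_ranks["S1"]) / se)

  # identical columns: z = 0, adjusted p = 1
  y <- cbind(a = 1:8 + rnorm(8), b = 0, c = rnorm(8))
  y[, "b"] <- y[, "a"]
  r2 <- suppressWarnings(dunn_posthoc(y, pairs = list(c("a", "b"))))
  expect_equal(r2$z, 0)
  expect_equal(r2$p_adj, 1)

  expect_error(dunn_posthoc(x, pairs = list(c("preS", "nope"))), "unknown")
})

test_that("a dominant column is significant against all others", {
  set.seed(63)
  # study-sized table: 22 seizures, six stage periods
  x <- matrix(rnorm(22 * 6), 22)
  colnames(x) <- c("preS", paste0("S", 1:4), "postS")
  x[, "S4"] <- x[, "S4"] + 50
  res <- dunn_posthoc(x)
  s4 <- grepl("S4", res$pair)
  expect_true(all(res$p_adj[s4] < 0.05))
  expect_true(all(res$stars[s4] != "ns"))

  # small-sample check against a within-row permutation null: the z-test
  # rejection of the dominant pair is reproduced by permutation
  n <- 8
  y <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n) + 50)
  obs <- dunn_posthoc(y, pairs = list(c("a", "c")))$z
  perm <- replicate(500, {
    yp <- t(apply(y, 1, sample))
    colnames(yp) <- colnames(y)
    dunn_posthoc(yp, pairs = list(c("a", "c")))$z
  })
  expect_lt(mean(abs(perm) >= abs(obs)), 0.05)
})

test_that("adjusted p is monotone in the number of pairs and Sidak is gentler", {
  set.seed(67)
  x <- matrix(rnorm(10 * 4), 10)
  colnames(x) <- letters[1:4]
  few <- dunn_posthoc(x, pairs = list(c("a", "b")))
  all6 <- dunn_posthoc(x)
  ab <- all6$pair == "a vs b"
  expect_gte(all6$p_adj[ab], few$p_adj)
  sid <- dunn_posthoc(x, p_adjust = "sidak")
  expect_true(all(sid$p_adj <= all6$p_adj + 1e-12))
})

test_that("Dunn z-based p is calibrated against permutation under the null", {
  set.seed(71)
  n <- 12; k <- 4
  reject <- replicate(400, {
    x <- matrix(rnorm(n * k), n)
    colnames(x) <- letters[1:k]
    r <- dunn_posthoc(x, pairs = list(c("a", "b")))
    r$p < 0.05
  })
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
})
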