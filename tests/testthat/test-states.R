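test_that("identical vectors merge first at zero cost", {
  x <- rbind(c(1, 2), c(1, 2), c(5, 9))
  link <- ward_linkage(x)
  expect_equal(link$height[1], 0)
  expect_equal(sort(link$merge[1, ]), c(-2, -1))
})

test_that("Ward merge costs are non-decreasing", {
  set.seed(17)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 3), 40)
    link <- ward_linkage(x)
    expect_false(is.unsorted(link$height))
  }
})

test_that("linkage matches the brute-force SSE-increase oracle", {
  set.seed(23)
  for (i in 1:4) {
    w <- sample(6:12, 1)
    x <- matrix(rnorm(w * 2), w)
    link <- ward_linkage(x)
    oracle <- ward_oracle(x)
    expect_identical(link$merge, oracle$merge)
    expect_equal(link$height, oracle$height, tolerance = 1e-9)
  }
  # and with exact ties from duplicated points
  x <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(10, 10))
  expect_identical(ward_linkage(x)$merge, ward_oracle(x)$merge)
})

test_that("linkage agrees with hclust ward.D2 up to the height convention", {
  set.seed(31)
  x <- matrix(rnorm(30 * 4), 30)
  link <- ward_linkage(x)
  hc <- hclust(dist(x), method = "ward.D2")
  # heights: hclust ward.D2 reports sqrt(2 * SSE increase)
  expect_equal(sqrt(2 * link$height), hc$height, tolerance = 1e-10)
  # identical partitions at every cut
  for (k in c(2, 3, 5, 10)) {
    expect_equal(adjusted_rand_index(cutree(as.hclust(link), k),
                                     cutree(hc, k)), 1)
  }
})

test_that("the distance-curve knee recovers planted cluster counts", {
  two <- make_blobs(rbind(c(0, 0), c(10, 10)))
  expect_equal(as.integer(select_k(ward_linkage(two$x))), 2L)

  five <- make_blobs(rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 20)))
  expect_equal(as.integer(select_k(ward_linkage(five$x))), 5L)
})

test_that("a featureless distance curve falls back to the smallest K", {
  # synthetic linkage whose dendrogram-scale curve is exactly linear in k
  w <- 12
  # heights (1:11)^2/2 give d(k) = w - k on the dendrogram scale: no knee
  fake <- structure(
    list(merge = cbind(-(1:(w - 1)), c(-w, 1:(w - 2))),
         height = (1:(w - 1))^2 / 2, order = seq_len(w),
         data = matrix(0, w, 2), window_centers_s = NULL),
    class = "ward_linkage")
  k <- select_k(fake)
  expect_equal(as.integer(k), 2L)
  expect_true(all(abs(attr(k, "second_derivative")$s) < 1e-9))
})

test_that("select_k validates its search range", {
  x <- matrix(rnorm(20), 10)
  link <- ward_linkage(x)
  expect_error(select_k(link, k_min = 1), "k_min")
  expect_error(select_k(link, k_min = 5, k_max = 9), "k_min")
  expect_error(select_k(ward_linkage(matrix(rnorm(6), 3)), k_min = 2),
               "at least 4")
})

test_that("state labels cut the tree and are numbered by first occurrence", {
  two <- make_blobs(rbind(c(0, 0), c(10, 10)), n_per = 10)
  link <- ward_linkage(two$x)
  st <- assign_states(link, 2)
  expect_equal(adjusted_rand_index(st$labels, two$labels), 1)
  expect_equal(st$labels[1], 1)                       # first window is state 1
  expect_equal(sort(unique(st$labels)), 1:2)
  expect_equal(dim(st$centroids), c(2, 2))

  expect_equal(assign_states(link, 1)$labels, rep(1L, 20))
  expect_equal(length(unique(assign_states(link, 20)$labels)), 20)
  expect_error(assign_states(link, 0), "K must be")
  expect_error(assign_states(link, 21), "K must be")
})

test_that("cutting at K-1 only merges states found at K", {
  set.seed(41)
  x <- matrix(rnorm(30 * 3), 30)
  link <- ward_linkage(x)
  for (k in 8:3) {
    fine <- assign_states(link, k)$labels
    coarse <- assign_states(link, k - 1)$labels
    # every fine state maps into exactly one coarse state
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("clustering is invariant to translating all degree vectors", {
  set.seed(43)
  x <- matrix(rnorm(25 * 4), 25)
  shift <- sweep(x, 2, c(100, -50, 3, 0.5), "+")
  a <- ward_linkage(x); b <- ward_linkage(shift)
  expect_identical(a$merge, b$merge)
  expect_equal(a$height, b$height, tolerance = 1e-8)
  expect_identical(assign_states(a, 4)$labels, assign_states(b, 4)$labels)
})

test_that("state change rates count within-period transitions per second", {
  seg <- manual_segmentation(c("preseizure_full", "seizure",
                               "postseizure_full"),
                             starts = c(0, 11, 21), ends = c(11, 21, 31))
  # constant labels in the seizure: rate 0
  st <- manual_states(c(rep(1L, 21), rep(2L, 19)), seq(0.5, 20, by = 0.5))
  r <- state_change_rate(st, seg)
  expect_equal(r$rate_per_s[r$period == "seizure"], 0)

  # alternating labels: 21 windows spanning 10.5 s inside an 11-s period
  st2 <- manual_states(rep(c(1L, 2L), length.out = 21),
                       seq(0.25, 10.25, by = 0.5))
  r2 <- state_change_rate(st2, seg)
  expect_equal(r2$n_changes[1], 20)
  expect_equal(r2$rate_per_s[1], 20 / 11)

  # a label change straddling the period boundary counts for neither period
  st3 <- manual_states(c(rep(1L, 22), rep(2L, 20)),
                       seq(0.25, 20.75, by = 0.5))
  r3 <- state_change_rate(st3, seg)  # change at 11.25/10.75 pair
  expect_equal(sum(r3$n_changes[1:2]), 0)

  # undefined rate when a period holds fewer than two windows
  r4 <- state_change_rate(st2, seg)
  expect_true(is.na(r4$rate_per_s[r4$period == "postseizure_full"]))
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(73)
  for (i in 1:5) {
    a <- sample(1:4, 50, TRUE)
    b <- sample(1:3, 50, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})
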