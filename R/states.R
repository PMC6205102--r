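#' Agglomerative Ward linkage of degree vectors
#'
#' Hierarchical clustering of the per-window degree vectors: start from
#' singletons and repeatedly merge the two clusters whose union minimally
#' increases the total within-cluster sum of squared (Euclidean) errors, SSE =
#' `sum_i sum_{x in C_i} ||x - c_i||^2`. The recorded merge distance is that
#' SSE increase, `size_a * size_b / (size_a + size_b) * ||c_a - c_b||^2`,
#' computed directly from cluster centroids (exact, no Lance-Williams
#' recursion). Ties are broken deterministically toward the pair with the
#' lexicographically smallest (older, younger) cluster creation order, so the
#' linkage is reproducible for any input order.
#'
#' @param x a [degree_vectors()] result, or a numeric matrix with one
#'   observation (window) per row.
#' @return an object of class `ward_linkage`: `merge` (`(W-1) x 2`, `hclust`
#'   convention), `height` (SSE increase per merge, non-decreasing), `order`,
#'   `data`, `window_centers_s` (when available). Convert with
#'   [as.hclust()] for plotting.
#' @export
ward_linkage <- function(x) {
  centers <- NULL
  if (inherits(x, "degree_series")) {
    centers <- x$window_centers_s
    x <- x$degrees
  }
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("degree vectors must be finite numeric", call. = FALSE)
  }
  w <- nrow(x)
  if (w < 2) stop("need at least 2 windows to cluster", call. = FALSE)

  size <- rep(1, w)
  centroid <- x
  code <- -seq_len(w)        # hclust codes: negative leaves
  rank <- seq_len(w)         # creation order for tie-breaking
  active <- rep(TRUE, w)
  d <- matrix(Inf, w, w)
  for (i in seq_len(w - 1)) {
    di <- colSums((t(centroid[(i + 1):w, , drop = FALSE]) - centroid[i, ])^2)
    d[i, (i + 1):w] <- di / 2    # singleton pairs: ||xi - xj||^2 / 2
  }

  merge <- matrix(0L, w - 1, 2)
  height <- numeric(w - 1)
  for (m in seq_len(w - 1)) {
    dmin <- min(d)
    cand <- which(d == dmin, arr.ind = TRUE)
    # order candidates by creation rank of the two clusters (older first)
    ra <- pmin(rank[cand[, 1]], rank[cand[, 2]])
    rb <- pmax(rank[cand[, 1]], rank[cand[, 2]])
    pick <- order(ra, rb)[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]
    if (rank[a] > rank[b]) { tmp <- a; a <- b; b <- tmp }
    merge[m, ] <- sort(c(code[a], code[b]))  # negatives first, hclust-style
    height[m] <- dmin
    # merged cluster lives in slot a
    sa <- size[a]; sb <- size[b]
    centroid[a, ] <- (sa * centroid[a, ] + sb * centroid[b, ]) / (sa + sb)
    size[a] <- sa + sb
    code[a] <- m
    rank[a] <- w + m
    active[b] <- FALSE
    d[b, ] <- Inf; d[, b] <- Inf
    others <- which(active); others <- others[others != a]
    if (length(others) > 0) {
      gap <- colSums((t(centroid[others, , drop = FALSE]) - centroid[a, ])^2)
      dn <- size[a] * size[others] / (size[a] + size[others]) * gap
      lo <- pmin(others, a); hi <- pmax(others, a)
      d[cbind(lo, hi)] <- dn
      d[cbind(hi, lo)] <- Inf
    }
  }
  # Ward merge costs are non-decreasing; guard against float jitter only
  run <- cummax(height)
  if (any(height < run - 1e-8 * pmax(run, 1))) {
    stop("internal error: non-monotone Ward merge costs", call. = FALSE)
  }
  height <- pmax(height, run)
  structure(list(merge = merge, height = height,
                 order = linkage_order(merge, w), data = x,
                 window_centers_s = centers),
            class = "ward_linkage")
}

# leaf ordering by tree traversal (for hclust compatibility / plotting)
linkage_order <- function(merge, w) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(w - 1)
}

#' @export
as.hclust.ward_linkage <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = NULL, method = "ward.sse",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' @export
print.ward_linkage <- function(x, ...) {
  cat("<ward_linkage> ", nrow(x$data), " windows, ", ncol(x$data),
      " channels; merge cost range [", signif(min(x$height), 4), ", ",
      signif(max(x$height), 4), "]\n", sep = "")
  invisible(x)
}

#' Merge-distance curve indexed by cluster count
#'
#' `d(k)` is the merge cost paid to go from `k + 1` clusters down to `k`.
#'
#' @param link a [ward_linkage()].
#' @param scale `"sse"` for the raw SSE-increase heights, `"dendrogram"` for
#'   the conventional dendrogram scale `sqrt(2 * height)` (the units in which
#'   Euclidean-based Ward trees are usually displayed).
#' @return data frame with columns `k`, `d`, for `k = 1 .. W-1`.
#' @export
distance_curve <- function(link, scale = c("sse", "dendrogram")) {
  stopifnot(inherits(link, "ward_linkage"))
  scale <- match.arg(scale)
  w <- nrow(link$data)
  h <- link$height
  if (scale == "dendrogram") h <- sqrt(2 * h)
  data.frame(k = seq_len(w - 1), d = rev(h))
}

#' Choose the number of network states from the distance curve
#'
#' Knee detection on the clustering distance curve: with `d(k)` the merge
#' distance that reduces `k + 1` clusters to `k`, the discrete second
#' derivative `s(k) = d(k-1) - 2 d(k) + d(k+1)` is evaluated on
#' `k = k_min .. k_max` and `K` is the argmax, ties broken toward smaller `K`
#' (parsimony). A genuine cluster structure with `K` groups makes `d(K)`
#' (still a within-group merge) small and `d(K-1)` (the first between-group
#' merge) large, so `s` peaks at `K`.
#'
#' The curve is evaluated on the dendrogram scale (`sqrt(2 * SSE-increase)`,
#' see [distance_curve()]) by default: on the raw SSE scale the final one or
#' two merges dominate the curvature whenever the data split into two
#' super-groups of dissimilar synchronization level — as peri-seizure
#' recordings do (low-sync versus high-sync regimes) — and the knee collapses
#' to `k = 2` regardless of finer structure. The square-root scale removes
#' that size-driven inflation while leaving the location of a well-separated
#' knee unchanged; `scale = "sse"` is available for comparison.
#'
#' @param link a [ward_linkage()] with `W >= 4` windows.
#' @param k_min,k_max search range; defaults 2 and `min(20, W - 2)`. Requires
#'   `2 <= k_min <= k_max <= W - 2` (the second difference needs `d(k-1)` and
#'   `d(k+1)`).
#' @param scale distance-curve scale, see above.
#' @return integer `K`, with the evaluated curve in attribute
#'   `"second_derivative"` (data frame `k`, `s`).
#' @export
select_k <- function(link, k_min = 2, k_max = NULL,
                     scale = c("dendrogram", "sse")) {
  stopifnot(inherits(link, "ward_linkage"))
  scale <- match.arg(scale)
  w <- nrow(link$data)
  if (w < 4) stop("need at least 4 windows to select K", call. = FALSE)
  k_max <- k_max %||% min(20, w - 2)
  if (!(2 <= k_min && k_min <= k_max && k_max <= w - 2)) {
    stop("need 2 <= k_min <= k_max <= W - 2 (W = ", w, ")", call. = FALSE)
  }
  dc <- distance_curve(link, scale = scale)
  d <- function(k) dc$d[match(k, dc$k)]
  ks <- k_min:k_max
  s <- d(ks - 1) - 2 * d(ks) + d(ks + 1)
  k <- ks[which.max(s)]   # which.max takes the first (smallest k) on ties
  structure(as.integer(k),
            second_derivative = data.frame(k = ks, s = s))
}

#' Cut the linkage into a labelled state sequence
#'
#' Cuts the merge tree at `K` clusters and renumbers the labels `1..K` by
#' first window of occurrence, so the numbering is stable and independent of
#' internal merge ids (state 1 is always the first state seen).
#'
#' @param link a [ward_linkage()].
#' @param K number of states, `1 <= K <= W`.
#' @return an object of class `state_sequence`: `labels` (per window, in
#'   `1..K`), `K`, `centroids` (K x M), `window_centers_s`.
#' @export
assign_states <- function(link, K) {
  stopifnot(inherits(link, "ward_linkage"))
  w <- nrow(link$data)
  if (!(K >= 1 && K <= w)) stop("K must be in 1..", w, call. = FALSE)
  K <- as.integer(K)
  raw <- if (K == w) seq_len(w) else stats::cutree(stats::as.hclust(link), k = K)
  lab <- match(raw, unique(raw))  # renumber by first occurrence
  centroids <- rowsum(link$data, lab) / as.vector(table(lab))
  structure(list(labels = lab, K = K, centroids = centroids,
                 window_centers_s = link$window_centers_s),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat("<state_sequence> ", length(x$labels), " windows, K = ", x$K,
      " states (occupancy: ",
      paste(table(x$labels), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Network state-change rate per period
#'
#' Counts label changes between consecutive windows whose centers both lie in
#' the period and divides by the period's annotated duration in seconds.
#' Pairs that straddle a period boundary are attributed to neither period.
#' Periods holding fewer than two windows have an undefined rate, reported as
#' missing.
#'
#' @param states an [assign_states()] result carrying window centers.
#' @param seg a [segment_periods()] result.
#' @param periods period names; defaults to the three equal-length periods
#'   used for the state-transition statistics.
#' @return a data frame of class `state_change_rates` with columns `period`,
#'   `n_windows`, `n_changes`, `rate_per_s`.
#' @export
state_change_rate <- function(states, seg,
                              periods = c("preseizure_full", "seizure",
                                          "postseizure_full")) {
  stopifnot(inherits(states, "state_sequence"),
            inherits(seg, "period_segmentation"))
  if (is.null(states$window_centers_s)) {
    stop("state sequence lacks window centers", call. = FALSE)
  }
  stopifnot(!is.unsorted(states$window_centers_s))
  rows <- lapply(periods, function(p) {
    inside <- centers_in_period(states$window_centers_s, seg, p)
    iv <- period_interval(seg, p)
    n <- sum(inside)
    lab <- states$labels[inside]
    # consecutive-in-period pairs: centers are sorted, and a pair straddling
    # the boundary has one member outside, so it is excluded by construction
    changes <- if (n >= 2) sum(diff(lab) != 0) else NA_integer_
    data.frame(period = p, n_windows = n, n_changes = changes,
               rate_per_s = if (n >= 2) changes / (iv[2] - iv[1]) else NA_real_)
  })
  structure(do.call(rbind, rows),
            class = c("state_change_rates", "data.frame"))
}
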