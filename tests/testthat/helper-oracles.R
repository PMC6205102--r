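# Independent oracles used to validate the first-principles implementations.

# Brute-force agglomerative Ward clustering: at every step, for every pair of
# clusters, compute the SSE increase of merging them by explicit sums over the
# member points (no centroid-update recursion), pick the minimum with the same
# (older, younger) creation-order tie rule.
ward_oracle <- function(x) {
  x <- as.matrix(x)
  w <- nrow(x)
  sse_of <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- lapply(seq_len(w), identity)  # member index sets
  codes <- -seq_len(w)
  ranks <- seq_len(w)
  merge <- matrix(0L, w - 1, 2)
  height <- numeric(w - 1)
  for (m in seq_len(w - 1)) {
    best <- NULL
    n <- length(clusters)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sse_of(c(clusters[[i]], clusters[[j]])) -
          sse_of(clusters[[i]]) - sse_of(clusters[[j]])
        ra <- min(ranks[i], ranks[j]); rb <- max(ranks[i], ranks[j])
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (ra < best$ra || (ra == best$ra && rb < best$rb)))) {
          best <- list(d = d, i = i, j = j, ra = ra, rb = rb)
        }
      }
    }
    merge[m, ] <- sort(c(codes[best$i], codes[best$j]))
    height[m] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[best$i] <- m
    ranks[best$i] <- w + m
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
    ranks <- ranks[-best$j]
  }
  list(merge = merge, height = height)
}

# Friedman statistic computed by a separate route (no tie handling needed for
# tie-free tables): the classical 12/(nk(k+1)) * sum(Rj - n(k+1)/2)^2 formula.
friedman_stat_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  12 / (n * k * (k + 1)) * sum((colSums(r) - n * (k + 1) / 2)^2)
}

# Exact Friedman p by full enumeration of within-row rank orderings, using
# the closed-form tie-free statistic (vectorized over the (k!)^n grid).
friedman_exact_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  all_perm <- perms_of(k)
  rpat <- lapply(seq_len(n), function(i) {
    t(apply(all_perm, 1, function(p) rank(x[i, p])))
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(nrow(all_perm))), n)))
  colsums <- matrix(0, nrow(grid), k)
  for (i in seq_len(n)) colsums <- colsums + rpat[[i]][grid[, i], ]
  stat <- 12 / (n * k * (k + 1)) *
    rowSums((colsums - n * (k + 1) / 2)^2)
  obs <- friedman_stat_oracle(x)
  mean(stat >= obs - 1e-9)
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

# Tight, well-separated Gaussian blobs with known membership.
make_blobs <- function(centers, n_per = 20, sd = 0.2, seed = 42) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}
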