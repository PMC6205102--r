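#' Friedman test for repeated measures across periods
#'
#' Nonparametric omnibus test for differences among `k` related conditions
#' (here: peri-seizure periods) measured on `n` subjects (here: seizures).
#' Values are ranked within each row with mid-ranks for ties; the
#' tie-corrected chi-square statistic is
#' `Q = (k - 1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with `A` the sum of
#' squared ranks and `C = n k (k+1)^2 / 4`, referred to the upper tail of
#' `chi^2(k - 1)`. Implemented from first principles so that a full
#' within-row permutation oracle can validate both the statistic and an exact
#' p-value on small tables.
#'
#' Rows (subjects) containing any missing value are dropped with a warning;
#' a row whose values are all tied carries no rank information (it is allowed
#' and noted). If every row is fully tied the statistic is 0 and p = 1.
#'
#' @param x numeric matrix or data frame, `n` rows (subjects) x `k >= 3`
#'   columns (conditions).
#' @param exact also compute an exact permutation p-value by enumerating all
#'   `(k!)^n` equally likely within-row orderings (guarded to small tables,
#'   `(k!)^n <= 5e6`).
#' @return an object of class `friedman_test`: `statistic`, `df`, `p.value`,
#'   `mean_ranks`, `n`, `k`, and `p.exact` when requested.
#' @seealso [dunn_posthoc()] for the pairwise follow-up.
#' @export
friedman_test <- function(x, exact = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  cn <- colnames(x) %||% paste0("c", seq_len(ncol(x)))
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sum(!complete), " row(s) with missing cells dropped",
            call. = FALSE)
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("need at least 2 complete rows", call. = FALSE)
  if (k < 3) stop("need at least 3 conditions", call. = FALSE)
  r <- t(apply(x, 1, rank))
  tied_rows <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(tied_rows)) {
    warning(sum(tied_rows), " fully tied row(s) carry no rank information",
            call. = FALSE)
  }
  rj <- colSums(r)
  a <- sum(r^2)
  c1 <- n * k * (k + 1)^2 / 4
  stat <- if (a - c1 <= 0) 0 else {
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / (a - c1)
  }
  out <- list(statistic = stat, df = k - 1,
              p.value = if (a - c1 <= 0) 1 else
                stats::pchisq(stat, k - 1, lower.tail = FALSE),
              mean_ranks = stats::setNames(rj / n, cn), n = n, k = k)
  if (exact) {
    if (factorial(k)^n > 5e6) {
      stop("exact enumeration infeasible for (k!)^n = ", factorial(k)^n,
           call. = FALSE)
    }
    out$p.exact <- friedman_exact_p(x, stat)
  }
  structure(out, class = "friedman_test")
}

# exact p by enumerating all within-row permutations of the observed values
friedman_exact_p <- function(x, observed) {
  n <- nrow(x); k <- ncol(x)
  perms <- permutations_of(k)
  np <- nrow(perms)
  c1 <- n * k * (k + 1)^2 / 4
  # per row: rank pattern under every permutation, and its sum of squares
  rpat <- lapply(seq_len(n), function(i) {
    t(apply(perms, 1, function(p) rank(x[i, p])))
  })
  a_row <- lapply(rpat, function(r) rowSums(r^2))
  grid <- rep(1L, n)
  total <- np^n
  count <- 0L
  for (idx in seq_len(total)) {
    rj <- numeric(k); a <- 0
    for (i in seq_len(n)) {
      rj <- rj + rpat[[i]][grid[i], ]
      a <- a + a_row[[i]][grid[i]]
    }
    stat <- if (a - c1 <= 0) 0 else {
      (k - 1) * sum((rj - n * (k + 1) / 2)^2) / (a - c1)
    }
    if (stat >= observed - 1e-9) count <- count + 1L
    # odometer increment
    j <- 1L
    while (j <= n) {
      grid[j] <- grid[j] + 1L
      if (grid[j] <= np) break
      grid[j] <- 1L
      j <- j + 1L
    }
  }
  count / total
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1))
  }))
}

#' @export
print.friedman_test <- function(x, ...) {
  cat("Friedman test: chi^2(", x$df, ") = ", signif(x$statistic, 5),
      ", p = ", signif(x$p.value, 4), " (n = ", x$n, ", k = ", x$k, ")\n",
      sep = "")
  if (!is.null(x$p.exact)) cat("  exact permutation p =",
                               signif(x$p.exact, 4), "\n")
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons on Friedman ranks
#'
#' For each requested pair of conditions the z statistic on the Friedman mean
#' ranks is `z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`, with a
#' two-sided normal p-value and family-wise adjustment by multiplying by the
#' number of compared pairs, capped at 1 (Bonferroni-style Dunn; the Sidak
#' variant `1 - (1 - p)^m` is available). Significance stars follow the
#' conventional 0.05 / 0.01 / 0.001 / 0.0001 thresholds.
#'
#' @param x the repeated-measures table passed to [friedman_test()].
#' @param pairs optional list of length-2 character vectors naming condition
#'   pairs; defaults to all `k (k - 1) / 2` pairs.
#' @param p_adjust `"bonferroni"` (default) or `"sidak"`.
#' @return a data frame of class `dunn_posthoc`: `pair`, `z`, `p`, `p_adj`,
#'   `stars`; the omnibus test as attribute `"friedman"`.
#' @export
dunn_posthoc <- function(x, pairs = NULL,
                         p_adjust = c("bonferroni", "sidak")) {
  p_adjust <- match.arg(p_adjust)
  ft <- friedman_test(x)
  cn <- names(ft$mean_ranks)
  if (is.null(pairs)) {
    idx <- utils::combn(length(cn), 2)
    pairs <- lapply(seq_len(ncol(idx)), function(j) cn[idx[, j]])
  }
  bad <- !vapply(pairs, function(p) all(p %in% cn), TRUE)
  if (any(bad)) {
    stop("unknown condition label(s) in pairs: ",
         paste(unique(unlist(pairs)[!unlist(pairs) %in% cn]), collapse = ", "),
         call. = FALSE)
  }
  m <- length(pairs)
  se <- sqrt(ft$k * (ft$k + 1) / (6 * ft$n))
  rows <- lapply(pairs, function(p) {
    z <- (ft$mean_ranks[[p[1]]] - ft$mean_ranks[[p[2]]]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(p[1], "vs", p[2]), z = z, p = praw)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- switch(p_adjust,
                      bonferroni = pmin(1, out$p * m),
                      sidak = 1 - (1 - out$p)^m)
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  structure(out, class = c("dunn_posthoc", "data.frame"),
            friedman = ft, p_adjust = p_adjust, n_pairs = m)
}

#' @export
print.dunn_posthoc <- function(x, ...) {
  print(attr(x, "friedman"))
  cat("Dunn's post hoc (", attr(x, "p_adjust"), " x ", attr(x, "n_pairs"),
      " pairs):\n", sep = "")
  df <- as.data.frame(x)
  df$z <- signif(df$z, 4); df$p <- signif(df$p, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
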