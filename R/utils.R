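#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same events.
#' Used throughout the test-suite to compare recovered clusters against
#' simulation ground truth.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor),
#'   equal length.
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: `p_adj[(i)] = min_{j >= i} p[(j)] * m / j`,
#' capped at 1.  `NA` p-values are excluded from the family (they get
#' `NA` adjusted values and are not counted in `m`).
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA` allowed.
#' @param level FDR level used for the significance flags (default 0.10).
#' @return list with `p_adj` (same length as `p`) and logical `significant`
#'   (`p_adj <= level`, `NA` where `p` is `NA`).
#' @export
adjust_bh <- function(p, level = 0.10) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m > 0L) {
    po <- p[ok]
    o <- order(po, decreasing = TRUE)
    ro <- order(o)
    adj[ok] <- pmin(1, cummin(po[o] * m / rev(seq_len(m))))[ro]
  }
  list(p_adj = adj, significant = !is.na(adj) & adj <= level)
}

# Exact 1-D two-class k-means (minimum within-class sum of squares over all
# sorted split points).  Returns the split cutoff (midpoint of class means),
# the two class means and a simplified silhouette of the 2-split.
split_1d_kmeans <- function(x) {
  n <- length(x)
  xs <- sort(x)
  if (xs[1] == xs[n]) {
    return(list(cutoff = xs[1], low = xs[1], high = xs[1], silhouette = 0))
  }
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  m <- seq_len(n - 1)
  sse_l <- cs2[m] - cs[m]^2 / m
  nr <- n - m
  sr <- cs[n] - cs[m]
  sse_r <- (cs2[n] - cs2[m]) - sr^2 / nr
  best <- which.min(sse_l + sse_r)
  mu_l <- cs[best] / best
  mu_r <- sr[best] / nr[best]
  a <- abs(x - ifelse(x <= xs[best], mu_l, mu_r))
  b <- abs(x - ifelse(x <= xs[best], mu_r, mu_l))
  sil <- mean((b - a) / pmax(a, b, .Machine$double.eps))
  list(cutoff = (mu_l + mu_r) / 2, low = mu_l, high = mu_r, silhouette = sil)
}

# Mean silhouette width of integer labels on a coordinate matrix (small n).
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  labels <- as.integer(factor(labels))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- sum(d[i, own]) / max(1, sum(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Derive a reproducible child seed below 2^31 from a base seed and a tag.
child_seed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 1009L + (sum(utf8ToInt(as.character(tag))) %% 1009L)
}
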