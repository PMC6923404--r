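#' Mean-expression heat-map matrix with dendrograms
#'
#' Mean arcsinh expression per grouping unit (cluster or sample) and
#' marker, with average-linkage Euclidean hierarchical clustering of rows
#' and columns.  Empty grouping units are excluded with a warning.
#'
#' @param expr events x markers matrix (arcsinh scale).
#' @param by grouping label per event (cluster or sample id).
#' @param stat `"mean"` (default) or `"median"`.
#' @return a `heatmap_matrix`: list with `matrix`, `row_hclust`,
#'   `col_hclust` (`NULL` when fewer than 2 rows/columns).
#' @export
heatmap_matrix <- function(expr, by, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!is.factor(by)) by <- factor(by)
  empty <- setdiff(levels(by), unique(as.character(by)))
  if (length(empty)) {
    warning("empty grouping unit(s) excluded: ", paste(empty, collapse = ", "))
    by <- droplevels(by)
  }
  f <- if (stat == "mean") colMeans else function(m) apply(m, 2, median)
  M <- do.call(rbind, lapply(levels(by), function(l)
    f(expr[by == l, , drop = FALSE])))
  rownames(M) <- levels(by)
  structure(list(matrix = M,
                 row_hclust = if (nrow(M) > 1)
                   hclust(dist(M), method = "average") else NULL,
                 col_hclust = if (ncol(M) > 1)
                   hclust(dist(t(M)), method = "average") else NULL),
            class = "heatmap_matrix")
}

#' Seeded dot-plot subsample of a cluster
#'
#' Uniform sample without replacement of `min(n, cluster size)` events of
#' one cluster, reproducible from the seed; used for the 256-cells-per-
#' cluster dot-plot displays.
#'
#' @param labels cluster label per event.
#' @param cluster cluster to sample from.
#' @param n subsample size (default 256).
#' @param seed integer seed.
#' @param expr optional events x markers matrix; when given, the sampled
#'   expression values are returned in attribute `"expr"`.
#' @return sorted integer vector of sampled event indices.
#' @export
dotplot_sample <- function(labels, cluster, n = 256L, seed = 1L,
                           expr = NULL) {
  idx <- which(labels == cluster)
  if (length(idx) == 0) stop("cluster ", cluster, " is empty")
  set.seed(child_seed(seed, paste0("dot", cluster)))
  if (length(idx) > n) idx <- sort(sample(idx, n))
  if (!is.null(expr)) attr(idx, "expr") <- expr[idx, , drop = FALSE]
  idx
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with margins
#' fixed, the p-value is the sum of hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed
#' table (within relative tolerance 1e-7).
#'
#' @param tab 2x2 matrix of non-negative integer counts, at least one
#'   positive.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("cell counts must be non-negative")
  if (sum(tab) == 0) stop("at least one cell must be positive")
  m <- sum(tab[1, ])      # row-1 margin
  n <- sum(tab[2, ])      # row-2 margin
  k <- sum(tab[, 1])      # column-1 margin
  x <- tab[1, 1]
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  pr <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t statistic with
#' `df = n1 + n2 - 2` and two-sided p-value; accepts either raw samples
#' or group summaries.
#'
#' @param x,y numeric vectors (raw data), each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  two_sample_t_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' @rdname two_sample_t
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
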