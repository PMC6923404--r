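#' Barnes-Hut t-SNE embedding of pooled events
#'
#' 2-D t-SNE with the standard cytometry hyperparameters: perplexity 30,
#' theta 0.5, and an iteration count of 1000 per 100,000 cells (bounded
#' below by 1000).  Deterministic given `seed`.
#'
#' @param X events x channels matrix (arcsinh-transformed values).
#' @param perplexity t-SNE perplexity (default 30).
#' @param theta Barnes-Hut accuracy parameter (default 0.5; 0 = exact).
#' @param seed integer seed.
#' @param max_iter iteration count; default `max(1000, ceiling(1000 * n /
#'   1e5))`.
#' @return an `embedding_result`: list with `coords` (events x 2),
#'   `hyperparams` and `channels_used`.
#' @export
embed_tsne <- function(X, perplexity = 30, theta = 0.5, seed = 1L,
                       max_iter = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("too few events (", n, ") for perplexity ", perplexity,
         "; lower the perplexity")
  if (is.null(max_iter)) max_iter <- max(1000L, ceiling(1000 * n / 1e5))
  set.seed(child_seed(seed, "tsne"))
  fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, theta = theta,
                      max_iter = max_iter, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE,
                      num_threads = 1L)
  coords <- fit$Y
  colnames(coords) <- c("tsne1", "tsne2")
  structure(list(coords = coords,
                 hyperparams = list(perplexity = perplexity, theta = theta,
                                    max_iter = max_iter, seed = seed),
                 channels_used = colnames(X)),
            class = "embedding_result")
}

#' Equal-frequency binning of a 2-D embedding
#'
#' Recursive median splits: at each node the axis with the larger variance
#' is split at its median into two equal-frequency halves (events equal to
#' the median go left; remaining ties are broken by event order), down to
#' `depth` levels, yielding `2^depth` bins of equal size within one event.
#'
#' @param coords events x 2 coordinate matrix.
#' @param depth number of split levels (default 8, i.e. 256 bins).
#' @return a `bin_partition`: list with `depth`, `bin` (id per event) and
#'   `tree` (data frame of splits: node, axis, threshold).
#' @export
bin_embedding <- function(coords, depth = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (depth < 1) stop("depth must be >= 1")
  if (n < 2^depth)
    stop("need at least 2^depth = ", 2^depth, " events, got ", n)
  bin <- integer(n)
  tree <- list()
  recurse <- function(idx, level, node) {
    if (level == depth) {
      bin[idx] <<- node - 2^depth + 1L
      return(invisible())
    }
    v <- coords[idx, , drop = FALSE]
    axis <- if (var(v[, 1]) >= var(v[, 2])) 1L else 2L
    x <- v[, axis]
    ord <- order(x, seq_along(x))  # stable: ties by event order
    nl <- ceiling(length(idx) / 2)
    left <- idx[ord[seq_len(nl)]]
    right <- idx[ord[-seq_len(nl)]]
    tree[[length(tree) + 1L]] <<-
      data.frame(node = node, axis = axis, threshold = x[ord[nl]])
    recurse(left, level + 1L, 2L * node)
    recurse(right, level + 1L, 2L * node + 1L)
  }
  recurse(seq_len(n), 0L, 1L)
  structure(list(depth = as.integer(depth), bin = bin,
                 tree = do.call(rbind, tree)),
            class = "bin_partition")
}

# Common NB dispersion by profile likelihood: bin-wise means are profiled
# out (per-bin intercept-only NB fit with library-size offsets) and the
# summed log-likelihood is maximized over log-dispersion.
estimate_common_dispersion <- function(counts, lib_sizes,
                                       interval = c(1e-4, 5)) {
  profile_ll <- function(log_phi) {
    phi <- exp(log_phi)
    size <- 1 / phi
    ll <- 0
    for (b in seq_len(nrow(counts))) {
      y <- counts[b, ]
      if (sum(y) == 0) next
      mu <- fit_nb_mean(y, lib_sizes, phi)
      ll <- ll + sum(dnbinom(y, size = size, mu = mu, log = TRUE))
    }
    ll
  }
  opt <- optimize(profile_ll, log(interval), maximum = TRUE, tol = 1e-4)
  exp(opt$maximum)
}

# Newton fit of an intercept-only NB model with offsets; returns fitted mu.
fit_nb_mean <- function(y, N, phi, iter = 25L) {
  b0 <- log(sum(y) / sum(N))
  for (i in seq_len(iter)) {
    mu <- exp(b0) * N
    score <- sum((y - mu) / (1 + phi * mu))
    info <- sum(mu * (1 + phi * y) / (1 + phi * mu)^2)
    if (info <= 0) break
    step <- score / info
    b0 <- b0 + sign(step) * min(abs(step), 2)
    if (abs(step) < 1e-10) break
  }
  exp(b0) * N
}

# NB GLM log-likelihood of a fitted glm object at fixed dispersion.
nb_loglik <- function(y, mu, phi) {
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Bin-wise differential abundance with a negative binomial GLM
#'
#' Per-bin counts per sample form a bins x samples table; per-sample
#' library size is the sample's total event count.  A single common NB
#' dispersion is estimated across bins by profile likelihood, then each
#' bin is tested with an NB GLM (log link, log library-size offset, group
#' fixed effect) by likelihood-ratio test of the group coefficient, with
#' Benjamini-Hochberg adjustment at `fdr`.
#'
#' @param partition a [bin_embedding()] result (or an integer bin id per
#'   event).
#' @param sample_id sample id per event.
#' @param metadata metadata data frame (`sample_id`, `group`); exactly two
#'   groups with at least two samples each.
#' @param fdr FDR level for the significance flags (default 0.10).
#' @param min_count bins with total count below this are dropped before
#'   testing (default 0 — keep all).
#' @return a `bin_da_result` data frame: per bin counts summary, `logFC`
#'   (log2 fold change of the second group over the first), `dispersion`,
#'   `p`, `p_adj`, `significant`; per-sample counts in attribute
#'   `"counts"`.
#' @export
test_bins <- function(partition, sample_id, metadata, fdr = 0.10,
                      min_count = 0L) {
  bin <- if (inherits(partition, "bin_partition")) partition$bin
         else as.integer(partition)
  stopifnot(length(bin) == length(sample_id))
  samples <- metadata$sample_id
  group <- factor(metadata$group)
  if (nlevels(group) != 2) stop("test_bins requires exactly two groups")
  if (any(table(group) < 2))
    stop("each group needs at least 2 samples (dispersion unidentifiable)")
  counts <- unclass(table(factor(bin), factor(sample_id, levels = samples)))
  keep <- rowSums(counts) >= min_count
  res <- nb_da_test(counts[keep, , drop = FALSE], group,
                    lib_sizes = colSums(counts), fdr = fdr)
  res
}

#' Negative-binomial differential-abundance test on a count matrix
#'
#' The counts-level engine behind [test_bins()]: a common NB dispersion by
#' profile likelihood, then per row an NB GLM (log link, log library-size
#' offset, two-level group effect) with a likelihood-ratio test and BH
#' adjustment.
#'
#' @param counts features x samples integer matrix.
#' @param group two-level factor over samples (>= 2 each).
#' @param lib_sizes per-sample library sizes (default column sums).
#' @param fdr FDR level for flags (default 0.10).
#' @return a `bin_da_result` data frame (see [test_bins()]).
#' @export
nb_da_test <- function(counts, group, lib_sizes = colSums(counts),
                       fdr = 0.10) {
  counts <- as.matrix(counts)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2))
    stop("each group needs at least 2 samples (dispersion unidentifiable)")
  lib <- lib_sizes
  phi <- estimate_common_dispersion(counts, lib)
  g <- as.integer(group) - 1L
  off <- log(lib)
  ids <- if (!is.null(rownames(counts))) rownames(counts)
         else as.character(seq_len(nrow(counts)))
  res <- data.frame(bin = suppressWarnings(as.integer(ids)),
                    mean_count = rowMeans(counts))
  if (anyNA(res$bin)) res$bin <- seq_len(nrow(counts))
  res$logFC <- res$p <- NA_real_
  fam <- MASS::negative.binomial(theta = 1 / phi)
  Xf <- cbind(1, g)
  X0 <- matrix(1, ncol(counts), 1)
  for (b in seq_len(nrow(counts))) {
    y <- counts[b, ]
    if (all(y == y[1]) && length(unique(lib)) == 1) {
      res$logFC[b] <- 0; res$p[b] <- 1
      next
    }
    f1 <- suppressWarnings(stats::glm.fit(Xf, y, family = fam, offset = off))
    f0 <- suppressWarnings(stats::glm.fit(X0, y, family = fam, offset = off))
    ll1 <- nb_loglik(y, f1$fitted.values, phi)
    ll0 <- nb_loglik(y, f0$fitted.values, phi)
    lrt <- max(0, 2 * (ll1 - ll0))
    res$logFC[b] <- f1$coefficients[2] / log(2)
    res$p[b] <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  adj <- adjust_bh(res$p, level = fdr)
  res$dispersion <- phi
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant
  gm <- t(apply(counts, 1, function(y)
    tapply(y / lib, group, mean) * mean(lib)))
  colnames(gm) <- paste0("mean_", levels(group))
  res <- cbind(res, gm)
  attr(res, "counts") <- counts
  attr(res, "fdr") <- fdr
  class(res) <- c("bin_da_result", class(res))
  res
}

#' Per-event adjusted-p map export
#'
#' Annotates every event with its bin's adjusted p-value for plotting the
#' statistical embedding map.
#'
#' @param result a [test_bins()] result.
#' @param partition the matching [bin_embedding()] partition.
#' @param coords optional events x 2 coordinates to include.
#' @param path optional CSV output path.
#' @return data frame with one row per event: `bin`, `p_adj`,
#'   `significant`, and coordinates when given.
#' @export
da_map_export <- function(result, partition, coords = NULL, path = NULL) {
  bin <- partition$bin
  m <- match(bin, result$bin)
  out <- data.frame(bin = bin, p_adj = result$p_adj[m],
                    significant = result$significant[m])
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(bin))
      stop("coords and partition are not aligned")
    out <- cbind(out, coords)
  }
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
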