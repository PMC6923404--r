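#' Cluster count container for differential-abundance testing
#'
#' Integer counts per cluster and sample, per-sample totals (the parent
#' lineage totals when testing subclusters), and the group label per
#' sample.
#'
#' @param counts clusters x samples integer matrix (row/column names
#'   required).
#' @param totals per-sample totals, named, `counts <= totals`.
#' @param group group label per sample (same order as columns).
#' @return object of class `cluster_counts`.
#' @export
cluster_counts <- function(counts, totals, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs cluster row names and sample column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- totals[colnames(counts)]
  if (any(sweep(counts, 2, totals, ">")))
    stop("counts exceed per-sample totals")
  structure(list(counts = counts, totals = totals,
                 group = factor(group)), class = "cluster_counts")
}

#' Build cluster counts from a frequency table
#'
#' @param freq a [cluster_frequencies()] result.
#' @param level `"lineage"` or `"subcluster"`.
#' @param parent for subclusters, restrict to this parent lineage (`NULL`
#'   = all).
#' @return a [cluster_counts()] object (totals are identified-cell totals
#'   for lineages, parent-lineage totals for subclusters).
#' @export
counts_from_frequencies <- function(freq, level = c("subcluster", "lineage"),
                                    parent = NULL) {
  level <- match.arg(level)
  f <- freq[freq$level == level, ]
  if (!is.null(parent)) f <- f[f$parent %in% parent, ]
  if (nrow(f) == 0) stop("no rows at level ", level)
  counts <- unclass(xtabs(count ~ cluster + sample_id, data = f))
  samples <- colnames(counts)
  if (level == "lineage") {
    totals <- colSums(counts)
  } else {
    par_of <- f$parent[match(rownames(counts), f$cluster)]
    lin <- freq[freq$level == "lineage", ]
    if (length(unique(par_of)) == 1) {
      totals <- setNames(vapply(samples, function(s)
        sum(lin$count[lin$sample_id == s & lin$cluster == par_of[1]]),
        numeric(1)), samples)
    } else {
      totals <- colSums(counts)  # mixed parents: totals within selection
    }
  }
  md <- unique(freq[, c("sample_id", "group")])
  cluster_counts(counts, totals, md$group[match(samples, md$sample_id)])
}

#' Filter clusters before testing
#'
#' Retains clusters having at least `min_cells` cells in at least
#' `min_samples` samples (defaults: 3 cells, half the samples).
#'
#' @param cc a [cluster_counts()].
#' @param min_cells minimum cells (default 3).
#' @param min_samples minimum number of samples (default half, rounded
#'   up).
#' @return the filtered `cluster_counts`; removed clusters in attribute
#'   `"removed"`.
#' @export
filter_clusters <- function(cc, min_cells = 3L,
                            min_samples = ceiling(ncol(cc$counts) / 2)) {
  keep <- rowSums(cc$counts >= min_cells) >= min_samples
  if (!any(keep)) stop("all clusters removed by the min-cells filter")
  out <- cluster_counts(cc$counts[keep, , drop = FALSE], cc$totals,
                        as.character(cc$group))
  attr(out, "removed") <- rownames(cc$counts)[!keep]
  out
}

# Fit the per-cluster binomial GLMM: logit P(cell in cluster | sample) =
# b0 + b_g group + u_sample, u ~ N(0, sigma^2).  The Wald statistic is
# referred to a t distribution with n_samples - 2 df: with one binomial
# observation per sample the normal reference is anti-conservative at
# cohort sizes of ~20 samples.  Returns estimate, se, p, or NULL on
# non-convergence.
fit_cluster_glmm <- function(y, totals, group, return_fit = FALSE) {
  df <- data.frame(y = y, n = totals, g = group,
                   s = factor(seq_along(y)))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(cbind(y, n - y) ~ g + (1 | s), data = df,
                  family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. constant response): sigma^2 = 0 limit, i.e.
    # ordinary logistic regression
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(y, n - y) ~ g, data = df,
                                  family = stats::binomial())),
      error = function(e) NULL)
  }
  if (is.null(fit)) return(NULL)
  if (return_fit) return(fit)
  co <- summary(fit)$coefficients
  list(estimate = co[2, 1], se = co[2, 2],
       p = 2 * pt(-abs(co[2, 1] / co[2, 2]), df = length(y) - 2))
}

# Full/null fit pair for the omnibus test, with the same glm fallback.
fit_glmm_pair <- function(df) {
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  full <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(cbind(y, n - y) ~ g + (1 | s), data = df,
                family = stats::binomial(), control = ctrl))),
    error = function(e) NULL)
  null <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(cbind(y, n - y) ~ 1 + (1 | s), data = df,
                family = stats::binomial(), control = ctrl))),
    error = function(e) NULL)
  if (is.null(full) || is.null(null)) {
    full <- tryCatch(suppressWarnings(
      stats::glm(cbind(y, n - y) ~ g, data = df,
                 family = stats::binomial())), error = function(e) NULL)
    null <- tryCatch(suppressWarnings(
      stats::glm(cbind(y, n - y) ~ 1, data = df,
                 family = stats::binomial())), error = function(e) NULL)
  }
  list(full = full, null = null)
}

fixef_any <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
}

#' Cluster-level differential abundance by binomial GLMM
#'
#' Per cluster, a binomial GLMM of the cluster's cell count out of the
#' sample total with a group fixed effect and a per-sample random
#' intercept (observation-level, absorbing biological overdispersion),
#' fitted by Laplace approximation; two-sided Wald test of the group
#' effect against a t reference with `n_samples - 2` degrees of freedom
#' (the normal reference is anti-conservative at ~20 samples);
#' Benjamini-Hochberg adjustment across clusters.  A cluster is
#' *significant* when `p_adj <= fdr` and `p < 0.05` (both printed
#' conditions of the emulated workflow); the final *differential* flag
#' additionally requires the presence criterion of [presence_filter()].
#'
#' @param cc a [cluster_counts()] with exactly two groups (>= 2 samples
#'   each).
#' @param fdr FDR level (default 0.10).
#' @param p_cut unadjusted significance cut (default 0.05).
#' @return a `cluster_da_result` data frame: `cluster`, `estimate`
#'   (log-odds group effect), `se`, `p`, `p_adj`, `unstable`,
#'   `significant`.
#' @export
test_clusters_glmm <- function(cc, fdr = 0.10, p_cut = 0.05) {
  group <- cc$group
  if (nlevels(group) != 2) stop("expected exactly two groups")
  if (any(table(group) < 2)) stop("each group needs >= 2 samples")
  if (any(cc$totals <= 0)) stop("per-sample totals must be positive")
  cl <- rownames(cc$counts)
  res <- data.frame(cluster = cl, estimate = NA_real_, se = NA_real_,
                    p = NA_real_, unstable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cl)) {
    f <- fit_cluster_glmm(cc$counts[i, ], cc$totals, group)
    if (is.null(f)) {
      res$unstable[i] <- TRUE
      warning("GLMM did not converge for cluster ", cl[i],
              "; excluded from the FDR family")
    } else {
      res$estimate[i] <- f$estimate
      res$se[i] <- f$se
      res$p[i] <- f$p
    }
  }
  adj <- adjust_bh(res$p, level = fdr)
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant & !is.na(res$p) & res$p < p_cut
  attr(res, "fdr") <- fdr
  attr(res, "groups") <- levels(group)
  class(res) <- c("cluster_da_result", class(res))
  res
}

#' Apply the presence criterion
#'
#' A cluster is *present* in a sample when its count is at least
#' `min_cells`.  The differential flag requires significance and a
#' presence fraction of at least `threshold` in each group
#' (`mode = "each"`) or in at least one group (`mode = "either"`, the
#' default, matching disease- or control-specific clusters).
#'
#' @param cc the [cluster_counts()] that was tested.
#' @param result a [test_clusters_glmm()] result.
#' @param threshold presence fraction (default 0.80).
#' @param mode `"either"` or `"each"`.
#' @param min_cells presence definition (default 3).
#' @return `result` with per-group `presence_*` columns and the final
#'   logical `differential` column.
#' @export
presence_filter <- function(cc, result, threshold = 0.80,
                            mode = c("either", "each"), min_cells = 3L) {
  mode <- match.arg(mode)
  groups <- levels(cc$group)
  pres <- sapply(groups, function(g)
    rowMeans(cc$counts[result$cluster, cc$group == g, drop = FALSE] >=
               min_cells))
  pres <- matrix(pres, nrow = nrow(result),
                 dimnames = list(NULL, paste0("presence_", groups)))
  meets <- if (mode == "either") apply(pres >= threshold, 1, any)
           else apply(pres >= threshold, 1, all)
  result <- cbind(result, pres)
  result$differential <- result$significant & meets
  result
}

#' Multi-group differential abundance (omnibus + pairwise)
#'
#' With three or more groups, each cluster gets an omnibus
#' likelihood-ratio test of the group factor (df = groups - 1) with BH
#' adjustment across clusters, plus unadjusted pairwise Wald contrasts
#' from the full fit.  With two groups this reduces to
#' [test_clusters_glmm()].
#'
#' @param cc a [cluster_counts()].
#' @param fdr FDR level (default 0.10).
#' @return list with `omnibus` (cluster, LRT statistic, df, p, p_adj,
#'   significant) and `pairwise` (cluster, contrast, estimate, se, p);
#'   for two groups, the `test_clusters_glmm` result is returned in both
#'   slots.
#' @export
test_multi_group <- function(cc, fdr = 0.10) {
  group <- cc$group
  if (any(table(group) < 2)) stop("each group needs >= 2 samples")
  if (nlevels(group) == 2) {
    r <- test_clusters_glmm(cc, fdr = fdr)
    return(list(omnibus = r, pairwise = r))
  }
  cl <- rownames(cc$counts)
  omni <- data.frame(cluster = cl, lrt = NA_real_,
                     df = nlevels(group) - 1L, p = NA_real_,
                     unstable = FALSE, stringsAsFactors = FALSE)
  pw <- list()
  for (i in seq_along(cl)) {
    df <- data.frame(y = cc$counts[i, ], n = cc$totals, g = group,
                     s = factor(seq_along(cc$totals)))
    fits <- fit_glmm_pair(df)
    full <- fits$full; null <- fits$null
    if (is.null(full) || is.null(null)) {
      omni$unstable[i] <- TRUE
      next
    }
    lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(null))))
    omni$lrt[i] <- lrt
    omni$p[i] <- pchisq(lrt, df = omni$df[i], lower.tail = FALSE)
    beta <- fixef_any(full)
    V <- as.matrix(stats::vcov(full))
    lv <- levels(group)
    ix <- function(g) paste0("g", g)
    contr <- list()
    for (a in 2:nlevels(group)) {
      est <- beta[ix(lv[a])]
      se <- sqrt(V[ix(lv[a]), ix(lv[a])])
      contr[[length(contr) + 1L]] <-
        data.frame(cluster = cl[i],
                   contrast = paste(lv[a], "vs", lv[1]),
                   estimate = unname(est), se = se,
                   p = 2 * pnorm(-abs(est / se)))
    }
    for (a in 2:(nlevels(group) - 1)) for (b in (a + 1):nlevels(group)) {
      est <- beta[ix(lv[b])] - beta[ix(lv[a])]
      se <- sqrt(V[ix(lv[b]), ix(lv[b])] + V[ix(lv[a]), ix(lv[a])] -
                   2 * V[ix(lv[b]), ix(lv[a])])
      contr[[length(contr) + 1L]] <-
        data.frame(cluster = cl[i],
                   contrast = paste(lv[b], "vs", lv[a]),
                   estimate = unname(est), se = se,
                   p = 2 * pnorm(-abs(est / se)))
    }
    pw[[length(pw) + 1L]] <- do.call(rbind, contr)
  }
  adj <- adjust_bh(omni$p, level = fdr)
  omni$p_adj <- adj$p_adj
  omni$significant <- adj$significant
  list(omnibus = omni, pairwise = do.call(rbind, pw))
}

#' Discriminating markers of a cluster
#'
#' Subsamples up to `n_subsample` events of the cluster (seeded, without
#' replacement) and, per marker, computes the standardized median
#' difference `(median in cluster - median in the rest) / (pooled MAD +
#' eps)`; markers are ranked by its absolute value and those exceeding
#' `cutoff` are reported as discriminating.  The pooled MAD is the mean of
#' the in- and out-of-cluster MADs.
#'
#' @param expr events x markers matrix (arcsinh scale).
#' @param labels cluster label per event.
#' @param cluster the cluster of interest.
#' @param n_subsample events sampled from the cluster (default 256).
#' @param seed integer seed.
#' @param cutoff discriminating threshold on |d| (default 1.0).
#' @param eps MAD regularizer (default 0.05).
#' @return a `marker_discrimination` data frame: `marker`, `median_in`,
#'   `median_out`, `d`, `rank`, `discriminating`.
#' @export
discriminating_markers <- function(expr, labels, cluster, n_subsample = 256L,
                                   seed = 1L, cutoff = 1.0, eps = 0.05) {
  inside <- which(labels == cluster)
  if (length(inside) == 0) stop("cluster ", cluster, " is empty")
  set.seed(child_seed(seed, paste0("markers", cluster)))
  if (length(inside) > n_subsample)
    inside <- sort(sample(inside, n_subsample))
  outside <- which(labels != cluster)
  xi <- expr[inside, , drop = FALSE]
  xo <- expr[outside, , drop = FALSE]
  med_i <- apply(xi, 2, median)
  med_o <- apply(xo, 2, median)
  mad_i <- apply(xi, 2, mad)
  mad_o <- apply(xo, 2, mad)
  d <- (med_i - med_o) / ((mad_i + mad_o) / 2 + eps)
  out <- data.frame(marker = colnames(expr), median_in = med_i,
                    median_out = med_o, d = d, row.names = NULL)
  out <- out[order(-abs(out$d)), ]
  out$rank <- seq_len(nrow(out))
  out$discriminating <- abs(out$d) >= cutoff
  attr(out, "n_used") <- length(inside)
  class(out) <- c("marker_discrimination", class(out))
  out
}
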