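#' Fit a batch self-organizing map
#'
#' Batch SOM on the chosen channels: the codebook is initialized on the
#' principal plane (a regular grid spanning the first two principal
#' components), then updated for `epochs` batch rounds with a truncated
#' Gaussian neighborhood (nodes at grid distance below the radius) whose
#' radius shrinks linearly from half the grid diagonal to 1 — so the final
#' rounds update best-matching nodes only, a pure quantization step.  Each
#' event is mapped to its best-matching node by Euclidean distance.  The fit is deterministic given the data (the PCA
#' initialization is deterministic up to a fixed sign convention); `seed`
#' is kept for interface stability and used only if the principal plane is
#' degenerate.
#'
#' @param X numeric matrix, events x channels (no `NA`/`NaN`).
#' @param grid_shape integer length-2 `(rows, cols)`; default `c(10, 10)`
#'   gives the 100-node grid.
#' @param seed integer seed.
#' @param epochs batch training rounds (default 10).
#' @return a `cluster_model`: list with `codebook`, `grid_shape`, `node`
#'   (best-matching node per event), `channels_used`, `node_to_meta`,
#'   `consensus`, `seed`.
#' @export
fit_som <- function(X, grid_shape = c(10, 10), seed = 1L, epochs = 10L) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NA/NaN/Inf")
  n_nodes <- prod(grid_shape)
  if (nrow(X) < n_nodes)
    stop("need at least ", n_nodes, " events for a ",
         grid_shape[1], "x", grid_shape[2], " grid")
  grid <- as.matrix(expand.grid(row = seq_len(grid_shape[1]),
                                col = seq_len(grid_shape[2])))
  ctr <- colMeans(X)
  codebook <- matrix(rep(ctr, each = n_nodes), nrow = n_nodes,
                     dimnames = list(NULL, colnames(X)))
  sv <- La.svd(sweep(X, 2, ctr), nu = 0, nv = min(2L, ncol(X)))
  dvals <- c(sv$d, 0, 0)[1:2]
  n_pc <- sum(dvals > 1e-12)
  if (n_pc >= 1 && n_nodes > 1) {
    # principal component 1 spans the longer grid axis
    axis_for_pc <- order(grid_shape, decreasing = TRUE)
    for (k in 1:min(2, n_pc, nrow(sv$vt))) {
      a <- axis_for_pc[k]
      if (grid_shape[a] == 1) next
      v <- sv$vt[k, ]
      if (v[which.max(abs(v))] < 0) v <- -v
      sdev <- sv$d[k] / sqrt(max(1, nrow(X) - 1))
      coef <- (grid[, a] - (grid_shape[a] + 1) / 2) /
        ((grid_shape[a] - 1) / 2) * sdev
      codebook <- codebook + outer(coef, v)
    }
  }
  grid_d2 <- as.matrix(dist(grid))^2
  r0 <- sqrt(sum((grid_shape - 1)^2)) / 2
  bmu <- rep(1L, nrow(X))
  for (e in seq_len(epochs)) {
    bmu <- nearest_node(X, codebook)
    r <- if (epochs == 1) 1 else max(r0 - (e - 1) * (r0 - 1) / (epochs - 1), 1)
    # truncated Gaussian neighborhood (nodes at grid distance < r): at the
    # final radius of 1 the update is pure quantization (BMU only), which
    # stops boundary nodes from blending well-separated populations
    H <- exp(-grid_d2 / (2 * r^2))
    H[grid_d2 >= r^2 - 1e-12] <- 0
    diag(H) <- pmax(diag(H), 1)
    rs <- rowsum(X, bmu)
    sums <- matrix(0, n_nodes, ncol(X))
    sums[as.integer(rownames(rs)), ] <- rs
    cnt <- tabulate(bmu, n_nodes)
    num <- H %*% sums
    den <- as.vector(H %*% cnt)
    upd <- den > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  bmu <- nearest_node(X, codebook)
  structure(list(codebook = codebook, grid_shape = grid_shape, node = bmu,
                 channels_used = colnames(X), node_to_meta = list(),
                 consensus = list(), seed = as.integer(seed)),
            class = "cluster_model")
}

# Best-matching node per event, chunked to bound memory.
nearest_node <- function(X, W, chunk = 50000L) {
  w2 <- rowSums(W^2)
  out <- integer(nrow(X))
  for (s in seq(1, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    D <- -2 * X[s:e, , drop = FALSE] %*% t(W)
    D <- sweep(D, 2, w2, "+")
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' Consensus meta-clustering of SOM nodes
#'
#' For each k in 2..`maxK`, `n_resample` subsamples of
#' `ceiling(subsample_frac * nodes)` codebook rows are hierarchically
#' clustered (Euclidean distance, `linkage` linkage) and cut at k; the
#' consensus matrix entry (i, j) is the fraction of runs with both nodes
#' present in which they co-clustered.  The final node-to-metacluster map
#' at each k is hierarchical clustering of `1 - consensus` cut at k.  The
#' same subsamples are reused across k, and everything is deterministic
#' given `seed`.
#'
#' The default linkage is Ward (`"ward.D2"`): with SOM codebooks, average
#' linkage lets boundary nodes chain phenotypically close populations
#' together and measurably degrades recovery of known mixtures, while Ward
#' separates them reliably; `linkage = "average"` restores the
#' ConsensusClusterPlus-style behaviour.
#'
#' @param model a `cluster_model` from [fit_som()].
#' @param maxK largest number of meta-clusters (default 25; must be below
#'   the node count).
#' @param n_resample number of subsampled clusterings (default 100).
#' @param subsample_frac fraction of nodes per subsample (default 0.9).
#' @param seed integer seed.
#' @param linkage hierarchical linkage for base and final clustering
#'   (default `"ward.D2"`; see Details).
#' @return the model with `node_to_meta[[k]]` and `consensus[[k]]` filled
#'   for k = 2..maxK.
#' @export
consensus_metacluster <- function(model, maxK = 25L, n_resample = 100L,
                                  subsample_frac = 0.9, seed = 1L,
                                  linkage = "ward.D2") {
  W <- model$codebook
  n <- nrow(W)
  if (maxK >= n) stop("maxK must be smaller than the node count (", n, ")")
  set.seed(child_seed(seed, "consensus"))
  m <- ceiling(subsample_frac * n)
  ks <- 2:maxK
  co <- setNames(lapply(ks, function(k) matrix(0, n, n)), ks)
  tog <- matrix(0, n, n)
  for (r in seq_len(n_resample)) {
    idx <- sort(sample.int(n, m))
    hc <- hclust(dist(W[idx, , drop = FALSE]), method = linkage)
    tog[idx, idx] <- tog[idx, idx] + 1
    cuts <- as.matrix(cutree(hc, k = ks))
    for (j in seq_along(ks)) {
      lab <- cuts[, j]
      for (g in unique(lab)) {
        ii <- idx[lab == g]
        co[[j]][ii, ii] <- co[[j]][ii, ii] + 1
      }
    }
  }
  model$consensus <- lapply(co, function(M) {
    C <- ifelse(tog > 0, M / pmax(tog, 1), 0)
    diag(C) <- 1
    C
  })
  names(model$consensus) <- ks
  model$node_to_meta <- setNames(vector("list", length(ks)), ks)
  for (j in seq_along(ks)) {
    hc <- hclust(as.dist(1 - model$consensus[[j]]), method = linkage)
    model$node_to_meta[[j]] <- cutree(hc, k = ks[j])
  }
  model$meta_seed <- as.integer(seed)
  model
}

#' Map meta-clusters to lineages
#'
#' Applies a (manual) merge map from meta-cluster ids at the chosen k to
#' lineage names.  Events mapped to the reserved lineage `"unidentified"`
#' are kept in the assignment but excluded from downstream frequency
#' denominators.
#'
#' @param model a `cluster_model` with consensus results.
#' @param k the chosen number of meta-clusters.
#' @param merge_map named character vector: meta-cluster id (as character)
#'   -> lineage name, covering every meta-cluster at k.
#' @param sample_id per-event sample ids aligned with the model's events.
#' @return a `cluster_assignment` data frame with columns `sample_id`,
#'   `lineage`, `subcluster` (NA until [subcluster()] fills it); the merge
#'   map and k are kept as attributes.
#' @export
choose_k_and_merge <- function(model, k, merge_map, sample_id) {
  meta <- model$node_to_meta[[as.character(k)]]
  if (is.null(meta)) stop("no consensus result at k = ", k)
  present <- as.character(sort(unique(meta)))
  uncovered <- setdiff(present, names(merge_map))
  if (length(uncovered))
    stop("merge map does not cover meta-cluster(s): ",
         paste(uncovered, collapse = ", "))
  lineage <- unname(merge_map[as.character(meta[model$node])])
  out <- data.frame(sample_id = sample_id, lineage = lineage,
                    subcluster = NA_character_, stringsAsFactors = FALSE)
  attr(out, "merge_map") <- merge_map
  attr(out, "k") <- k
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Second-level meta-clustering within one lineage
#'
#' Re-clusters the events of a single lineage with a smaller SOM grid
#' (default 7x7) and consensus meta-clustering at `k`.  Clusters whose mean
#' frequency (as percent of the parent lineage, averaged over samples)
#' falls below `min_freq_pct` are merged into the nearest retained cluster
#' by codebook-centroid Euclidean distance, so event accounting is
#' conserved.
#'
#' @param X events x channels matrix of the lineage's events (all panel
#'   markers, arcsinh scale).
#' @param sample_id sample id per event.
#' @param k number of subclusters.
#' @param grid_shape SOM grid (default `c(7, 7)`).
#' @param min_freq_pct minimum mean frequency in percent of parent
#'   (default 0.1).
#' @param seed integer seed.
#' @param lineage lineage name used in labels and error messages.
#' @return character vector of subcluster labels (`"<lineage>.<i>"`).
#' @export
subcluster <- function(X, sample_id, k, grid_shape = c(7, 7),
                       min_freq_pct = 0.1, seed = 1L,
                       lineage = "lineage") {
  if (nrow(X) < 200)
    stop("lineage ", lineage, " has fewer than 200 events (",
         nrow(X), ")")
  model <- fit_som(X, grid_shape, seed = seed)
  if (k == 1) {
    lab <- rep(1L, nrow(X))
  } else {
    model <- consensus_metacluster(model, maxK = max(k, 2), seed = seed)
    lab <- model$node_to_meta[[as.character(k)]][model$node]
  }
  # mean per-sample frequency (% of parent) per cluster
  freq <- prop.table(table(factor(sample_id), factor(lab)), margin = 1) * 100
  mean_freq <- colMeans(freq, na.rm = TRUE)
  keep <- names(mean_freq)[mean_freq >= min_freq_pct]
  if (length(keep) == 0) keep <- names(which.max(mean_freq))
  drop <- setdiff(names(mean_freq), keep)
  if (length(drop)) {
    cent <- do.call(rbind, lapply(c(keep, drop), function(g)
      colMeans(X[lab == as.integer(g), , drop = FALSE])))
    rownames(cent) <- c(keep, drop)
    for (g in drop) {
      d <- colSums((t(cent[keep, , drop = FALSE]) - cent[g, ])^2)
      lab[lab == as.integer(g)] <- as.integer(keep[which.min(d)])
    }
  }
  lab <- as.integer(factor(lab, levels = sort(unique(lab))))
  paste0(lineage, ".", lab)
}

#' Per-sample cluster frequency table
#'
#' Counts and frequencies per (sample, cluster) at both levels: lineages as
#' percent of total identified cells (the `"unidentified"` lineage is
#' excluded from denominators but reported), subclusters as percent of
#' their parent lineage.  Zero-count pairs are materialized explicitly.
#'
#' @param assignment a `cluster_assignment` (with or without subclusters).
#' @param metadata sample metadata data frame (`sample_id`, `group`).
#' @return a `frequency_table` data frame with columns `sample_id`,
#'   `group`, `level`, `parent`, `cluster`, `count`, `pct_of_parent`,
#'   `pct_of_total`.
#' @export
cluster_frequencies <- function(assignment, metadata) {
  miss <- setdiff(unique(assignment$sample_id), metadata$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  samples <- metadata$sample_id
  ident <- assignment$lineage != "unidentified"
  tot <- table(factor(assignment$sample_id[ident], levels = samples))
  lin_levels <- sort(unique(assignment$lineage[ident]))
  tab <- table(factor(assignment$sample_id[ident], levels = samples),
               factor(assignment$lineage[ident], levels = lin_levels))
  rows <- list()
  for (L in lin_levels) {
    cnt <- as.vector(tab[, L])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = samples, level = "lineage", parent = "total", cluster = L,
      count = cnt,
      pct_of_parent = 100 * cnt / pmax(as.vector(tot), 1),
      pct_of_total = 100 * cnt / pmax(as.vector(tot), 1),
      stringsAsFactors = FALSE)
  }
  has_sub <- ident & !is.na(assignment$subcluster)
  for (L in unique(assignment$lineage[has_sub])) {
    sel <- has_sub & assignment$lineage == L
    sub_levels <- sort(unique(assignment$subcluster[sel]))
    stab <- table(factor(assignment$sample_id[sel], levels = samples),
                  factor(assignment$subcluster[sel], levels = sub_levels))
    parent_tot <- rowSums(stab)
    for (sc in sub_levels) {
      cnt <- as.vector(stab[, sc])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples, level = "subcluster", parent = L, cluster = sc,
        count = cnt,
        pct_of_parent = 100 * cnt / pmax(parent_tot, 1),
        pct_of_total = 100 * cnt / pmax(as.vector(tot), 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$group <- metadata$group[match(out$sample_id, metadata$sample_id)]
  out <- out[, c("sample_id", "group", "level", "parent", "cluster",
                 "count", "pct_of_parent", "pct_of_total")]
  class(out) <- c("frequency_table", class(out))
  out
}
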