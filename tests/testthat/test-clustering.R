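test_that("SOM maps duplicates together and solves the degenerate grid", {
  blobs <- make_blobs(300, rbind(c(0, 0), c(5, 5)), 0.3, seed = 2)
  X <- rbind(blobs$X, blobs$X[1:10, ])
  model <- fit_som(X, grid_shape = c(3, 3), seed = 1)
  expect_equal(model$node[301:310], model$node[1:10])
  # 1x1 grid: one node, codebook is the data mean
  m1 <- fit_som(blobs$X, grid_shape = c(1, 1), seed = 1)
  expect_true(all(m1$node == 1))
  expect_equal(as.vector(m1$codebook), colMeans(blobs$X), tolerance = 1e-8)
  expect_error(fit_som(matrix(NaN, 10, 2), c(2, 2)), "NA")
})

test_that("SOM nodes partition well-separated blobs cleanly", {
  ctr <- matrix(0, 3, 5)
  ctr[2, 1] <- 5; ctr[3, 2] <- 5
  blobs <- make_blobs(3000, ctr, 0.2, seed = 8)
  model <- fit_som(blobs$X, grid_shape = c(4, 4), seed = 3)
  purity <- vapply(split(blobs$labels, model$node), function(l)
    max(table(l)) / length(l), numeric(1))
  expect_true(all(purity >= 0.99))
})

test_that("consensus matrix is exact for duplicated codebook groups", {
  X <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
             matrix(rnorm(200, 10, 0.1), ncol = 2))
  model <- fit_som(X, grid_shape = c(2, 2), seed = 1)
  # overwrite codebook with two groups of identical rows
  model$codebook <- rbind(matrix(0, 2, 2), matrix(10, 2, 2))
  model <- consensus_metacluster(model, maxK = 3, n_resample = 50, seed = 5)
  C <- model$consensus[["2"]]
  expect_true(all(C[1:2, 1:2] == 1))
  expect_true(all(C[3:4, 3:4] == 1))
  expect_true(all(C[1:2, 3:4] == 0))
  for (k in names(model$consensus)) {
    Ck <- model$consensus[[k]]
    expect_equal(Ck, t(Ck))
    expect_true(all(diag(Ck) == 1))
    expect_true(all(Ck >= 0 & Ck <= 1))
    expect_true(all(sort(unique(model$node_to_meta[[k]])) ==
                      seq_len(as.integer(k))))
  }
  expect_error(consensus_metacluster(model, maxK = 4), "maxK")
})

test_that("consensus meta-clustering recovers 3 blobs with high ARI", {
  ctr <- matrix(0, 3, 5)
  ctr[2, 1] <- 5; ctr[3, 2] <- 5
  blobs <- make_blobs(3000, ctr, 0.2, seed = 8)
  model <- fit_som(blobs$X, grid_shape = c(5, 5), seed = 3)
  model <- consensus_metacluster(model, maxK = 6, seed = 3)
  lab <- model$node_to_meta[["3"]][model$node]
  expect_gte(adjusted_rand_index(lab, blobs$labels), 0.95)
})

test_that("two-level clustering is deterministic given data and seed", {
  blobs <- make_blobs(1200, rbind(c(0, 0), c(6, 0), c(0, 6)), 0.3, seed = 4)
  run <- function() {
    m <- fit_som(blobs$X, grid_shape = c(4, 4), seed = 9)
    m <- consensus_metacluster(m, maxK = 5, seed = 9)
    m$node_to_meta[["3"]][m$node]
  }
  expect_identical(run(), run())
})

test_that("SOM+consensus matches the exhaustive best-partition oracle in 1-D", {
  # 12 well-separated 1-D points, 3 groups; oracle = minimum within-group
  # sum of squares over all contiguous 3-partitions
  x <- c(0.1, 0.2, 0.3, 0.35, 5.0, 5.1, 5.2, 5.3, 10.0, 10.1, 10.2, 10.4)
  X <- matrix(rep(x, 30), ncol = 1)  # enough events for the grid
  oracle_best <- function(x, k) {
    n <- length(x)
    best <- NULL; best_ss <- Inf
    cuts <- combn(n - 1, k - 1)
    for (j in seq_len(ncol(cuts))) {
      bounds <- c(0, cuts[, j], n)
      lab <- rep(seq_len(k), diff(bounds))
      ss <- sum(vapply(split(x, lab), function(g)
        sum((g - mean(g))^2), numeric(1)))
      if (ss < best_ss) { best_ss <- ss; best <- lab }
    }
    best
  }
  oracle <- oracle_best(x, 3)[match(X[, 1], x)]
  model <- fit_som(X, grid_shape = c(1, 6), seed = 2)
  model <- consensus_metacluster(model, maxK = 3, seed = 2)
  lab <- model$node_to_meta[["3"]][model$node]
  expect_equal(adjusted_rand_index(lab, oracle), 1)
})

test_that("merge map applies, adds counts, and flags unidentified events", {
  blobs <- make_blobs(600, rbind(c(0, 0), c(6, 0), c(0, 6)), 0.3, seed = 6)
  model <- fit_som(blobs$X, grid_shape = c(4, 4), seed = 1)
  model <- consensus_metacluster(model, maxK = 4, seed = 1)
  sample_id <- rep(c("S1", "S2"), length.out = 600)
  meta <- model$node_to_meta[["3"]]
  ident <- setNames(as.character(1:3), 1:3)
  asg <- choose_k_and_merge(model, 3, ident, sample_id)
  expect_equal(sort(unique(asg$lineage)), c("1", "2", "3"))
  # merging two metaclusters adds their counts
  mm <- c("1" = "myeloid", "2" = "myeloid", "3" = "rest")
  asg2 <- choose_k_and_merge(model, 3, mm, sample_id)
  expect_equal(sum(asg2$lineage == "myeloid"),
               sum(asg$lineage %in% c("1", "2")))
  expect_error(choose_k_and_merge(model, 3, c("1" = "a"), sample_id),
               "cover")
  # unidentified events are excluded from denominators but counted
  mm3 <- c("1" = "A", "2" = "B", "3" = "unidentified")
  asg3 <- choose_k_and_merge(model, 3, mm3, sample_id)
  md <- data.frame(sample_id = c("S1", "S2"), group = c("g", "g"))
  freq <- cluster_frequencies(asg3, md)
  lin <- freq[freq$level == "lineage", ]
  expect_false("unidentified" %in% lin$cluster)
  tot <- tapply(lin$count, lin$sample_id, sum)
  expect_equal(unname(tot[c("S1", "S2")]),
               unname(table(sample_id[asg3$lineage != "unidentified"])[c("S1", "S2")]))
})

test_that("subclustering recovers structure and merges rare clusters", {
  blobs <- make_blobs(2000, rbind(c(0, 0, 0), c(6, 0, 0)), 0.3, seed = 12)
  sample_id <- rep(paste0("S", 1:4), length.out = 2000)
  lab <- subcluster(blobs$X, sample_id, k = 2, grid_shape = c(3, 3),
                    seed = 5, lineage = "T")
  expect_gte(adjusted_rand_index(lab, blobs$labels), 0.95)
  expect_true(all(startsWith(lab, "T.")))
  # k = 1: a single subcluster at 100%
  lab1 <- subcluster(blobs$X, sample_id, k = 1, grid_shape = c(3, 3),
                     seed = 5, lineage = "T")
  expect_equal(unique(lab1), "T.1")
  expect_error(subcluster(blobs$X[1:100, ], sample_id[1:100], k = 2,
                          lineage = "T"), "200")
  # a 0.05%-frequency cluster is merged away
  X <- rbind(matrix(rnorm(4000, 0, 0.2), ncol = 2),
             matrix(rnorm(4000, 8, 0.2), ncol = 2),
             matrix(rnorm(2, 20, 0.01), ncol = 2))
  sid <- rep(paste0("S", 1:2), length.out = nrow(X))
  labs <- subcluster(X, sid, k = 3, grid_shape = c(3, 3), seed = 5,
                     lineage = "L")
  expect_equal(length(unique(labs)), 2)
})

test_that("frequencies are normalized, order-invariant, and recover truth", {
  set.seed(41)
  md <- data.frame(sample_id = c("S1", "S2"), group = c("CON", "MS"))
  asg <- data.frame(
    sample_id = rep("S1", 100),
    lineage = rep("T", 100),
    subcluster = rep(c("T.1", "T.2"), times = c(30, 70)),
    stringsAsFactors = FALSE)
  class(asg) <- c("cluster_assignment", class(asg))
  freq <- cluster_frequencies(asg, md)
  sub <- freq[freq$level == "subcluster" & freq$sample_id == "S1", ]
  expect_equal(sort(sub$pct_of_parent), c(30, 70))
  # per sample, pct_of_parent sums to 100
  expect_equal(sum(sub$pct_of_parent), 100, tolerance = 1e-6)
  # zero-count pairs materialized for S2
  sub2 <- freq[freq$level == "subcluster" & freq$sample_id == "S2", ]
  expect_equal(nrow(sub2), 2)
  expect_true(all(sub2$count == 0))
  # permutation of event order changes nothing
  perm <- sample(nrow(asg))
  freq2 <- cluster_frequencies(asg[perm, ], md)
  expect_equal(freq, freq2, ignore_attr = TRUE)
  expect_error(cluster_frequencies(asg,
                                   data.frame(sample_id = "X", group = "g")),
               "missing")
})

test_that("recovered frequencies stay within multinomial error of truth", {
  exp <- tiny_experiment(n_events = 2000, seed = 37)
  sim <- exp$sim
  nd <- !sim$truth$is_doublet & !sim$truth$is_bead
  md <- data.frame(sample_id = vapply(exp$truth$samples, `[[`, "",
                                      "sample_id"),
                   group = vapply(exp$truth$samples, `[[`, "", "group"))
  asg <- data.frame(sample_id = sim$truth$sample_id[nd],
                    lineage = sim$truth$population[nd],
                    subcluster = NA_character_)
  class(asg) <- c("cluster_assignment", class(asg))
  freq <- cluster_frequencies(asg, md)
  lin <- freq[freq$level == "lineage", ]
  for (s in md$sample_id[1:3]) {
    pr <- exp$truth$samples[[match(s, md$sample_id)]]$population_proportions
    for (p in names(pr)) {
      obs <- lin$pct_of_total[lin$sample_id == s & lin$cluster == p] / 100
      bound <- 3 * sqrt(pr[[p]] * (1 - pr[[p]]) / 2000)
      expect_lt(abs(obs - pr[[p]]), bound + 1e-9)
    }
  }
})
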