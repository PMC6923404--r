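test_that("min-cells filter retains and removes per the rule", {
  counts <- rbind(c0 = rep(0L, 22),
                  c1 = c(rep(5L, 11), rep(0L, 11)),
                  c2 = rep(10L, 22))
  colnames(counts) <- paste0("s", 1:22)
  cc <- cluster_counts(counts, setNames(rep(100L, 22), colnames(counts)),
                       rep(c("CON", "MS"), each = 11))
  f <- filter_clusters(cc)  # min_cells 3 in >= 11 of 22 samples
  expect_setequal(rownames(f$counts), c("c1", "c2"))
  expect_equal(attr(f, "removed"), "c0")
  # min_cells = 0 keeps everything
  f0 <- filter_clusters(cc, min_cells = 0)
  expect_equal(nrow(f0$counts), 3)
  expect_error(filter_clusters(cluster_counts(counts["c0", , drop = FALSE] ,
                                              cc$totals,
                                              as.character(cc$group))),
               "removed")
})

test_that("GLMM gives a null result on exactly balanced counts", {
  counts <- matrix(rep(c(50L, 100L), each = 22), 2, 22, byrow = TRUE,
                   dimnames = list(c("a", "b"), paste0("s", 1:22)))
  cc <- cluster_counts(counts, setNames(rep(1000L, 22), colnames(counts)),
                       rep(c("CON", "MS"), each = 11))
  res <- test_clusters_glmm(cc)
  expect_true(all(abs(res$estimate) < 1e-6))
  expect_true(all(res$p > 0.999))
})

test_that("GLMM recovers a spiked odds ratio of 2 with power", {
  # scaled-down in-suite check (50 reps); the acceptance suite runs 200
  base <- c(0.05, 0.10, 0.15, 0.03, 0.08, 0.12, 0.20, 0.06)
  beta <- c(log(2), rep(0, 7))
  est <- det <- logical(0)
  for (r in 1:50) {
    cc <- simulate_glmm_counts(base, beta, 0.3, 10000, 1000 + r)
    res <- presence_filter(cc, test_clusters_glmm(filter_clusters(cc)))
    i <- match("c1", res$cluster)
    est <- c(est, res$estimate[i])
    det <- c(det, res$differential[i])
  }
  expect_lt(abs(mean(est) - log(2)), 0.1)
  expect_gte(mean(det), 0.8)
})

test_that("GLMM matches plain logistic regression when variance is nil", {
  # balanced toy data, 2 samples per group, no overdispersion
  counts <- matrix(c(30L, 32L, 61L, 59L), 1, 4,
                   dimnames = list("c", paste0("s", 1:4)))
  totals <- setNames(rep(1000L, 4), colnames(counts))
  g <- rep(c("A", "B"), each = 2)
  cc <- cluster_counts(counts, totals, g)
  res <- test_clusters_glmm(cc)
  glmfit <- stats::glm(cbind(y, n - y) ~ g,
                       data = data.frame(y = counts[1, ], n = totals, g = g),
                       family = stats::binomial())
  z_glm <- summary(glmfit)$coefficients[2, 3]
  z_glmm <- res$estimate[1] / res$se[1]
  expect_lt(abs(z_glm - z_glmm), 1e-3)
})

test_that("presence criterion finalizes the differential flag", {
  counts <- rbind(hit = c(rep(50L, 9), 0L, 0L, rep(10L, 11)),
                  sparse = c(rep(50L, 7), rep(0L, 4), rep(10L, 7),
                             rep(0L, 4)))
  colnames(counts) <- paste0("s", 1:22)
  cc <- cluster_counts(counts, setNames(rep(1000L, 22), colnames(counts)),
                       rep(c("CON", "MS"), each = 11))
  res <- test_clusters_glmm(cc)
  res$significant <- c(TRUE, TRUE)  # isolate the presence logic
  out_either <- presence_filter(cc, res, mode = "either")
  out_each <- presence_filter(cc, res, mode = "each")
  # hit: present 9/11 (81.8%) in CON, 11/11 in MS -> flagged in both modes
  expect_true(out_either$differential[1])
  expect_true(out_each$differential[1])
  # sparse: 7/11 (63.6%) in both groups -> removed
  expect_false(out_either$differential[2])
  # threshold 0 reduces to significance alone
  out0 <- presence_filter(cc, res, threshold = 0)
  expect_equal(out0$differential, res$significant)
  # invariant: no differential flag without significance
  res2 <- test_clusters_glmm(cc)
  out2 <- presence_filter(cc, res2)
  expect_true(all(!out2$differential | out2$significant))
})

test_that("multi-group omnibus detects a single-group spike", {
  groups <- rep(c("CON", "MS", "CD"), times = c(11, 11, 8))
  base <- c(0.05, 0.10, 0.15)
  hits <- nulls <- logical(0)
  for (r in 1:15) {
    set.seed(300 + r)
    counts <- matrix(0L, 3, 30,
                     dimnames = list(paste0("c", 1:3), paste0("s", 1:30)))
    for (k in 1:3) for (s in 1:30) {
      eta <- qlogis(base[k]) +
        (if (k == 1 && groups[s] == "CD") log(2) else 0) + rnorm(1, 0, 0.3)
      counts[k, s] <- rbinom(1, 10000, plogis(eta))
    }
    cc <- cluster_counts(counts, setNames(rep(10000L, 30), colnames(counts)),
                         groups)
    res <- test_multi_group(cc)
    hits <- c(hits, res$omnibus$significant[1])
    pw <- res$pairwise
    cm <- pw[pw$cluster == "c1" & pw$contrast == "MS vs CON", ]
    nulls <- c(nulls, cm$p < 0.05)
  }
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(nulls), 0.2)   # CON-vs-MS contrast stays null-ish
  # three identical groups -> omnibus p near 1
  counts <- matrix(rep(c(100L, 50L, 20L), 30), 3, 30,
                   dimnames = list(paste0("c", 1:3), paste0("s", 1:30)))
  cc0 <- cluster_counts(counts, setNames(rep(1000L, 30), colnames(counts)),
                        groups)
  res0 <- test_multi_group(cc0)
  expect_true(all(res0$omnibus$p > 0.99))
  # two-group input reduces to test_clusters_glmm
  cc2 <- simulate_glmm_counts(c(0.1, 0.2), c(0, 0), 0.2, 1000, 77)
  r2 <- test_multi_group(cc2)
  expect_identical(r2$omnibus$p, test_clusters_glmm(cc2)$p)
})

test_that("discriminating markers rank shifted markers first", {
  set.seed(5)
  n_in <- 400; n_out <- 4000
  expr <- rbind(
    cbind(rnorm(n_in, 4, 0.5), rnorm(n_in, 2, 0.75)),
    cbind(rnorm(n_out, 2, 0.5), rnorm(n_out, 2, 0.75)))
  colnames(expr) <- c("shifted", "flat")
  labels <- rep(c("c1", "rest"), c(n_in, n_out))
  md <- discriminating_markers(expr, labels, "c1", seed = 3)
  expect_equal(md$marker[1], "shifted")
  expect_gte(abs(md$d[1]), 2)
  expect_lt(abs(md$d[md$marker == "flat"]), 0.2)
  expect_equal(attr(md, "n_used"), 256)
  # n_subsample >= cluster size: all events, deterministic
  md_all <- discriminating_markers(expr, labels, "c1", n_subsample = 1000,
                                   seed = 1)
  md_all2 <- discriminating_markers(expr, labels, "c1", n_subsample = 1000,
                                    seed = 99)
  expect_equal(attr(md_all, "n_used"), n_in)
  expect_identical(md_all$d, md_all2$d)
  expect_error(discriminating_markers(expr, labels, "nope"), "empty")
})

test_that("BH adjustment matches the hand-computed and brute-force oracle", {
  # hand-computed step-up example
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04))$p_adj, rep(0.04, 4))
  expect_equal(adjust_bh(0.03)$p_adj, 0.03)
  expect_equal(adjust_bh(c(1, 1, 1))$p_adj, c(1, 1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA handling: excluded from the family
  r <- adjust_bh(c(0.01, NA, 0.04))
  expect_true(is.na(r$p_adj[2]))
  expect_equal(r$p_adj[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  # brute-force step-up oracle over all length <= 8 grids
  brute_bh <- function(p) {
    m <- length(p); o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
      min(1, min(ps[i:m] * m / (i:m))), numeric(1))
    out <- numeric(m); out[o] <- adj; out
  }
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.8, 1)
  set.seed(8)
  for (len in 1:8) {
    for (rep in 1:30) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(adjust_bh(p)$p_adj, brute_bh(p))
      expect_equal(adjust_bh(p)$p_adj, p.adjust(p, "BH"))
    }
  }
})
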