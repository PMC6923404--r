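# Hand-built run: beads at known intensity over a 600 s acquisition plus
# DNA-positive cells, with an imposed multiplicative sensitivity profile.
drifting_run <- function(decay_to = 1, n_bead_per_iv = 200, n_cell = 600,
                         bead_level = 2000, seed = 11, run_t = 600,
                         jitter = 0) {
  set.seed(seed)
  n_iv <- run_t / 100
  tb <- sort(runif(n_bead_per_iv * n_iv, 0, run_t))
  tc <- sort(runif(n_cell, 0, run_t))
  mk_bead <- function(t) bead_level * (1 + jitter * rnorm(length(t)))
  fac <- function(t) 1 + (decay_to - 1) * t / run_t
  tt <- sort(c(tb, tc))
  is_bead <- tt %in% tb
  n <- length(tt)
  vals <- list(
    M1 = ifelse(is_bead, 0, 150) * fac(tt),
    BC1 = ifelse(is_bead, 0, 250) * fac(tt),
    Bead1 = ifelse(is_bead, mk_bead(tt), 0) * fac(tt),
    Bead2 = ifelse(is_bead, mk_bead(tt), 0) * fac(tt),
    DNA1 = ifelse(is_bead, 0, 600) * fac(tt),
    DNA2 = ifelse(is_bead, 0, 600) * fac(tt),
    EL = rep(30, n), Time = tt)
  list(et = manual_event_table(vals), is_bead = is_bead, fac = fac(tt))
}

test_that("bead normalization is the identity under flat drift", {
  run <- drifting_run(decay_to = 1)
  out <- normalize_beads(run$et)
  expect_true(all(out$kept))
  expect_equal(out$events$values, run$et$values, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("bead normalization removes an imposed 1.0 -> 0.5 decay", {
  run <- drifting_run(decay_to = 0.5, jitter = 0.02)
  iv_median <- function(et, flags) {
    iv <- pmax(1, ceiling(event_time(et) / 100))
    vapply(split(which(flags), iv[flags]), function(i)
      median(et$values[i, "Bead1"]), numeric(1))
  }
  pre <- iv_median(run$et, run$is_bead)
  expect_gt(sd(pre) / mean(pre), 0.15)
  out <- normalize_beads(run$et)
  post <- iv_median(out$events, out$is_bead)
  expect_lt(sd(post) / mean(post), 0.02)
  # cells are corrected too: M1 was constant before drift
  cells <- out$events$values[!out$is_bead, "M1"]
  expect_lt(sd(cells) / mean(cells), 0.02)
})

test_that("intervals with fewer than 50 beads per 100 s are excluded", {
  run <- drifting_run(decay_to = 1)
  # thin interval 3 (200-300 s) down to 30 beads
  iv <- pmax(1, ceiling(event_time(run$et) / 100))
  bead3 <- which(run$is_bead & iv == 3)
  drop <- bead3[-seq_len(30)]
  et <- cytoda:::subset_events(run$et, setdiff(seq_along(iv), drop))
  out <- normalize_beads(et)
  expect_true(out$report$excluded[3])
  expect_equal(out$report$n_beads[3], 30)
  kept_iv <- pmax(1, ceiling(event_time(run$et)[setdiff(seq_along(iv), drop)] / 100))
  expect_equal(sum(!out$kept), sum(kept_iv == 3))
  expect_false(any(pmax(1, ceiling(event_time(out$events) / 100)) == 3))
})

test_that("singlet gating follows DNA, event length and bead rules", {
  vals <- list(M1 = c(100, 100, 100, 100, 0),
               BC1 = c(10, 10, 10, 10, 0),
               Bead1 = c(0, 0, 0, 0, 3000),
               Bead2 = c(0, 0, 0, 0, 3000),
               DNA1 = c(600, 600, 600, 2, 0),
               DNA2 = c(600, 600, 600, 2, 0),
               EL = c(30, 9, 160, 30, 20),
               Time = c(1, 2, 3, 4, 5))
  et <- manual_event_table(vals)
  out <- gate_singlets(et)
  reason <- attr(out, "gate_reason")
  expect_equal(as.character(reason),
               c("kept", "gate", "gate", "gate", "bead"))
  expect_equal(nrow(out$values), 1)
  # all-in-gate table passes unchanged
  ok <- manual_event_table(lapply(vals, `[`, 1))
  out2 <- gate_singlets(ok)
  expect_equal(out2$values, ok$values, ignore_attr = TRUE)
})

test_that("barcode thresholds split on/off and warn on unimodal channels", {
  set.seed(3)
  n <- 2000
  on <- rlnorm(n, log(200), 0.3)
  off <- rlnorm(n, log(1), 0.8)
  y <- asinh(c(on, off) / 5)
  vals <- list(BC1 = c(on, off), BC2 = rep(2, 2 * n),
               DNA1 = rep(600, 2 * n), DNA2 = rep(600, 2 * n),
               Bead1 = rep(0, 2 * n), EL = rep(30, 2 * n),
               Time = seq_len(2 * n) / 100)
  et <- manual_event_table(vals)
  codes <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                  dimnames = list(c("A", "B"), c("BC1", "BC2")))
  scheme <- barcode_scheme(codes)
  expect_warning(cut <- estimate_barcode_thresholds(et, scheme), "BC2")
  expect_gt(cut[["BC1"]], median(asinh(off / 5)))
  expect_lt(cut[["BC1"]], median(asinh(on / 5)))
  # threshold moves monotonically when intensities are scaled up
  et2 <- et; et2$values[, "BC1"] <- et2$values[, "BC1"] * 4
  cut2 <- suppressWarnings(estimate_barcode_thresholds(et2, scheme))
  expect_gt(cut2[["BC1"]], cut[["BC1"]])
})

test_that("debarcoding assigns exact patterns and rejects doublet patterns", {
  codes <- matrix(c(1, 0, 1,
                    0, 1, 1,
                    1, 1, 0), 3, 3, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"),
                                  c("BC1", "BC2", "BC3")))
  scheme <- barcode_scheme(codes)
  # events: exact A pattern, all-on, all-off, weakly separated A
  # (on-values just above, off-value just below the asinh(50/5) cutoff)
  bc <- rbind(c(300, 0.5, 300),
              c(300, 300, 300),
              c(0.5, 0.5, 0.5),
              c(51, 49, 51))
  vals <- list(BC1 = bc[, 1], BC2 = bc[, 2], BC3 = bc[, 3],
               DNA1 = rep(600, 4), DNA2 = rep(600, 4),
               Bead1 = rep(0, 4), EL = rep(30, 4), Time = 1:4)
  et <- manual_event_table(vals)
  cutoffs <- setNames(rep(asinh(50 / 5), 3), colnames(codes))
  db <- debarcode(et, scheme, cutoffs)
  expect_equal(db$sample_id, c("A", NA, NA, NA))
  # the weakly separated event fails the delta filter but passes with delta 0
  db0 <- debarcode(et, scheme, cutoffs, delta = 0)
  expect_equal(db0$sample_id[4], "A")
})

test_that("debarcoding reaches 99% accuracy on synthetic pooled data", {
  exp <- tiny_experiment(n_events = 2000, seed = 7)
  pp <- preprocess_pipeline(exp$sim$events, exp$scheme,
                            spillover = exp$truth$spillover)
  tr <- exp$sim$truth[pp$index, ]
  nd <- !tr$is_doublet & !tr$is_bead
  acc <- mean(!is.na(pp$sample_id[nd]) & pp$sample_id[nd] == tr$sample_id[nd])
  cross <- mean(!is.na(pp$sample_id[nd]) &
                  pp$sample_id[nd] != tr$sample_id[nd])
  expect_gte(acc, 0.99)
  expect_lte(cross, 0.005)
})

test_that("debarcoding is permutation-equivariant in sample labels", {
  exp <- tiny_experiment(n_events = 300, seed = 19)
  et <- exp$sim$events
  cut <- estimate_barcode_thresholds(et, exp$scheme)
  db1 <- debarcode(et, exp$scheme, cut)
  perm <- rev(rownames(exp$scheme$codes))
  codes2 <- exp$scheme$codes
  rownames(codes2) <- NULL
  codes2 <- codes2[match(perm, rownames(exp$scheme$codes)), ]
  rownames(codes2) <- perm
  scheme2 <- barcode_scheme(codes2, min_hamming = 1)
  db2 <- debarcode(et, scheme2, cut)
  expect_identical(db1$sample_id, db2$sample_id)
})

test_that("spillover estimation recovers the generating matrix", {
  S <- default_spillover()
  ss <- simulate_single_stained(S, n = 2000, seed = 31)
  S_hat <- estimate_spillover(ss)
  expect_lt(max(abs(unclass(S_hat) - unclass(S))), 0.005)
  # zero off-target signal gives the identity
  ch <- c("A", "B")
  clean <- lapply(setNames(ch, ch), function(c0) {
    m <- matrix(0, 100, 2, dimnames = list(NULL, ch)); m[, c0] <- 500; m
  })
  expect_equal(unclass(estimate_spillover(clean)), diag(2),
               ignore_attr = TRUE)
  # negative/epsilon entries clip to [0, 1)
  noisy <- clean
  noisy$A[, "B"] <- -3
  S2 <- estimate_spillover(noisy)
  expect_gte(S2["A", "B"], 0)
})

test_that("NNLS compensation solves the printed 2-channel example", {
  S <- spillover_matrix(matrix(c(1, 0.1, 0, 1), 2, byrow = TRUE,
                               dimnames = list(c("A", "B"), c("A", "B"))))
  ch <- data.frame(name = c("A", "B", "Time"), metal = c("a", "b", "Time"),
                   marker = c("A", "B", ""),
                   role = c("marker", "marker", "time"),
                   lineage = FALSE, embedding = FALSE)
  et <- event_table(matrix(c(100, 110, 0,
                             0, 5, 1), 2, 3, byrow = TRUE,
                           dimnames = list(NULL, ch$name)), ch)
  out <- compensate(et, S)
  expect_equal(out$values[1, c("A", "B")], c(A = 100, B = 100),
               tolerance = 1e-9)
  # x >= 0 is never violated
  expect_equal(out$values[2, c("A", "B")], c(A = 0, B = 5),
               tolerance = 1e-9)
  # S = I is the identity
  I2 <- spillover_matrix(diag(2) |>
                           (\(m) {dimnames(m) <- list(c("A", "B"),
                                                      c("A", "B")); m})())
  expect_equal(compensate(et, I2)$values, et$values, ignore_attr = TRUE)
})

test_that("compensation recovers pre-spill signal on synthetic data", {
  exp <- tiny_experiment(n_events = 2000, seed = 23)
  sim <- exp$sim
  comp <- compensate(sim$events, exp$truth$spillover)
  mk <- channels_by_role(sim$events, "marker")
  rec <- comp$values[, mk] / sim$drift_factor
  clean <- sim$clean[, mk]
  sel <- clean >= 25
  expect_lt(median(abs(rec[sel] - clean[sel]) / clean[sel]), 0.02)
})

test_that("arcsinh transform follows the closed form and guards re-entry", {
  vals <- list(M1 = c(0, 5, 10), BC1 = c(0, 1, 2), DNA1 = c(1, 2, 3),
               DNA2 = c(1, 2, 3), Bead1 = c(0, 0, 0), EL = c(30, 30, 30),
               Time = c(1, 2, 3))
  et <- manual_event_table(vals)
  out <- transform_arcsinh(et, cofactor = 5)
  expect_equal(out$values[, "M1"], asinh(c(0, 5, 10) / 5))
  expect_equal(unname(out$values[2, "M1"]), 0.881374, tolerance = 1e-6)
  expect_equal(unname(out$values[1, "M1"]), 0)
  # event length and time untouched
  expect_equal(out$values[, "EL"], vals$EL)
  expect_true(all(diff(out$values[, "M1"]) > 0))  # strict monotonicity
  expect_error(transform_arcsinh(out), "already")
})

test_that("pipeline conserves events across the five outcomes", {
  exp <- tiny_experiment(n_events = 800, seed = 29)
  pp <- preprocess_pipeline(exp$sim$events, exp$scheme,
                            spillover = exp$truth$spillover)
  expect_equal(sum(pp$counts[-1]), pp$counts[["input"]])
  expect_equal(pp$counts[["input"]], nrow(exp$sim$events$values))
})
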