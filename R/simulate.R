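#' Population specification for the synthetic generator
#'
#' A cell population is a lognormal intensity model per marker: positive
#' markers are drawn lognormal around `marker_medians`, negative markers from
#' a near-zero zero-inflated lognormal (dropout probability `dropout`).
#'
#' @param name population name.
#' @param marker_medians named non-negative vector, median ion count per
#'   marker channel.
#' @param marker_cv named positive vector, lognormal coefficient of variation
#'   per marker.
#' @param positivity_mask named logical vector; `FALSE` markers get the
#'   zero-inflated near-zero distribution.
#' @param dropout zero-inflation probability for negative markers
#'   (default 0.3).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(name, marker_medians, marker_cv, positivity_mask,
                            dropout = 0.3) {
  stopifnot(length(marker_medians) == length(marker_cv),
            length(marker_medians) == length(positivity_mask))
  if (any(marker_medians < 0)) stop("marker medians must be >= 0")
  if (any(marker_cv <= 0)) stop("marker CVs must be > 0")
  structure(list(name = name, marker_medians = marker_medians,
                 marker_cv = marker_cv, positivity_mask = positivity_mask,
                 dropout = dropout),
            class = "population_spec")
}

#' Sample specification for the synthetic generator
#'
#' @param sample_id sample name.
#' @param group group label (e.g. `"CON"`, `"MS"`, `"CD"`).
#' @param barcode_code binary vector over the barcode channels.
#' @param population_proportions named simplex vector over the populations.
#' @param n_events number of cell events to generate for this sample.
#' @return object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, group, barcode_code,
                        population_proportions, n_events) {
  if (n_events <= 0) stop("n_events must be positive")
  if (length(population_proportions) &&
      abs(sum(population_proportions) - 1) > 1e-9)
    stop("population proportions must sum to 1")
  structure(list(sample_id = sample_id, group = group,
                 barcode_code = as.integer(barcode_code),
                 population_proportions = population_proportions,
                 n_events = as.integer(n_events)),
            class = "sample_spec")
}

#' Full generating specification for a synthetic experiment
#'
#' Bundles the panel, samples, populations, spillover, drift profile and
#' nuisance-event fractions that define one simulated pooled acquisition.
#' This object *is* the ground truth against which the pipeline is tested.
#'
#' @param panel panel definition data frame (see [default_panel()]).
#' @param samples list of [sample_spec()] objects.
#' @param populations list of [population_spec()] objects.
#' @param spillover a [spillover_matrix()] applied as `observed = true %*% S`,
#'   or `NULL` for identity.
#' @param drift_profile data frame with columns `t` (fraction of run time,
#'   0..1) and `factor` (>0); sensitivity is piecewise-linear between the
#'   knots and multiplies every ion-count channel.
#' @param doublet_fraction fraction (of cell events) of channel-wise-summed
#'   random cell pairs added to the run.
#' @param bead_fraction fraction of EQ-bead events added to the run.
#' @param barcode_on_median,barcode_off_median median counts of "on" / "off"
#'   barcode channels (defaults 200 / 1).
#' @param acquisition_rate events per second, used to lay events out in time.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(panel, samples, populations,
                             spillover = NULL,
                             drift_profile = data.frame(t = c(0, 1),
                                                        factor = c(1, 1)),
                             doublet_fraction = 0.02,
                             bead_fraction = 0.02,
                             barcode_on_median = 200,
                             barcode_off_median = 1,
                             acquisition_rate = 350,
                             seed = 1L) {
  stopifnot(doublet_fraction >= 0, doublet_fraction < 1, bead_fraction >= 0)
  if (any(drift_profile$factor <= 0))
    stop("drift sensitivity multiplier must be > 0 everywhere")
  pop_names <- vapply(populations, `[[`, "", "name")
  for (s in samples) {
    if (length(s$population_proportions) &&
        !all(names(s$population_proportions) %in% pop_names))
      stop("sample ", s$sample_id, " references unknown populations")
  }
  structure(list(panel = panel, samples = samples, populations = populations,
                 spiked_effects = list(), spillover = spillover,
                 drift_profile = drift_profile,
                 doublet_fraction = doublet_fraction,
                 bead_fraction = bead_fraction,
                 barcode_on_median = barcode_on_median,
                 barcode_off_median = barcode_off_median,
                 acquisition_rate = acquisition_rate,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Default 35-marker CyTOF panel
#'
#' A Panel-A-like layout: 35 marker channels (14 of them flagged for
#' lineage meta-clustering, all flagged for embedding), 6 CD45 barcode
#' channels, 5 EQ-bead channels, two DNA intercalator channels, event
#' length and time.
#'
#' @return panel definition data frame.
#' @export
default_panel <- function() {
  lineage <- c("HLA-DR", "CD19", "CD44", "CD4", "CD11c", "CD16", "CD3",
               "CD56", "CD14", "CD8a", "Tbet", "CD33", "CCR2", "CD11b")
  functional <- c("CD45", "CD62L", "NFAT1", "ADRP", "CCR7", "IRF4", "IRF8",
                  "IL10", "CCL2", "IFNg", "TNFa", "CD38", "MIPb", "CD172a",
                  "PDL1", "GATA6", "GMCSF", "GLUT1", "IL4", "IL8", "CD95")
  markers <- c(lineage, functional)
  metals <- paste0(141:175, rep(c("Nd", "Sm", "Gd", "Dy", "Er", "Yb", "Lu"),
                                each = 5))
  bc <- paste0("BC", 1:6)
  bead <- paste0("Bead", 1:5)
  data.frame(
    name = c(markers, bc, bead, "DNA1", "DNA2", "Event_length", "Time"),
    metal = c(metals, "89Y", "113In", "115In", "195Pt", "196Pt", "198Pt",
              "140Ce", "151Eu", "153Eu", "165Ho", "175Lu",
              "191Ir", "193Ir", "Event_length", "Time"),
    marker = c(markers, rep("CD45-BC", 6), rep("EQ-bead", 5),
               "DNA", "DNA", "", ""),
    role = c(rep("marker", length(markers)), rep("barcode", 6),
             rep("bead", 5), "dna", "dna", "event_length", "time"),
    lineage = c(markers %in% lineage, rep(FALSE, 15)),
    embedding = c(rep(TRUE, length(markers)), rep(FALSE, 15)),
    stringsAsFactors = FALSE)
}

# Positivity patterns of the 14 default populations over the 14 lineage
# markers: a constant-weight cyclic code built from the perfect difference
# set {0, 1, 4, 6} mod 14, so any two populations share at most one
# positive marker (pairwise Hamming distance 6).  This mirrors the strong
# separation of major PBMC lineages on lineage markers; subtler phenotypes
# belong to the second clustering level.  Names are mnemonic archetypes.
default_population_patterns <- function(lineage_markers) {
  pops <- c("B", "CD4T_naive", "CD4T_mem", "CD8T_naive", "CD8T_eff",
            "DNT", "NK_dim", "NK_bright", "Mono_class", "Mono_int",
            "Mono_nonclass", "mDC", "pDC", "Baso_like")
  offsets <- c(0, 1, 4, 6)
  out <- lapply(seq_along(pops) - 1L, function(i)
    lineage_markers[(i + offsets) %% 14L + 1L])
  names(out) <- pops
  out
}

#' Default 14 cell populations
#'
#' Immune-lineage-like archetypes (B / T / NK / monocyte / DC subsets) with
#' positivity patterns over the 14 lineage markers drawn from a
#' constant-weight cyclic code (any two populations share at most one
#' positive lineage marker, pairwise Hamming distance >= 6 — the strong
#' separation major PBMC lineages show on lineage panels), plus
#' deterministic functional-marker positivity so the second clustering
#' level has recoverable structure too.  Positive markers get medians of
#' 150-360 counts (CV 0.5), negative markers a zero-inflated median of 1
#' count (CV 1, dropout 0.3).
#'
#' @param panel panel definition (default [default_panel()]).
#' @return list of [population_spec()] objects.
#' @export
default_populations <- function(panel = default_panel()) {
  markers <- panel$name[panel$role == "marker"]
  functional <- panel$name[panel$role == "marker" & !panel$lineage]
  pats <- default_population_patterns(panel$name[panel$lineage])
  pops <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    pos_fun <- functional[(((i - 1) * 3 + 0:4) %% length(functional)) + 1]
    pos <- markers %in% c(pats[[i]], pos_fun)
    med <- ifelse(pos, 150 + 30 * ((i + seq_along(markers)) %% 8), 1)
    cv <- ifelse(pos, 0.5, 1.0)
    pops[[i]] <- population_spec(names(pats)[i],
                                 setNames(med, markers),
                                 setNames(cv, markers),
                                 setNames(pos, markers))
  }
  pops
}

#' Default barcode code book
#'
#' All twenty 3-of-6 codes plus two distinct 4-of-6 codes, covering 22
#' samples over 6 barcode channels.  Note that any 4-of-6 code is at
#' Hamming distance 1 from the 3-of-6 codes it contains, so this code book
#' is only Hamming-1 separated; exact-pattern Boolean matching still
#' deconvolutes it cleanly because channel misclassification is rare at
#' the default on/off separation.
#'
#' @param sample_ids character vector of at most 22 sample ids.
#' @return a [barcode_scheme()] (with `min_hamming = 1`).
#' @export
default_barcode_scheme <- function(sample_ids) {
  k3 <- t(combn(6, 3))
  codes <- matrix(0L, nrow = 22, ncol = 6)
  for (i in seq_len(20)) codes[i, k3[i, ]] <- 1L
  codes[21, c(1, 2, 3, 4)] <- 1L
  codes[22, c(3, 4, 5, 6)] <- 1L
  if (length(sample_ids) > 22) stop("default code book covers 22 samples")
  codes <- codes[seq_along(sample_ids), , drop = FALSE]
  rownames(codes) <- sample_ids
  colnames(codes) <- paste0("BC", 1:6)
  barcode_scheme(codes, min_hamming = 1L)
}

#' Default spillover matrix over marker channels
#'
#' Spill from each marker channel into its neighbours in mass order:
#' 3\% into the next-higher channel (M+1 impurity), 1\% into the
#' next-lower (M-1).
#'
#' @param panel panel definition.
#' @param up,down spill fractions into the adjacent channels.
#' @return a [spillover_matrix()].
#' @export
default_spillover <- function(panel = default_panel(), up = 0.03,
                              down = 0.01) {
  ch <- panel$name[panel$role == "marker"]
  S <- diag(length(ch))
  for (i in seq_along(ch)) {
    if (i < length(ch)) S[i, i + 1] <- up
    if (i > 1) S[i, i - 1] <- down
  }
  dimnames(S) <- list(ch, ch)
  spillover_matrix(S)
}

#' Default synthetic experiment matching the emulated study design
#'
#' 11 CON + 11 MS samples (optionally + 8 CD), 10,000 cells per sample, 14
#' populations over a 35-marker panel, 6-channel barcoding, 2\% beads, 2\%
#' doublets, adjacent-channel spillover, and a linear sensitivity decline
#' from 1.0 to 0.7 over the run.  Sample-to-sample composition varies by a
#' lognormal perturbation (sd 0.15 on the log scale) of the base
#' proportions — the "biological" overdispersion the GLMM absorbs.
#'
#' @param n_per_group named integer vector of samples per group.
#' @param n_events cells per sample.
#' @param prop_noise_sd sd of the per-sample log-proportion perturbation.
#' @param drift_to final relative sensitivity at the end of the run.
#' @param seed integer seed.
#' @param ... passed on to [simulation_truth()].
#' @return a `simulation_truth`.
#' @export
default_truth <- function(n_per_group = c(CON = 11, MS = 11),
                          n_events = 10000, prop_noise_sd = 0.15,
                          drift_to = 0.7, seed = 1L, ...) {
  panel <- default_panel()
  pops <- default_populations(panel)
  base <- c(8, 15, 12, 8, 7, 3, 8, 3, 14, 5, 4, 4, 2, 7) / 100
  names(base) <- vapply(pops, `[[`, "", "name")
  groups <- rep(names(n_per_group), n_per_group)
  ids <- paste0(groups, "_", unlist(lapply(n_per_group, seq_len)))
  scheme <- default_barcode_scheme(ids)
  set.seed(child_seed(seed, "design"))
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pr <- base * exp(rnorm(length(base), 0, prop_noise_sd))
    pr <- pr / sum(pr)
    samples[[i]] <- sample_spec(ids[i], groups[i], scheme$codes[i, ],
                                pr, n_events)
  }
  simulation_truth(panel, samples, pops,
                   spillover = default_spillover(panel),
                   drift_profile = data.frame(t = c(0, 1),
                                              factor = c(1, drift_to)),
                   seed = seed, ...)
}

#' Spike a differential-abundance effect into the truth
#'
#' For every sample of the target group, the population's proportion `p` is
#' moved to `plogis(qlogis(p) + log_odds_shift)` and the remaining
#' proportions rescaled so each sample stays on the simplex.  The effect is
#' recorded in `spiked_effects`.
#'
#' @param truth a `simulation_truth`.
#' @param population population name to spike.
#' @param group group whose samples receive the shift.
#' @param log_odds_shift shift on the log-odds scale (e.g. `log(2)` for an
#'   odds ratio of 2).
#' @return the modified `simulation_truth`.
#' @export
spike_differential <- function(truth, population, group, log_odds_shift) {
  pop_names <- vapply(truth$populations, `[[`, "", "name")
  if (!population %in% pop_names)
    stop("unknown population: ", population)
  for (i in seq_along(truth$samples)) {
    s <- truth$samples[[i]]
    if (s$group != group) next
    p <- s$population_proportions[[population]]
    p2 <- plogis(qlogis(p) + log_odds_shift)
    if (p < 1 && p > 0) {
      rest <- setdiff(names(s$population_proportions), population)
      s$population_proportions[rest] <-
        s$population_proportions[rest] * (1 - p2) / (1 - p)
    }
    s$population_proportions[[population]] <- p2
    truth$samples[[i]] <- s
  }
  truth$spiked_effects <- c(truth$spiked_effects,
                            list(list(population = population, group = group,
                                      log_odds_shift = log_odds_shift)))
  truth
}

# Draw a block of lognormal marker intensities for one population.
draw_population_block <- function(pop, markers, n) {
  out <- matrix(0, nrow = n, ncol = length(markers),
                dimnames = list(NULL, markers))
  for (j in seq_along(markers)) {
    m <- markers[j]
    med <- pop$marker_medians[[m]]
    cv <- pop$marker_cv[[m]]
    sdlog <- sqrt(log(1 + cv^2))
    v <- if (med > 0) rlnorm(n, log(med), sdlog) else numeric(n)
    if (!pop$positivity_mask[[m]] && pop$dropout > 0)
      v[runif(n) < pop$dropout] <- 0
    out[, j] <- v
  }
  out
}

#' Simulate a pooled multiplexed acquisition
#'
#' Generates, per sample, multinomially-assigned cell events with lognormal
#' marker intensities, barcode-channel signal according to the sample's
#' code, positive DNA and a uniform event length; adds EQ-bead events
#' (positive on all bead channels, DNA-negative) and doublets (channel-wise
#' sums of two random cell events); lays all events out in acquisition
#' time, applies the sensitivity-drift profile multiplicatively to every
#' ion-count channel, and mixes channels through the spillover matrix
#' (`observed = true %*% S`).  Fully reproducible from `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @return list with `events` (a time-sorted raw `event_table`), `truth`
#'   (data frame with per-event `sample_id`, `population`, `is_bead`,
#'   `is_doublet`), `clean` (the pre-drift, pre-spillover intensity matrix,
#'   for recovery testing), `drift_factor` (realized sensitivity multiplier
#'   per event), and `spec` (the generating truth).
#' @export
simulate_experiment <- function(truth) {
  panel <- truth$panel
  set.seed(child_seed(truth$seed, "events"))
  markers <- panel$name[panel$role == "marker"]
  bc_ch <- panel$name[panel$role == "barcode"]
  bead_ch <- panel$name[panel$role == "bead"]
  dna_ch <- panel$name[panel$role == "dna"]
  el_ch <- panel$name[panel$role == "event_length"]
  time_ch <- panel$name[panel$role == "time"]
  all_ch <- panel$name
  pop_names <- vapply(truth$populations, `[[`, "", "name")

  blocks <- list(); info <- list()
  for (s in truth$samples) {
    if (length(s$population_proportions) == 0) next
    counts <- as.vector(rmultinom(1, s$n_events, s$population_proportions))
    for (k in seq_along(counts)) {
      nk <- counts[k]
      if (nk == 0) next
      pop <- truth$populations[[match(names(s$population_proportions)[k],
                                      pop_names)]]
      m <- matrix(0, nrow = nk, ncol = length(all_ch),
                  dimnames = list(NULL, all_ch))
      m[, markers] <- draw_population_block(pop, markers, nk)
      on <- s$barcode_code == 1L
      sd_on <- sqrt(log(1 + 0.3^2)); sd_off <- sqrt(log(1 + 1^2))
      for (j in seq_along(bc_ch)) {
        if (on[j]) {
          m[, bc_ch[j]] <- rlnorm(nk, log(truth$barcode_on_median), sd_on)
        } else {
          v <- rlnorm(nk, log(truth$barcode_off_median), sd_off)
          v[runif(nk) < 0.5] <- 0
          m[, bc_ch[j]] <- v
        }
      }
      for (d in dna_ch) m[, d] <- rlnorm(nk, log(600), sqrt(log(1 + 0.25^2)))
      m[, el_ch] <- floor(runif(nk, 15, 81))
      blocks[[length(blocks) + 1L]] <- m
      info[[length(info) + 1L]] <-
        data.frame(sample_id = rep(s$sample_id, nk),
                   population = rep(pop$name, nk),
                   is_bead = FALSE, is_doublet = FALSE,
                   stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(blocks)) do.call(rbind, blocks)
           else matrix(0, 0, length(all_ch), dimnames = list(NULL, all_ch))
  cinfo <- if (length(info)) do.call(rbind, info)
           else data.frame(sample_id = character(), population = character(),
                           is_bead = logical(), is_doublet = logical())
  n_cells <- nrow(cells)

  n_doub <- round(truth$doublet_fraction * n_cells)
  if (n_doub > 0) {
    i1 <- sample.int(n_cells, n_doub, replace = TRUE)
    i2 <- sample.int(n_cells, n_doub, replace = TRUE)
    doub <- cells[i1, , drop = FALSE] + cells[i2, , drop = FALSE]
    dinfo <- data.frame(sample_id = NA_character_, population = NA_character_,
                        is_bead = FALSE, is_doublet = TRUE,
                        stringsAsFactors = FALSE)[rep(1, n_doub), ]
  } else {
    doub <- cells[0, , drop = FALSE]; dinfo <- cinfo[0, ]
  }

  n_bead <- round(truth$bead_fraction * n_cells)
  if (n_bead > 0) {
    beads <- matrix(0, nrow = n_bead, ncol = length(all_ch),
                    dimnames = list(NULL, all_ch))
    for (b in bead_ch)
      beads[, b] <- rlnorm(n_bead, log(2000), sqrt(log(1 + 0.2^2)))
    beads[, el_ch] <- floor(runif(n_bead, 10, 31))
    binfo <- data.frame(sample_id = NA_character_, population = NA_character_,
                        is_bead = TRUE, is_doublet = FALSE,
                        stringsAsFactors = FALSE)[rep(1, n_bead), ]
  } else {
    beads <- cells[0, , drop = FALSE]; binfo <- cinfo[0, ]
  }

  X <- rbind(cells, doub, beads)
  tr <- rbind(cinfo, dinfo, binfo)
  n <- nrow(X)
  if (n > 0) {
    perm <- sample.int(n)
    X <- X[perm, , drop = FALSE]
    tr <- tr[perm, , drop = FALSE]
    run_t <- n / truth$acquisition_rate
    X[, time_ch] <- sort(runif(n, 0, run_t))
  }
  rownames(tr) <- NULL

  int_ch <- c(markers, bc_ch, bead_ch, dna_ch)
  clean <- X[, int_ch, drop = FALSE]
  fac <- numeric(n)
  if (n > 0) {
    dp <- truth$drift_profile
    run_t <- max(X[, time_ch], 1)
    fac <- approx(dp$t * run_t, dp$factor, xout = X[, time_ch],
                  rule = 2)$y
    X[, int_ch] <- X[, int_ch] * fac
    if (!is.null(truth$spillover)) {
      sch <- rownames(truth$spillover)
      X[, sch] <- X[, sch, drop = FALSE] %*% unclass(truth$spillover)
    }
  }
  et <- event_table(X, panel, transformed = FALSE)
  list(events = et, truth = tr, clean = clean, drift_factor = fac,
       spec = truth)
}

#' Simulate single-stained compensation beads
#'
#' One bead table per channel of the spillover matrix: beads carry signal on
#' their stained channel only, observed through `S`.  Used to exercise
#' [estimate_spillover()].
#'
#' @param S a [spillover_matrix()].
#' @param n beads per channel.
#' @param median,cv lognormal signal model of the stained channel.
#' @param seed integer seed.
#' @return named list (channel -> events x channels matrix).
#' @export
simulate_single_stained <- function(S, n = 2000, median = 500, cv = 0.3,
                                    seed = 1L) {
  set.seed(child_seed(seed, "sstain"))
  ch <- rownames(S)
  out <- setNames(vector("list", length(ch)), ch)
  for (i in seq_along(ch)) {
    m <- matrix(0, nrow = n, ncol = length(ch), dimnames = list(NULL, ch))
    m[, i] <- rlnorm(n, log(median), sqrt(log(1 + cv^2)))
    out[[i]] <- m %*% unclass(S)
  }
  out
}

#' Write the generating truth and design sidecars of a simulation
#'
#' Writes `truth.json` (populations, samples, spiked effects, drift),
#' `panel.csv`, `barcodes.csv`, `metadata.csv` and `spillover.csv` into a
#' directory.
#'
#' @param truth a `simulation_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$panel, file.path(dir, "panel.csv"), row.names = FALSE)
  codes <- do.call(rbind, lapply(truth$samples, `[[`, "barcode_code"))
  bc <- data.frame(sample_id = vapply(truth$samples, `[[`, "", "sample_id"))
  bcn <- truth$panel$name[truth$panel$role == "barcode"]
  bc[bcn] <- codes
  write.csv(bc, file.path(dir, "barcodes.csv"), row.names = FALSE)
  md <- data.frame(sample_id = bc$sample_id,
                   group = vapply(truth$samples, `[[`, "", "group"))
  write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(truth$spillover)) {
    sp <- data.frame(channel = rownames(truth$spillover),
                     unclass(truth$spillover), check.names = FALSE)
    write.csv(sp, file.path(dir, "spillover.csv"), row.names = FALSE)
  }
  js <- list(
    seed = truth$seed,
    doublet_fraction = truth$doublet_fraction,
    bead_fraction = truth$bead_fraction,
    drift_profile = truth$drift_profile,
    spiked_effects = truth$spiked_effects,
    samples = lapply(truth$samples, function(s)
      list(sample_id = s$sample_id, group = s$group, n_events = s$n_events,
           proportions = as.list(s$population_proportions))),
    populations = lapply(truth$populations, function(p)
      list(name = p$name, medians = as.list(p$marker_medians),
           cv = as.list(p$marker_cv),
           positive = as.list(p$positivity_mask))))
  jsonlite::write_json(js, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
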