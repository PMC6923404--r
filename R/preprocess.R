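#' Gating configuration
#'
#' Bundles the thresholds used by bead identification, bead normalization
#' and singlet gating.  DNA bounds are on the arcsinh scale (cofactor
#' `cofactor`); event-length bounds are in pushes.
#'
#' @param dna_low,dna_high DNA-intercalator gate on the arcsinh scale
#'   (defaults 3.5 / 7.5).
#' @param event_length_range numeric length-2, kept event-length range in
#'   pushes (default `c(10, 150)`).
#' @param bead_interval_seconds width of the normalization time interval
#'   (default 100 s).
#' @param min_beads_per_interval minimum beads required per interval;
#'   intervals below it are excluded (default 50).
#' @param bead_threshold arcsinh intensity above which a bead channel counts
#'   as positive (default 3).
#' @param cofactor arcsinh cofactor used for gating (default 5).
#' @return a `gating_config` list.
#' @export
gating_config <- function(dna_low = 3.5, dna_high = 7.5,
                          event_length_range = c(10, 150),
                          bead_interval_seconds = 100,
                          min_beads_per_interval = 50,
                          bead_threshold = 3, cofactor = 5) {
  stopifnot(event_length_range[1] < event_length_range[2],
            bead_interval_seconds > 0, min_beads_per_interval > 0)
  structure(list(dna_low = dna_low, dna_high = dna_high,
                 event_length_range = event_length_range,
                 bead_interval_seconds = bead_interval_seconds,
                 min_beads_per_interval = min_beads_per_interval,
                 bead_threshold = bead_threshold, cofactor = cofactor),
            class = "gating_config")
}

# Logical bead flag: positive on all bead channels and below the DNA gate.
identify_beads <- function(et, gating) {
  bead_ch <- channels_by_role(et, "bead")
  dna_ch <- channels_by_role(et, "dna")
  if (length(bead_ch) == 0) stop("no bead channels in table")
  b <- asinh(et$values[, bead_ch, drop = FALSE] / gating$cofactor)
  d <- asinh(et$values[, dna_ch, drop = FALSE] / gating$cofactor)
  rowSums(b > gating$bead_threshold) == length(bead_ch) &
    apply(d, 1, max) < gating$dna_low
}

#' EQ-bead time-interval normalization
#'
#' Corrects instrument sensitivity drift: bead events are identified
#' (positive on all bead channels, DNA-negative), the run is cut into
#' intervals of `bead_interval_seconds`, and each interval gets a scalar
#' correction factor — the ratio of the global to the interval median bead
#' intensity, averaged over bead channels on the raw count scale.  Factors
#' are linearly interpolated at interval midpoints and applied
#' multiplicatively to every ion-count channel.  Events falling into
#' intervals with fewer than `min_beads_per_interval` beads are dropped and
#' reported.
#'
#' @param et a raw `event_table`.
#' @param gating a [gating_config()].
#' @return list with `events` (normalized table, excluded intervals
#'   removed), `report` (per-interval bead counts, factors and exclusion
#'   flags), `kept` (logical over input events) and `is_bead` (logical over
#'   kept events).
#' @export
normalize_beads <- function(et, gating = gating_config()) {
  validate_event_table(et)
  is_bead <- identify_beads(et, gating)
  if (!any(is_bead))
    stop("no bead events found; check the bead channels and threshold")
  tm <- event_time(et)
  iv <- gating$bead_interval_seconds
  idx <- pmax(1L, ceiling(tm / iv))
  n_iv <- max(idx)
  bead_ch <- channels_by_role(et, "bead")
  bead_vals <- et$values[is_bead, bead_ch, drop = FALSE]
  bead_iv <- idx[is_bead]
  global_med <- apply(bead_vals, 2, median)
  report <- data.frame(interval = seq_len(n_iv),
                       start = (seq_len(n_iv) - 1) * iv,
                       end = seq_len(n_iv) * iv,
                       n_beads = as.vector(tabulate(bead_iv, n_iv)))
  report$excluded <- report$n_beads < gating$min_beads_per_interval
  report$factor <- NA_real_
  for (k in which(!report$excluded)) {
    med_k <- apply(bead_vals[bead_iv == k, , drop = FALSE], 2, median)
    report$factor[k] <- mean(global_med / med_k)
  }
  ok <- !report$excluded
  if (!any(ok)) stop("all intervals excluded; not enough beads")
  mid <- (report$start + report$end) / 2
  fac <- if (sum(ok) == 1) rep(report$factor[ok], length(tm))
         else approx(mid[ok], report$factor[ok], xout = tm, rule = 2)$y
  kept <- !report$excluded[idx]
  int_ch <- intensity_channels(et)
  et$values[, int_ch] <- et$values[, int_ch, drop = FALSE] * fac
  out <- subset_events(et, kept)
  list(events = out, report = report, kept = kept,
       is_bead = is_bead[kept])
}

#' Singlet gating on DNA and event length
#'
#' Retains nucleated single intact cells: both DNA channels inside the
#' arcsinh gate, event length inside the configured push range, and
#' bead-positive events removed.
#'
#' @param et an `event_table` (raw counts).
#' @param gating a [gating_config()].
#' @return the gated `event_table`; attribute `"gate_reason"` holds a factor
#'   over the input events with levels `kept` / `bead` / `gate`.
#' @export
gate_singlets <- function(et, gating = gating_config()) {
  dna_ch <- channels_by_role(et, "dna")
  el_ch <- channels_by_role(et, "event_length")
  if (length(dna_ch) == 0 || length(el_ch) == 0)
    stop("DNA and event-length channels are required")
  is_bead <- identify_beads(et, gating)
  d <- asinh(et$values[, dna_ch, drop = FALSE] / gating$cofactor)
  in_dna <- rowSums(d >= gating$dna_low & d <= gating$dna_high) ==
    length(dna_ch)
  el <- et$values[, el_ch[1]]
  in_el <- el >= gating$event_length_range[1] &
    el <= gating$event_length_range[2]
  keep <- in_dna & in_el & !is_bead
  reason <- factor(ifelse(is_bead, "bead", ifelse(keep, "kept", "gate")),
                   levels = c("kept", "bead", "gate"))
  if (!any(keep)) warning("singlet gate retained no events")
  out <- subset_events(et, keep)
  attr(out, "gate_reason") <- reason
  out
}

#' Per-channel barcode thresholds
#'
#' For each barcode channel the arcsinh-transformed intensities are split
#' into off/on classes by exact two-class 1-D k-means (minimum within-class
#' sum of squares); the cutoff is the midpoint of the two class means.  A
#' channel whose 2-split has simplified silhouette below 0.2 is flagged as
#' unimodal with a warning.
#'
#' @param et an `event_table` (raw counts).
#' @param scheme a [barcode_scheme()].
#' @param cofactor arcsinh cofactor (default 5).
#' @return named numeric vector of cutoffs (arcsinh scale) with attribute
#'   `"silhouette"`.
#' @export
estimate_barcode_thresholds <- function(et, scheme, cofactor = 5) {
  ch <- scheme$barcode_channels
  miss <- setdiff(ch, et$channels$name)
  if (length(miss)) stop("barcode channels missing: ", paste(miss, collapse = ", "))
  cutoffs <- sil <- setNames(numeric(length(ch)), ch)
  for (b in ch) {
    y <- asinh(et$values[, b] / cofactor)
    sp <- split_1d_kmeans(y)
    cutoffs[b] <- sp$cutoff
    sil[b] <- sp$silhouette
    if (sp$silhouette < 0.2)
      warning("barcode channel ", b, " looks unimodal (silhouette ",
              round(sp$silhouette, 3), ")")
  }
  attr(cutoffs, "silhouette") <- sil
  cutoffs
}

#' Boolean debarcoding
#'
#' Each event is binarized per barcode channel against the supplied cutoffs
#' and assigned to the unique sample whose code equals the observed on/off
#' pattern.  Events matching no code (including all-on doublet patterns)
#' stay unassigned, as do events whose separation — lowest "on" minus
#' highest "off" arcsinh intensity — is below `delta`.
#'
#' @param et an `event_table` (raw counts).
#' @param scheme a [barcode_scheme()].
#' @param cutoffs per-channel cutoffs from [estimate_barcode_thresholds()].
#' @param delta minimum on/off separation on the arcsinh scale (default
#'   0.3).
#' @param cofactor arcsinh cofactor (default 5).
#' @return list with `sample_id` (character per event, `NA` when
#'   unassigned) and `yield` (per-sample assigned counts and overall
#'   yield).
#' @export
debarcode <- function(et, scheme, cutoffs, delta = 0.3, cofactor = 5) {
  ch <- scheme$barcode_channels
  key <- apply(scheme$codes, 1, paste, collapse = "")
  if (anyDuplicated(key)) stop("barcode scheme has duplicate codes")
  Y <- asinh(et$values[, ch, drop = FALSE] / cofactor)
  B <- sweep(Y, 2, cutoffs[ch], ">") * 1L
  pattern <- apply(B, 1, paste, collapse = "")
  m <- match(pattern, key)
  sample_id <- rownames(scheme$codes)[m]
  n_on <- rowSums(B)
  if (nrow(Y) > 0) {
    y_on <- Y; y_on[B == 0L] <- Inf
    y_off <- Y; y_off[B == 1L] <- -Inf
    lo_on <- apply(y_on, 1, min)
    hi_off <- apply(y_off, 1, max)
    sep <- ifelse(n_on == 0 | n_on == length(ch), 0, lo_on - hi_off)
    sample_id[!is.na(m) & sep < delta] <- NA_character_
  }
  yield <- data.frame(sample_id = rownames(scheme$codes))
  yield$n_assigned <- as.vector(table(factor(sample_id,
                                             levels = yield$sample_id)))
  yield$yield <- if (nrow(Y)) yield$n_assigned / nrow(Y) else 0
  list(sample_id = sample_id, yield = yield,
       n_unassigned = sum(is.na(sample_id)))
}

#' Estimate a spillover matrix from single-stained beads
#'
#' For beads single-stained for channel *i*, `S[i, j]` is the ratio of the
#' median signal in channel *j* to the median signal in channel *i*,
#' clipped to \[0, 1); the diagonal is set to 1.
#'
#' @param single_stained named list (stained channel -> events x channels
#'   matrix or `event_table`); names define the channels of the matrix.
#' @return a [spillover_matrix()].
#' @export
estimate_spillover <- function(single_stained) {
  ch <- names(single_stained)
  S <- diag(length(ch))
  dimnames(S) <- list(ch, ch)
  for (i in seq_along(ch)) {
    x <- single_stained[[i]]
    if (inherits(x, "event_table")) x <- x$values
    med <- apply(x[, ch, drop = FALSE], 2, median)
    if (med[i] <= 0)
      stop("stained-channel median is <= 0 for ", ch[i])
    S[i, ] <- pmin(pmax(med / med[i], 0), 1 - 1e-9)
    S[i, i] <- 1
  }
  spillover_matrix(S)
}

#' Spillover compensation by non-negative least squares
#'
#' Per event, the compensated vector `x` solves
#' `min || x S - observed ||^2` subject to `x >= 0` (Lawson-Hanson active
#' set).  Channels outside `S` pass through unchanged.
#'
#' @param et an untransformed `event_table`.
#' @param S a [spillover_matrix()] whose channels are a subset of the
#'   table's channels.
#' @return the compensated `event_table`.
#' @export
compensate <- function(et, S) {
  if (et$transformed) stop("compensation requires untransformed counts")
  ch <- rownames(S)
  miss <- setdiff(ch, et$channels$name)
  if (length(miss)) stop("spillover channels missing: ", paste(miss, collapse = ", "))
  if (nrow(et$values) > 0)
    et$values[, ch] <- compensate_counts(et$values[, ch, drop = FALSE],
                                         unclass(S))
  et
}

#' Arcsinh transformation
#'
#' Replaces every marker, barcode and DNA value `v` by `asinh(v /
#' cofactor)`; event length and time are untouched.  Transforming twice is
#' an error.
#'
#' @param et an untransformed `event_table`.
#' @param cofactor positive scale factor (default 5).
#' @return the transformed `event_table` (`transformed = TRUE`).
#' @export
transform_arcsinh <- function(et, cofactor = 5) {
  if (et$transformed) stop("event table is already arcsinh-transformed")
  stopifnot(cofactor > 0)
  ch <- channels_by_role(et, c("marker", "barcode", "dna"))
  et$values[, ch] <- asinh(et$values[, ch, drop = FALSE] / cofactor)
  et$transformed <- TRUE
  attr(et, "cofactor") <- cofactor
  et
}

#' Full preprocessing pipeline
#'
#' normalize -> gate beads/singlets -> debarcode -> compensate ->
#' transform, with conservation accounting: every input event ends up in
#' exactly one of \{assigned, unassigned, excluded-by-gate,
#' excluded-interval, bead\}.
#'
#' @param et pooled raw `event_table`.
#' @param scheme a [barcode_scheme()].
#' @param spillover optional [spillover_matrix()].
#' @param gating a [gating_config()].
#' @param cofactor arcsinh cofactor (default 5).
#' @param delta debarcoding separation cutoff (default 0.3).
#' @return list with `samples` (named list of per-sample transformed
#'   tables), `sample_id` (per gated event), `counts` (the five
#'   conservation counts), `cutoffs`, `norm_report`, `yield`.
#' @export
preprocess_pipeline <- function(et, scheme, spillover = NULL,
                                gating = gating_config(), cofactor = 5,
                                delta = 0.3) {
  n_input <- nrow(et$values)
  norm <- normalize_beads(et, gating)
  n_excluded <- sum(!norm$kept)
  gated <- gate_singlets(norm$events, gating)
  reason <- attr(gated, "gate_reason")
  n_bead <- sum(reason == "bead")
  n_gate <- sum(reason == "gate")
  cutoffs <- estimate_barcode_thresholds(gated, scheme, cofactor)
  db <- debarcode(gated, scheme, cutoffs, delta, cofactor)
  if (!is.null(spillover)) gated <- compensate(gated, spillover)
  gated <- transform_arcsinh(gated, cofactor)
  counts <- c(input = n_input, excluded_interval = n_excluded,
              bead = n_bead, gated_out = n_gate,
              assigned = sum(!is.na(db$sample_id)),
              unassigned = db$n_unassigned)
  samples <- lapply(setNames(nm = rownames(scheme$codes)), function(s)
    subset_events(gated, which(!is.na(db$sample_id) & db$sample_id == s)))
  list(samples = samples, events = gated, sample_id = db$sample_id,
       index = which(norm$kept)[reason == "kept"],
       counts = counts, cutoffs = cutoffs, norm_report = norm$report,
       yield = db$yield)
}
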