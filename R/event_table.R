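#' Event table: events x channels with channel metadata
#'
#' The central container of the package: a numeric matrix of ion dual counts
#' (or arcsinh-transformed values once [transform_arcsinh()] has run) with one
#' row per acquired event, plus a channel-description data frame assigning
#' each channel a role.
#'
#' @param values numeric matrix, events x channels; column names must match
#'   `channels$name`.
#' @param channels data frame with columns `name`, `metal`, `marker`, `role`
#'   (one of `"marker"`, `"barcode"`, `"bead"`, `"dna"`, `"event_length"`,
#'   `"time"`, `"other"`), and logical `lineage` / `embedding` flags (only
#'   marker channels may carry them).
#' @param transformed logical; `TRUE` once values are on the arcsinh scale.
#' @return an object of class `event_table`.
#' @export
event_table <- function(values, channels, transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  req <- c("name", "metal", "marker", "role", "lineage", "embedding")
  miss <- setdiff(req, names(channels))
  if (length(miss))
    stop("channel table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(colnames(values))) colnames(values) <- channels$name
  et <- structure(list(values = values, channels = channels,
                       transformed = isTRUE(transformed)),
                  class = "event_table")
  validate_event_table(et)
  et
}

#' Validate an event table
#'
#' Checks the structural invariants: unique channel names matching the value
#' columns, finite values, non-negative raw counts, exactly one time channel,
#' and role/flag consistency.
#'
#' @param et an `event_table`.
#' @return `et`, invisibly; stops on violation.
#' @export
validate_event_table <- function(et) {
  ch <- et$channels
  if (anyDuplicated(ch$name))
    stop("channel names must be unique")
  if (!identical(colnames(et$values), ch$name))
    stop("value columns do not match channel table")
  if (nrow(et$values) > 0 && !all(is.finite(et$values)))
    stop("event values must be finite")
  bad <- setdiff(unique(ch$role),
                 c("marker", "barcode", "bead", "dna", "event_length",
                   "time", "other"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (sum(ch$role == "time") != 1L)
    stop("exactly one time channel is required")
  if (any((ch$lineage | ch$embedding) & ch$role != "marker"))
    stop("only marker channels may carry clustering/embedding flags")
  if (!et$transformed && nrow(et$values) > 0 &&
      any(et$values[, ch$role != "time", drop = FALSE] < 0))
    stop("raw counts must be non-negative")
  tm <- event_time(et)
  if (length(tm) > 1 && any(diff(tm) < 0))
    stop("acquisition time must be non-decreasing")
  invisible(et)
}

#' @exportS3Method base::print
print.event_table <- function(x, ...) {
  cat(sprintf("event_table: %d events x %d channels (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "arcsinh-transformed" else "raw counts"))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$channels$role)),
                              table(x$channels$role)), collapse = " "), "\n")
  invisible(x)
}

#' Per-event acquisition time in seconds
#' @param et an `event_table`.
#' @return numeric vector, one entry per event.
#' @export
event_time <- function(et) {
  et$values[, which(et$channels$role == "time")]
}

#' Channel names with a given role
#' @param et an `event_table`.
#' @param role one of the channel roles (`"marker"`, `"barcode"`, ...).
#' @return character vector of channel names.
#' @export
channels_by_role <- function(et, role) {
  et$channels$name[et$channels$role %in% role]
}

# Channels that carry ion counts (everything except event_length and time);
# these are the channels bead normalization and drift act on.
intensity_channels <- function(et) {
  et$channels$name[!et$channels$role %in% c("event_length", "time")]
}

# Row-subset an event table, keeping channel metadata.
subset_events <- function(et, idx) {
  et$values <- et$values[idx, , drop = FALSE]
  et
}
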