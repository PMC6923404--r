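#' Read a panel definition CSV
#'
#' The panel CSV assigns every channel a role and the analysis flags.
#' Required columns: `name`, `metal`, `marker`, `role`, `lineage`,
#' `embedding` (the last two as 0/1 or TRUE/FALSE).
#'
#' @param path CSV file path.
#' @return data frame with validated columns (a `panel_definition`).
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "metal", "marker", "role", "lineage", "embedding")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("panel CSV lacks columns: ", paste(miss, collapse = ", "))
  df$lineage <- as.logical(as.integer(df$lineage))
  df$embedding <- as.logical(as.integer(df$embedding))
  if (anyDuplicated(df$name)) stop("duplicate channel names in panel")
  df
}

#' Construct / read a barcode scheme
#'
#' A barcode scheme maps each sample to a binary on/off code over the
#' barcode channels.  Codes must be unique with pairwise Hamming distance
#' at least `min_hamming`.
#'
#' @param codes integer 0/1 matrix, samples x barcode channels, with sample
#'   ids as row names and channel names as column names.
#' @param min_hamming minimum pairwise Hamming distance between codes
#'   (default 2).
#' @return object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(codes, min_hamming = 2L) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes)) || is.null(colnames(codes)))
    stop("codes must have sample ids as row names and channels as column names")
  if (anyDuplicated(rownames(codes))) stop("duplicate sample ids")
  if (!all(codes %in% c(0L, 1L))) stop("codes must be binary")
  key <- apply(codes, 1, paste, collapse = "")
  if (anyDuplicated(key)) stop("duplicate barcode codes")
  if (nrow(codes) > 1) {
    hd <- as.matrix(dist(codes, method = "manhattan"))
    diag(hd) <- Inf
    if (min(hd) < min_hamming)
      stop("pairwise Hamming distance below ", min_hamming)
  }
  structure(list(barcode_channels = colnames(codes), codes = codes,
                 min_hamming = as.integer(min_hamming)),
            class = "barcode_scheme")
}

#' @rdname barcode_scheme
#' @param path CSV with a `sample_id` column plus one 0/1 column per
#'   barcode channel.
#' @details When reading a CSV, `min_hamming = NULL` (the default) infers
#'   the realized minimum pairwise distance of the code book instead of
#'   enforcing one; codes must still be unique.
#' @export
read_barcode_scheme <- function(path, min_hamming = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("barcode CSV lacks 'sample_id'")
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  if (is.null(min_hamming)) {
    min_hamming <- if (nrow(m) > 1)
      min(dist(m, method = "manhattan")) else 1L
  }
  barcode_scheme(m, min_hamming)
}

#' Construct / read a spillover matrix
#'
#' Square matrix over the compensated channels; rows are source channels,
#' columns receiving channels.  Unit diagonal, off-diagonals in \[0, 1),
#' row sums below 2.
#'
#' @param S square numeric matrix with identical row/column channel names.
#' @return object of class `spillover_matrix` (the validated matrix).
#' @export
spillover_matrix <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("spillover matrix must be square")
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("spillover matrix needs identical row/column channel names")
  if (any(abs(diag(S) - 1) > 1e-12)) stop("spillover diagonal must be 1")
  off <- S; diag(off) <- 0
  if (any(off < 0) || any(off >= 1)) stop("off-diagonal spill must be in [0, 1)")
  if (any(rowSums(S) >= 2)) stop("row-wise spill sums must be < 2")
  structure(S, class = c("spillover_matrix", "matrix"))
}

#' @rdname spillover_matrix
#' @param path CSV whose first column holds source-channel names and whose
#'   header names the receiving channels.
#' @export
read_spillover <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  spillover_matrix(m)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id` and `group` (plus optional
#'   covariates such as `sex`, `age`).
#' @return validated data frame.
#' @export
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata CSV needs 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (any(is.na(df$group) | df$group == "")) stop("every sample needs a group")
  df
}

#' Read and cross-validate all sidecar tables
#'
#' Reads the panel, barcode scheme, spillover matrix and sample metadata and
#' checks them against each other: barcode channels must be panel channels of
#' role `"barcode"`, spillover channels must be panel channels, and barcode
#' scheme samples must match the metadata.
#'
#' @param panel,barcodes,spillover,metadata CSV file paths (spillover and
#'   metadata may be `NULL`).
#' @return list with elements `panel`, `scheme`, `spillover`, `metadata`.
#' @export
read_sidecar_tables <- function(panel, barcodes, spillover = NULL,
                                metadata = NULL) {
  pan <- read_panel(panel)
  sch <- read_barcode_scheme(barcodes)
  extra <- setdiff(sch$barcode_channels, pan$name[pan$role == "barcode"])
  if (length(extra))
    stop("barcode channels not in panel (role 'barcode'): ",
         paste(extra, collapse = ", "))
  sp <- NULL
  if (!is.null(spillover)) {
    sp <- read_spillover(spillover)
    extra <- setdiff(rownames(sp), pan$name)
    if (length(extra))
      stop("spillover channels not in panel: ", paste(extra, collapse = ", "))
  }
  md <- NULL
  if (!is.null(metadata)) {
    md <- read_metadata(metadata)
    extra <- setdiff(rownames(sch$codes), md$sample_id)
    if (length(extra))
      stop("barcoded samples missing from metadata: ",
           paste(extra, collapse = ", "))
  }
  list(panel = pan, scheme = sch, spillover = sp, metadata = md)
}
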