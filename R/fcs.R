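#' Write an event table as an FCS 3.1 file
#'
#' Writes single-precision float list-mode data with little-endian byte order
#' and the mandatory `$TOT`/`$PAR`/`$BEGINDATA`/`$ENDDATA` keywords.  Channel
#' short names (`$PnN`) carry the metal label, `$PnS` the marker name.  The
#' package's channel roles and flags are stored in vendor keywords
#' (`CYTODAnROLE` etc.) so that [read_fcs()] round-trips them exactly; other
#' software simply ignores them.  Delimiter characters occurring inside
#' keyword values are escaped by doubling, per the FCS standard.
#'
#' @param et an `event_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(et, path) {
  validate_event_table(et)
  n <- nrow(et$values); p <- ncol(et$values)
  delim <- "/"
  esc <- function(x) {
    x <- as.character(x)
    x[x == ""] <- " "
    gsub(delim, paste0(delim, delim), x, fixed = TRUE)
  }
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p),
          "$TIMESTEP", "1", "CYTODATRANSFORMED",
          if (et$transformed) "1" else "0")
  rng <- apply(et$values, 2, function(v) if (length(v)) max(v, 1) else 1)
  for (i in seq_len(p)) {
    ch <- et$channels[i, ]
    kw <- c(kw,
            sprintf("$P%dN", i), esc(ch$metal),
            sprintf("$P%dS", i), esc(ch$marker),
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), as.character(ceiling(rng[i]) + 1),
            sprintf("CYTODA%dNAME", i), esc(ch$name),
            sprintf("CYTODA%dROLE", i), esc(ch$role),
            sprintf("CYTODA%dLINEAGE", i), if (isTRUE(ch$lineage)) "1" else "0",
            sprintf("CYTODA%dEMBED", i), if (isTRUE(ch$embedding)) "1" else "0")
  }
  data_size <- n * p * 4L
  # TEXT segment size depends on the data offsets it contains; iterate to a
  # fixed point (always converges in <= 3 passes since widths only grow).
  text_begin <- 58L
  data_begin <- 0L; data_end <- 0L
  build_text <- function(db, de) {
    kv <- c(kw, "$BEGINDATA", as.character(db), "$ENDDATA", as.character(de))
    paste0(delim, paste0(kv, collapse = delim), delim)
  }
  for (pass in 1:4) {
    txt <- build_text(data_begin, data_end)
    nb <- text_begin + nchar(txt, type = "bytes")
    db <- nb
    de <- db + data_size - 1L
    if (db == data_begin && de == data_end) break
    data_begin <- db; data_end <- de
  }
  txt <- build_text(data_begin, data_end)
  text_end <- text_begin + nchar(txt, type = "bytes") - 1L
  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", off(text_begin), off(text_end),
                   if (data_end <= 99999999) off(data_begin) else off(0),
                   if (data_end <= 99999999) off(data_end) else off(0),
                   off(0), off(0))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  if (n * p > 0)
    writeBin(as.vector(t(et$values)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS file into an event table
#'
#' Supports FCS 2.0/3.0/3.1 list-mode files with float (`$DATATYPE F`),
#' double (`D`) or integer (`I`, 8/16/32-bit) data.  `$PnN` is mapped to the
#' metal label and `$PnS` to the marker name.  Channel roles are taken, in
#' order of precedence, from the `panel` argument or from the vendor keywords
#' written by [write_fcs()]; they are never guessed silently — without either
#' source all channels get role `"other"` (except a channel named `Time`)
#' and a message is emitted.  Time is converted to seconds using `$TIMESTEP`
#' (default 0.001 s per tick when the keyword is absent); a file without a
#' time channel gets a synthetic event-index time with a warning.
#'
#' @param path path to an FCS file.
#' @param panel optional panel definition (see [read_panel()]) assigning
#'   roles by channel name or metal.
#' @return an `event_table`.
#' @export
read_fcs <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (is.na(header) || nchar(header, type = "bytes") < 58 ||
      substr(header, 1, 3) != "FCS")
    stop("FCS format error: missing 'FCS' magic in header")
  version <- trimws(substr(header, 1, 10))
  offs <- suppressWarnings(as.integer(
    vapply(0:5, function(i) substr(header, 11 + 8 * i, 18 + 8 * i), "")))
  if (any(is.na(offs[1:2])))
    stop("FCS format error: unreadable TEXT offsets in header")
  text_begin <- offs[1]; text_end <- offs[2]
  if (text_end <= text_begin || text_end > sz)
    stop("FCS format error: invalid TEXT segment offsets")
  seek(con, text_begin)
  raw_txt <- readBin(con, "raw", text_end - text_begin + 1L)
  txt <- rawToChar(raw_txt)
  Encoding(txt) <- "latin1"
  kw <- parse_fcs_text(txt)
  need <- function(k, default = NULL) {
    v <- kw[[k]]
    if (is.null(v)) {
      if (is.null(default))
        stop("FCS format error: missing required keyword ", k)
      default
    } else v
  }
  n <- as.integer(need("$TOT"))
  p <- as.integer(need("$PAR"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD", "1,2,3,4")
  endian <- if (substr(byteord, 1, 1) == "1") "little" else "big"
  data_begin <- as.integer(need("$BEGINDATA", "0"))
  data_end <- as.integer(need("$ENDDATA", "0"))
  if (data_begin == 0 && !is.na(offs[3]) && offs[3] > 0) {
    data_begin <- offs[3]; data_end <- offs[4]
  }
  bits <- as.integer(vapply(seq_len(p), function(i)
    need(sprintf("$P%dB", i), "32"), ""))
  seek(con, data_begin)
  if (n * p == 0) {
    vals <- matrix(numeric(0), nrow = max(n, 0L), ncol = p)
  } else if (dtype == "F") {
    vals <- matrix(readBin(con, "numeric", n * p, size = 4L, endian = endian),
                   nrow = n, ncol = p, byrow = TRUE)
  } else if (dtype == "D") {
    vals <- matrix(readBin(con, "numeric", n * p, size = 8L, endian = endian),
                   nrow = n, ncol = p, byrow = TRUE)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !unique(bits) %in% c(8L, 16L, 32L))
      stop("FCS format error: unsupported $PnB layout for integer data")
    b <- unique(bits) / 8L
    vals <- matrix(readBin(con, "integer", n * p, size = b, signed = b > 2,
                           endian = endian),
                   nrow = n, ncol = p, byrow = TRUE)
    vals[vals < 0] <- vals[vals < 0] + 2^unique(bits)  # unsigned widths <= 16
  } else stop("FCS format error: unsupported $DATATYPE ", dtype)
  metal <- vapply(seq_len(p), function(i) need(sprintf("$P%dN", i), ""), "")
  marker <- vapply(seq_len(p), function(i) need(sprintf("$P%dS", i), " "), "")
  marker <- trimws(marker)
  namek <- vapply(seq_len(p), function(i)
    need(sprintf("CYTODA%dNAME", i), ""), "")
  has_vendor <- all(nzchar(namek))
  name <- if (has_vendor) namek else ifelse(nzchar(marker), marker, metal)
  name <- make.unique(name)
  role <- rep("other", p)
  lineage <- embedding <- rep(FALSE, p)
  if (has_vendor) {
    role <- vapply(seq_len(p), function(i)
      need(sprintf("CYTODA%dROLE", i), "other"), "")
    lineage <- vapply(seq_len(p), function(i)
      need(sprintf("CYTODA%dLINEAGE", i), "0"), "") == "1"
    embedding <- vapply(seq_len(p), function(i)
      need(sprintf("CYTODA%dEMBED", i), "0"), "") == "1"
  } else if (!is.null(panel)) {
    m <- match(name, panel$name)
    m2 <- match(metal, panel$metal)
    m[is.na(m)] <- m2[is.na(m)]
    if (anyNA(m))
      stop("panel does not describe channel(s): ",
           paste(name[is.na(m)], collapse = ", "))
    role <- panel$role[m]
    lineage <- panel$lineage[m]
    embedding <- panel$embedding[m]
    name <- panel$name[m]
  } else {
    role[tolower(name) == "time" | tolower(metal) == "time"] <- "time"
    message("read_fcs: no panel given; channel roles set to 'other'")
  }
  timestep <- as.numeric(need("$TIMESTEP", "0.001"))
  ti <- which(role == "time")
  if (length(ti) == 0) {
    warning("no time channel found; substituting event-index time")
    vals <- cbind(vals, seq_len(nrow(vals)))
    name <- c(name, "Time"); metal <- c(metal, "Time")
    marker <- c(marker, ""); role <- c(role, "time")
    lineage <- c(lineage, FALSE); embedding <- c(embedding, FALSE)
    p <- p + 1L
  } else {
    vals[, ti[1]] <- vals[, ti[1]] * timestep
  }
  colnames(vals) <- name
  event_table(vals,
              data.frame(name = name, metal = metal, marker = marker,
                         role = role, lineage = lineage,
                         embedding = embedding, stringsAsFactors = FALSE),
              transformed = identical(kw[["CYTODATRANSFORMED"]], "1"))
}

# Parse an FCS TEXT segment into a named list, honouring doubled-delimiter
# escapes.  The first byte is the delimiter.
parse_fcs_text <- function(txt) {
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  # trailing delimiter required; drop everything after the final one
  pieces <- strsplit(body, delim, fixed = TRUE)[[1]]
  # re-join escaped delimiters: an empty piece between two pieces means a
  # literal delimiter joining its neighbours
  out <- character(0); cur <- NULL
  i <- 1L
  while (i <= length(pieces)) {
    if (is.null(cur)) cur <- pieces[i]
    else cur <- paste0(cur, delim, pieces[i])
    if (i < length(pieces) && pieces[i + 1L] == "" && i + 1L < length(pieces)) {
      # escaped delimiter inside this token: skip the empty piece and keep going
      i <- i + 2L
      next
    }
    out <- c(out, cur); cur <- NULL
    i <- i + 1L
  }
  if (!is.null(cur)) out <- c(out, cur)
  if (length(out) %% 2L == 1L) out <- out[-length(out)]
  keys <- out[seq(1, length(out), by = 2)]
  vals <- out[seq(2, length(out), by = 2)]
  setNames(as.list(trimws(vals)), trimws(keys))
}
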