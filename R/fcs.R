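#' Read an FCS 3.0/3.1 file
#'
#' Parses the header, TEXT and DATA segments of a list-mode FCS file and
#' returns the events unmodified (no transform is applied). Channel names are
#' taken from the `$PnN` keywords; `$PnS` marker tokens, when present, are
#' attached as the `marker_names` attribute. Channel kinds round-trip through
#' the custom `SFKINDn` keywords written by [write_fcs()]; for files from
#' other software they are inferred from channel names (FSC/SSC -> scatter,
#' otherwise detector).
#'
#' Supported datatypes: `F` (float32), `D` (float64), `I` (unsigned integers
#' of 8/16/32/64 bits). Errors are signalled with distinct condition classes:
#' `sf_malformed_header`, `sf_unsupported_datatype`, `sf_truncated_data`.
#'
#' @param path path to an existing FCS file.
#' @return an [event_matrix()].
#' @seealso [write_fcs()]
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) {
    sf_stop(sprintf("file not found: %s", path), "sf_missing_file")
  }
  n_bytes <- file.info(path)$size
  raw <- readBin(path, "raw", n = n_bytes)
  if (length(raw) < 58) sf_stop("file too short for an FCS header", "sf_malformed_header")

  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    sf_stop(sprintf("not an FCS 3.0/3.1 file (header '%s')", version),
            "sf_malformed_header")
  }
  off <- function(a, b) {
    s <- trimws(rawToChar(raw[a:b]))
    if (s == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) sf_stop("non-numeric segment offset in header", "sf_malformed_header")
    v
  }
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg ||
      text_end + 1 > length(raw)) {
    sf_stop("invalid TEXT segment offsets", "sf_malformed_header")
  }

  delim <- rawToChar(raw[text_beg + 1])
  body <- rawToChar(raw[(text_beg + 2):(text_end + 1)])
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # trailing delimiter produces a final empty element; drop it
  if (length(parts) %% 2 == 1 && parts[length(parts)] == "") {
    parts <- parts[-length(parts)]
  }
  if (length(parts) %% 2 == 1) {
    sf_stop("TEXT segment has an unpaired keyword", "sf_malformed_header")
  }
  kw <- parts[seq(2, length(parts), by = 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  get_kw <- function(key, required = TRUE) {
    if (!key %in% names(kw)) {
      if (required) {
        sf_stop(sprintf("required keyword %s missing", key), "sf_malformed_header")
      }
      return(NULL)
    }
    kw[[key]]
  }

  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(get_kw("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(get_kw("$ENDDATA"))

  mode <- get_kw("$MODE")
  if (toupper(mode) != "L") {
    sf_stop(sprintf("only list mode is supported ($MODE=%s)", mode),
            "sf_unsupported_datatype")
  }
  dtype <- toupper(get_kw("$DATATYPE"))
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  byteord <- get_kw("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else sf_stop(sprintf("unsupported $BYTEORD '%s'", byteord),
                         "sf_unsupported_datatype")

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(get_kw(sprintf("$P%dB", i)))
  }, integer(1))

  if (dtype == "F") {
    if (any(bits != 32)) sf_stop("$DATATYPE=F requires $PnB=32", "sf_malformed_header")
    what <- "numeric"; size <- 4
  } else if (dtype == "D") {
    if (any(bits != 64)) sf_stop("$DATATYPE=D requires $PnB=64", "sf_malformed_header")
    what <- "numeric"; size <- 8
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1 || !bits[1] %in% c(8L, 16L, 32L, 64L)) {
      sf_stop("integer data requires one uniform $PnB of 8/16/32/64",
              "sf_unsupported_datatype")
    }
    what <- "integer"; size <- bits[1] / 8
  } else {
    sf_stop(sprintf("unsupported $DATATYPE '%s'", dtype), "sf_unsupported_datatype")
  }

  need <- as.numeric(n_tot) * n_par * size
  avail <- length(raw) - data_beg
  if (need > 0 && (data_beg >= length(raw) || avail < need)) {
    sf_stop(sprintf("DATA segment truncated: need %.0f bytes, have %.0f",
                    need, max(avail, 0)),
            "sf_truncated_data")
  }

  if (need > 0) {
    con <- rawConnection(raw[(data_beg + 1):(data_beg + need)])
    on.exit(close(con))
    vals <- readBin(con, what, n = n_tot * n_par, size = size,
                    endian = endian, signed = size > 2)
  } else {
    vals <- numeric(0)
  }
  m <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)

  ch_names <- vapply(seq_len(n_par), function(i) get_kw(sprintf("$P%dN", i)),
                     character(1))
  markers <- vapply(seq_len(n_par), function(i) {
    get_kw(sprintf("$P%dS", i), required = FALSE) %||% NA_character_
  }, character(1))
  kinds <- vapply(seq_len(n_par), function(i) {
    k <- get_kw(sprintf("SFKIND%d", i), required = FALSE)
    if (!is.null(k)) return(k)
    if (grepl("^(FSC|SSC)", ch_names[i])) "scatter" else "detector"
  }, character(1))

  out <- event_matrix(m, ch_names, kinds,
                      sample_id = get_kw("SFSAMPLEID", required = FALSE) %||%
                        get_kw("$FIL", required = FALSE) %||% basename(path),
                      batch_id = get_kw("SFBATCHID", required = FALSE))
  attr(out, "marker_names") <- markers
  attr(out, "fcs_keywords") <- kw
  out
}

#' Write an event matrix to an FCS 3.1 file
#'
#' Writes list-mode, float32 (`$DATATYPE=F`), little-endian FCS 3.1 — the
#' layout modern spectral instruments emit. `$PnN` carries the channel token
#' and `$PnS` the marker token, so gating configurations stay
#' instrument-agnostic. Channel order is preserved exactly; values round-trip
#' through [read_fcs()] within float32 precision. Sample/batch identifiers
#' and channel kinds are stored in custom keywords so they survive the
#' round trip.
#'
#' @param events an [event_matrix()] with finite values.
#' @param path output file path.
#' @param marker_names optional `$PnS` tokens, one per channel.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, marker_names = NULL) {
  vals <- events$values
  if (length(vals) && !all(is.finite(vals))) {
    bad <- events$channel_names[unique(((which(!is.finite(t(vals))) - 1L) %%
                                          ncol(vals)) + 1L)]
    sf_stop(sprintf("non-finite values in channel(s): %s",
                    paste(bad, collapse = ", ")),
            "sf_nonfinite_values")
  }
  n <- nrow(vals); p <- ncol(vals)
  if (is.null(marker_names)) {
    marker_names <- attr(events, "marker_names") %||% events$channel_names
  }

  d <- "/"
  esc <- function(x) {
    x <- as.character(x)
    if (any(grepl(d, x, fixed = TRUE))) {
      sf_stop("keyword values may not contain the delimiter '/'", "sf_bad_input")
    }
    x
  }
  ranges <- if (n > 0) pmax(ceiling(apply(vals, 2, max)) + 1, 1) else rep(262144, p)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%012d", "$ENDDATA" = "%012d",
    "$NEXTDATA" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$PAR" = as.character(p), "$TOT" = as.character(n),
    "SFSAMPLEID" = esc(events$sample_id)
  )
  if (!is.null(events$batch_id)) kw["SFBATCHID"] <- esc(events$batch_id)
  for (i in seq_len(p)) {
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- esc(events$channel_names[i])
    kw[sprintf("$P%dR", i)] <- as.character(ranges[i])
    if (!is.na(marker_names[i])) kw[sprintf("$P%dS", i)] <- esc(marker_names[i])
    kw[sprintf("SFKIND%d", i)] <- events$channel_kinds[i]
  }

  build_text <- function(begin_data, end_data) {
    k <- kw
    k["$BEGINDATA"] <- sprintf("%012d", begin_data)
    k["$ENDDATA"] <- sprintf("%012d", end_data)
    paste0(d, paste0(names(k), d, unname(k), d, collapse = ""))
  }
  text_beg <- 58
  # offsets are fixed-width, so TEXT length does not depend on their values
  text_len <- nchar(build_text(0, 0), type = "bytes")
  data_beg <- text_beg + text_len
  data_end <- if (n * p > 0) data_beg + 4 * n * p - 1 else 0
  text <- build_text(data_beg, data_end)

  hdr_off <- function(x) {
    s <- sprintf("%8d", x)
    if (nchar(s) > 8) sf_stop("segment offset exceeds FCS header field", "sf_bad_input")
    s
  }
  header <- paste0("FCS3.1    ",
                   hdr_off(text_beg), hdr_off(text_beg + text_len - 1),
                   hdr_off(if (n * p > 0) data_beg else 0), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (n * p > 0) {
    writeBin(as.vector(t(vals)), con, size = 4, endian = "little")
  }
  invisible(path)
}
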