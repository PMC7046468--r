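## Minimal FCS 3.0/3.1 support for list-mode float data.
##
## Cytometry exports in this pipeline carry two float channels; neither a
## flow-cytometry package nor compensation is needed to read them. The
## reader parses the 58-byte HEADER, the delimited TEXT segment and a
## $DATATYPE F ($MODE L) DATA segment; the writer emits the same minimal
## subset. Keyword offsets follow the published FCS 3.0 byte layout.

.fcs_text_value <- function(kw, key) {
  v <- kw[[toupper(key)]]
  if (is.null(v)) NULL else v
}

#' Read a minimal FCS 3.0/3.1 file
#'
#' Supports list-mode (`$MODE L`) float data (`$DATATYPE F`, 32-bit) with
#' little- or big-endian byte order — the subset written by
#' [write_fcs()] and exported by plate cytometers in float mode.
#'
#' @param path FCS file path.
#'
#' @return A `data.table` with one column per channel, named by `$PnN`.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop(sprintf("'%s': unsupported FCS version '%s'", path, version))
  }
  ## HEADER offsets are 0-based byte positions (R indexing is 1-based)
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  text_beg <- off(11, 18)
  text_end <- off(19, 26)
  data_beg <- off(27, 34)
  data_end <- off(35, 42)
  txt <- rawToChar(raw[(text_beg + 1L):(text_end + 1L)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  kw <- as.list(parts[seq(2, length(parts), by = 2)])
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  if (data_beg == 0L) data_beg <- as.integer(.fcs_text_value(kw, "$BEGINDATA"))
  if (data_end == 0L) data_end <- as.integer(.fcs_text_value(kw, "$ENDDATA"))
  n_par <- as.integer(.fcs_text_value(kw, "$PAR"))
  n_tot <- as.integer(.fcs_text_value(kw, "$TOT"))
  dtype <- .fcs_text_value(kw, "$DATATYPE")
  if (!identical(dtype, "F")) {
    stop(sprintf("'%s': only $DATATYPE F is supported (got '%s')", path, dtype))
  }
  byteord <- .fcs_text_value(kw, "$BYTEORD")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(.fcs_text_value(kw, sprintf("$P%dB", i)))
  }, integer(1L))
  if (any(bits != 32L)) stop(sprintf("'%s': only 32-bit floats supported", path))
  ch <- vapply(seq_len(n_par), function(i) {
    v <- .fcs_text_value(kw, sprintf("$P%dN", i))
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1L))
  vals <- readBin(raw[(data_beg + 1L):(data_end + 1L)], "numeric", size = 4L,
                  n = n_par * n_tot, endian = endian)
  m <- matrix(vals, ncol = n_par, byrow = TRUE)
  colnames(m) <- ch
  as.data.table(m)
}

#' Write a minimal FCS 3.0 file
#'
#' List-mode 32-bit float data, little-endian, one parameter per column.
#'
#' @param events A data.frame of numeric columns (channel per column).
#' @param path Output path.
#'
#' @return The path, invisibly.
#' @export
write_fcs <- function(events, path) {
  events <- as.data.frame(events)
  stopifnot(ncol(events) >= 1L, all(vapply(events, is.numeric, logical(1L))))
  n_par <- ncol(events)
  n_tot <- nrow(events)
  d <- "/"
  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$BEGINSTEXT", "0",
    "$ENDSTEXT", "0", "$NEXTDATA", "0",
    "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
    "$PAR", as.character(n_par), "$TOT", as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), colnames(events)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  ## data offsets appear both in the HEADER and as zero-padded TEXT keywords,
  ## so the TEXT length is known before the offsets are
  kw <- c(kw, "$BEGINDATA", "%BEG%", "$ENDDATA", "%END%")
  build_text <- function(beg, end) {
    k <- kw
    k[which(k == "%BEG%")] <- sprintf("%010d", beg)
    k[which(k == "%END%")] <- sprintf("%010d", end)
    paste0(d, paste(k, collapse = d), d)
  }
  text_beg <- 58L
  text_len <- nchar(build_text(0L, 0L))
  text_end <- text_beg + text_len - 1L
  data_beg <- text_end + 1L
  data_len <- 4L * n_par * n_tot
  data_end <- data_beg + data_len - 1L
  txt <- build_text(data_beg, data_end)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(as.matrix(events))), con, size = 4L,
           endian = "little")
  invisible(path)
}
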