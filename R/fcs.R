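# Minimal FCS 3.0/3.1 list-mode I/O.
#
# Only the pieces the pipeline consumes are implemented: the header offsets,
# the primary TEXT segment ($PnN channel names, $DATATYPE, $BYTEORD, $PAR,
# $TOT, $PnB, data offsets) and a numeric DATA segment ($DATATYPE F or D,
# little- or big-endian). No analysis segment, no integer data, no multi-
# dataset files, no escaped delimiters. The writer stores doubles so that a
# write -> read cycle is lossless.

read_fcs_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (substr(header, 1, 3) != "FCS") {
    stop_cytomito(sprintf("'%s' is not an FCS file", path), "cytomito_format_error")
  }
  off <- function(i) {
    s <- substr(header, 10 + 8 * (i - 1) + 1, 10 + 8 * i)
    suppressWarnings(as.integer(trimws(s)))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg) {
    stop_cytomito("corrupt FCS header (TEXT offsets)", "cytomito_format_error")
  }
  seek(con, text_beg)
  txt <- readChar(con, text_end - text_beg + 1L, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  vals <- trimws(parts[seq(2, length(parts), 2)])
  kw <- setNames(vals, keys)

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D")) {
    stop_cytomito(sprintf("unsupported FCS $DATATYPE '%s' (only F/D)", dtype),
                  "cytomito_format_error")
  }
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_end) || data_end == 0) data_end <- as.integer(kw[["$ENDDATA"]])
  size <- if (dtype == "F") 4L else 8L
  channels <- vapply(seq_len(npar),
                     function(i) kw[[sprintf("$P%dN", i)]], character(1))
  seek(con, data_beg)
  vals <- readBin(con, "numeric", n = npar * ntot, size = size, endian = endian)
  mat <- matrix(vals, ncol = npar, byrow = TRUE)
  colnames(mat) <- channels
  list(data = mat, channels = channels, keywords = kw)
}

write_fcs_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  npar <- ncol(mat); ntot <- nrow(mat)
  nbytes <- 8L * npar * ntot
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$NEXTDATA", "0",
          "$MODE", "L", "$DATATYPE", "D", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), "64",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(ceiling(max(mat[, i], 1)), scientific = FALSE))
  }
  # data offsets padded to fixed width so TEXT length does not depend on them
  begin_data_fmt <- "%010d"
  mk_text <- function(bd, ed) {
    paste0("/", paste(c(kw, "$BEGINDATA", sprintf(begin_data_fmt, bd),
                        "$ENDDATA", sprintf(begin_data_fmt, ed)),
                      collapse = "/"), "/")
  }
  probe <- mk_text(0, 0)
  text_beg <- 58L
  text_end <- text_beg + nchar(probe, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + nbytes - 1L
  txt <- mk_text(data_beg, data_end)
  hdr_off <- function(x) formatC(x, width = 8)
  # offsets above 99,999,999 do not fit the header; signal via TEXT only (0s)
  fits <- data_end <= 99999999
  header <- paste0("FCS3.0    ",
                   hdr_off(text_beg), hdr_off(text_end),
                   hdr_off(if (fits) data_beg else 0),
                   hdr_off(if (fits) data_end else 0),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(mat)), con, size = 8L, endian = "little")
  invisible(path)
}
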