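#' Construct an event table
#'
#' An event table holds per-cell flow-cytometry measurements on the linear
#' instrument scale: a DNA-stain fluorescence area channel (e.g. Sytox Green
#' on FITC-A) and forward-scatter area (FSC-A), plus optional ground-truth
#' labels when the events come from the synthetic generator. Non-positive
#' values on either channel are dropped (not clamped) because the analysis is
#' carried out on log2-transformed signals; the number of dropped events is
#' recorded in the `dropped_count` attribute.
#'
#' @param fluor_linear Numeric vector, DNA-stain fluorescence (arbitrary
#'   linear units).
#' @param fsc_linear Numeric vector, forward-scatter area (arbitrary linear
#'   units), same length as `fluor_linear`.
#' @param sample_id Character scalar identifying the sample.
#' @param channel_map Named list with `fluor` and `fsc` channel names as they
#'   appear in the source file.
#' @param truth Optional data frame of per-event ground truth with columns
#'   `ploidy_class` (one of `"G1"`, `"S"`, `"G2M"`), `mtdna_copies` and
#'   `cell_size`; rows must align with the events before filtering.
#' @return A tibble of class `event_table` with columns `fluor_linear` and
#'   `fsc_linear` (plus truth columns if supplied) and attributes `sample_id`,
#'   `channel_map`, `dropped_count` and `n_events`.
#' @export
event_table <- function(fluor_linear, fsc_linear, sample_id = "sample",
                        channel_map = list(fluor = "FITC-A", fsc = "FSC-A"),
                        truth = NULL) {
  if (length(fluor_linear) != length(fsc_linear)) {
    stop_cytomito("fluor_linear and fsc_linear must have the same length",
                  "cytomito_contract_error")
  }
  tbl <- tibble::tibble(fluor_linear = as.numeric(fluor_linear),
                        fsc_linear = as.numeric(fsc_linear))
  if (!is.null(truth)) {
    stopifnot(nrow(truth) == nrow(tbl))
    tbl$ploidy_class <- as.character(truth$ploidy_class)
    tbl$mtdna_copies <- truth$mtdna_copies
    tbl$cell_size <- truth$cell_size
  }
  keep <- is.finite(tbl$fluor_linear) & is.finite(tbl$fsc_linear) &
    tbl$fluor_linear > 0 & tbl$fsc_linear > 0
  dropped <- sum(!keep)
  tbl <- tbl[keep, , drop = FALSE]
  structure(tbl,
            class = c("event_table", class(tbl)),
            sample_id = sample_id,
            channel_map = channel_map,
            dropped_count = dropped,
            n_events = nrow(tbl))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> sample '%s': %d events (%d dropped), channels %s/%s%s\n",
              attr(x, "sample_id"), nrow(x), attr(x, "dropped_count"),
              attr(x, "channel_map")$fluor, attr(x, "channel_map")$fsc,
              if (is_transformed(x)) ", log2-transformed" else ""))
  NextMethod()
  invisible(x)
}

is_transformed <- function(t) all(c("fluor_log2", "fsc_log2") %in% names(t))

# subset an event_table preserving its metadata attributes
subset_events <- function(t, idx) {
  out <- t[idx, , drop = FALSE]
  for (a in c("sample_id", "channel_map", "dropped_count")) {
    attr(out, a) <- attr(t, a)
  }
  attr(out, "n_events") <- nrow(out)
  if (!inherits(out, "event_table")) class(out) <- c("event_table", class(out))
  out
}

#' Read flow-cytometry events from FCS or CSV
#'
#' Reads an event matrix from a standard FCS 3.0/3.1 file or from a CSV table
#' whose header row carries the channel names, selects the fluorescence and
#' forward-scatter channels, and drops non-positive events (counted in the
#' `dropped_count` attribute of the result).
#'
#' @param path Path to the file.
#' @param fluor_channel,fsc_channel Channel names to select; defaults are the
#'   CytoFlex names used for Sytox Green acquisition.
#' @param format `"auto"` (by file extension and magic bytes), `"fcs"` or
#'   `"csv"`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [event_table()].
#' @export
read_events <- function(path, fluor_channel = "FITC-A", fsc_channel = "FSC-A",
                        format = c("auto", "fcs", "csv"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_cytomito(sprintf("file not found: %s", path), "cytomito_format_error")
  }
  if (format == "auto") {
    magic <- tryCatch(readBin(path, "raw", n = 3L), error = function(e) raw())
    format <- if (identical(rawToChar(magic), "FCS")) "fcs"
              else if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs"
              else "csv"
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "fcs") {
    parsed <- read_fcs_matrix(path)
    mat <- parsed$data
    chans <- parsed$channels
  } else {
    df <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) stop_cytomito(
                     sprintf("cannot read CSV '%s': %s", path, conditionMessage(e)),
                     "cytomito_format_error"))
    chans <- names(df)
    mat <- df
  }
  for (ch in c(fluor_channel, fsc_channel)) {
    if (!ch %in% chans) {
      stop_cytomito(
        sprintf("channel '%s' not found; available channels: %s",
                ch, paste(chans, collapse = ", ")),
        "cytomito_channel_error", data = list(available = chans))
    }
  }
  col <- function(ch) if (is.data.frame(mat)) mat[[ch]] else mat[, ch]
  event_table(col(fluor_channel), col(fsc_channel),
              sample_id = sample_id,
              channel_map = list(fluor = fluor_channel, fsc = fsc_channel))
}

#' Write an event table
#'
#' `write_events_csv()` writes the linear channels back out as a CSV with the
#' channel names from the table's `channel_map` as header, so that
#' [read_events()] round-trips. `write_events_fcs()` writes a minimal FCS 3.0
#' file (list mode, double-precision data) with the same property.
#' `write_processed_csv()` writes the log2-transformed table
#' (`sample_id, fluor_log2, fsc_log2`) for downstream use outside R.
#'
#' @param t An [event_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(t, path) {
  cm <- attr(t, "channel_map")
  out <- data.frame(t$fluor_linear, t$fsc_linear, check.names = FALSE)
  names(out) <- c(cm$fluor, cm$fsc)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_events_fcs <- function(t, path) {
  cm <- attr(t, "channel_map")
  mat <- cbind(t$fluor_linear, t$fsc_linear)
  colnames(mat) <- c(cm$fluor, cm$fsc)
  write_fcs_matrix(mat, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_processed_csv <- function(t, path) {
  if (!is_transformed(t)) {
    stop_cytomito("event table is not log2-transformed; call log2_transform() first",
                  "cytomito_contract_error")
  }
  out <- data.frame(sample_id = attr(t, "sample_id"),
                    fluor_log2 = t$fluor_log2, fsc_log2 = t$fsc_log2)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an event table
#'
#' Applies the base-2 logarithm to both channels, the scale on which 1n and 2n
#' density modes of a DNA-content histogram sit one unit apart. Linear values
#' are retained (the binned CV statistic is computed on the linear signal).
#'
#' @param t An [event_table()] with positive linear values.
#' @return The same table with `fluor_log2` and `fsc_log2` columns appended;
#'   event order is preserved.
#' @export
log2_transform <- function(t) {
  if (any(t$fluor_linear <= 0) || any(t$fsc_linear <= 0)) {
    stop_cytomito("non-positive values present; they must be filtered before log2",
                  "cytomito_contract_error")
  }
  t$fluor_log2 <- log2(t$fluor_linear)
  t$fsc_log2 <- log2(t$fsc_linear)
  t
}
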