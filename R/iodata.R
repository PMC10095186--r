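#' Canonical event-table schema
#'
#' An event table is a tibble with one row per acquired object. Mandatory
#' columns are `event_id` (unique integer), `rsg_intensity` and `pi_intensity`
#' (relative fluorescence units, nonnegative). Optional columns are the
#' feature columns of [feature_columns()], `true_label` (generator ground
#' truth), `assigned_label` (pipeline output) and `replicate_id`. Any other
#' column is carried through unchanged as passthrough metadata.
#'
#' @return `event_labels()` returns the vocabulary of per-event labels;
#'   `feature_columns()` the canonical feature column names;
#'   `classifier_features()` the default candidate feature set for the
#'   cells-vs-debris classifier.
#' @export
event_labels <- function() {
  c("active", "mid_active_1", "mid_active_2", "dead",
    "debris", "aggregate", "out_of_focus", "unclassified")
}

#' @rdname event_labels
#' @export
feature_columns <- function() {
  c("gradient_rms", "area_um2", "aspect_ratio", "major_axis_um",
    "major_axis_intensity_um",
    "h_entropy_mean_bf", "h_entropy_std_bf",
    "h_homogeneity_mean_bf", "h_homogeneity_std_bf",
    "h_entropy_mean_rsg", "h_entropy_std_rsg")
}

#' @rdname event_labels
#' @export
classifier_features <- function() {
  c("h_entropy_std_rsg", "h_entropy_std_bf", "h_homogeneity_std_bf",
    "area_um2", "h_entropy_mean_rsg", "major_axis_intensity_um",
    "h_entropy_mean_bf")
}

mandatory_columns <- function() c("event_id", "rsg_intensity", "pi_intensity")

#' Construct and validate an event table
#'
#' Coerces a data frame to the canonical schema: checks mandatory columns,
#' uniqueness of `event_id`, nonnegative intensities and finite features, and
#' fills `assigned_label = "unclassified"` and `replicate_id = 1` when absent.
#'
#' @param x A data frame with at least `event_id`, `rsg_intensity`,
#'   `pi_intensity`.
#' @return A validated tibble.
#' @export
event_table <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(mandatory_columns(), names(x))
  if (length(missing_cols)) {
    abort(paste0("Event table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ifcgate_schema_error")
  }
  x$event_id <- as.integer(x$event_id)
  if (anyDuplicated(x$event_id)) {
    abort("`event_id` must be unique within an event table.",
          class = "ifcgate_validation_error")
  }
  for (col in c("rsg_intensity", "pi_intensity")) {
    bad <- which(!is.finite(x[[col]]) | x[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("Column `%s` must be finite and >= 0; first bad row: %d.",
                    col, bad[1]),
            class = "ifcgate_validation_error")
    }
  }
  if (!"assigned_label" %in% names(x)) x$assigned_label <- "unclassified"
  bad_lab <- setdiff(unique(x$assigned_label), event_labels())
  if (length(bad_lab)) {
    abort(paste0("Unknown assigned_label value(s): ",
                 paste(bad_lab, collapse = ", ")),
          class = "ifcgate_validation_error")
  }
  if (!"replicate_id" %in% names(x)) x$replicate_id <- 1L
  x$replicate_id <- as.integer(x$replicate_id)
  x
}

#' Read an event table from CSV or FCS
#'
#' CSV is the canonical on-disk format (comma-separated, UTF-8, `.` decimal,
#' header row mandatory). FCS 3.0/3.1 list-mode files are supported for
#' interoperability: parameter short names (`$PnN`) are matched to schema
#' columns, optionally through `channel_map`.
#'
#' @param path File path.
#' @param format `"csv"`, `"fcs"`, or `"auto"` (by file extension).
#' @param channel_map Named character vector mapping FCS parameter short
#'   names to schema column names, e.g. `c(FL1 = "rsg_intensity")`.
#' @return A validated event table.
#' @export
read_event_table <- function(path, format = c("auto", "csv", "fcs"),
                             channel_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    fcs = read_fcs_table(path, channel_map = channel_map)
  )
  event_table(x)
}

#' Write an event table to CSV or FCS
#'
#' CSV stores the full schema including labels; FCS stores `event_id`,
#' intensities and numeric feature columns as parameters (labels and other
#' non-numeric columns are not representable in FCS list mode).
#'
#' @param table A validated event table.
#' @param path Output file path.
#' @param format `"csv"`, `"fcs"`, or `"auto"` (by file extension).
#' @export
write_event_table <- function(table, path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  table <- event_table(table)
  switch(format,
    csv = readr::write_csv(table, path, progress = FALSE),
    fcs = write_fcs_table(table, path)
  )
  invisible(path)
}

# ---- minimal FCS 3.0 codec -------------------------------------------------
# List mode, $DATATYPE F (float32), little-endian. One parameter per numeric
# column. This is a deliberately small codec for interoperability, not a full
# FCS implementation (no analysis segment, no compensation keywords).

write_fcs_table <- function(table, path) {
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  mat <- as.matrix(as.data.frame(table[num_cols]))
  storage.mode(mat) <- "double"
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  d <- "/"
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- num_cols[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(max(1, ceiling(max(mat[, i], 0,
                                                               na.rm = TRUE))))
  }
  build_text <- function(begin_data, end_data) {
    all_kw <- c(kw, "$BEGINDATA" = sprintf("%12d", begin_data),
                "$ENDDATA" = sprintf("%12d", end_data))
    paste0(d, paste0(names(all_kw), d, unname(all_kw), d, collapse = ""))
  }
  header_len <- 58L
  text0 <- build_text(0L, 0L)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  text <- build_text(data_begin, data_end)
  stopifnot(nchar(text) == nchar(text0))
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0L,
                    if (data_end <= 99999999) data_end else 0L,
                    0L, 0L)
  stopifnot(nchar(header) == header_len)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  # row-major event stream, float32
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs_table <- function(path, channel_map = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  header <- rawToChar(raw[1:58])
  if (!grepl("^FCS3\\.", header)) {
    abort("Not an FCS 3.x file.", class = "ifcgate_schema_error")
  }
  off <- function(i) {
    as.integer(substr(header, 11 + (i - 1) * 8, 10 + i * 8))
  }
  text_raw <- raw[(off(1) + 1):(off(2) + 1)]
  txt <- rawToChar(text_raw)
  d <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), d, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, keys)
  if (toupper(trimws(kw[["$DATATYPE"]])) != "F") {
    abort("Only $DATATYPE F (float) FCS files are supported.",
          class = "ifcgate_schema_error")
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  data_begin <- as.integer(trimws(kw[["$BEGINDATA"]]))
  if (is.na(data_begin) || data_begin == 0L) data_begin <- off(3)
  little <- trimws(kw[["$BYTEORD"]]) == "1,2,3,4"
  vals <- readBin(raw[(data_begin + 1):length(raw)], "numeric",
                  n = n_par * n_tot, size = 4L,
                  endian = if (little) "little" else "big")
  mat <- matrix(vals, ncol = n_par, byrow = TRUE)
  pn <- vapply(seq_len(n_par),
               function(i) kw[[sprintf("$P%dN", i)]], character(1))
  if (!is.null(channel_map)) {
    hit <- pn %in% names(channel_map)
    pn[hit] <- unname(channel_map[pn[hit]])
  }
  colnames(mat) <- pn
  out <- tibble::as_tibble(mat)
  if (!"event_id" %in% names(out)) out$event_id <- seq_len(nrow(out))
  out
}
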