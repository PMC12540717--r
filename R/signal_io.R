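#' Construct a multi-channel sEMG signal record
#'
#' A `signal_record` bundles a block of samples with its sampling rate and
#' the labels needed downstream: gesture class, subject id and recording
#' session id.
#'
#' @param samples Numeric matrix, one row per sample, one column per channel.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector naming the columns of `samples`.
#' @param gesture Gesture label for the whole record.
#' @param subject Subject identifier.
#' @param session Recording-session identifier.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, channel_names = NULL,
                          gesture = NA_character_, subject = NA_character_,
                          session = NA_character_) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stop("signal_record: samples must have at least one row and one column")
  if (!all(is.finite(samples)))
    stop("signal_record: samples contain non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("signal_record: fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_names) != ncol(samples))
    stop("signal_record: channel_names length must match channel count")
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         gesture = as.character(gesture), subject = as.character(subject),
         session = as.character(session)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "signal_record: %d samples x %d channels @ %g Hz (%.3g s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  gesture=%s subject=%s session=%s\n",
              x$gesture, x$subject, x$session))
  invisible(x)
}

#' Read a delimited-text signal file
#'
#' Reads a plain-text signal export: one row per sample, one column per
#' channel, comma- or whitespace-delimited (auto-detected), no header by
#' default. Parse failures report the offending line number.
#'
#' @param path Path to the signal file.
#' @param fs Sampling rate in Hz to attach to the record.
#' @param channel_names Channel names; also fixes the expected column count.
#' @param header Logical; skip a single header line when `TRUE`.
#' @inheritParams signal_record
#' @return A [signal_record()].
#' @export
read_signal <- function(path, fs, channel_names = NULL, header = FALSE,
                        gesture = NA_character_, subject = NA_character_,
                        session = NA_character_) {
  if (!file.exists(path))
    stop(sprintf("read_signal: file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (header && length(lines) >= 1L) {
    lines <- lines[-1L]
    offset <- 1L
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("read_signal: no data rows in %s", path))
  delim <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "[[:space:]]+"
  cells <- strsplit(trimws(lines), delim)
  ncols <- lengths(cells)
  if (any(ncols != ncols[[1L]])) {
    bad <- which(ncols != ncols[[1L]])[[1L]]
    stop(sprintf("read_signal: ragged row at line %d of %s (%d columns, expected %d)",
                 bad + offset, path, ncols[[bad]], ncols[[1L]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ((which(is.na(vals))[[1L]] - 1L) %/% ncols[[1L]]) + 1L
    stop(sprintf("read_signal: non-numeric value at line %d of %s",
                 bad_row + offset, path))
  }
  samples <- matrix(vals, ncol = ncols[[1L]], byrow = TRUE)
  if (!is.null(channel_names) && length(channel_names) != ncol(samples))
    stop(sprintf(
      "read_signal: %s has %d channels but %d channel names were given",
      path, ncol(samples), length(channel_names)))
  signal_record(samples, fs, channel_names, gesture, subject, session)
}

#' Write a signal record as delimited text
#'
#' Values are serialized at full double precision so a read/write cycle is
#' lossless.
#'
#' @param record A [signal_record()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` by default.
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path, delim = ",") {
  stopifnot(inherits(record, "signal_record"))
  rows <- apply(record$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = delim))
  writeLines(rows, path)
  invisible(path)
}

#' Construct a dataset manifest
#'
#' A manifest assigns a gesture, subject and session label to each signal
#' file and carries the shared sampling rate and channel names. Entry order
#' is load-bearing: the temporal split downstream preserves it.
#'
#' @param entries Data frame with columns `path`, `gesture`, `subject`,
#'   `session`.
#' @param fs Sampling rate in Hz shared by all files.
#' @param channel_names Shared channel names.
#' @param label_set Declared set of admissible gesture labels; defaults to
#'   the labels present in `entries`.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(entries, fs, channel_names,
                             label_set = unique(entries$gesture)) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("path", "gesture", "subject", "session")
  if (!all(needed %in% names(entries)))
    stop("dataset_manifest: entries must have columns path, gesture, subject, session")
  if (anyDuplicated(entries$path))
    stop("dataset_manifest: duplicate paths in manifest")
  if (!all(entries$gesture %in% label_set))
    stop("dataset_manifest: gesture label outside the declared label set")
  structure(
    list(entries = entries[, needed], fs = fs,
         channel_names = as.character(channel_names),
         label_set = as.character(label_set)),
    class = "dataset_manifest"
  )
}

#' Read / write a YAML dataset manifest
#'
#' @param path Manifest file path.
#' @return `read_manifest` returns a [dataset_manifest()];
#'   `write_manifest` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_manifest: file not found: %s", path))
  y <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(y$entries, function(e)
    data.frame(path = e$path, gesture = e$gesture, subject = e$subject,
               session = e$session, stringsAsFactors = FALSE)))
  # relative paths resolve against the manifest's own directory
  rel <- !grepl("^(/|[A-Za-z]:)", entries$path)
  entries$path[rel] <- file.path(dirname(path), entries$path[rel])
  dataset_manifest(entries, fs = y$fs, channel_names = y$channel_names,
                   label_set = if (!is.null(y$label_set)) y$label_set
                               else unique(entries$gesture))
}

#' @rdname read_manifest
#' @param manifest A [dataset_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  y <- list(
    fs = manifest$fs,
    channel_names = as.list(manifest$channel_names),
    label_set = as.list(manifest$label_set),
    entries = lapply(seq_len(nrow(manifest$entries)), function(i) {
      e <- manifest$entries[i, ]
      list(path = e$path, gesture = e$gesture, subject = e$subject,
           session = e$session)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load all records referenced by a manifest
#'
#' Records come back in manifest order; any unreadable entry aborts the
#' load naming the offending path.
#'
#' @param manifest A [dataset_manifest()].
#' @return List of [signal_record()] objects, in manifest order.
#' @export
load_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  lapply(seq_len(nrow(manifest$entries)), function(i) {
    e <- manifest$entries[i, ]
    if (!file.exists(e$path))
      stop(sprintf("load_dataset: cannot read manifest entry: %s", e$path))
    read_signal(e$path, fs = manifest$fs,
                channel_names = manifest$channel_names,
                gesture = e$gesture, subject = e$subject,
                session = e$session)
  })
}

#' Construct a feature matrix
#'
#' Rows are analysis windows; columns are `<feature>_<channel>` values.
#' Gesture/subject/session labels ride along one per row.
#'
#' @param values Numeric matrix, windows x features, with column names.
#' @param gesture,subject,session Per-row label vectors.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, gesture, subject, session) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("feature_matrix: values must have column names")
  if (anyDuplicated(colnames(values)))
    stop("feature_matrix: duplicate feature column names")
  if (!all(is.finite(values)))
    stop("feature_matrix: non-finite feature values")
  n <- nrow(values)
  if (length(gesture) != n || length(subject) != n || length(session) != n)
    stop("feature_matrix: label lengths must equal the number of rows")
  structure(
    list(values = values, gesture = as.character(gesture),
         subject = as.character(subject), session = as.character(session)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d windows x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$gesture))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the rows of a feature matrix
#'
#' @param m A [feature_matrix()].
#' @param idx Row index vector.
#' @return A `feature_matrix` with the selected rows.
#' @export
fm_rows <- function(m, idx) {
  stopifnot(inherits(m, "feature_matrix"))
  feature_matrix(m$values[idx, , drop = FALSE], m$gesture[idx],
                 m$subject[idx], m$session[idx])
}

#' Bind feature matrices by row
#' @param ... `feature_matrix` objects with identical columns.
#' @return A combined `feature_matrix`.
#' @export
fm_rbind <- function(...) {
  ms <- list(...)
  cols <- colnames(ms[[1L]]$values)
  for (m in ms)
    if (!identical(colnames(m$values), cols))
      stop("fm_rbind: column schemas differ")
  feature_matrix(do.call(rbind, lapply(ms, `[[`, "values")),
                 unlist(lapply(ms, `[[`, "gesture")),
                 unlist(lapply(ms, `[[`, "subject")),
                 unlist(lapply(ms, `[[`, "session")))
}

#' Write / read a feature table as CSV
#'
#' The on-disk layout is one header row of feature names followed by the
#' three label columns `gesture`, `subject`, `session`. Feature values are
#' serialized at full double precision so `read_feature_table(write(...))`
#' reproduces the matrix bit for bit.
#'
#' @param m A [feature_matrix()].
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_matrix`.
#' @export
write_feature_table <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  hdr <- paste(c(colnames(m$values), "gesture", "subject", "session"),
               collapse = ",")
  rows <- vapply(seq_len(nrow(m$values)), function(i)
    paste(c(sprintf("%.17g", m$values[i, ]),
            m$gesture[i], m$subject[i], m$session[i]), collapse = ","),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_feature_table: file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- c("gesture", "subject", "session")
  if (!all(lab %in% names(df)))
    stop("read_feature_table: schema error: missing label column(s) ",
         paste(setdiff(lab, names(df)), collapse = ", "))
  feat_cols <- setdiff(names(df), lab)
  if (length(feat_cols) == 0L)
    stop("read_feature_table: schema error: no feature columns")
  vals <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(vals))
    stop("read_feature_table: schema error: non-numeric feature column")
  feature_matrix(vals, df$gesture, df$subject, df$session)
}
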