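#' Construct a single-channel signal object
#'
#' A `msld_signal` wraps an ordered numeric series with its sampling
#' frequency and optional class label. Amplitude units are arbitrary
#' (typically microvolts for EEG); no operation depends on `fs` except
#' duration reporting.
#'
#' @param samples Numeric vector, length >= 2, all values finite.
#' @param fs Sampling frequency in Hz (> 0). Default 173.61, the rate of
#'   the one-sample-per-line EEG archive dialect this package reads.
#' @param record_id Opaque identifier string.
#' @param label Optional class tag (e.g. "ictal", "interictal", "normal").
#' @return An object of class `msld_signal`: a list with elements
#'   `samples`, `fs`, `record_id`, `label`.
#' @export
#' @examples
#' s <- signal(sin(seq_len(256) / 10), fs = 173.61, record_id = "demo")
#' signal_duration(s)
signal <- function(samples, fs = 173.61, record_id = "signal", label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a signal needs at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) {
    stop("signal '", record_id, "' contains non-finite samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (!is.null(label)) label <- as.character(label)
  structure(
    list(samples = samples, fs = fs,
         record_id = as.character(record_id), label = label),
    class = "msld_signal"
  )
}

#' @export
print.msld_signal <- function(x, ...) {
  cat(sprintf("<msld_signal> %s: %d samples @ %.2f Hz (%.1f s)%s\n",
              x$record_id, length(x$samples), x$fs,
              signal_duration(x),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' @export
length.msld_signal <- function(x) length(x$samples)

#' Record duration in seconds
#'
#' @param x A `msld_signal`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "msld_signal"))
  length(x$samples) / x$fs
}

#' Read a one-sample-per-line ASCII signal file
#'
#' Reads the plain-text dialect used by the Bonn EEG archive: one integer
#' or decimal amplitude per line, optional surrounding whitespace, blank
#' lines ignored. Class labels are never parsed from file contents; they
#' come from the manifest (see [read_labeled_set()]).
#'
#' @param path Path to the file.
#' @param fs Sampling frequency in Hz attached to the result.
#' @param label Optional class tag.
#' @return A [signal()] with samples in file line order and `record_id`
#'   derived from the file name (basename without extension).
#' @export
read_signal <- function(path, fs = 173.61, label = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  txt <- trimws(lines[keep])
  vals <- suppressWarnings(as.numeric(txt))
  bad <- which(!is.finite(vals))
  if (length(bad) > 0L) {
    stop("non-numeric value at line ", line_no[bad[1L]],
         " of ", path, ": '", txt[bad[1L]], "'")
  }
  if (length(vals) < 2L) {
    stop("degenerate input: ", path, " holds ", length(vals),
         " sample(s); at least 2 required")
  }
  rid <- sub("\\.[^.]*$", "", basename(path))
  signal(vals, fs = fs, record_id = rid, label = label)
}

#' Read a labeled collection of signal files
#'
#' @param manifest Named list mapping class label -> character vector of
#'   file paths. Manifest order is preserved; `class_names` are labels in
#'   first-appearance order.
#' @param fs Sampling frequency attached to every signal.
#' @return An object of class `msld_signal_set`: list with `signals`
#'   (list of `msld_signal`) and `class_names`.
#' @export
read_labeled_set <- function(manifest, fs = 173.61) {
  if (!is.list(manifest) || is.null(names(manifest)) ||
      any(!nzchar(names(manifest)))) {
    stop("manifest must be a named list of label -> file paths")
  }
  labels <- names(manifest)
  if (anyDuplicated(labels)) stop("duplicate labels in manifest")
  signals <- list()
  for (lab in labels) {
    paths <- manifest[[lab]]
    if (length(paths) == 0L) stop("class '", lab, "' has no files")
    for (p in paths) {
      signals[[length(signals) + 1L]] <- read_signal(p, fs = fs, label = lab)
    }
  }
  signal_set(signals, class_names = labels)
}

#' Construct a labeled signal set
#'
#' @param signals List of [signal()] objects, each carrying a label.
#' @param class_names Optional ordered label vector; defaults to labels in
#'   first-appearance order.
#' @return An object of class `msld_signal_set`.
#' @export
signal_set <- function(signals, class_names = NULL) {
  if (length(signals) == 0L) stop("signal set is empty")
  labs <- vapply(signals, function(s) {
    if (is.null(s$label)) NA_character_ else s$label
  }, character(1))
  if (anyNA(labs)) stop("every signal in a labeled set needs a label")
  if (is.null(class_names)) class_names <- unique(labs)
  if (!all(labs %in% class_names)) {
    stop("labels outside class_names: ",
         paste(setdiff(labs, class_names), collapse = ", "))
  }
  structure(list(signals = signals, class_names = class_names),
            class = "msld_signal_set")
}

#' @export
print.msld_signal_set <- function(x, ...) {
  labs <- vapply(x$signals, `[[`, character(1), "label")
  cat(sprintf("<msld_signal_set> %d signals, %d classes\n",
              length(x$signals), length(x$class_names)))
  print(table(factor(labs, levels = x$class_names)))
  invisible(x)
}

#' @export
length.msld_signal_set <- function(x) length(x$signals)

#' Write a feature table to CSV
#'
#' Writes `record_id`, `label`, then one `sampen_d<d>` column per
#' distance. Values are written at full double precision (17 significant
#' digits) so that [read_feature_table()] round-trips losslessly.
#'
#' @param table A feature table from [extract_feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "msld_feature_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty feature table")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param params Optional [sampen_params()] to re-attach (CSV carries no
#'   metadata beyond the header).
#' @return A `msld_feature_table`.
#' @export
read_feature_table <- function(path, params = sampen_params()) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character",
                                       label = "character"))
  fcols <- grep("^sampen_d[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L) stop("no sampen_d* columns in ", path)
  dd <- as.integer(sub("^sampen_d", "", fcols))
  if (!identical(dd, seq(min(dd), max(dd)))) {
    stop("feature columns are not a contiguous distance range")
  }
  new_feature_table(df[c("record_id", "label", fcols)],
                    d_min = min(dd), d_max = max(dd), params = params)
}
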