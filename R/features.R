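new_feature_table <- function(df, d_min, d_max, params) {
  stopifnot(is.data.frame(df))
  structure(df,
            d_min = as.integer(d_min), d_max = as.integer(d_max),
            params = params,
            class = c("msld_feature_table", "data.frame"))
}

#' MSLD sample-entropy feature vector for one signal
#'
#' Computes the MSLD transform at every distance in `d_min..d_max` and
#' the sample entropy of each difference signal, giving one feature per
#' distance. In `relative_sd` mode the tolerance is scaled by each
#' difference signal's own SD. Undefined entropies (no template matches)
#' are substituted by the finite ceiling `log((N - m) * (N - m - 1) / 2)`
#' where `N` is the length of that difference signal, preserving the
#' "maximally irregular" ordering while keeping every feature finite.
#'
#' @param signal A [signal()] or numeric vector.
#' @param d_min,d_max Contiguous distance range (defaults 1..20).
#' @param params A [sampen_params()].
#' @return Named numeric vector (`sampen_d1`, ...) with attributes
#'   `record_id`, `label`, and `n_substituted` (count of ceiling
#'   substitutions).
#' @export
extract_features <- function(signal, d_min = 1L, d_max = 20L,
                             params = sampen_params()) {
  v <- .as_series(signal)
  n <- length(v)
  if (d_max > n - params$m - 2L) {
    stop("d_max = ", d_max, " too large: need d_max <= N - m - 2 = ",
         n - params$m - 2L, " so every difference signal supports SampEn")
  }
  ms <- msld_set(v, d_min, d_max)
  vals <- vapply(ms$diffs, function(dsig) {
    sample_entropy(dsig$values, params)
  }, numeric(1))
  nsub <- sum(is.na(vals))
  if (nsub > 0L) {
    for (i in which(is.na(vals))) {
      nd <- length(ms$diffs[[i]]$values) - params$m
      vals[i] <- log(nd * (nd - 1) / 2)
    }
  }
  names(vals) <- paste0("sampen_", names(ms$diffs))
  rid <- if (inherits(signal, "msld_signal")) signal$record_id else "signal"
  lab <- if (inherits(signal, "msld_signal")) signal$label else NULL
  structure(vals, record_id = rid, label = lab, n_substituted = nsub)
}

#' Feature table for a labeled signal set
#'
#' One row per signal, input order preserved; columns `record_id`,
#' `label`, `sampen_d<d_min>` .. `sampen_d<d_max>`.
#'
#' @param set A `msld_signal_set` (see [signal_set()], [read_labeled_set()],
#'   [gen_labeled_set()]).
#' @inheritParams extract_features
#' @param progress Emit a progress message every `progress` records via
#'   `message()`; 0 disables.
#' @return A `msld_feature_table` (data frame with `d_min`, `d_max`,
#'   `params` attributes). The total number of undefined-entropy ceiling
#'   substitutions is reported once via `message()` when non-zero.
#' @export
extract_feature_table <- function(set, d_min = 1L, d_max = 20L,
                                  params = sampen_params(), progress = 0L) {
  stopifnot(inherits(set, "msld_signal_set"))
  if (length(set$signals) == 0L) stop("empty signal set")
  nsub_total <- 0L
  rows <- vector("list", length(set$signals))
  for (i in seq_along(set$signals)) {
    s <- set$signals[[i]]
    fv <- tryCatch(
      extract_features(s, d_min, d_max, params),
      error = function(e) {
        stop("feature extraction failed for record '", s$record_id,
             "': ", conditionMessage(e))
      }
    )
    nsub_total <- nsub_total + attr(fv, "n_substituted")
    rows[[i]] <- c(list(record_id = s$record_id, label = s$label),
                   as.list(unclass(fv)))
    if (progress > 0L && i %% progress == 0L) {
      message("extracted ", i, "/", length(set$signals), " records")
    }
  }
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  if (nsub_total > 0L) {
    message(nsub_total, " undefined SampEn value(s) replaced by the ",
            "finite ceiling")
  }
  new_feature_table(df, d_min, d_max, params)
}

#' Restrict a feature table to a narrower distance range
#'
#' Because each feature depends only on its own distance, slicing the
#' columns of a wide table is exactly equivalent to re-extracting at the
#' narrower range. The grid driver uses this to derive the reduced-scale
#' feature sets from a single wide extraction.
#'
#' @param table A `msld_feature_table`.
#' @param d_min,d_max Target range, contained in the table's range.
#' @return The column-sliced `msld_feature_table`.
#' @export
restrict_scales <- function(table, d_min, d_max) {
  stopifnot(inherits(table, "msld_feature_table"))
  t_min <- attr(table, "d_min"); t_max <- attr(table, "d_max")
  d_min <- as.integer(d_min); d_max <- as.integer(d_max)
  if (d_min < t_min || d_max > t_max || d_min > d_max) {
    stop("requested range [", d_min, ", ", d_max,
         "] not contained in table range [", t_min, ", ", t_max, "]")
  }
  keep <- c("record_id", "label", paste0("sampen_d", d_min:d_max))
  new_feature_table(as.data.frame(table)[keep], d_min, d_max,
                    attr(table, "params"))
}

#' Create a feature table from a data frame
#'
#' For features computed outside [extract_feature_table()] (or read from
#' foreign CSV): the data frame must hold `record_id`, `label` and a
#' contiguous block of `sampen_d<d>` columns.
#'
#' @param df A data frame.
#' @param params The [sampen_params()] the features were computed with.
#' @return A `msld_feature_table`.
#' @export
as_feature_table <- function(df, params = sampen_params()) {
  stopifnot(is.data.frame(df))
  if (!all(c("record_id", "label") %in% names(df))) {
    stop("data frame needs 'record_id' and 'label' columns")
  }
  fcols <- grep("^sampen_d[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L) stop("no sampen_d* columns")
  dd <- sort(as.integer(sub("^sampen_d", "", fcols)))
  if (!identical(dd, seq(min(dd), max(dd)))) {
    stop("feature columns are not a contiguous distance range")
  }
  ordered <- df[c("record_id", "label", paste0("sampen_d", dd))]
  new_feature_table(ordered, min(dd), max(dd), params)
}

#' Numeric feature matrix of a feature table
#'
#' @param table A `msld_feature_table`.
#' @return Numeric matrix (rows = records, columns = distances).
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "msld_feature_table"))
  fcols <- grep("^sampen_d[0-9]+$", names(table), value = TRUE)
  as.matrix(as.data.frame(table)[fcols])
}

#' @export
print.msld_feature_table <- function(x, ...) {
  cat(sprintf("<msld_feature_table> %d records x distances %d..%d\n",
              nrow(x), attr(x, "d_min"), attr(x, "d_max")))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}
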