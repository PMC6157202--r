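#' Multidistance Signal Level Difference transform
#'
#' Computes the absolute difference of the series with a copy of itself
#' shifted by `d` samples: `y_d(i) = |x(i) - x(i + d)|` for
#' `i = 1 .. N - d`. This is the one-dimensional analogue of the
#' gray-level difference texture statistic; unlike coarse-graining it does
#' not shrink signal variance with increasing distance.
#'
#' The admissible range is `1 <= d <= N - 2` (not `N - 1`): the result
#' must retain at least 2 samples so that sample entropy remains
#' computable downstream.
#'
#' @param x A [signal()] or a plain numeric vector.
#' @param d Positive integer distance.
#' @return An object of class `msld_diff`: list with `values`
#'   (non-negative numeric vector of length `N - d`), `distance`, and
#'   `source_length`.
#' @export
#' @examples
#' msld_transform(c(3, 1, 4, 1, 5), 1)$values  # 2 3 3 4
msld_transform <- function(x, d) {
  v <- if (inherits(x, "msld_signal")) x$samples else as.numeric(x)
  n <- length(v)
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L || d > n - 2L) {
    stop("distance d must satisfy 1 <= d <= N - 2 = ", n - 2L,
         " (got d = ", d, ", N = ", n, ")")
  }
  structure(
    list(values = abs(v[seq_len(n - d)] - v[(d + 1L):n]),
         distance = d, source_length = n),
    class = "msld_diff"
  )
}

#' @export
print.msld_diff <- function(x, ...) {
  cat(sprintf("<msld_diff> d=%d, %d values (source N=%d)\n",
              x$distance, length(x$values), x$source_length))
  invisible(x)
}

#' MSLD transform over a contiguous distance range
#'
#' @param x A [signal()] or numeric vector.
#' @param d_min,d_max Positive integers, `1 <= d_min <= d_max <= N - 2`.
#'   The default range 1..20 matches the widest feature set the grid
#'   driver uses; distances beyond ~15 are reported by practitioners to
#'   add little, but the full range is supported.
#' @return An object of class `msld_set`: list with `diffs` (list of
#'   `msld_diff`, names `d<d>`), `d_min`, `d_max`.
#' @export
msld_set <- function(x, d_min = 1L, d_max = 20L) {
  v <- if (inherits(x, "msld_signal")) x$samples else as.numeric(x)
  n <- length(v)
  d_min <- as.integer(d_min); d_max <- as.integer(d_max)
  if (d_min < 1L || d_min > d_max || d_max > n - 2L) {
    stop("invalid distance range [", d_min, ", ", d_max,
         "]; need 1 <= d_min <= d_max <= N - 2 = ", n - 2L)
  }
  ds <- d_min:d_max
  diffs <- lapply(ds, function(d) msld_transform(v, d))
  names(diffs) <- paste0("d", ds)
  structure(list(diffs = diffs, d_min = d_min, d_max = d_max),
            class = "msld_set")
}

#' @export
print.msld_set <- function(x, ...) {
  cat(sprintf("<msld_set> distances %d..%d (source N=%d)\n",
              x$d_min, x$d_max, x$diffs[[1L]]$source_length))
  invisible(x)
}
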