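#' Sample entropy parameters
#'
#' @param m Embedding dimension (template length), a positive integer.
#'   Default 2, the standard Richman-Moorman choice.
#' @param r Match tolerance, a positive real. In `relative_sd` mode it is
#'   a fraction of the analyzed series' population standard deviation;
#'   in `absolute` mode it is used as-is in signal units.
#' @param tolerance_mode `"relative_sd"` (default) or `"absolute"`. With
#'   `relative_sd` the tolerance is taken from each analyzed series' own
#'   SD, which makes the measure invariant to amplitude scaling.
#' @return An object of class `sampen_params`.
#' @export
sampen_params <- function(m = 2L, r = 0.25,
                          tolerance_mode = c("relative_sd", "absolute")) {
  m <- as.integer(m)
  tolerance_mode <- match.arg(tolerance_mode)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be an integer >= 1")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("r must be a single positive number")
  }
  structure(list(m = m, r = r, tolerance_mode = tolerance_mode),
            class = "sampen_params")
}

#' @export
print.sampen_params <- function(x, ...) {
  cat(sprintf("<sampen_params> m=%d, r=%g (%s)\n", x$m, x$r,
              x$tolerance_mode))
  invisible(x)
}

.as_series <- function(x) {
  if (inherits(x, "msld_diff")) return(x$values)
  if (inherits(x, "msld_signal")) return(x$samples)
  as.numeric(x)
}

.check_series <- function(v, m, what = "series") {
  if (length(v) < m + 2L) {
    stop(what, " too short for m = ", m, ": need at least ", m + 2L,
         " samples, got ", length(v))
  }
  if (!all(is.finite(v))) stop(what, " contains non-finite values")
}

# Population (divide-by-N) standard deviation; the conventional scaling
# for the r * SD tolerance.
.pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Count template-match pairs
#'
#' Counts unordered distinct pairs of templates matching under the
#' Chebyshev (max-norm) distance at lengths `m` and `m + 1`, both taken
#' over the same index range `i = 1 .. N - m` so the two counts are
#' comparable. A match at `m + 1` implies a match at `m`, hence
#' `a_pairs <= b_pairs`. Matching is inclusive (`<= tol`), which matters
#' for integer-valued series.
#'
#' @param series Numeric vector (or `msld_diff` / `msld_signal`) with at
#'   least `m + 2` finite samples.
#' @param m Template length, integer >= 1.
#' @param tol Absolute match tolerance, > 0.
#' @return List with `b_pairs` (matches at length m), `a_pairs` (matches
#'   at length m + 1) and `n_templates` (`N - m`).
#' @export
count_template_matches <- function(series, m, tol) {
  v <- .as_series(series)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be an integer >= 1")
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop("tol must be a single positive number")
  }
  .check_series(v, m)
  cnt <- .count_matches_cpp(v, m, tol)
  list(b_pairs = cnt[[1L]], a_pairs = cnt[[2L]], n_templates = cnt[[3L]])
}

.sampen_from_counts <- function(b, a) {
  if (b == 0 || a == 0) NA_real_ else -log(a / b)
}

#' Sample entropy of a series
#'
#' Computes `SampEn(m, r, N) = -ln(A / B)` where `B` and `A` count
#' template pairs matching within the tolerance at lengths `m` and
#' `m + 1` respectively (Chebyshev distance, self-matches excluded; see
#' [count_template_matches()]). Higher values indicate greater
#' irregularity.
#'
#' Edge cases: a constant series is defined as perfectly regular and
#' returns 0 before any SD scaling is attempted (this is the limit of the
#' definition as all pairs match). When no pairs match at length `m`
#' (`B = 0`) or none survive to `m + 1` (`A = 0`) the estimator is
#' undefined and `NA` is returned; the feature layer substitutes the
#' finite ceiling `log((N - m) * (N - m - 1) / 2)` (the value `-ln(1/B)`
#' would take if exactly one of the `choose(N - m, 2)` pairs matched), so
#' classifiers downstream always see finite values.
#'
#' @param series Numeric vector (or `msld_diff` / `msld_signal`).
#' @param params A [sampen_params()].
#' @return A single non-negative number, or `NA_real_` when undefined.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500), sampen_params(m = 2, r = 0.2))
sample_entropy <- function(series, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  v <- .as_series(series)
  .check_series(v, params$m)
  if (max(v) == min(v)) return(0)
  tol <- switch(params$tolerance_mode,
    relative_sd = params$r * .pop_sd(v),
    absolute    = params$r
  )
  cnt <- .count_matches_cpp(v, params$m, tol)
  .sampen_from_counts(cnt[[1L]], cnt[[2L]])
}

#' Brute-force sample entropy (verification oracle)
#'
#' Same contract as [sample_entropy()], computed in R by exhaustive
#' enumeration of every template pair with no algorithmic shortcuts: the
#' full pairwise Chebyshev distance matrix is built offset by offset and
#' the counts read off its upper triangle. Intended for testing; refuses
#' series longer than 2000 samples to guard against the quadratic cost.
#'
#' @inheritParams sample_entropy
#' @return As [sample_entropy()].
#' @export
sample_entropy_bruteforce <- function(series, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  v <- .as_series(series)
  if (length(v) > 2000L) {
    stop("brute-force oracle is capped at 2000 samples (got ",
         length(v), ")")
  }
  .check_series(v, params$m)
  if (max(v) == min(v)) return(0)
  tol <- switch(params$tolerance_mode,
    relative_sd = params$r * .pop_sd(v),
    absolute    = params$r
  )
  m <- params$m
  nt <- length(v) - m
  idx <- seq_len(nt)
  # Chebyshev distance between every pair of length-(m+1) templates,
  # accumulated one offset at a time.
  cheb_m <- matrix(0, nt, nt)
  for (k in 0:(m - 1L)) {
    cheb_m <- pmax(cheb_m, abs(outer(v[idx + k], v[idx + k], "-")))
  }
  cheb_m1 <- pmax(cheb_m, abs(outer(v[idx + m], v[idx + m], "-")))
  upper <- upper.tri(cheb_m)
  b <- sum(cheb_m[upper] <= tol)
  a <- sum(cheb_m1[upper] <= tol)
  .sampen_from_counts(b, a)
}
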