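#' Synthetic signal class specification
#'
#' Describes one generator for the three-class synthetic EEG stand-in.
#' Available generators:
#' \describe{
#'   \item{white_noise}{i.i.d. Gaussian samples (`sd`).}
#'   \item{ar1}{First-order autoregression `x(t) = phi * x(t-1) + e(t)`
#'     with Gaussian innovations (`phi`, `sd` of innovations), started
#'     from the stationary distribution. With `stages > 1` the recursion
#'     is applied that many times in cascade, giving a steeper low-pass
#'     whose first differences are themselves smooth — single-stage AR
#'     differences at short lags are nearly white, which is too irregular
#'     to emulate smooth background EEG.}
#'   \item{sine_plus_noise}{`amp * sin(2 * pi * freq * t / fs)` plus
#'     Gaussian noise (`freq` in Hz, `amp`, `noise_sd`).}
#'   \item{ar1_sine}{Sum of a (cascaded) `ar1` process and a sinusoid
#'     (`phi`, `sd`, `stages`, `freq` in Hz, `amp_rel` = sine amplitude
#'     as a multiple of the AR component's realized SD): strongly
#'     autocorrelated background with a rhythmic component.}
#'   \item{spike_wave}{Rhythmic spike-and-wave morphology: a sinusoidal
#'     wave (`freq`, `amp`) with one sharp transient per cycle
#'     (`spike_amp`, `spike_width` in samples) riding on broadband
#'     Gaussian noise (`noise_sd`). Emulates ictal discharges.}
#' }
#'
#' @param name Class tag.
#' @param generator Generator name (see above).
#' @param params Named list of generator parameters.
#' @param expected_rank Complexity rank within a set (1 = lowest sample
#'   entropy profile).
#' @return An object of class `msld_class_spec`.
#' @export
class_spec <- function(name, generator, params = list(),
                       expected_rank = NA_integer_) {
  generator <- match.arg(generator, c("white_noise", "ar1",
                                      "sine_plus_noise", "ar1_sine",
                                      "spike_wave"))
  if (!is.null(params$phi) && abs(params$phi) >= 1) {
    stop("AR coefficient phi must satisfy |phi| < 1")
  }
  structure(list(name = as.character(name), generator = generator,
                 params = params, expected_rank = as.integer(expected_rank)),
            class = "msld_class_spec")
}

.p <- function(params, key, default) {
  if (is.null(params[[key]])) default else params[[key]]
}

.gen_white_noise <- function(n, p) rnorm(n, sd = .p(p, "sd", 1))

.gen_ar1 <- function(n, p) {
  phi <- .p(p, "phi", 0.9)
  sd_innov <- .p(p, "sd", 1)
  stages <- .p(p, "stages", 1L)
  x <- numeric(n)
  # stationary start; with phi = 0 this reduces exactly to white noise
  x[1] <- rnorm(1, sd = sd_innov / sqrt(1 - phi^2))
  e <- rnorm(n - 1, sd = sd_innov)
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  if (stages > 1L) {
    for (k in 2:stages) {
      x <- as.numeric(stats::filter(x, phi, method = "recursive"))
    }
  }
  x
}

.gen_sine_plus_noise <- function(n, p, fs) {
  t <- seq_len(n)
  .p(p, "amp", 1) * sin(2 * pi * .p(p, "freq", 5) * t / fs) +
    rnorm(n, sd = .p(p, "noise_sd", 0.1))
}

.gen_ar1_sine <- function(n, p, fs) {
  t <- seq_len(n)
  ar <- .gen_ar1(n, p)
  ar + .p(p, "amp_rel", 2) * stats::sd(ar) *
    sin(2 * pi * .p(p, "freq", 4) * t / fs)
}

.gen_spike_wave <- function(n, p, fs) {
  freq <- .p(p, "freq", 3)
  amp <- .p(p, "amp", 1)
  spike_amp <- .p(p, "spike_amp", 5)
  spike_width <- .p(p, "spike_width", 3)
  noise_sd <- .p(p, "noise_sd", 2)
  t <- seq_len(n)
  x <- amp * sin(2 * pi * freq * t / fs) + rnorm(n, sd = noise_sd)
  # one sharp transient per wave cycle, jittered within the cycle
  period <- fs / freq
  starts <- round(seq(1, n - spike_width, by = period) +
                    runif(length(seq(1, n - spike_width, by = period)),
                          0, period / 4))
  starts <- starts[starts >= 1 & starts + spike_width <= n]
  for (s in starts) {
    x[s:(s + spike_width - 1L)] <- x[s:(s + spike_width - 1L)] +
      spike_amp * sample(c(-1, 1), 1) *
        sin(pi * seq_len(spike_width) / (spike_width + 1))
  }
  x
}

#' Generate one synthetic signal
#'
#' Deterministic given `(spec, n_samples, seed)`; the caller's RNG state
#' is left untouched.
#'
#' @param spec A [class_spec()].
#' @param n_samples Number of samples (>= 64).
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param record_id Identifier for the resulting signal.
#' @return A [signal()] labeled with `spec$name`.
#' @export
gen_signal <- function(spec, n_samples = 4096L, fs = 173.61, seed = 1L,
                       record_id = NULL) {
  stopifnot(inherits(spec, "msld_class_spec"))
  n <- as.integer(n_samples)
  if (n < 64L) stop("n_samples must be >= 64")
  x <- .with_seed(seed, switch(spec$generator,
    white_noise     = .gen_white_noise(n, spec$params),
    ar1             = .gen_ar1(n, spec$params),
    sine_plus_noise = .gen_sine_plus_noise(n, spec$params, fs),
    ar1_sine        = .gen_ar1_sine(n, spec$params, fs),
    spike_wave      = .gen_spike_wave(n, spec$params, fs)
  ))
  if (is.null(record_id)) {
    record_id <- sprintf("%s_seed%d", spec$name, seed)
  }
  signal(x, fs = fs, record_id = record_id, label = spec$name)
}

#' Default three-class specifications
#'
#' The frozen defaults emulate the qualitative complexity ordering of
#' epileptic EEG: seizure activity is the most irregular, interictal
#' activity the most regular, with normal EEG in between. They make no
#' claim of physiological realism beyond that ordering and the
#' spike-burst morphology of the ictal class:
#' \itemize{
#'   \item `ictal-like` — `spike_wave`: 3 Hz spike-and-wave riding on
#'     dominant broadband noise (rank 3, highest entropy profile);
#'   \item `normal-like` — two-stage `ar1` with `phi = 0.9`: smooth
#'     background activity of intermediate complexity (rank 2);
#'   \item `interictal-like` — two-stage `ar1_sine` with `phi = 0.97`
#'     plus a 4 Hz rhythm at twice the background SD: strongly
#'     autocorrelated and rhythmic, most regular (rank 1).
#' }
#' The two smooth classes use cascaded AR(1) stages because the entropy
#' of the difference signals at short distances tracks the smoothness of
#' the *increments*: single-stage AR increments are nearly white, which
#' would push the regular classes above the ictal class at d = 1..2.
#' @return List of three [class_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    class_spec("ictal-like", "spike_wave",
               list(freq = 3, amp = 1, spike_amp = 5, spike_width = 3,
                    noise_sd = 2),
               expected_rank = 3L),
    class_spec("normal-like", "ar1",
               list(phi = 0.9, sd = 1, stages = 2L),
               expected_rank = 2L),
    class_spec("interictal-like", "ar1_sine",
               list(phi = 0.97, sd = 1, stages = 2L, freq = 4,
                    amp_rel = 2),
               expected_rank = 1L)
  )
}

# Per-record seed: a documented mix of (master seed, class index, record
# index) kept below 2^31 so any record is regenerable in isolation and
# generation order is irrelevant.
.record_seed <- function(seed, class_index, record_index) {
  as.integer((as.double(seed %% 65011L) * 33013 +
                class_index * 7577 + record_index * 257) %% 2147483647)
}

#' Generate a labeled synthetic signal set
#'
#' @param n_per_class Records per class (>= 5). Default 100, mirroring
#'   the archive layout the package targets (3 classes x 100 records).
#' @param n_samples Samples per record; default 4096.
#' @param seed Master seed; each record uses a seed derived from
#'   (seed, class index, record index).
#' @param specs List of [class_spec()]; default [default_class_specs()].
#' @param fs Sampling frequency in Hz.
#' @return A `msld_signal_set` of `length(specs) * n_per_class` signals.
#' @export
#' @examples
#' set <- gen_labeled_set(n_per_class = 5, n_samples = 256, seed = 1)
#' length(set)
gen_labeled_set <- function(n_per_class = 100L, n_samples = 4096L,
                            seed = 1L, specs = default_class_specs(),
                            fs = 173.61) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 5L) stop("n_per_class must be >= 5")
  ranks <- vapply(specs, `[[`, integer(1), "expected_rank")
  if (anyDuplicated(ranks[!is.na(ranks)])) {
    stop("expected_rank must be unique across specs")
  }
  signals <- list()
  for (ci in seq_along(specs)) {
    for (i in seq_len(n_per_class)) {
      rid <- sprintf("%s_%03d", specs[[ci]]$name, i)
      signals[[length(signals) + 1L]] <-
        gen_signal(specs[[ci]], n_samples, fs,
                   seed = .record_seed(seed, ci, i), record_id = rid)
    }
  }
  signal_set(signals,
             class_names = vapply(specs, `[[`, character(1), "name"))
}

#' Write a signal set as one-sample-per-line ASCII files
#'
#' Writes one file per record into a class-named subdirectory of `dir`,
#' plus a `manifest.csv` (columns `label`, `path`) so the set can be
#' re-read with [read_labeled_set()] through the same I/O path as real
#' archive data.
#'
#' @param set A `msld_signal_set`.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for written samples (default 10).
#' @return Path of the manifest file, invisibly.
#' @export
write_signal_dir <- function(set, dir, digits = 10L) {
  stopifnot(inherits(set, "msld_signal_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in set$signals) {
    cls_dir <- file.path(dir, s$label)
    dir.create(cls_dir, showWarnings = FALSE)
    path <- file.path(cls_dir, paste0(s$record_id, ".txt"))
    writeLines(formatC(s$samples, digits = digits, format = "g"), path)
    rows[[length(rows) + 1L]] <- data.frame(label = s$label, path = path,
                                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a manifest written by [write_signal_dir()]
#'
#' @param path Path to a `manifest.csv` with columns `label`, `path`
#'   (relative paths are resolved against the manifest's directory).
#' @param fs Sampling frequency attached to every signal.
#' @return A `msld_signal_set`.
#' @export
read_manifest <- function(path, fs = 173.61) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "path") %in% names(df))) {
    stop("manifest needs 'label' and 'path' columns")
  }
  base <- dirname(path)
  paths <- ifelse(file.exists(df$path), df$path, file.path(base, df$path))
  manifest <- split(paths, factor(df$label, levels = unique(df$label)))
  read_labeled_set(as.list(manifest), fs = fs)
}
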