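# Shared fixture builders; everything is generated in code at test time.

# Write a one-sample-per-line ASCII signal file, returning its path.
write_sig_file <- function(values, dir = withr::local_tempdir(),
                           name = "rec.txt") {
  path <- file.path(dir, name)
  writeLines(as.character(values), path)
  path
}

# A feature table of well-separated Gaussian clouds: one cluster centre
# per class, k features, n rows per class.
gauss_table <- function(centers, n_per_class = 20, k = 4, sd = 0.5,
                        seed = 1) {
  stopifnot(!is.null(names(centers)))
  withr::with_seed(seed, {
    rows <- lapply(names(centers), function(cl) {
      X <- matrix(rnorm(n_per_class * k, mean = centers[[cl]], sd = sd),
                  n_per_class, k)
      df <- as.data.frame(X)
      names(df) <- paste0("sampen_d", seq_len(k))
      cbind(data.frame(record_id = sprintf("%s_%02d", cl,
                                           seq_len(n_per_class)),
                       label = cl, stringsAsFactors = FALSE), df)
    })
    as_feature_table(do.call(rbind, rows))
  })
}

# Four tight clusters in an XOR layout: class depends on the sign
# product of the two coordinates, so no linear separator exists.
xor_table <- function(n_per_cluster = 25, sd = 0.1, seed = 7) {
  withr::with_seed(seed, {
    centers <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    cls <- c("same", "same", "diff", "diff")
    rows <- lapply(1:4, function(i) {
      X <- cbind(rnorm(n_per_cluster, centers[i, 1], sd),
                 rnorm(n_per_cluster, centers[i, 2], sd))
      data.frame(record_id = sprintf("c%d_%02d", i, seq_len(n_per_cluster)),
                 label = cls[i], sampen_d1 = X[, 1], sampen_d2 = X[, 2],
                 stringsAsFactors = FALSE)
    })
    as_feature_table(do.call(rbind, rows))
  })
}
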