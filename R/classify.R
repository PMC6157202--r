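# Run code under a fixed RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Kernel specification for SVM classification
#'
#' Linear kernel: `k(x, y) = x . y`. Polynomial kernel:
#' `k(x, y) = (x . y + coef0)^degree`; degree 2 is the quadratic and
#' degree 3 the cubic kernel. The default `coef0 = 1` gives the
#' inhomogeneous form, which is well behaved on standardized features;
#' set `coef0 = 0` for the homogeneous form.
#'
#' @param kind `"linear"` or `"polynomial"`.
#' @param degree Polynomial degree in 1..3 (forced to 1 for linear).
#' @param coef0 Additive offset of the polynomial kernel.
#' @param cost Soft-margin box constraint C (> 0).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial"), degree = 1L,
                        coef0 = 1, cost = 1) {
  kind <- match.arg(kind)
  degree <- as.integer(degree)
  if (kind == "linear" && degree != 1L) {
    stop("linear kernel implies degree 1")
  }
  if (is.na(degree) || degree < 1L || degree > 3L) {
    stop("degree must be 1, 2 or 3")
  }
  if (!is.numeric(cost) || cost <= 0) stop("cost must be positive")
  structure(list(kind = kind, degree = degree, coef0 = coef0, cost = cost),
            class = "kernel_spec")
}

#' Convenience kernel constructors matching the grid driver's menu
#' @rdname kernel_spec
#' @param name `"linear"`, `"quadratic"` or `"cubic"`.
#' @export
kernel_by_name <- function(name, coef0 = 1, cost = 1) {
  switch(name,
    linear    = kernel_spec("linear", 1L, coef0, cost),
    quadratic = kernel_spec("polynomial", 2L, coef0, cost),
    cubic     = kernel_spec("polynomial", 3L, coef0, cost),
    stop("unknown kernel name: ", name)
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  nm <- if (x$kind == "linear") "linear"
        else c("linear", "quadratic", "cubic")[x$degree]
  cat(sprintf("<kernel_spec> %s (degree=%d, coef0=%g, C=%g)\n",
              nm, x$degree, x$coef0, x$cost))
  invisible(x)
}

.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2L, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mean = mu, sd = sg)
}

.apply_scaler <- function(X, scaler) {
  scale(X, center = scaler$mean, scale = scaler$sd)
}

.table_xy <- function(table) {
  X <- feature_matrix(table)
  if (!all(is.finite(X))) stop("feature table contains non-finite values")
  y <- factor(table$label)
  list(X = X, y = y)
}

.svm_fit <- function(X, y, kernel) {
  if (kernel$kind == "linear") {
    e1071::svm(X, y, kernel = "linear", cost = kernel$cost, scale = FALSE)
  } else {
    e1071::svm(X, y, kernel = "polynomial", degree = kernel$degree,
               gamma = 1, coef0 = kernel$coef0, cost = kernel$cost,
               scale = FALSE)
  }
}

#' Train an SVM on a feature table
#'
#' Standardizes features to the table's mean/SD, then fits a soft-margin
#' SVM with the requested kernel. Multiclass problems use one-vs-one
#' voting (the standard reduction for kernel SVMs).
#'
#' @param table A `msld_feature_table` with >= 2 classes.
#' @param kernel A [kernel_spec()].
#' @return An object of class `msld_svm` holding the fitted model and the
#'   standardization statistics; use [predict()] on new feature rows.
#' @export
train_svm <- function(table, kernel = kernel_by_name("cubic")) {
  stopifnot(inherits(table, "msld_feature_table"),
            inherits(kernel, "kernel_spec"))
  xy <- .table_xy(table)
  if (nlevels(xy$y) < 2L) stop("need at least 2 classes, got ",
                               nlevels(xy$y))
  scaler <- .fit_scaler(xy$X)
  fit <- .svm_fit(.apply_scaler(xy$X, scaler), xy$y, kernel)
  structure(list(fit = fit, scaler = scaler, kernel = kernel,
                 levels = levels(xy$y)),
            class = "msld_svm")
}

#' @export
predict.msld_svm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "msld_feature_table")) feature_matrix(newdata)
       else as.matrix(newdata)
  stats::predict(object$fit, .apply_scaler(X, object$scaler))
}

#' @export
print.msld_svm <- function(x, ...) {
  cat("<msld_svm> classes:", paste(x$levels, collapse = ", "), "\n")
  print(x$kernel)
  invisible(x)
}

#' Stratified fold assignment
#'
#' @param y Factor of class labels.
#' @param n_folds Number of folds.
#' @param seed RNG seed; assignment is deterministic given (y, n_folds,
#'   seed).
#' @param stratified Preserve class proportions per fold (default). When
#'   `FALSE`, rows are assigned to folds irrespective of class.
#' @return Integer vector of fold ids in 1..n_folds, one per row.
#' @export
assign_folds <- function(y, n_folds = 5L, seed = 0L, stratified = TRUE) {
  y <- as.factor(y)
  n_folds <- as.integer(n_folds)
  folds <- integer(length(y))
  .with_seed(seed, {
    if (stratified) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        folds[idx] <- sample(rep(seq_len(n_folds), length.out =
                                   length(idx))[sample.int(length(idx))])
      }
    } else {
      folds[] <- rep(seq_len(n_folds),
                     length.out = length(y))[sample.int(length(y))]
    }
  })
  folds
}

#' k-fold cross-validated SVM accuracy
#'
#' Splits the table into stratified folds, and for each fold fits the SVM
#' on the remaining folds and scores the held-out one. Standardization
#' statistics are computed inside each training fold only, so no
#' information leaks from test to training data.
#'
#' @param table A `msld_feature_table`; every class must have at least
#'   `n_folds` rows.
#' @param kernel A [kernel_spec()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment.
#' @param stratified See [assign_folds()].
#' @return An object of class `msld_cv`: `fold_accuracies`,
#'   `mean_accuracy`, `confusion` (true class x predicted class counts
#'   pooled over folds), `kernel`, `n_folds`, `seed`.
#' @export
cross_validate <- function(table, kernel = kernel_by_name("cubic"),
                           n_folds = 5L, seed = 0L, stratified = TRUE) {
  stopifnot(inherits(table, "msld_feature_table"),
            inherits(kernel, "kernel_spec"))
  xy <- .table_xy(table)
  if (nlevels(xy$y) < 2L) stop("need at least 2 classes")
  cls_n <- table(xy$y)
  if (stratified && any(cls_n < n_folds)) {
    stop("every class needs at least n_folds = ", n_folds,
         " rows; smallest has ", min(cls_n))
  }
  folds <- assign_folds(xy$y, n_folds, seed, stratified)
  acc <- numeric(n_folds)
  conf <- matrix(0L, nlevels(xy$y), nlevels(xy$y),
                 dimnames = list(true = levels(xy$y),
                                 predicted = levels(xy$y)))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    scaler <- .fit_scaler(xy$X[tr, , drop = FALSE])
    fit <- .svm_fit(.apply_scaler(xy$X[tr, , drop = FALSE], scaler),
                    droplevels(xy$y[tr]), kernel)
    pred <- stats::predict(fit,
                           .apply_scaler(xy$X[!tr, , drop = FALSE], scaler))
    pred <- factor(as.character(pred), levels = levels(xy$y))
    truth <- xy$y[!tr]
    acc[k] <- mean(pred == truth)
    conf <- conf + table(truth, pred)
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 confusion = conf, kernel = kernel,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "msld_cv")
}

#' @export
print.msld_cv <- function(x, ...) {
  cat(sprintf("<msld_cv> %d-fold, mean accuracy %.1f%% (folds: %s)\n",
              x$n_folds, 100 * x$mean_accuracy,
              paste(sprintf("%.1f", 100 * x$fold_accuracies),
                    collapse = ", ")))
  print(x$confusion)
  invisible(x)
}

#' Accuracy grid over tolerance values, scale ranges and kernels
#'
#' For each tolerance `r`, extracts the feature table once at the widest
#' scale range, derives each narrower range by column slicing (exact, by
#' per-distance independence), and runs one cross-validation per
#' (r, range, kernel) cell. Cells hold mean accuracy in percent.
#'
#' @param set A `msld_signal_set`.
#' @param kernels List of [kernel_spec()] (default linear, quadratic,
#'   cubic). An empty list yields an empty grid.
#' @param r_values Tolerances to sweep (default 0.1, 0.15, 0.2, 0.25).
#' @param scale_ranges List of `c(d_min, d_max)` ranges; all must start
#'   at the same `d_min` or be contained in the widest range.
#' @param m Embedding dimension.
#' @param tolerance_mode See [sampen_params()].
#' @param n_folds,seed Cross-validation controls.
#' @param progress Passed to [extract_feature_table()].
#' @return An object of class `msld_grid`: list with `cells` (named list
#'   per kernel of r x range matrices, percent, one decimal), `detail`
#'   (the `msld_cv` objects), and the sweep parameters.
#' @export
accuracy_grid <- function(set,
                          kernels = lapply(c("linear", "quadratic", "cubic"),
                                           kernel_by_name),
                          r_values = c(0.1, 0.15, 0.2, 0.25),
                          scale_ranges = list(c(1, 20), c(1, 15),
                                              c(1, 10), c(1, 5)),
                          m = 2L, tolerance_mode = "relative_sd",
                          n_folds = 5L, seed = 0L, progress = 0L) {
  stopifnot(inherits(set, "msld_signal_set"))
  kn <- vapply(kernels, function(k) {
    if (k$kind == "linear") "linear"
    else c("linear", "quadratic", "cubic")[k$degree]
  }, character(1))
  widest <- scale_ranges[[which.max(vapply(scale_ranges, function(x)
    x[2] - x[1], numeric(1)))]]
  rng_lab <- vapply(scale_ranges, function(x)
    paste0(x[1], "-", x[2]), character(1))
  cells <- lapply(kernels, function(k) {
    matrix(NA_real_, length(r_values), length(scale_ranges),
           dimnames = list(paste0("r=", r_values), rng_lab))
  })
  names(cells) <- kn
  detail <- list()
  for (ri in seq_along(r_values)) {
    params <- sampen_params(m = m, r = r_values[ri],
                            tolerance_mode = tolerance_mode)
    wide <- extract_feature_table(set, widest[1], widest[2], params,
                                  progress = progress)
    for (si in seq_along(scale_ranges)) {
      rng <- scale_ranges[[si]]
      tab <- restrict_scales(wide, rng[1], rng[2])
      for (ki in seq_along(kernels)) {
        cv <- cross_validate(tab, kernels[[ki]], n_folds, seed)
        cells[[ki]][ri, si] <- round(100 * cv$mean_accuracy, 1L)
        detail[[paste(kn[ki], rng_lab[si],
                      paste0("r=", r_values[ri]), sep = "|")]] <- cv
      }
    }
  }
  structure(list(cells = cells, detail = detail, r_values = r_values,
                 scale_ranges = scale_ranges, seed = as.integer(seed)),
            class = "msld_grid")
}

#' @export
print.msld_grid <- function(x, ...) {
  for (kn in names(x$cells)) {
    cat("Accuracy (%),", kn, "kernel:\n")
    print(x$cells[[kn]])
    cat("\n")
  }
  invisible(x)
}
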