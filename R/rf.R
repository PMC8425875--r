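#' Seeded random forest (binary classification)
#'
#' A self-contained CART/Gini random forest used for subtype-relevant gene
#' ranking and MPI link prediction: bootstrap resampling, `mtry` random
#' feature subsampling per node, impurity-decrease variable importance, and
#' probability predictions by leaf-frequency averaging. The RNG is private
#' and seeded, so a fixed seed gives an identical forest.
#'
#' @param x Numeric matrix, observations in rows, features in columns.
#' @param y Binary labels: factor with 2 levels, or 0/1 vector.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features sampled per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node Minimum observations per leaf (default 1).
#' @param max_depth Depth cap (default 30).
#' @param seed RNG seed.
#' @return Object of class `rforest` with elements `forest` (opaque),
#'   `importance` (named, mean Gini decrease), `levels`, `feature_names`.
#' @export
rforest <- function(x, y, n_trees = 500, mtry = NULL, min_node = 1,
                    max_depth = 30, seed = 1) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2)
      stop_mpinet("rforest requires exactly 2 classes, got ", nlevels(y),
                  class = "mpinet_parameter_error")
    lev <- levels(y)
    yi <- as.integer(y) - 1L
  } else {
    if (!all(y %in% c(0, 1)))
      stop_mpinet("numeric y must be 0/1", class = "mpinet_parameter_error")
    lev <- c("0", "1")
    yi <- as.integer(y)
  }
  if (length(unique(yi)) < 2)
    stop_mpinet("y has a single class", class = "mpinet_parameter_error")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_fit_cpp(x, yi, as.integer(n_trees), as.integer(mtry),
                     as.integer(min_node), as.integer(max_depth),
                     as.integer(seed))
  imp <- setNames(as.numeric(fit$importance),
                  colnames(x) %||% paste0("f", seq_len(ncol(x))))
  structure(list(forest = fit, importance = imp, levels = lev,
                 feature_names = names(imp), n_trees = n_trees,
                 mtry = mtry, seed = seed),
            class = "rforest")
}

#' @param object An `rforest`.
#' @param newdata Matrix with the training feature columns.
#' @param type `"prob"` for second-class probability, `"class"` for labels.
#' @param ... Unused.
#' @rdname rforest
#' @export
predict.rforest <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  p <- as.numeric(.rf_predict_cpp(object$forest, newdata))
  if (type == "prob") return(p)
  object$levels[ifelse(p > 0.5, 2L, 1L)]
}

#' @export
print.rforest <- function(x, ...) {
  cat("rforest:", x$n_trees, "trees,", length(x$feature_names),
      "features, mtry", x$mtry, "\n")
  invisible(x)
}
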