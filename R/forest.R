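#' Fit a bagged regression-tree ensemble
#'
#' The regression engine behind the perception-scoring system: a random
#' forest grown with bootstrap resampling and `mtry` feature subsampling,
#' splitting on maximum variance reduction, with mean-valued leaves.
#' Implemented in C++; randomness comes from R's RNG, so results are
#' reproducible under [set.seed()].
#'
#' @param x numeric matrix of predictors (rows = observations).
#' @param y numeric response vector, `length(y) == nrow(x)`.
#' @param ntree number of trees (default 150).
#' @param mtry features tried per split; default `max(3, floor(ncol(x)/3))`.
#' @param min_node stop splitting nodes of this size or smaller (default 5).
#' @return an object of class `rf_ensemble`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 50, 4)
#' f <- rf_fit(x, x[, 1] * 2, ntree = 25)
#' rf_predict(f, x)[1:3]
#' @export
rf_fit <- function(x, y, ntree = 150L, mtry = NULL, min_node = 5L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (nrow(x) < 2L) stop("need at least 2 training observations")
  if (is.null(mtry)) mtry <- max(3L, ncol(x) %/% 3L)
  mtry <- min(as.integer(mtry), ncol(x))
  trees <- .rf_fit_cpp(x, as.numeric(y), as.integer(ntree), mtry,
                       as.integer(min_node))
  structure(list(trees = trees, p = ncol(x), ntree = as.integer(ntree),
                 mtry = mtry, min_node = as.integer(min_node)),
            class = "rf_ensemble")
}

#' Predict from a bagged-tree ensemble
#' @param object an `rf_ensemble` from [rf_fit()].
#' @param x numeric matrix with the same number of columns as at fit time.
#' @return numeric vector of ensemble-mean predictions.
#' @export
rf_predict <- function(object, x) {
  stopifnot(inherits(object, "rf_ensemble"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != object$p)
    stop(sprintf("feature length mismatch: model expects %d columns, got %d",
                 object$p, ncol(x)))
  .rf_predict_cpp(object$trees, x)
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("rf_ensemble: %d trees, %d features, mtry %d, min node %d\n",
              x$ntree, x$p, x$mtry, x$min_node))
  invisible(x)
}
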