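#' @include utils.R
NULL

#' The supported downstream regressor kinds
#' @export
REGRESSOR_KINDS <- c("RF", "LGBM", "MLP", "SVR", "KNN")

#' Specify a downstream regressor
#'
#' The feature-to-angle map is a conventional regressor fit on the (z-scored)
#' feature matrix with targets in degrees. Supported kinds and their default
#' hyperparameters:
#' \describe{
#'   \item{RF}{random forest (ranger), 500 trees, each grown on a 50\%
#'     subsample without replacement, minimum leaf size 25 (analysis windows
#'     overlap heavily, so bootstrap duplicate draws and tiny leaves fit
#'     within-stride noise rather than signal).}
#'   \item{LGBM}{gradient-boosted trees (xgboost, histogram method), 500
#'     rounds, learning rate 0.05, depth 6.}
#'   \item{MLP}{single-hidden-layer perceptron (nnet), 64 units, weight decay
#'     1e-4, 200 BFGS iterations, internally standardized targets.}
#'   \item{SVR}{epsilon-SVR with RBF kernel (e1071), C = 10.}
#'   \item{KNN}{k-nearest-neighbour regression (caret), 5 neighbours.}
#' }
#'
#' @param kind one of `"RF"`, `"LGBM"`, `"MLP"`, `"SVR"`, `"KNN"`.
#' @param seed seed for the stochastic kinds (RF, MLP).
#' @param ... hyperparameter overrides (`num.trees`, `sample.fraction`,
#'   `min.node.size`, `nrounds`, `eta`, `max_depth`, `size`, `decay`,
#'   `maxit`, `cost`, `kernel`, `neighbors`).
#' @return a `regressorSpec` object.
#' @export
regressorSpec <- function(kind = "RF", ..., seed = 1L) {
  kind <- match.arg(kind, REGRESSOR_KINDS)
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "regressorSpec")
}

#' @export
print.regressorSpec <- function(x, ...) {
  cat(sprintf("regressorSpec: %s (seed %d)%s\n", x$kind, x$seed,
              if (length(x$params))
                paste0("; ", paste(names(x$params), unlist(x$params),
                                   sep = "=", collapse = ", ")) else ""))
  invisible(x)
}

param <- function(spec, name, default) {
  if (!is.null(spec$params[[name]])) spec$params[[name]] else default
}

#' Fit a regressor on a feature matrix
#'
#' Features are z-scored with training statistics (stored in the model);
#' targets stay in degrees -- the fusion tanh output is only a training
#' signal for feature learning, the final angle estimate always comes from
#' this regressor. The fitted model records its feature width and refuses
#' prediction on mismatched input.
#'
#' @param features N x d numeric matrix (d = 14 or 28 for the standard
#'   feature sets, but any width is accepted).
#' @param targetsDeg length-N angle targets, degrees.
#' @param spec a [regressorSpec()].
#' @return a fitted model of class `fgcnnRegressor`.
#' @export
fitRegressor <- function(features, targetsDeg, spec = regressorSpec()) {
  features <- as.matrix(features)
  stopIf(!all(is.finite(features)), "features contain non-finite values",
         class = "fgcnnInputError")
  stopIf(length(targetsDeg) != nrow(features),
         "targets length must equal the number of feature rows",
         class = "fgcnnDimensionError")
  stopIf(nrow(features) < 2L, "need at least two training rows",
         class = "fgcnnInputError")
  st <- columnStats(features)
  x <- applyColumnStats(features, st)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.numeric(targetsDeg)
  fit <- switch(spec$kind,
    RF = ranger::ranger(
      x = x, y = y,
      num.trees = param(spec, "num.trees", 500L),
      # heavily overlapping analysis windows: subsampling without
      # replacement beats bootstrap duplicates at these sample sizes
      replace = param(spec, "replace", FALSE),
      sample.fraction = param(spec, "sample.fraction", 0.5),
      min.node.size = param(spec, "min.node.size", 25L),
      seed = spec$seed, num.threads = 1L, verbose = FALSE),
    LGBM = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      eta = param(spec, "eta", 0.05),
                      max_depth = param(spec, "max_depth", 6L),
                      tree_method = "hist", nthread = 1L),
        data = dtrain, nrounds = param(spec, "nrounds", 500L), verbose = 0)
    },
    MLP = withSeed(spec$seed, {
      ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
      nnet::nnet(x, ys, size = param(spec, "size", 64L), linout = TRUE,
                 decay = param(spec, "decay", 1e-4),
                 maxit = param(spec, "maxit", 200L),
                 MaxNWts = 100000L, trace = FALSE)
    }),
    SVR = e1071::svm(
      x = x, y = y, type = "eps-regression",
      kernel = param(spec, "kernel", "radial"),
      cost = param(spec, "cost", 10)),
    KNN = caret::knnreg(x, y, k = param(spec, "neighbors", 5L)))
  structure(list(kind = spec$kind, fit = fit, stats = st, d = ncol(features),
                 spec = spec, yCenter = mean(y),
                 yScale = max(stats::sd(y), 1e-12)),
            class = "fgcnnRegressor")
}

#' Predict knee angles from features
#'
#' @param model a fitted `fgcnnRegressor` from [fitRegressor()].
#' @param features N x d matrix with the same width the model was fit on.
#' @return length-N numeric vector of angles in degrees.
#' @export
predictAngles <- function(model, features) {
  features <- as.matrix(features)
  stopIf(ncol(features) != model$d,
         sprintf("model expects %d features but got %d", model$d,
                 ncol(features)), class = "fgcnnDimensionError")
  stopIf(!all(is.finite(features)), "features contain non-finite values",
         class = "fgcnnInputError")
  x <- applyColumnStats(features, model$stats)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  out <- switch(model$kind,
    RF = stats::predict(model$fit, data = x,
                        num.threads = 1L)$predictions,
    LGBM = stats::predict(model$fit, xgboost::xgb.DMatrix(x)),
    MLP = as.numeric(stats::predict(model$fit, x)) * model$yScale +
      model$yCenter,
    SVR = as.numeric(stats::predict(model$fit, x)),
    KNN = as.numeric(stats::predict(model$fit, as.data.frame(x))))
  as.numeric(out)
}

#' @export
print.fgcnnRegressor <- function(x, ...) {
  cat(sprintf("fgcnnRegressor: %s on %d features\n", x$kind, x$d))
  invisible(x)
}
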