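#' Fit a multiple linear regression pIC50 model
#'
#' Ordinary least squares of `pIC50` on the named descriptor columns of the
#' training split. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param table training table (descriptor columns, `pIC50`, optional
#'   `split` column restricting the fit to `"train"` rows).
#' @param descriptors descriptor columns (default: canonical ten present).
#' @return a [linear_model] (subclass `mlr_model`) with training R^2.
#' @export
fit_mlr <- function(table, descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_names(), names(table))
    if (!length(descriptors))
      descriptors <- setdiff(names(table), c("id", "pIC50", "split"))
  }
  if (!is.null(table$split)) table <- table[table$split == "train", , drop = FALSE]
  if (nrow(table) <= length(descriptors) + 1)
    stop("need more training rows than descriptors + 1")
  X <- cbind(`(Intercept)` = 1, as.matrix(table[, descriptors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(setdiff(bad, "(Intercept)"), collapse = ", "))
  }
  fit <- .ls_fit(table, descriptors)
  m <- linear_model(fit$intercept, fit$coefficients, r_squared = fit$r2)
  class(m) <- c("mlr_model", class(m))
  m
}

#' Fit an epsilon-support-vector regression pIC50 model
#'
#' Radial-basis SVR via libsvm (the e1071 interface). Descriptors are
#' z-scored internally on training statistics; constant columns are dropped
#' with a warning.
#'
#' @param table training table as in [fit_mlr()].
#' @param descriptors descriptor columns.
#' @param cost,epsilon,gamma libsvm hyperparameters; `gamma` defaults to
#'   1/(number of descriptors).
#' @return object of class `svr_model`.
#' @export
fit_svr <- function(table, descriptors = NULL, cost = 10, epsilon = 0.1,
                    gamma = NULL) {
  stopifnot(cost > 0, epsilon >= 0)
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_names(), names(table))
    if (!length(descriptors))
      descriptors <- setdiff(names(table), c("id", "pIC50", "split"))
  }
  if (!is.null(table$split)) table <- table[table$split == "train", , drop = FALSE]
  if (nrow(table) < 1) stop("empty training set")
  X <- as.matrix(table[, descriptors, drop = FALSE])
  y <- table$pIC50
  if (nrow(X) == 1) {
    # degenerate single-row fit: constant predictor
    return(structure(list(constant = y, descriptors = descriptors),
                     class = "svr_model"))
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant descriptor column(s): ",
            paste(descriptors[sds == 0], collapse = ", "))
    descriptors <- descriptors[sds > 0]
    X <- X[, descriptors, drop = FALSE]
  }
  if (is.null(gamma)) gamma <- 1 / max(1, length(descriptors))
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = mu, scale = sdv)
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, descriptors = descriptors, center = mu,
                 scale = sdv,
                 hyper = list(cost = cost, epsilon = epsilon, gamma = gamma)),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  if (!is.null(x$constant))
    cat("SVR pIC50 model: degenerate single-row fit (constant",
        format(x$constant), ")\n")
  else
    cat(sprintf(
      "SVR pIC50 model: radial kernel, C=%g, eps=%g, gamma=%g, %d SV(s)\n",
      x$hyper$cost, x$hyper$epsilon, x$hyper$gamma, nrow(x$fit$SV)))
  invisible(x)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata))
    newdata <- as.data.frame(as.list(newdata))
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  X <- as.matrix(newdata[, object$descriptors, drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  as.numeric(stats::predict(object$fit, Xs))
}

#' Predict pIC50 from any fitted model
#'
#' Dispatches on [linear_model], `svr_model` or `bn_model`.
#'
#' @param model fitted model object.
#' @param d named descriptor vector or data.frame.
#' @return predicted pIC50 value(s).
#' @export
predict_pic50 <- function(model, d) {
  if (inherits(model, "linear_model")) return(predict(model, d))
  if (inherits(model, "svr_model")) return(predict(model, d))
  if (inherits(model, "bn_model")) return(predict(model, d))
  stop("not a fitted pIC50 model")
}
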