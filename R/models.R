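#' Sequence-identity baseline predictors of log rates
#'
#' Three simple predictors of a variant's log carboxylation rate from the
#' rates of training variants and their sequence identities to the query:
#'
#' * `predict_nn()` returns the ln-rate of the most similar training
#'   sequence; exact identity ties are averaged.
#' * `predict_mean()` returns the unweighted mean of the training
#'   ln-rates.
#' * `predict_weighted_mean()` returns an identity-weighted average with
#'   exponential weights `w_i = exp(-lambda * (1 - s_i))`, where `s_i` is
#'   the identity of training sequence i to the query. `lambda = 0`
#'   recovers the unweighted mean; large `lambda` approaches the nearest
#'   neighbor.
#'
#' @param identities Numeric vector of identities (in `[0, 1]`) of each
#'   training sequence to the query.
#' @param ln_rates Numeric vector of training ln-rates.
#' @param lambda Exponential decay per unit identity loss, >= 0. The
#'   default 14 halves the weight for every 5 identity points lost.
#' @return A single predicted ln-rate.
#' @export
predict_nn <- function(identities, ln_rates) {
  if (length(ln_rates) == 0) abort("empty training set")
  best <- max(identities)
  mean(ln_rates[identities == best])
}

#' @rdname predict_nn
#' @export
predict_mean <- function(identities, ln_rates) {
  if (length(ln_rates) == 0) abort("empty training set")
  mean(ln_rates)
}

#' @rdname predict_nn
#' @export
predict_weighted_mean <- function(identities, ln_rates, lambda = 14) {
  if (length(ln_rates) == 0) abort("empty training set")
  stopifnot(lambda >= 0)
  w <- exp(-lambda * (1 - identities))
  sum(w * ln_rates) / sum(w)
}

#' RBF-kernel support vector regression on one-hot features
#'
#' Thin wrapper around [e1071::svm()] pinning the conventional default
#' hyperparameters for epsilon-SVR on one-hot sequence features:
#' `C = 1`, `epsilon = 0.1`, and kernel width
#' `gamma = 1 / (n_features * var(x))` with `var(x)` the variance of the
#' flattened training feature matrix. Features are not rescaled. The fit
#' is deterministic given the training data.
#'
#' @param x Numeric feature matrix (rows = sequences), e.g. from
#'   [one_hot_encode()].
#' @param y Numeric targets (ln-rates).
#' @param cost,epsilon SVR regularization and tube width.
#' @param gamma Kernel width; `NULL` applies the variance rule above.
#' @return An object of class `svr_fit` with a [predict()] method.
#' @export
fit_svr <- function(x, y, cost = 1, epsilon = 0.1, gamma = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("SVR needs at least 2 training rows")
  if (is.null(gamma)) gamma <- svr_gamma(x)
  if (max(y) - min(y) <= 2 * epsilon) {
    # all targets fit inside one epsilon tube around their midrange: the
    # optimal function is constant (libsvm keeps no support vectors)
    return(structure(list(svm = NULL, constant = mean(range(y)),
                          gamma = gamma, cost = cost, epsilon = epsilon),
                     class = "svr_fit"))
  }
  fit <- e1071::svm(
    x = x, y = y, type = "eps-regression", kernel = "radial",
    cost = cost, epsilon = epsilon, gamma = gamma, scale = FALSE,
    fitted = FALSE
  )
  if (fit$tot.nSV == 0) {
    # borderline numerics can still yield an empty support set
    return(structure(list(svm = NULL, constant = mean(range(y)),
                          gamma = gamma, cost = cost, epsilon = epsilon),
                     class = "svr_fit"))
  }
  structure(list(svm = fit, constant = NULL, gamma = gamma, cost = cost,
                 epsilon = epsilon), class = "svr_fit")
}

# kernel width rule: 1 / (n_features * total variance of the matrix)
svr_gamma <- function(x) {
  v <- var(as.vector(x))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  unname(predict(object$svm, newdata))
}
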