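#' @include AllClasses.R accessors.R
NULL

#' Train a generalized regression neural network
#'
#' A GRNN stores the training exemplars verbatim and predicts with
#' Gaussian-kernel Nadaraya-Watson regression,
#' \deqn{\hat y = \sum_i w_i Y_i / \sum_i w_i, \quad
#'       w_i = \exp(-\|x - x_i\|^2 / 2\sigma^2).}
#' If no spread is supplied and at least three exemplars are available, the
#' spread is selected by leave-one-out cross-validation over a log-spaced
#' grid (\code{\link{fitSpread}}). The common "spread" parameterization of
#' neural-network toolboxes uses a Gaussian with bias \code{0.8326/spread};
#' published spread values translate to this sigma as
#' \code{sigma = spread / (0.8326 * sqrt(2))}.
#'
#' @param X n x d matrix of feature vectors (one row per training
#'   structure instance).
#' @param Y n x m matrix of 50-point target curves (volume %).
#' @param spread kernel width sigma; if \code{NULL}, selected by LOO.
#' @param sigmaGrid candidate spreads for LOO selection; default 25
#'   log-spaced values spanning 0.01 to 10 times the median nonzero
#'   pairwise exemplar distance, so the grid tracks the feature scale.
#' @param method \code{"IDVHS"} or \code{"DTH_CPDVH"}.
#' @param structureType label of the structure type the model serves.
#' @param normsRef provenance hash of the normalization constants.
#' @return a \linkS4class{GRNNModel}.
#' @export
grnnTrain <- function(X, Y, spread = NULL, sigmaGrid = NULL,
                      method = "IDVHS", structureType = "structure",
                      normsRef = "") {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(spread)) {
    if (nrow(X) >= 3L) {
      if (is.null(sigmaGrid)) sigmaGrid <- defaultSigmaGrid(X)
      spread <- fitSpread(X, Y, sigmaGrid)
    } else {
      spread <- if (is.null(sigmaGrid)) 1 else sigmaGrid[1]
    }
  }
  new("GRNNModel", exemplarsX = X, exemplarsY = Y, spread = spread,
      method = method, structureType = structureType, normsRef = normsRef)
}

defaultSigmaGrid <- function(X, nSigma = 25L) {
  n <- nrow(X)
  idx <- if (n > 60L) unique(round(seq(1, n, length.out = 60L))) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  d <- d[d > 0]
  scale <- if (length(d)) stats::median(d) else 1
  exp(seq(log(0.01 * scale), log(10 * scale), length.out = nSigma))
}

grnnWeights <- function(model, x) {
  dx <- sweep(model@exemplarsX, 2, x)
  d2 <- rowSums(dx * dx)
  exp(-d2 / (2 * model@spread^2))
}

#' Predict a DVH curve with a GRNN
#'
#' Componentwise kernel-weighted average of the stored target curves; the
#' output is a convex combination of training targets. If every kernel
#' weight underflows to zero the nearest exemplar's curve is returned.
#'
#' @param object a \linkS4class{GRNNModel}.
#' @param x feature vector of the model's input dimension.
#' @param ... ignored.
#' @return numeric vector (one predicted curve, same length as the stored
#'   target curves).
#' @export
setMethod("predict", "GRNNModel", function(object, x, ...) {
  x <- as.numeric(x)
  if (length(x) != ncol(object@exemplarsX))
    stop("feature vector length ", length(x), " does not match model input ",
         "dimension ", ncol(object@exemplarsX))
  w <- grnnWeights(object, x)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) {
    dx <- sweep(object@exemplarsX, 2, x)
    nn <- which.min(rowSums(dx * dx))
    return(as.numeric(object@exemplarsY[nn, ]))
  }
  as.numeric(crossprod(object@exemplarsY, w) / sw)
})

#' Select the GRNN spread by leave-one-out cross-validation
#'
#' For each candidate sigma every exemplar is predicted from the remaining
#' ones and scored with the mean absolute curve error; the sigma minimizing
#' the mean LOO MAE is returned, with ties broken towards the smallest
#' sigma. Fully deterministic.
#'
#' @param X n x d feature matrix, n >= 3.
#' @param Y n x m target matrix.
#' @param sigmaGrid positive candidate spreads.
#' @return the selected sigma.
#' @export
fitSpread <- function(X, Y, sigmaGrid = defaultSigmaGrid(X)) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop("spread selection requires at least 3 exemplars")
  if (length(sigmaGrid) == 0 || any(sigmaGrid <= 0))
    stop("'sigmaGrid' must contain positive values")
  sigmaGrid <- sort(sigmaGrid)
  D2 <- as.matrix(stats::dist(X))^2
  looMae <- vapply(sigmaGrid, function(sig) {
    W <- exp(-D2 / (2 * sig^2))
    diag(W) <- 0
    sw <- rowSums(W)
    pred <- matrix(0, n, ncol(Y))
    ok <- sw > 0
    if (any(ok))
      pred[ok, ] <- (W[ok, , drop = FALSE] %*% Y) / sw[ok]
    if (any(!ok)) {
      for (i in which(!ok)) { # all weights underflow: nearest other exemplar
        d2i <- D2[i, ]
        d2i[i] <- Inf
        pred[i, ] <- Y[which.min(d2i), ]
      }
    }
    mean(abs(pred - Y))
    }, numeric(1))
  sigmaGrid[which.min(looMae)] # which.min takes the first (smallest) tie
}

#' Post-process a predicted curve into a valid cumulative DVH
#'
#' Clips to [0, 100] and enforces monotone non-increase by a running
#' minimum from the low-dose end. Valid curves pass through unchanged.
#'
#' @param yhat numeric predicted curve.
#' @return numeric curve in [0, 100], monotone non-increasing.
#' @export
postprocessCurve <- function(yhat) {
  y <- pmin(pmax(as.numeric(yhat), 0), 100)
  cummin(y)
}
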