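#' Thin-plate-spline regression classifier (TPSRC)
#'
#' Penalized radial-basis regression on +/-1 labels. The predictor is
#' \deqn{h(x) = \omega_0 + \omega^\top x + \sum_j \psi_j\,\phi(\|x - x_j\|),
#'       \qquad \phi(r) = r^2 \log r,\ \phi(0) = 0,}
#' fitted by the standard augmented thin-plate smoothing system
#' \deqn{\begin{pmatrix} K + \eta I & P \\ P^\top & 0 \end{pmatrix}
#'       \begin{pmatrix} \psi \\ (\omega_0, \omega) \end{pmatrix}
#'       = \begin{pmatrix} y \\ 0 \end{pmatrix}}
#' with \eqn{K_{ij} = \phi(\|x_i - x_j\|)} and \eqn{P = [1 \mid X]}. The side
#' conditions \eqn{\sum_j \psi_j = 0} and \eqn{\sum_j \psi_j x_j = 0} make the
#' radial part orthogonal to the affine part; eta >= 0 trades data fit for
#' smoothness (eta -> 0 interpolates).
#'
#' @name tpsrc
NULL

#' Labeled two-class dataset
#'
#' @param features numeric n x k matrix (no missing values).
#' @param labels numeric vector in \{-1, +1\}; -1 encodes the "high quality"
#'   class.
#' @return object of class \code{"labeled_set"}.
#' @export
labeled_set <- function(features, labels) {
  features <- as.matrix(features)
  if (anyNA(features) || anyNA(labels)) stop("missing values not allowed")
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  structure(list(features = features, labels = as.numeric(labels)),
            class = "labeled_set")
}

## thin-plate Green's function r^2 log r with phi(0) = 0
tps_phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)

tps_kernel_matrix <- function(A, B) {
  ## pairwise distances between rows of A (n x k) and B (m x k)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  tps_phi(sqrt(d2))
}

#' Fit a TPSRC model
#'
#' @param data a \code{\link{labeled_set}} (needs n >= k + 2, both classes
#'   present for a meaningful classifier; a constant-label set is accepted
#'   and yields the constant solution).
#' @param eta non-negative regularization parameter; \code{NULL} selects eta
#'   by generalized cross-validation over \code{eta_grid}.
#' @param eta_grid log-spaced candidate grid used when \code{eta} is NULL.
#' @return object of class \code{"tpsrc_model"}: list with \code{omega0},
#'   \code{omega}, \code{psi}, \code{anchors}, \code{eta}.
#' @export
tpsrc_fit <- function(data, eta = 1e-8,
                      eta_grid = 10^seq(-6, 2, length.out = 9)) {
  stopifnot(inherits(data, "labeled_set"))
  X <- data$features; y <- data$labels
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2L) stop("under-determined: need at least k + 2 training samples")
  if (is.null(eta)) eta <- tpsrc_select_eta(data, eta_grid)
  if (eta < 0) stop("eta must be >= 0")
  K <- tps_kernel_matrix(X, X)
  P <- cbind(1, X)
  A <- rbind(cbind(K + diag(eta, n), P),
             cbind(t(P), matrix(0, k + 1L, k + 1L)))
  rhs <- c(y, rep(0, k + 1L))
  sol <- NULL
  eta_use <- eta
  for (attempt in 1:6) {
    sol <- tryCatch(solve(rbind(cbind(K + diag(eta_use, n), P),
                                cbind(t(P), matrix(0, k + 1L, k + 1L))), rhs),
                    error = function(e) NULL)
    if (!is.null(sol)) break
    eta_use <- eta_use * 10 + 1e-8
    warning("singular thin-plate system; bumping eta to ", signif(eta_use, 3))
  }
  if (is.null(sol)) stop("thin-plate system is singular even after regularization")
  psi <- sol[seq_len(n)]
  omega0 <- sol[n + 1L]
  omega <- sol[(n + 2L):(n + k + 1L)]
  structure(list(omega0 = omega0, omega = omega, psi = psi,
                 anchors = X, eta = eta_use),
            class = "tpsrc_model")
}

#' Select the TPSRC regularization by generalized cross-validation
#'
#' GCV(eta) = (RSS/n) / (1 - tr(H)/n)^2 where H is the smoother ("hat")
#' matrix mapping y to the fitted training scores.
#'
#' @param data a \code{\link{labeled_set}}.
#' @param eta_grid candidate values.
#' @return the eta minimizing GCV.
#' @export
tpsrc_select_eta <- function(data, eta_grid = 10^seq(-6, 2, length.out = 9)) {
  X <- data$features; y <- data$labels
  n <- nrow(X); k <- ncol(X)
  K <- tps_kernel_matrix(X, X)
  P <- cbind(1, X)
  best <- eta_grid[1]; best_gcv <- Inf
  for (eta in eta_grid) {
    A <- rbind(cbind(K + diag(eta, n), P),
               cbind(t(P), matrix(0, k + 1L, k + 1L)))
    S <- tryCatch(solve(A, rbind(diag(n), matrix(0, k + 1L, n))),
                  error = function(e) NULL)
    if (is.null(S)) next
    H <- K %*% S[seq_len(n), , drop = FALSE] +
         P %*% S[(n + 1L):(n + k + 1L), , drop = FALSE]
    fitted <- drop(H %*% y)
    rss <- sum((y - fitted)^2)
    edf <- sum(diag(H))
    if (edf >= n) next
    g <- (rss / n) / (1 - edf / n)^2
    if (is.finite(g) && g < best_gcv) { best_gcv <- g; best <- eta }
  }
  best
}

#' Predict with a TPSRC model
#'
#' @param model a \code{tpsrc_model}.
#' @param x numeric vector of length k or an m x k matrix.
#' @return numeric score(s); threshold at 0 for class labels.
#' @export
tpsrc_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (ncol(x) != ncol(model$anchors))
    stop("feature length mismatch: expected ", ncol(model$anchors))
  K <- tps_kernel_matrix(x, model$anchors)
  drop(model$omega0 + x %*% model$omega + K %*% model$psi)
}

#' @export
print.tpsrc_model <- function(x, ...) {
  cat(sprintf("TPSRC model: %d anchors, k = %d, eta = %.3g\n",
              nrow(x$anchors), ncol(x$anchors), x$eta))
  invisible(x)
}

#' Threshold a real-valued score into a class label
#'
#' Scores less than or equal to the threshold map to -1 ("high quality");
#' scores above map to +1.
#'
#' @param score numeric score(s).
#' @param threshold decision threshold (default 0, the "medium" value between
#'   the two label codes).
#' @return numeric label(s) in \{-1, +1\}.
#' @export
threshold_label <- function(score, threshold = 0) {
  if (any(!is.finite(score))) stop("scores must be finite")
  ifelse(score <= threshold, -1, 1)
}
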