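#' Multivariate adaptive regression splines classifier (MARSC)
#'
#' An adaptive expansion in products of hinge functions,
#' \deqn{h(x) = \alpha_0 + \sum_i \alpha_i \prod_k
#'       [s_{ki}(x_{v(k,i)} - t_{ki})]_+,}
#' fitted by the classical forward/backward stepwise strategy: the forward
#' pass greedily adds reflected hinge pairs (parent basis x new variable x
#' data-value knot) minimizing the residual sum of squares; the backward pass
#' deletes basis functions one at a time keeping the subset minimizing the
#' generalized cross-validation error. Each factor within a product uses a
#' distinct variable and products are capped at \code{max_degree} factors.
#'
#' @name marsc
NULL

#' Generalized cross-validation error
#'
#' \eqn{GCV = (RSS/M) / (1 - C(K)/M)^2} with complexity penalty
#' \eqn{C(K) = K (d/2 + 1)}; K counts the non-constant basis functions and M
#' the training samples. If \eqn{M \le C(K)} the penalty is infinite and
#' \code{Inf} is returned.
#'
#' @param rss non-negative residual sum of squares.
#' @param K number of (non-constant) basis functions.
#' @param M number of training samples.
#' @param d smoothing parameter of the complexity penalty (default 3).
#' @return the GCV value (possibly \code{Inf}).
#' @export
mars_gcv <- function(rss, K, M, d = 3) {
  CK <- K * (d / 2 + 1)
  if (M <= CK) return(Inf)
  (rss / M) / (1 - CK / M)^2
}

## evaluate one basis function (list of factors) on a feature matrix
mars_basis_column <- function(factors, X) {
  col <- rep(1, nrow(X))
  for (f in factors)
    col <- col * pmax(f$s * (X[, f$v] - f$t), 0)
  col
}

mars_basis_matrix <- function(basis, X) {
  cols <- lapply(basis, function(b) mars_basis_column(b, X))
  if (length(cols) == 0L) return(matrix(1, nrow(X), 1L))
  cbind(1, do.call(cbind, cols))
}

#' Fit a MARSC model
#'
#' @param data a \code{\link{labeled_set}} (regression targets are the +/-1
#'   labels; any numeric response is accepted for regression use).
#' @param max_terms maximum number of non-constant basis functions (default
#'   \code{min(21, floor(n/2))}).
#' @param max_degree maximum number of hinge factors per product (default 2,
#'   up to 3).
#' @param d GCV smoothing parameter (default 3).
#' @param max_knots per-variable cap on candidate knots; knots are observed
#'   data values, quantile-thinned when more than \code{max_knots} are
#'   available (default \code{Inf}: all observed values).
#' @param minspan minimum number of observations between adjacent candidate
#'   knots; \code{NULL} uses Friedman's adaptive rule
#'   \eqn{\lceil -\log_2(-\ln(1-\alpha)/(nk))/2.5 \rceil} at \eqn{\alpha =
#'   0.05}. Set to 1 to allow every observed value.
#' @param endspan number of observations at each end of a variable's active
#'   range excluded from knot candidacy; \code{NULL} uses Friedman's rule
#'   \eqn{\lceil 3 - \log_2(\alpha/k) \rceil}. Edge knots give single
#'   observations huge leverage and make out-of-range predictions erratic;
#'   excluding them is the standard variance guard.
#' @param forward_tol relative RSS improvement below which the forward pass
#'   stops.
#' @return object of class \code{"marsc_model"}: list with \code{alpha0},
#'   \code{alphas}, \code{basis} (list of factor lists with fields \code{s},
#'   \code{v}, \code{t}), \code{gcv}, \code{d}, \code{k}.
#' @export
marsc_fit <- function(data, max_terms = NULL, max_degree = 2L, d = 3,
                      max_knots = Inf, minspan = NULL, endspan = NULL,
                      forward_tol = 1e-10) {
  stopifnot(inherits(data, "labeled_set") || is.list(data))
  X <- as.matrix(data$features); y <- as.numeric(data$labels)
  n <- nrow(X); k <- ncol(X)
  if (is.null(max_terms)) max_terms <- min(21L, floor(n / 2))
  if (n <= max_terms) stop("need n > max_terms training samples")
  alpha_span <- 0.05
  if (is.null(minspan))
    minspan <- max(1L, as.integer(ceiling(-log2(-log(1 - alpha_span) / (n * k)) / 2.5)))
  if (is.null(endspan))
    endspan <- max(1L, as.integer(ceiling(3 - log2(alpha_span / k))))
  sst <- sum((y - mean(y))^2)
  if (sst == 0)   # constant response: intercept-only model
    return(structure(list(alpha0 = mean(y), alphas = numeric(0), basis = list(),
                          gcv = mars_gcv(0, 0L, n, d), d = d, k = k),
                     class = "marsc_model"))
  basis <- list()           # list of factor lists; column j+1 of B
  B <- matrix(1, n, 1L)
  ## ---- forward pass: add reflected hinge pairs minimizing RSS ----
  repeat {
    if (length(basis) >= max_terms) break
    qrB <- qr(B)
    ry <- qr.resid(qrB, y)
    rss0 <- sum(ry^2)
    if (rss0 <= forward_tol * sst) break
    best <- NULL
    parents <- c(list(NULL), basis)   # NULL = intercept parent
    for (p in parents) {
      pcol <- if (is.null(p)) rep(1, n) else mars_basis_column(p, X)
      if (!is.null(p) && length(p) >= max_degree) next
      used <- if (is.null(p)) integer(0) else vapply(p, `[[`, 1L, "v")
      active <- pcol > 0
      if (sum(active) < 2L) next
      for (v in setdiff(seq_len(k), used)) {
        xa <- sort(X[active, v])
        if (endspan > 0L && length(xa) > 2L * endspan)
          xa <- xa[(endspan + 1L):(length(xa) - endspan)]
        if (minspan > 1L && length(xa) > minspan)
          xa <- xa[seq(1L, length(xa), by = minspan)]
        knots <- unique(xa)
        if (is.finite(max_knots) && length(knots) > max_knots)
          knots <- unique(stats::quantile(knots, probs = seq(0, 1, length.out = max_knots),
                                          names = FALSE, type = 1))
        if (length(knots) == 0L) next
        ## candidate pair columns for all knots at once
        xv <- X[, v]
        C1 <- pcol * pmax(outer(xv, knots, "-"), 0)
        C2 <- pcol * pmax(outer(knots, xv, "-") |> t(), 0)
        RC1 <- qr.resid(qrB, C1)
        RC2 <- qr.resid(qrB, C2)
        a11 <- colSums(RC1^2); a22 <- colSums(RC2^2); a12 <- colSums(RC1 * RC2)
        b1 <- colSums(RC1 * ry); b2 <- colSums(RC2 * ry)
        det <- a11 * a22 - a12^2
        scale2 <- pmax(a11, a22)
        red2 <- ifelse(det > 1e-12 * scale2^2,
                       (a22 * b1^2 - 2 * a12 * b1 * b2 + a11 * b2^2) / det,
                       NA_real_)
        red1 <- pmax(ifelse(a11 > 1e-12, b1^2 / a11, 0),
                     ifelse(a22 > 1e-12, b2^2 / a22, 0))
        red <- ifelse(is.na(red2), red1, pmax(red2, red1))
        j <- which.max(red)
        if (length(j) && is.finite(red[j]) &&
            (is.null(best) || red[j] > best$red)) {
          best <- list(red = red[j], parent = p, v = v, t = knots[j])
        }
      }
    }
    if (is.null(best) || best$red <= forward_tol * sst) break
    newf1 <- c(best$parent, list(list(s = 1, v = best$v, t = best$t)))
    newf2 <- c(best$parent, list(list(s = -1, v = best$v, t = best$t)))
    c1 <- mars_basis_column(newf1, X)
    c2 <- mars_basis_column(newf2, X)
    add <- list()
    if (stats::sd(c1) > 0) add <- c(add, list(newf1))
    if (stats::sd(c2) > 0 && length(basis) + length(add) < max_terms + 1L)
      add <- c(add, list(newf2))
    if (length(add) == 0L) break
    for (f in add) {
      basis[[length(basis) + 1L]] <- f
      B <- cbind(B, mars_basis_column(f, X))
    }
  }
  ## ---- backward pass: prune to the GCV-minimizing subset ----
  fit_subset <- function(keep) {
    Bk <- mars_basis_matrix(basis[keep], X)
    cf <- qr.coef(qr(Bk), y)
    cf[is.na(cf)] <- 0          # aliased (collinear) columns drop out
    rss <- sum((y - drop(Bk %*% cf))^2)
    list(coef = cf, rss = rss,
         gcv = mars_gcv(rss, length(keep), n, d))
  }
  keep <- seq_along(basis)
  cur <- fit_subset(keep)
  best_keep <- keep; best_fit <- cur
  while (length(keep) > 0L) {
    trial_best <- NULL
    for (i in seq_along(keep)) {
      cand <- keep[-i]
      f <- fit_subset(cand)
      if (is.null(trial_best) || f$gcv < trial_best$fit$gcv)
        trial_best <- list(keep = cand, fit = f)
    }
    keep <- trial_best$keep
    if (trial_best$fit$gcv <= best_fit$gcv) {
      best_keep <- keep; best_fit <- trial_best$fit
    }
  }
  basis <- basis[best_keep]
  coefs <- unname(best_fit$coef)
  structure(list(alpha0 = coefs[1],
                 alphas = if (length(basis)) coefs[-1] else numeric(0),
                 basis = basis, gcv = best_fit$gcv, d = d, k = k),
            class = "marsc_model")
}

#' Predict with a MARSC model
#'
#' @param model a \code{marsc_model}.
#' @param x numeric vector of length k or an m x k matrix.
#' @return numeric score(s); threshold at 0 for class labels.
#' @export
marsc_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (ncol(x) != model$k)
    stop("feature length mismatch: expected ", model$k)
  B <- mars_basis_matrix(model$basis, x)
  drop(B %*% c(model$alpha0, model$alphas))
}

#' @export
print.marsc_model <- function(x, ...) {
  cat(sprintf("MARSC model: %d basis function(s), k = %d, GCV = %.4g\n",
              length(x$basis), x$k, x$gcv))
  invisible(x)
}
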