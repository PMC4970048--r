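#' COSC-Boosting: co-training of two complementary classifiers
#'
#' A semi-supervised loop in which the thin-plate-spline classifier (TPSRC)
#' and the MARS classifier (MARSC) label unlabeled samples for each other.
#' Per iteration a pool of M' samples is drawn with replacement from the
#' unlabeled set; a pool sample is a candidate only if both classifiers give
#' it the same thresholded label AND appending it (with that label) does not
#' increase either classifier's squared error on its labeled set. The most
#' confident candidate for each classifier augments the other classifier's
#' labeled set (cross-teaching), both classifiers are retrained, and the loop
#' stops early once neither labeled set changes. The final predictor is the
#' average of the two classifier scores, thresholded at zero.
#'
#' @name cosc-boosting
NULL

#' COSC-Boosting configuration
#'
#' @param max_iterations maximum number of co-training iterations (T >= 1).
#' @param pool_size number M' of unlabeled samples drawn with replacement per
#'   iteration (default 100).
#' @param threshold decision threshold for label agreement and final labels.
#' @param seed integer seed driving the pool draws.
#' @param eta TPSRC regularization (\code{NULL} = GCV-selected per fit).
#' @param mars_options list of arguments forwarded to
#'   \code{\link{marsc_fit}} (\code{max_terms}, \code{max_degree}, \code{d},
#'   \code{max_knots}).
#' @param cross_teach logical; TRUE (default) lets each classifier's pick
#'   augment the other classifier's labeled set. FALSE reproduces the literal
#'   pseudocode variant in which the TPSRC pick augments both sets.
#' @param remove_accepted logical; TRUE (default) removes accepted samples
#'   from the unlabeled reservoir, FALSE keeps the literal
#'   with-replacement/no-removal reading.
#' @return object of class \code{"cosc_config"}.
#' @export
cosc_config <- function(max_iterations = 10L, pool_size = 100L, threshold = 0,
                        seed = 1L, eta = 1e-6, mars_options = list(),
                        cross_teach = TRUE, remove_accepted = TRUE) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (pool_size < 1L) stop("pool_size must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 pool_size = as.integer(pool_size),
                 threshold = threshold, seed = as.integer(seed),
                 eta = eta, mars_options = mars_options,
                 cross_teach = isTRUE(cross_teach),
                 remove_accepted = isTRUE(remove_accepted)),
            class = "cosc_config")
}

## score() dispatches over the two base model classes and plain functions
cosc_score <- function(model, X) {
  if (inherits(model, "tpsrc_model")) return(tpsrc_predict(model, X))
  if (inherits(model, "marsc_model")) return(marsc_predict(model, X))
  if (is.function(model)) return(model(X))
  stop("unsupported model type")
}

#' Labeling confidence of a refined classifier
#'
#' The decrease in squared error on the labeled set,
#' \eqn{\sum_{(x_i,y_i)} [(y_i - h(x_i))^2 - (y_i - h^*(x_i))^2]}; positive
#' values mean the refinement is more consistent with the labeled data. The
#' normalized form (divided by the labeled-set size, sign-identical) is
#' returned alongside.
#'
#' @param h_current,h_refined fitted models (\code{tpsrc_model},
#'   \code{marsc_model}) or score functions.
#' @param labeled a \code{\link{labeled_set}} to evaluate on.
#' @return list with \code{total} and \code{normalized}.
#' @export
labeling_confidence <- function(h_current, h_refined, labeled) {
  X <- labeled$features; y <- labeled$labels
  e_cur <- (y - cosc_score(h_current, X))^2
  e_ref <- (y - cosc_score(h_refined, X))^2
  total <- sum(e_cur - e_ref)
  list(total = total, normalized = total / length(y))
}

append_labeled <- function(L, x, y) {
  labeled_set(rbind(L$features, matrix(x, 1L)), c(L$labels, y))
}

fit_tpsrc_cfg <- function(L, config) tpsrc_fit(L, eta = config$eta)
fit_marsc_cfg <- function(L, config)
  do.call(marsc_fit, c(list(data = L), config$mars_options))

#' Fit a COSC-Boosting model
#'
#' @param L a \code{\link{labeled_set}} containing both classes.
#' @param U numeric m x k matrix of unlabeled features (may have zero rows,
#'   in which case the result is the plain two-classifier ensemble).
#' @param config a \code{\link{cosc_config}}.
#' @return object of class \code{"cosc_model"}: list with \code{tpsrc},
#'   \code{marsc}, \code{augmented_L1}, \code{augmented_L2} (labeled sets
#'   including virtual labels), \code{n_original} (size of the original L),
#'   \code{history} (per-iteration log: pool indices, candidate indices,
#'   confidences, accepted samples, set sizes, stop reason), \code{config}.
#' @export
cosc_fit <- function(L, U, config = cosc_config()) {
  stopifnot(inherits(L, "labeled_set"))
  if (length(unique(L$labels)) < 2L)
    stop("labeled set must contain both classes")
  U <- as.matrix(U)
  if (nrow(U) > 0 && ncol(U) != ncol(L$features))
    stop("feature length mismatch between L and U")
  L1 <- L; L2 <- L
  h1 <- fit_tpsrc_cfg(L1, config)
  h2 <- fit_marsc_cfg(L2, config)
  history <- list()
  if (nrow(U) == 0L)
    return(structure(list(tpsrc = h1, marsc = h2, augmented_L1 = L1,
                          augmented_L2 = L2, n_original = nrow(L$features),
                          history = history, config = config),
                     class = "cosc_model"))
  avail <- seq_len(nrow(U))       # reservoir of unlabeled indices
  run_loop <- function() {
    for (iter in seq_len(config$max_iterations)) {
      ## hold one eta fixed across all candidate refits of this iteration so
      ## that confidence comparisons are not confounded by re-selection noise
      iter_config <- config
      if (is.null(config$eta)) iter_config$eta <- tpsrc_select_eta(L1)
      if (length(avail) == 0L) {
        history[[length(history) + 1L]] <<- list(iteration = iter,
                                                 stop = "unlabeled set exhausted")
        break
      }
      pool <- sample(avail, config$pool_size, replace = TRUE)
      cand_idx <- integer(0); conf1 <- numeric(0); conf2 <- numeric(0)
      cand_lab <- numeric(0)
      seen <- unique(pool)
      s1 <- cosc_score(h1, U[seen, , drop = FALSE])
      s2 <- cosc_score(h2, U[seen, , drop = FALSE])
      lab1 <- threshold_label(s1, config$threshold)
      lab2 <- threshold_label(s2, config$threshold)
      agree <- seen[lab1 == lab2]
      agree_lab <- lab1[lab1 == lab2]
      for (j in seq_along(agree)) {
        u <- agree[j]; yv <- agree_lab[j]
        h1s <- tryCatch(fit_tpsrc_cfg(append_labeled(L1, U[u, ], yv), iter_config),
                        error = function(e) NULL)
        h2s <- tryCatch(fit_marsc_cfg(append_labeled(L2, U[u, ], yv), iter_config),
                        error = function(e) NULL)
        if (is.null(h1s) || is.null(h2s)) next
        c1 <- labeling_confidence(h1, h1s, L1)$total
        c2 <- labeling_confidence(h2, h2s, L2)$total
        if (c1 >= 0 && c2 >= 0) {
          cand_idx <- c(cand_idx, u)
          cand_lab <- c(cand_lab, yv)
          conf1 <- c(conf1, c1)
          conf2 <- c(conf2, c2)
        }
      }
      accepted1 <- NA_integer_; accepted2 <- NA_integer_
      if (length(cand_idx) > 0L) {
        pick1 <- cand_idx[which.max(conf1)]   # ties: lowest candidate position
        pick2 <- cand_idx[which.max(conf2)]
        y1 <- cand_lab[which.max(conf1)]
        y2 <- cand_lab[which.max(conf2)]
        if (config$cross_teach) {
          ## each classifier labels for the other: TPSRC's pick teaches MARSC
          ## (L2) and MARSC's pick teaches TPSRC (L1)
          L1 <<- append_labeled(L1, U[pick2, ], y2)
          L2 <<- append_labeled(L2, U[pick1, ], y1)
        } else {
          L1 <<- append_labeled(L1, U[pick1, ], y1)
          L2 <<- append_labeled(L2, U[pick1, ], y1)
        }
        accepted1 <- if (config$cross_teach) pick2 else pick1
        accepted2 <- pick1
        if (config$remove_accepted)
          avail <<- setdiff(avail, unique(c(pick1, pick2)))
      }
      history[[length(history) + 1L]] <<- list(
        iteration = iter, pool = pool, n_agree = length(agree),
        candidates = cand_idx, conf_tpsrc = conf1, conf_marsc = conf2,
        accepted_L1 = accepted1, accepted_L2 = accepted2,
        size_L1 = nrow(L1$features), size_L2 = nrow(L2$features),
        stop = if (length(cand_idx) == 0L) "no labeled-set change" else NA_character_)
      if (length(cand_idx) == 0L) break
      h1 <<- fit_tpsrc_cfg(L1, iter_config)
      h2 <<- fit_marsc_cfg(L2, config)
    }
  }
  with_seed(config$seed, run_loop())
  structure(list(tpsrc = h1, marsc = h2, augmented_L1 = L1, augmented_L2 = L2,
                 n_original = nrow(L$features), history = history,
                 config = config),
            class = "cosc_model")
}

#' @export
print.cosc_model <- function(x, ...) {
  cat(sprintf(paste0("COSC-Boosting model: %d original labels, L1 = %d, ",
                     "L2 = %d, %d iteration(s)\n"),
              x$n_original, nrow(x$augmented_L1$features),
              nrow(x$augmented_L2$features), length(x$history)))
  invisible(x)
}

#' Predict with the co-trained ensemble
#'
#' Ensemble score \eqn{f(x) = (h_{TPSRC}(x) + h_{MARSC}(x))/2}, thresholded
#' into \{-1, +1\}.
#'
#' @param model a \code{cosc_model}.
#' @param X numeric vector (length k) or m x k matrix.
#' @return list with \code{scores} and \code{labels}.
#' @export
ensemble_predict <- function(model, X) {
  s <- (cosc_score(model$tpsrc, X) + cosc_score(model$marsc, X)) / 2
  list(scores = s, labels = threshold_label(s, model$config$threshold))
}

#' Classification-error metrics
#'
#' Per-group classification error \eqn{CE_g = 100 \cdot
#' \mathrm{mean}(|\hat y - y| / 2)} over group g, the unweighted mean over
#' groups (\code{ace_rv}), and the pooled error over all samples
#' (\code{ace_ts}), all in percent.
#'
#' @param pred_labels,true_labels numeric vectors in \{-1, +1\}.
#' @param group_ids vector of group identifiers (default: one group).
#' @return list with \code{ce} (named per-group vector), \code{ace_rv},
#'   \code{ace_ts}.
#' @export
ce_metrics <- function(pred_labels, true_labels, group_ids = NULL) {
  if (length(pred_labels) != length(true_labels))
    stop("label vectors must have equal length")
  if (!all(c(pred_labels, true_labels) %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  if (is.null(group_ids)) group_ids <- rep(1L, length(true_labels))
  err <- abs(pred_labels - true_labels) / 2
  groups <- unique(group_ids)
  ce <- vapply(groups, function(g) {
    idx <- group_ids == g
    if (!any(idx)) { warning("empty group ", g, " excluded"); return(NA_real_) }
    100 * mean(err[idx])
  }, 1.0)
  names(ce) <- as.character(groups)
  ce <- ce[!is.na(ce)]
  list(ce = ce, ace_rv = mean(ce), ace_ts = 100 * mean(err))
}

#' Seeded semi-supervised co-training benchmark
#'
#' Runs the full COSC-Boosting loop on the synthetic two-Gaussian task
#' (k features, class means at +/- separation/2 on every coordinate, unit
#' within-class sd) at a given label rate, over a set of seeds, and reports
#' the pooled classification error of the initial two-classifier ensemble
#' (trained on the labeled subset only) and of the final co-trained ensemble,
#' both evaluated on the unlabeled samples against the hidden truth. The
#' MARS side runs additive (degree-1) splines with a small term budget: the
#' generator's class boundary is linear, so an additive spline class is the
#' appropriate complementary learner at these sample sizes.
#'
#' @param seeds integer vector of dataset seeds (one run per seed).
#' @param n_per_class,k,separation,label_rate generator conditions (defaults:
#'   200 per class, 4 features, separation 1.6, 10\% labeled).
#' @param max_iterations,pool_size co-training loop controls.
#' @param mars_options MARSC options for both the initial ensemble and the
#'   loop.
#' @param eta TPSRC regularization (\code{NULL} = GCV-selected).
#' @return data.frame with one row per seed: \code{seed}, \code{initial_ce},
#'   \code{final_ce}, \code{improvement} (percentage points).
#' @export
cosc_benchmark <- function(seeds = 1:20, n_per_class = 200L, k = 4L,
                           separation = 1.6, label_rate = 0.10,
                           max_iterations = 30L, pool_size = 100L,
                           mars_options = list(max_terms = 8L, max_degree = 1L),
                           eta = NULL) {
  rows <- lapply(seeds, function(seed) {
    d <- generate_ss_dataset(ss_dataset_spec(n_per_class = n_per_class, k = k,
                                             separation = separation,
                                             label_rate = label_rate,
                                             seed = seed))
    cfg <- cosc_config(max_iterations = max_iterations, pool_size = pool_size,
                       seed = seed + 1000L, eta = eta,
                       mars_options = mars_options)
    h1 <- fit_tpsrc_cfg(d$labeled, cfg)
    h2 <- fit_marsc_cfg(d$labeled, cfg)
    init_scores <- (tpsrc_predict(h1, d$unlabeled) +
                    marsc_predict(h2, d$unlabeled)) / 2
    init_ce <- ce_metrics(threshold_label(init_scores), d$truth)$ace_ts
    m <- cosc_fit(d$labeled, d$unlabeled, cfg)
    final_ce <- ce_metrics(ensemble_predict(m, d$unlabeled)$labels, d$truth)$ace_ts
    data.frame(seed = seed, initial_ce = init_ce, final_ce = final_ce,
               improvement = init_ce - final_ce)
  })
  do.call(rbind, rows)
}
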