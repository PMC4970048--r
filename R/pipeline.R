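#' End-to-end pipeline: extract, train, predict
#'
#' Thin orchestration over the filtering/feature, classifier and co-training
#' modules: images in, feature CSVs and model JSONs out, with YAML run
#' configuration. Feature columns are standardized (centered/scaled by
#' labeled-set statistics, stored in the model) before classifier training:
#' thin-plate radial distances across location/scale/shape columns of very
#' different magnitudes would otherwise be dominated by the largest-scale
#' columns.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' Bundles the feature and co-training configurations with a seed; round-trips
#' losslessly through YAML.
#'
#' @param feature a \code{\link{feature_config}}.
#' @param cosc a \code{\link{cosc_config}}.
#' @param seed integer seed recorded with every artifact.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(feature = feature_config(), cosc = cosc_config(),
                       seed = 1L) {
  structure(list(feature = feature, cosc = cosc, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  obj <- list(feature = unclass(config$feature), cosc = unclass(config$cosc),
              seed = config$seed)
  obj$cosc$eta <- if (is.null(config$cosc$eta)) "gcv" else config$cosc$eta
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @param config a \code{run_config} (for writing).
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  fc <- do.call(feature_config, obj$feature)
  cc <- obj$cosc
  if (identical(cc$eta, "gcv")) cc["eta"] <- list(NULL)  # keep the NULL entry
  cc <- do.call(cosc_config, cc)
  run_config(feature = fc, cosc = cc, seed = obj$seed)
}

#' Extract features from a set of images
#'
#' One feature-vector row per readable image; unreadable or degenerate images
#' are skipped with a message. Per-image Weibull fit diagnostics (chi-square,
#' KL divergence of the first global direction at the first scale) are
#' reported on stderr.
#'
#' @param image_paths character vector of image files.
#' @param config a \code{\link{feature_config}}.
#' @param out_csv optional CSV output path (sidecar JSON written alongside).
#' @return data.frame of features (invisibly if written to file).
#' @export
run_extract <- function(image_paths, config = feature_config(), out_csv = NULL) {
  rows <- list()
  for (p in image_paths) {
    fv <- tryCatch({
      img <- if (is.matrix(p)) p else read_grain_image(p)
      extended_features(img, config,
                        source_id = if (is.matrix(p)) "matrix" else basename(p))
    }, error = function(e) {
      message("skipping ", if (is.matrix(p)) "matrix" else p, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(fv)) rows[[length(rows) + 1L]] <- fv
  }
  if (length(rows) == 0L) stop("no image could be processed")
  df <- do.call(rbind, lapply(rows, function(fv)
    data.frame(source_id = fv$source_id, t(fv$values), check.names = FALSE)))
  if (!is.null(out_csv)) {
    write_features_csv(df, out_csv, config)
    return(invisible(df))
  }
  df
}

## standardization helpers: statistics from the labeled block only
standardize_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = mu, scale = sd)
}
standardize_apply <- function(X, st)
  sweep(sweep(as.matrix(X), 2, st$center), 2, st$scale, "/")

#' Train a COSC-Boosting model from feature tables
#'
#' @param labeled data.frame/matrix with a \code{label} column in \{-1, +1\}
#'   (and optionally \code{source_id}); remaining columns are features.
#' @param unlabeled data.frame/matrix of features (same layout, no label).
#' @param config a \code{\link{cosc_config}}.
#' @param truth optional true labels of the unlabeled rows; when given, the
#'   report includes initial/final CE and the improvement
#'   (initial-ensemble CE minus final CE).
#' @param groups optional group ids of the unlabeled rows for per-group CE.
#' @return list with \code{model} (a \code{cosc_model}), \code{standardize}
#'   (centering/scaling used), \code{metrics} (NULL without truth).
#' @export
run_train_eval <- function(labeled, unlabeled, config = cosc_config(),
                           truth = NULL, groups = NULL) {
  labeled <- as.data.frame(labeled, check.names = FALSE)
  if (!"label" %in% colnames(labeled)) stop("labeled table needs a 'label' column")
  y <- labeled$label
  drop_cols <- intersect(c("label", "source_id"), colnames(labeled))
  XL <- as.matrix(labeled[, setdiff(colnames(labeled), drop_cols), drop = FALSE])
  unlabeled <- as.data.frame(unlabeled, check.names = FALSE)
  XU <- as.matrix(unlabeled[, setdiff(colnames(unlabeled), "source_id"),
                            drop = FALSE])
  if (ncol(XU) != ncol(XL) ||
      !identical(colnames(XU), colnames(XL)))
    stop("feature layout mismatch between labeled and unlabeled tables: ",
         paste(utils::head(setdiff(colnames(XL), colnames(XU)), 3), collapse = ", "))
  st <- standardize_stats(XL)
  L <- labeled_set(standardize_apply(XL, st), y)
  U <- standardize_apply(XU, st)
  h1 <- fit_tpsrc_cfg(L, config)
  h2 <- fit_marsc_cfg(L, config)
  model <- cosc_fit(L, U, config)
  metrics <- NULL
  if (!is.null(truth) && nrow(U) > 0) {
    init_scores <- (tpsrc_predict(h1, U) + marsc_predict(h2, U)) / 2
    init <- ce_metrics(threshold_label(init_scores, config$threshold), truth, groups)
    fin <- ce_metrics(ensemble_predict(model, U)$labels, truth, groups)
    metrics <- list(initial = init, final = fin,
                    improvement = init$ace_ts - fin$ace_ts)
  }
  list(model = model, standardize = st, metrics = metrics)
}

#' Predict labels for a feature table
#'
#' @param trained result of \code{\link{run_train_eval}} (or a reloaded model
#'   list with \code{model} and \code{standardize}).
#' @param features data.frame/matrix of features (optionally with
#'   \code{source_id}).
#' @return data.frame with \code{score} and \code{label} columns.
#' @export
run_predict <- function(trained, features) {
  features <- as.data.frame(features, check.names = FALSE)
  X <- as.matrix(features[, setdiff(colnames(features), "source_id"),
                          drop = FALSE])
  Xs <- standardize_apply(X, trained$standardize)
  pr <- ensemble_predict(trained$model, Xs)
  data.frame(score = pr$scores, label = pr$labels)
}

## ---- model JSON serialization ----

#' Save / load a trained COSC model as JSON
#'
#' Serializes both base classifiers (anchors and coefficients for TPSRC,
#' basis functions for MARSC), the augmented label sets' sizes, the
#' standardization statistics and the configuration; reloading reproduces
#' predictions bit-for-bit.
#'
#' @param trained result of \code{\link{run_train_eval}}.
#' @param path JSON output path.
#' @return the path, invisibly.
#' @export
save_cosc_model <- function(trained, path) {
  m <- trained$model
  obj <- list(
    tpsrc = list(omega0 = m$tpsrc$omega0, omega = m$tpsrc$omega,
                 psi = m$tpsrc$psi, anchors = m$tpsrc$anchors,
                 eta = m$tpsrc$eta),
    marsc = list(alpha0 = m$marsc$alpha0, alphas = m$marsc$alphas,
                 basis = m$marsc$basis, gcv = m$marsc$gcv, d = m$marsc$d,
                 k = m$marsc$k),
    n_original = m$n_original,
    n_augmented = c(nrow(m$augmented_L1$features), nrow(m$augmented_L2$features)),
    config = serialize_cosc_config(m$config),
    standardize = trained$standardize)
  ## digits = I(17): full significant digits so doubles round-trip exactly
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

serialize_cosc_config <- function(cfg) {
  out <- unclass(cfg)
  out$eta <- if (is.null(cfg$eta)) "gcv" else cfg$eta
  out
}

#' @rdname save_cosc_model
#' @export
load_cosc_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  cfg <- obj$config
  if (identical(cfg$eta, "gcv")) cfg["eta"] <- list(NULL)
  cfg <- do.call(cosc_config, cfg)
  tpsrc <- structure(list(omega0 = obj$tpsrc$omega0,
                          omega = as.numeric(obj$tpsrc$omega),
                          psi = as.numeric(obj$tpsrc$psi),
                          anchors = as.matrix(obj$tpsrc$anchors),
                          eta = obj$tpsrc$eta),
                     class = "tpsrc_model")
  marsc <- structure(list(alpha0 = obj$marsc$alpha0,
                          alphas = as.numeric(obj$marsc$alphas),
                          basis = lapply(obj$marsc$basis, function(b)
                            lapply(b, function(f)
                              list(s = f$s, v = f$v, t = f$t))),
                          gcv = obj$marsc$gcv, d = obj$marsc$d, k = obj$marsc$k),
                     class = "marsc_model")
  model <- structure(list(tpsrc = tpsrc, marsc = marsc,
                          augmented_L1 = NULL, augmented_L2 = NULL,
                          n_original = obj$n_original, history = NULL,
                          config = cfg),
                     class = "cosc_model")
  list(model = model,
       standardize = list(center = as.numeric(obj$standardize$center),
                          scale = as.numeric(obj$standardize$scale)))
}
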