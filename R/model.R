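#' Model-fitting configuration
#'
#' Controls LASSO selection and the downstream MLP classifier grid
#' search (hidden sizes \{(32), (64), (64, 16)\} crossed with L2
#' strengths \{1e-4, 1e-3, 1e-2\}), both tuned by stratified 5-fold
#' cross-validation under a fixed seed.
#'
#' @param cv_folds Stratified CV folds.
#' @param mlp_grid List with \code{hidden} (list of hidden-size
#'   vectors) and \code{l2} (numeric penalties); the grid is their
#'   cross product.
#' @param threshold Classification threshold for thresholded metrics.
#' @param mlp_lr,mlp_epochs,mlp_batch Classifier training settings.
#' @param lasso_lambda Optional lambda grid passed to glmnet.
#' @param seed RNG seed (folds, initializations).
#' @return Object of class \code{model_config}.
#' @export
model_config <- function(cv_folds = 5L,
                         mlp_grid = list(hidden = list(32L, 64L,
                                                       c(64L, 16L)),
                                         l2 = c(1e-4, 1e-3, 1e-2)),
                         threshold = 0.5, mlp_lr = 1e-3,
                         mlp_epochs = 150L, mlp_batch = 32L,
                         lasso_lambda = NULL, seed = 1L) {
  stopifnot(cv_folds >= 2L, threshold > 0, threshold < 1)
  structure(list(cv_folds = as.integer(cv_folds), mlp_grid = mlp_grid,
                 threshold = threshold, mlp_lr = mlp_lr,
                 mlp_epochs = as.integer(mlp_epochs),
                 mlp_batch = as.integer(mlp_batch),
                 lasso_lambda = lasso_lambda, seed = as.integer(seed)),
            class = "model_config")
}

# stratified fold assignment: shuffles within class, deals folds round-robin
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.zscore_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.zscore_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
}

#' LASSO feature selection
#'
#' L1-penalized logistic regression on (column-standardized) features;
#' the penalty is chosen by stratified cross-validation and the
#' selected set is the features with nonzero coefficients at that
#' penalty. If the CV-optimal penalty zeroes every coefficient, the
#' smallest penalty on the path retaining at least one feature is used
#' instead. Constant columns are excluded with a warning (their
#' coefficient is forced to 0). Deterministic given \code{seed}.
#'
#' @param X Feature matrix (rows = samples), already z-scored.
#' @param y Binary labels, at least 2 samples per class.
#' @param config A \code{\link{model_config}}.
#' @return List with \code{selected} (integer column indices),
#'   \code{coefficients} (named, length \code{ncol(X)}),
#'   \code{lambda}.
#' @export
lasso_select <- function(X, y, config = model_config()) {
  X <- as.matrix(X)
  stopifnot(min(table(y)) >= 2L)
  const <- apply(X, 2L, function(v) max(v) == min(v))
  if (any(const)) {
    warning("constant feature column(s) forced to zero coefficient: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  Xu <- X[, !const, drop = FALSE]
  if (ncol(Xu) == 0L) {
    return(list(selected = integer(0),
                coefficients = stats::setNames(numeric(ncol(X)),
                                               colnames(X)),
                lambda = NA_real_))
  }
  if (ncol(Xu) == 1L) {
    # a single usable candidate: plain logistic slope, no path to tune
    b1 <- unname(suppressWarnings(stats::coef(stats::glm(
      y ~ Xu[, 1L], family = stats::binomial()))[2L]))
    coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
    coefs[!const] <- b1
    return(list(selected = which(coefs != 0), coefficients = coefs,
                lambda = 0))
  }
  foldid <- .stratified_folds(y, config$cv_folds, config$seed)
  cvfit <- glmnet::cv.glmnet(Xu, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE,
                             lambda = config$lasso_lambda,
                             lambda.min.ratio = 0.01)
  beta_at <- function(lam) {
    as.numeric(stats::coef(cvfit$glmnet.fit, s = lam))[-1L]
  }
  lam <- cvfit$lambda.min
  b <- beta_at(lam)
  if (all(b == 0)) {
    nz <- cvfit$glmnet.fit$df > 0
    if (any(nz)) {
      lam <- max(cvfit$glmnet.fit$lambda[nz])
      b <- beta_at(lam)
    }
  }
  coefs <- stats::setNames(numeric(ncol(X)), colnames(X))
  coefs[!const] <- b
  list(selected = which(coefs != 0), coefficients = coefs, lambda = lam)
}

# mean stratified-CV AUC for one MLP configuration on a fixed feature set
.cv_config_auc <- function(X, y, hidden, l2, config) {
  fold <- .stratified_folds(y, config$cv_folds, config$seed)
  aucs <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L || length(unique(y[tr])) < 2L) {
      stop("degenerate single-class fold; use fewer folds")
    }
    sc <- .zscore_fit(X[tr, , drop = FALSE])
    m <- mlp_train(.zscore_apply(X[tr, , drop = FALSE], sc), y[tr],
                   hidden = hidden, lr = config$mlp_lr,
                   batch_size = config$mlp_batch, l2 = l2,
                   max_epochs = config$mlp_epochs, seed = config$seed)
    p <- mlp_predict(m, .zscore_apply(X[!tr, , drop = FALSE], sc))
    aucs[f] <- evaluate(p, y[!tr])$auc
  }
  mean(aucs)
}

#' Train the per-compartment MLP classifier with grid search
#'
#' Evaluates every (hidden sizes, L2) configuration in the grid by
#' mean stratified cross-validated AUC (features re-standardized
#' inside each training fold), then refits the best configuration on
#' all training data. Deterministic given the config seed.
#'
#' @param X_selected Feature matrix after LASSO selection (raw scale).
#' @param y Binary labels; at least 10 samples, both classes present.
#' @param config A \code{\link{model_config}}.
#' @return Object of class \code{compartment_classifier} with the
#'   fitted scaler, MLP, chosen hyperparameters and the CV grid table.
#' @export
train_compartment_classifier <- function(X_selected, y,
                                         config = model_config()) {
  X_selected <- as.matrix(X_selected)
  y <- as.numeric(y)
  stopifnot(nrow(X_selected) >= 10L, length(unique(y)) == 2L)
  grid <- expand.grid(h = seq_along(config$mlp_grid$hidden),
                      l2 = config$mlp_grid$l2)
  grid$cv_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    grid$cv_auc[i] <- .cv_config_auc(X_selected, y,
                                     config$mlp_grid$hidden[[grid$h[i]]],
                                     grid$l2[i], config)
  }
  best <- which.max(grid$cv_auc)  # deterministic first-max tie-break
  hidden <- config$mlp_grid$hidden[[grid$h[best]]]
  sc <- .zscore_fit(X_selected)
  mlp <- mlp_train(.zscore_apply(X_selected, sc), y, hidden = hidden,
                   lr = config$mlp_lr, batch_size = config$mlp_batch,
                   l2 = grid$l2[best], max_epochs = config$mlp_epochs,
                   seed = config$seed)
  grid$hidden <- vapply(grid$h, function(i)
    paste(config$mlp_grid$hidden[[i]], collapse = "x"), "")
  structure(list(scaler = sc, mlp = mlp, hidden = hidden,
                 l2 = grid$l2[best], cv_results = grid[, c("hidden", "l2",
                                                           "cv_auc")],
                 cv_auc = grid$cv_auc[best],
                 feature_names = colnames(X_selected)),
            class = "compartment_classifier")
}

#' @export
predict.compartment_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  mlp_predict(object$mlp, .zscore_apply(newdata, object$scaler))
}

# assemble the design matrix for a cohort; trains tile scorers when
# requested and none are supplied
.design_matrix <- function(cohort, compartment, feature_set, gparams,
                           sparams, dlps_cfg, scorers, sna_features) {
  y <- cohort_labels(cohort)
  blocks <- list()
  if ("sna" %in% feature_set) {
    blocks$sna <- if (is.null(sna_features)) {
      cohort_sna_matrix(cohort, compartment, gparams, sparams)
    } else sna_features
  }
  if ("dlps" %in% feature_set) {
    emb <- lapply(cohort$patients, `[[`, "embeddings")
    if (any(vapply(emb, is.null, logical(1)))) {
      stop("feature set includes DLPS but the cohort has no embeddings; ",
           "simulate with with_embeddings = TRUE or drop 'dlps'")
    }
    base_comps <- if (compartment == "TIL") c("ITIL", "STIL") else compartment
    if (is.null(scorers)) {
      scorers <- lapply(stats::setNames(base_comps, base_comps),
                        function(cc) train_tile_scorer(emb, y, cc, dlps_cfg))
    }
    D <- dlps_feature_matrix(emb, scorers)
    blocks$dlps <- D[, paste0(compartment, c("_mean", "_sd")), drop = FALSE]
    colnames(blocks$dlps) <- c("DLPS_mean", "DLPS_sd")
  }
  if ("clinical" %in% feature_set) {
    blocks$clinical <- cohort_clinical_matrix(cohort)
  }
  list(X = do.call(cbind, blocks), y = y, scorers = scorers)
}

#' Fit a tissue-specific response model
#'
#' The central fitting routine: builds the compartment's tissue graph
#' for every patient and extracts SNA features, optionally trains the
#' compartment's tile-level scorer on the cohort's embeddings and
#' aggregates DLPS features, appends the shared clinical covariates,
#' then performs LASSO feature selection followed by a grid-searched
#' MLP classifier (stratified 5-fold CV), refit on the full training
#' cohort.
#'
#' @param cohort A \code{tme_cohort} used for training.
#' @param compartment One of \code{TTA_COMPARTMENTS}.
#' @param feature_set Subset of \code{c("sna", "dlps", "clinical")}.
#' @param gparams A \code{\link{graph_params}}.
#' @param sparams An \code{\link{sna_params}}.
#' @param dlps_cfg A \code{\link{dlps_config}} (used when
#'   \code{"dlps"} is in the feature set and no scorers are given).
#' @param config A \code{\link{model_config}}.
#' @param scorers Optional pre-trained tile scorers (named list by
#'   base compartment) to reuse.
#' @param sna_features Optional precomputed SNA matrix for
#'   \code{cohort} (as from \code{\link{cohort_sna_matrix}}), to avoid
#'   rebuilding graphs.
#' @return Object of class \code{pcr_model}.
#' @export
fit_response_model <- function(cohort, compartment,
                               feature_set = c("sna", "dlps", "clinical"),
                               gparams = graph_params(),
                               sparams = sna_params(),
                               dlps_cfg = dlps_config(),
                               config = model_config(),
                               scorers = NULL, sna_features = NULL) {
  stopifnot(inherits(cohort, "tme_cohort"),
            compartment %in% TTA_COMPARTMENTS,
            all(feature_set %in% c("sna", "dlps", "clinical")))
  dm <- .design_matrix(cohort, compartment, feature_set, gparams, sparams,
                       dlps_cfg, scorers, sna_features)
  sc <- .zscore_fit(dm$X)
  lasso <- lasso_select(.zscore_apply(dm$X, sc), dm$y, config)
  sel <- lasso$selected
  if (length(sel) == 0L) sel <- seq_len(ncol(dm$X))  # degenerate fallback
  clf <- train_compartment_classifier(dm$X[, sel, drop = FALSE], dm$y,
                                      config)
  structure(list(compartment = compartment, feature_set = feature_set,
                 gparams = gparams, sparams = sparams,
                 dlps_cfg = dlps_cfg, config = config,
                 scorers = dm$scorers, scaler = sc, lasso = lasso,
                 selected = colnames(dm$X)[sel], classifier = clf,
                 feature_names = colnames(dm$X), n = length(dm$y),
                 fitted = predict.compartment_classifier(
                   clf, dm$X[, sel, drop = FALSE]),
                 y = dm$y),
            class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("pcr_model [%s | %s]: n = %d, %d/%d features selected\n",
              x$compartment, paste(x$feature_set, collapse = "+"),
              x$n, length(x$selected), length(x$feature_names)))
  cat(sprintf("  classifier: MLP (%s), L2 = %g, CV AUC = %.3f\n",
              paste(x$classifier$hidden, collapse = "x"),
              x$classifier$l2, x$classifier$cv_auc))
  invisible(x)
}

#' @export
summary.pcr_model <- function(object, ...) {
  cat("Tissue-specific response model\n")
  print(object)
  cat("\nSelected features (LASSO coefficients):\n")
  cf <- object$lasso$coefficients
  cf <- cf[cf != 0]
  print(round(sort(cf, decreasing = TRUE), 4))
  cat("\nClassifier grid (mean CV AUC):\n")
  print(object$classifier$cv_results, row.names = FALSE)
  invisible(object)
}

#' @export
coef.pcr_model <- function(object, ...) {
  object$lasso$coefficients
}

#' Predict response probabilities from a fitted tissue-specific model
#'
#' @param object A \code{pcr_model}.
#' @param newdata A \code{tme_cohort} (features are rebuilt with the
#'   stored parameters and, for DLPS, the stored tile scorers) or a
#'   numeric matrix with the model's feature columns.
#' @param ... Unused.
#' @return Named probability vector.
#' @export
predict.pcr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "tme_cohort")) {
    dm <- .design_matrix(newdata, object$compartment, object$feature_set,
                         object$gparams, object$sparams, object$dlps_cfg,
                         object$scorers, NULL)
    X <- dm$X
  } else {
    X <- as.matrix(newdata)
  }
  X <- X[, object$feature_names, drop = FALSE]
  sel <- match(object$selected, object$feature_names)
  predict.compartment_classifier(object$classifier,
                                 X[, sel, drop = FALSE])
}

#' @export
residuals.pcr_model <- function(object, ...) {
  object$y - object$fitted
}

#' Plot LASSO-selected feature weights of a fitted model
#'
#' Horizontal bar chart of the nonzero standardized LASSO
#' coefficients, grouped by feature source (SNA / DLPS / clinical) —
#' the model's attribution view.
#'
#' @param x A \code{pcr_model}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.pcr_model <- function(x, ...) {
  cf <- x$lasso$coefficients
  cf <- sort(cf[cf != 0])
  if (length(cf) == 0L) {
    warning("no nonzero coefficients to plot")
    return(invisible(x))
  }
  src <- ifelse(names(cf) %in% c("DLPS_mean", "DLPS_sd"), "DLPS",
                ifelse(names(cf) %in% .clinical_fields, "clinical", "SNA"))
  cols <- c(SNA = "#4477AA", DLPS = "#EE6677", clinical = "#228833")[src]
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(cf, horiz = TRUE, las = 1, col = cols,
                    cex.names = 0.7,
                    xlab = "standardized LASSO coefficient",
                    main = sprintf("%s compartment", x$compartment), ...)
  graphics::legend("bottomright", legend = names(table(src)),
                   fill = c(SNA = "#4477AA", DLPS = "#EE6677",
                            clinical = "#228833")[names(table(src))],
                   bty = "n")
  invisible(x)
}

#' Serialize a fitted model's manifest to JSON
#'
#' Writes a versioned JSON manifest (configuration, seed, selected
#' features, LASSO coefficients, chosen classifier hyperparameters)
#' for auditability.
#'
#' @param model A \code{pcr_model}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_model_manifest <- function(model, path) {
  manifest <- list(
    format_version = "1.0",
    compartment = model$compartment,
    feature_set = model$feature_set,
    n_train = model$n,
    seed = model$config$seed,
    graph_params = unclass(model$gparams),
    lasso = list(lambda = model$lasso$lambda,
                 selected = model$selected,
                 coefficients = as.list(
                   model$lasso$coefficients[model$lasso$coefficients != 0])),
    classifier = list(hidden = model$classifier$hidden,
                      l2 = model$classifier$l2,
                      cv_auc = model$classifier$cv_auc))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
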