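# Sensitivity and ablation harnesses, plus the per-fold CV pipeline
# (standardization and LASSO refit inside every training fold, so no
# information leaks from validation folds into selection).

.cv_pipeline_auc <- function(X, y, config) {
  fold <- .stratified_folds(y, config$cv_folds, config$seed)
  hidden <- config$mlp_grid$hidden[[1L]]
  l2 <- config$mlp_grid$l2[1L]
  aucs <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    sc <- .zscore_fit(X[tr, , drop = FALSE])
    Xtr <- .zscore_apply(X[tr, , drop = FALSE], sc)
    las <- lasso_select(Xtr, y[tr], config)
    sel <- if (length(las$selected) > 0L) las$selected else
      seq_len(ncol(X))
    m <- mlp_train(Xtr[, sel, drop = FALSE], y[tr], hidden = hidden,
                   lr = config$mlp_lr, batch_size = config$mlp_batch,
                   l2 = l2, max_epochs = config$mlp_epochs,
                   seed = config$seed)
    Xva <- .zscore_apply(X[!tr, , drop = FALSE], sc)
    aucs[f] <- evaluate(mlp_predict(m, Xva[, sel, drop = FALSE]),
                        y[!tr])$auc
  }
  mean(aucs)
}

#' Graph-parameter sensitivity grid
#'
#' For every (K, P) combination, rebuilds the compartment graphs,
#' extracts SNA features alone (no DLPS or clinical confounders) and
#' reports the mean stratified cross-validated AUC, with
#' standardization and LASSO refit inside each training fold. AP
#' clustering is run once per preference value and reused across K.
#'
#' @param cohort A \code{tme_cohort} with labels.
#' @param K_values KNN sizes to evaluate.
#' @param P_values AP preference values to evaluate.
#' @param compartments Compartments to evaluate.
#' @param gparams Base \code{\link{graph_params}} (damping etc.).
#' @param sparams An \code{\link{sna_params}}.
#' @param config A \code{\link{model_config}}; only the first grid
#'   configuration is used, keeping each cell a single model fit.
#' @return Data frame with \code{compartment}, \code{K}, \code{P},
#'   \code{mean_auc}.
#' @export
sensitivity_grid <- function(cohort, K_values = c(4L, 5L, 6L),
                             P_values = c(-100, -50, -20),
                             compartments = "STROMA",
                             gparams = graph_params(),
                             sparams = sna_params(),
                             config = model_config(
                               mlp_grid = list(hidden = list(64L),
                                               l2 = 1e-3))) {
  y <- cohort_labels(cohort)
  out <- list()
  for (comp in compartments) {
    pts_list <- lapply(cohort$patients, function(p)
      extract_compartment(p$tta, comp))
    for (P in P_values) {
      nodes_list <- lapply(pts_list, function(pts) {
        if (nrow(pts) == 0L) return(NULL)
        cl <- ap_cluster(pts, preference = P, damping = gparams$damping,
                         max_iter = gparams$max_iter,
                         conv_iter = gparams$conv_iter,
                         seed = gparams$seed)
        pts[cl$exemplars, , drop = FALSE]
      })
      for (K in K_values) {
        X <- matrix(0, length(nodes_list), 91L,
                    dimnames = list(names(cohort$patients),
                                    sna_feature_names()))
        for (i in seq_along(nodes_list)) {
          np <- nodes_list[[i]]
          g <- if (is.null(np)) {
            structure(list(compartment = comp,
                           node_positions = matrix(numeric(0), 0L, 2L),
                           edges = matrix(integer(0), 0L, 2L),
                           assignments = integer(0), n_tiles = 0L,
                           params = gparams, empty = TRUE),
                      class = "tissue_graph")
          } else {
            colnames(np) <- c("row", "col")
            structure(list(compartment = comp, node_positions = np,
                           edges = knn_edges(np, K),
                           assignments = integer(0),
                           n_tiles = nrow(np), params = gparams,
                           empty = FALSE),
                      class = "tissue_graph")
          }
          X[i, ] <- extract_sna_features(g, sparams)
        }
        out[[length(out) + 1L]] <- data.frame(
          compartment = comp, K = K, P = P,
          mean_auc = .cv_pipeline_auc(X, y, config))
      }
    }
  }
  do.call(rbind, out)
}

#' Training-size ablation
#'
#' Retrains the compartment model on stratified subsamples of the
#' training cohort at each fraction and evaluates every refit on the
#' same fixed held-out cohort. Fractions too small to retain both
#' classes are skipped with a warning.
#'
#' @param train_cohort,test_cohort \code{tme_cohort}s.
#' @param fractions Training fractions to evaluate (1 reproduces the
#'   full-cohort model).
#' @param compartment Compartment to model.
#' @param feature_set Feature subset (see
#'   \code{\link{fit_response_model}}).
#' @param gparams,sparams,dlps_cfg,config Passed through to the fit.
#' @param seed Subsampling seed.
#' @param sna_train,sna_test Optional precomputed SNA matrices for the
#'   two cohorts (as from \code{\link{cohort_sna_matrix}}), so repeated
#'   subsampling seeds do not rebuild graphs.
#' @return Data frame with \code{compartment}, \code{fraction},
#'   \code{n_train}, \code{auc}, \code{f1}, \code{ppv},
#'   \code{recall}, \code{npv}.
#' @export
ablation_run <- function(train_cohort, test_cohort,
                         fractions = c(0.2, 0.4, 0.6, 0.8),
                         compartment = "STROMA",
                         feature_set = c("sna", "clinical"),
                         gparams = graph_params(),
                         sparams = sna_params(),
                         dlps_cfg = dlps_config(),
                         config = model_config(
                           mlp_grid = list(hidden = list(64L),
                                           l2 = 1e-3)),
                         seed = 1L, sna_train = NULL, sna_test = NULL) {
  y <- cohort_labels(train_cohort)
  sna_tr <- if ("sna" %in% feature_set) {
    if (is.null(sna_train)) {
      cohort_sna_matrix(train_cohort, compartment, gparams, sparams)
    } else sna_train
  }
  y_te <- cohort_labels(test_cohort)
  X_te <- if (!is.null(sna_test) && !("dlps" %in% feature_set)) {
    cbind(sna_test, cohort_clinical_matrix(test_cohort))
  }
  rows <- list()
  for (frac in fractions) {
    set.seed(seed)
    keep <- unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, max(1L, round(frac * length(idx))))))
    keep <- sort(keep)
    if (length(unique(y[keep])) < 2L ||
        min(table(y[keep])) < config$cv_folds) {
      warning("fraction ", frac,
              " leaves too few samples per class; skipped")
      next
    }
    sub <- train_cohort
    sub$patients <- sub$patients[keep]
    fit <- fit_response_model(sub, compartment, feature_set, gparams,
                              sparams, dlps_cfg, config,
                              sna_features = if (!is.null(sna_tr))
                                sna_tr[keep, , drop = FALSE])
    p <- if (is.null(X_te)) predict(fit, test_cohort) else
      predict(fit, X_te)
    ev <- evaluate(p, y_te, config$threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      compartment = compartment, fraction = frac,
      n_train = length(keep), auc = ev$auc, f1 = ev$f1, ppv = ev$ppv,
      recall = ev$recall, npv = ev$npv)
  }
  do.call(rbind, rows)
}
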