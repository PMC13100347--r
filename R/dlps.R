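#' DLPS training configuration
#'
#' Training settings for the tile-level response scorer: a lightweight
#' MLP (1024 -> 256 -> 64 -> 1) trained with Adam (learning rate 1e-4,
#' batch size 512) and dropout on weakly labelled tile embeddings,
#' with a stratified 80/20 patient-level split and early stopping on
#' validation loss for up to 500 epochs.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param dropout_rate Dropout on hidden activations.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param val_fraction Fraction of patients held out for validation
#'   (stratified by label).
#' @param hidden_sizes Hidden-layer widths.
#' @param seed RNG seed.
#' @return Object of class \code{dlps_config}.
#' @export
dlps_config <- function(learning_rate = 1e-4, batch_size = 512L,
                        dropout_rate = 0.25, max_epochs = 500L,
                        patience = 20L, val_fraction = 0.2,
                        hidden_sizes = c(256L, 64L), seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 hidden_sizes = as.integer(hidden_sizes),
                 seed = as.integer(seed)),
            class = "dlps_config")
}

.dlps_compartments <- c("TUMOR", "STROMA", "ITIL", "STIL", "TIL")

# stratified split of patient ids by binary label
.stratified_split <- function(labels, val_fraction, seed) {
  set.seed(seed)
  ids <- names(labels)
  val <- character(0)
  for (cls in unique(labels)) {
    cls_ids <- ids[labels == cls]
    n_val <- max(1L, round(length(cls_ids) * val_fraction))
    val <- c(val, sample(cls_ids, n_val))
  }
  list(train = setdiff(ids, val), val = val)
}

# rows of a patient's embedding index belonging to a compartment
.compartment_rows <- function(index, compartment) {
  if (compartment == "TIL") {
    which(index$compartment %in% c("ITIL", "STIL"))
  } else {
    which(index$compartment == compartment)
  }
}

#' Train a tile-level response scorer for one compartment
#'
#' Every tile inherits its patient's slide-level pCR label (weak
#' supervision); the scorer is trained on that compartment's tile
#' embeddings only, with a stratified 80/20 patient-level split and
#' early stopping on validation loss.
#'
#' @param embeddings Named list (by patient id); each element a list
#'   with \code{matrix} (tiles x 1024) and \code{index} (data frame
#'   with a \code{compartment} column).
#' @param labels Named binary vector of patient-level pCR labels.
#' @param compartment One of \code{"TUMOR"}, \code{"STROMA"},
#'   \code{"ITIL"}, \code{"STIL"}, \code{"TIL"}.
#' @param config A \code{\link{dlps_config}}.
#' @return Object of class \code{tile_scorer}.
#' @export
train_tile_scorer <- function(embeddings, labels, compartment,
                              config = dlps_config()) {
  stopifnot(compartment %in% .dlps_compartments)
  labels <- labels[names(embeddings)]
  if (length(unique(labels)) < 2L) {
    stop("tile scorer needs both response classes in the training cohort")
  }
  if (length(labels) < 5L) {
    stop("fewer than 5 patients; patient-level validation split infeasible")
  }
  split <- .stratified_split(labels, config$val_fraction, config$seed)
  gather <- function(ids) {
    X <- list(); y <- list()
    for (pid in ids) {
      rows <- .compartment_rows(embeddings[[pid]]$index, compartment)
      if (length(rows) == 0L) next
      X[[pid]] <- embeddings[[pid]]$matrix[rows, , drop = FALSE]
      y[[pid]] <- rep(labels[[pid]], length(rows))
    }
    list(X = do.call(rbind, X), y = unlist(y, use.names = FALSE))
  }
  tr <- gather(split$train); va <- gather(split$val)
  if (is.null(tr$X) || length(unique(tr$y)) < 2L) {
    stop("compartment ", compartment,
         " has no tiles for one of the classes in the training split")
  }
  model <- mlp_train(tr$X, tr$y, hidden = config$hidden_sizes,
                     lr = config$learning_rate,
                     batch_size = config$batch_size,
                     dropout = config$dropout_rate,
                     max_epochs = config$max_epochs,
                     patience = config$patience,
                     X_val = va$X, y_val = va$y, seed = config$seed)
  structure(list(model = model, compartment = compartment, config = config),
            class = "tile_scorer")
}

#' Score tiles with a trained scorer
#'
#' @param scorer A \code{tile_scorer}.
#' @param embeddings Numeric matrix of tile embeddings (rows = tiles).
#' @return Probability per tile, order-preserving.
#' @export
score_tiles <- function(scorer, embeddings) {
  mlp_predict(scorer$model, embeddings)
}

#' Aggregate tile scores into DLPS features for one patient
#'
#' Per compartment (tumor, stroma, iTILs, sTILs and their union TILs):
#' mean and population standard deviation of that compartment's tile
#' scores — 10 values. TIL aggregates the pooled iTIL and sTIL scores.
#' A compartment with no tiles carries (0, 0) and is listed in the
#' \code{missing} attribute.
#'
#' @param scores Numeric vector of tile probabilities in \code{[0, 1]}.
#' @param compartments Character vector (same length) of tile
#'   compartment labels (\code{"TUMOR"}, \code{"STROMA"},
#'   \code{"ITIL"}, \code{"STIL"}).
#' @return Named numeric vector of length 10
#'   (\code{TUMOR_mean, TUMOR_sd, ..., TIL_sd}) with attribute
#'   \code{missing}.
#' @export
aggregate_dlps <- function(scores, compartments) {
  stopifnot(length(scores) == length(compartments),
            all(scores >= 0 & scores <= 1))
  out <- numeric(0)
  missing <- character(0)
  for (comp in .dlps_compartments) {
    sel <- if (comp == "TIL") compartments %in% c("ITIL", "STIL")
           else compartments == comp
    s <- scores[sel]
    if (length(s) == 0L) {
      out <- c(out, 0, 0)
      missing <- c(missing, comp)
    } else {
      out <- c(out, mean(s), sqrt(sum((s - mean(s))^2) / length(s)))
    }
  }
  names(out) <- paste0(rep(.dlps_compartments, each = 2L), c("_mean", "_sd"))
  attr(out, "missing") <- missing
  out
}

#' Compute DLPS features for a cohort from trained scorers
#'
#' Scores every patient's tiles with the per-compartment scorers (the
#' TIL entry reuses the iTIL and sTIL tile scores rather than a sixth
#' model) and aggregates to the per-patient 10-vector.
#'
#' @param embeddings Named list of per-patient embedding bundles (see
#'   \code{\link{train_tile_scorer}}).
#' @param scorers Named list of \code{tile_scorer}s by compartment
#'   (\code{TUMOR}, \code{STROMA}, \code{ITIL}, \code{STIL}).
#' @return Matrix, one row per patient, 10 named DLPS columns.
#' @export
dlps_feature_matrix <- function(embeddings, scorers) {
  out <- matrix(0, length(embeddings), 10L,
                dimnames = list(names(embeddings),
                                paste0(rep(.dlps_compartments, each = 2L),
                                       c("_mean", "_sd"))))
  for (pid in names(embeddings)) {
    idx <- embeddings[[pid]]$index
    sc <- rep(NA_real_, nrow(idx))
    for (comp in c("TUMOR", "STROMA", "ITIL", "STIL")) {
      rows <- which(idx$compartment == comp)
      if (length(rows) > 0L && !is.null(scorers[[comp]])) {
        sc[rows] <- score_tiles(scorers[[comp]],
                                embeddings[[pid]]$matrix[rows, , drop = FALSE])
      }
    }
    keep <- !is.na(sc)
    out[pid, ] <- aggregate_dlps(sc[keep], idx$compartment[keep])
  }
  out
}
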