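#' Partition an image into non-overlapping square tiles
#'
#' Tiles are half-open pixel intervals \code{[r0, r0+tile_px) x
#' [c0, c0+tile_px)}; partial tiles at the right/bottom edges are
#' dropped rather than padded, so every tile sees a full field of
#' tissue.
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param tile_px Tile side in pixels.
#' @return Data frame with one row per tile: 0-based tile indices
#'   \code{row}, \code{col} and pixel offsets \code{r0}, \code{c0}
#'   (upper-left corner; the tile spans \code{tile_px} pixels).
#' @export
tile_partition <- function(image_height_px, image_width_px, tile_px = 175L) {
  tile_px <- as.integer(tile_px)
  stopifnot(tile_px >= 1L)
  n_r <- image_height_px %/% tile_px
  n_c <- image_width_px %/% tile_px
  if (n_r < 1L || n_c < 1L) {
    warning("image smaller than one tile; no tiles produced")
    return(data.frame(row = integer(0), col = integer(0),
                      r0 = integer(0), c0 = integer(0)))
  }
  grid <- expand.grid(col = seq_len(n_c) - 1L, row = seq_len(n_r) - 1L)
  data.frame(row = grid$row, col = grid$col,
             r0 = grid$row * tile_px, c0 = grid$col * tile_px)
}

#' Otsu threshold of a grayscale histogram
#'
#' Returns the intensity threshold maximizing the between-class
#' variance of the two classes it induces. Pixels with intensity
#' strictly below the threshold are treated as tissue (H&E tissue is
#' darker than the glass background). A histogram with all mass at a
#' single intensity is degenerate: that intensity is returned and
#' flagged.
#'
#' @param gray_histogram Numeric vector of 256 non-negative counts for
#'   intensities 0..255.
#' @return Integer threshold in \code{[0, 255]} with attribute
#'   \code{degenerate} (logical).
#' @export
otsu_threshold <- function(gray_histogram) {
  stopifnot(length(gray_histogram) == 256L, all(gray_histogram >= 0))
  total <- sum(gray_histogram)
  if (total <= 0) stop("histogram has no mass")
  nz <- which(gray_histogram > 0)
  if (length(nz) == 1L) {
    return(structure(nz - 1L, degenerate = TRUE))
  }
  p <- gray_histogram / total
  lev <- 0:255
  # candidate threshold t splits into [0, t-1] (below) vs [t, 255]
  w0 <- cumsum(p)[1:255]              # P(intensity < t), t = 1..255
  mu0 <- cumsum(p * lev)[1:255]
  mu_tot <- sum(p * lev)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_tot * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  structure(which.max(bcv), degenerate = FALSE)  # threshold t in 1..255
}

#' Filter tiles by tissue fraction
#'
#' Retains tiles whose tissue fraction is at least
#' \code{min_tissue_fraction} (only tiles with strictly less are
#' discarded); input order is preserved.
#'
#' @param tiles Data frame with a \code{tissue_fraction} column in
#'   \code{[0, 1]}.
#' @param min_tissue_fraction Retention threshold.
#' @return The retained subset of \code{tiles}.
#' @export
filter_tiles <- function(tiles, min_tissue_fraction = 0.20) {
  stopifnot(all(tiles$tissue_fraction >= 0 & tiles$tissue_fraction <= 1))
  tiles[tiles$tissue_fraction >= min_tissue_fraction, , drop = FALSE]
}

#' Assign tissue labels to retained tiles
#'
#' Sequential binary labelling of retained tiles. The classifier chain
#' supplies four tile-scoring functions, each mapping a tile record to
#' a probability in \code{[0, 1]}; a score of at least 0.5 triggers the
#' positive class. Order of application: (1) tumor vs stroma; (2) tumor
#' tiles scored necrotic become necrosis (tested before lymphocytes to
#' keep necrosis out of the iTIL pool); (3) remaining tumor tiles
#' scored lymphocytic become iTILs; (4) stroma tiles scored lymphocytic
#' become sTILs. Grid cells with no retained tile are background;
#' discarded tiles are marked excluded.
#'
#' @param tiles Data frame of retained tiles with 0-based \code{row},
#'   \code{col} columns (as from \code{\link{tile_partition}} after
#'   \code{\link{filter_tiles}}).
#' @param classifier_chain Named list of functions
#'   \code{tumor_vs_stroma}, \code{necrosis}, \code{itil}, \code{stil};
#'   each takes the tile data frame and returns a probability vector.
#' @param grid_dim Integer c(rows, cols) of the tile grid.
#' @param patient_id Patient identifier.
#' @param config A \code{\link{preprocess_config}}.
#' @param discarded Optional data frame of discarded tiles (marked
#'   \code{EXCLUDED} in the grid).
#' @return A \code{\link{tta_image}}.
#' @export
assign_tissue_labels <- function(tiles, classifier_chain, grid_dim,
                                 patient_id = "unknown",
                                 config = preprocess_config(),
                                 discarded = NULL) {
  need <- c("tumor_vs_stroma", "necrosis", "itil", "stil")
  stopifnot(all(need %in% names(classifier_chain)))
  grid <- matrix(TTA_LABELS[["BACKGROUND"]], grid_dim[1L], grid_dim[2L])
  if (!is.null(discarded) && nrow(discarded) > 0L) {
    grid[cbind(discarded$row + 1L, discarded$col + 1L)] <-
      TTA_LABELS[["EXCLUDED"]]
  }
  if (nrow(tiles) == 0L) return(tta_image(grid, patient_id, config))

  score <- function(stage) {
    p <- classifier_chain[[stage]](tiles)
    if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
      stop("classifier stage '", stage, "' returned scores outside [0, 1]")
    }
    p
  }
  lab <- ifelse(score("tumor_vs_stroma") >= 0.5, "TUMOR", "STROMA")
  is_tum <- lab == "TUMOR"
  nec <- score("necrosis") >= 0.5
  lab[is_tum & nec] <- "NECROSIS"
  iti <- score("itil") >= 0.5
  lab[is_tum & !nec & iti] <- "ITIL"
  sti <- score("stil") >= 0.5
  lab[lab == "STROMA" & sti] <- "STIL"
  grid[cbind(tiles$row + 1L, tiles$col + 1L)] <- TTA_LABELS[lab]
  tta_image(grid, patient_id, config)
}
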