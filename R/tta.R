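#' Tissue compartment labels
#'
#' Canonical label set for tile-level tissue type annotation images
#' (TTA-images). Each retained slide tile carries exactly one label:
#' tumor, stroma, intratumoral TILs (iTILs), stromal TILs (sTILs),
#' necrosis, background (no tissue) or excluded (filtered out).
#' The pseudo-compartment \code{"TIL"} denotes the union of iTILs and
#' sTILs and is accepted wherever a compartment name is expected.
#'
#' @format Named character vector of single-character grid codes.
#' @export
TTA_LABELS <- c(
  BACKGROUND = "B",
  EXCLUDED   = "X",
  TUMOR      = "T",
  STROMA     = "S",
  ITIL       = "I",
  STIL       = "L",
  NECROSIS   = "N"
)

#' Compartments for which tissue graphs are built
#' @export
TTA_COMPARTMENTS <- c("TUMOR", "STROMA", "ITIL", "STIL", "TIL")

#' Preprocessing configuration
#'
#' Tiling and filtering parameters. Defaults follow the standard 20x
#' H&E setting: 175-pixel tiles at 0.5 micron per pixel, i.e. 87.5
#' micron of tissue per tile side, and discarding tiles with less than
#' 20\% tissue area.
#'
#' @param tile_px Integer, pixels per (square) tile side.
#' @param microns_per_px Physical resolution in micron per pixel.
#' @param min_tissue_fraction Minimum tissue fraction a tile must reach
#'   to be retained (tiles strictly below are discarded).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(tile_px = 175L, microns_per_px = 0.5,
                              min_tissue_fraction = 0.20) {
  tile_px <- as.integer(tile_px)
  stopifnot(tile_px >= 1L, microns_per_px > 0,
            min_tissue_fraction >= 0, min_tissue_fraction <= 1)
  structure(list(tile_px = tile_px,
                 microns_per_px = microns_per_px,
                 min_tissue_fraction = min_tissue_fraction),
            class = "preprocess_config")
}

#' Physical tile side implied by a preprocessing configuration
#'
#' @param config A \code{\link{preprocess_config}}.
#' @return Tile side length in micron (\code{tile_px * microns_per_px}).
#' @export
tile_side_um <- function(config = preprocess_config()) {
  config$tile_px * config$microns_per_px
}

#' Construct a TTA-image
#'
#' A TTA-image is a 2-D grid of tile labels — the structural substrate
#' from which all compartment graphs are built. Rows/columns are
#' 0-based tile indices in row-major order.
#'
#' @param grid Character matrix of labels; either full names
#'   (\code{"TUMOR"}, ...) or single-character codes (\code{"T"}, ...).
#' @param patient_id Patient identifier string.
#' @param config A \code{\link{preprocess_config}} carried as metadata.
#' @return Object of class \code{tta_image}.
#' @export
tta_image <- function(grid, patient_id, config = preprocess_config()) {
  stopifnot(is.matrix(grid), nrow(grid) >= 1L, ncol(grid) >= 1L)
  g <- as.character(grid)
  if (all(g %in% names(TTA_LABELS))) {
    grid[] <- TTA_LABELS[g]
  } else if (!all(g %in% TTA_LABELS)) {
    bad <- unique(g[!(g %in% TTA_LABELS) & !(g %in% names(TTA_LABELS))])
    stop("unknown tissue labels in grid: ", paste(bad, collapse = ", "))
  }
  structure(list(grid = grid, patient_id = as.character(patient_id),
                 config = config),
            class = "tta_image")
}

#' @export
print.tta_image <- function(x, ...) {
  tab <- table(factor(x$grid, levels = TTA_LABELS))
  names(tab) <- names(TTA_LABELS)
  cat(sprintf("TTA-image for patient %s: %d x %d tiles (%.1f um/side)\n",
              x$patient_id, nrow(x$grid), ncol(x$grid),
              tile_side_um(x$config)))
  print(tab)
  invisible(x)
}

#' Extract the tile coordinates of one tissue compartment
#'
#' The \code{"TIL"} compartment is the union of intratumoral and
#' stromal TIL tiles; all other names match their label exactly.
#' Coordinates are returned 0-based in deterministic row-major order.
#'
#' @param tta A \code{\link{tta_image}}.
#' @param compartment One of \code{"TUMOR"}, \code{"STROMA"},
#'   \code{"ITIL"}, \code{"STIL"}, \code{"TIL"}, \code{"NECROSIS"}.
#' @return Integer matrix with columns \code{row}, \code{col} (0-based).
#' @export
extract_compartment <- function(tta, compartment) {
  stopifnot(inherits(tta, "tta_image"))
  compartment <- toupper(compartment)
  codes <- if (compartment == "TIL") {
    TTA_LABELS[c("ITIL", "STIL")]
  } else if (compartment %in% names(TTA_LABELS)) {
    TTA_LABELS[compartment]
  } else {
    stop("unknown compartment: ", compartment)
  }
  hit <- which(matrix(tta$grid %in% codes, nrow(tta$grid)), arr.ind = TRUE)
  # row-major order: sort by row, then column
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  out <- cbind(row = hit[, 1L] - 1L, col = hit[, 2L] - 1L)
  storage.mode(out) <- "integer"
  out
}

#' Write a TTA-image to disk
#'
#' Writes the label grid as a tab-separated matrix of single-character
#' codes plus a JSON sidecar (\code{<path>.json}) holding patient id and
#' tiling metadata. The pair round-trips losslessly through
#' \code{\link{read_tta}}.
#'
#' @param tta A \code{\link{tta_image}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_tta <- function(tta, path) {
  stopifnot(inherits(tta, "tta_image"))
  utils::write.table(tta$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(patient_id = tta$patient_id,
               tile_px = tta$config$tile_px,
               microns_per_px = tta$config$microns_per_px,
               min_tissue_fraction = tta$config$min_tissue_fraction)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TTA-image written by \code{\link{write_tta}}
#'
#' @param path TSV path (sidecar \code{<path>.json} must exist).
#' @return A \code{\link{tta_image}}.
#' @export
read_tta <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = "\t",
                                      colClasses = "character"))
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tta_image(grid, meta$patient_id,
            preprocess_config(meta$tile_px, meta$microns_per_px,
                              meta$min_tissue_fraction))
}

#' Export a TTA-image as a PNG label map
#'
#' Fixed palette: background white, excluded grey, tumor red, stroma
#' green, iTIL blue, sTIL cyan, necrosis black.
#'
#' @param tta A \code{\link{tta_image}}.
#' @param path Output PNG path.
#' @param scale Integer pixel size per tile.
#' @return \code{path}, invisibly.
#' @export
write_tta_png <- function(tta, path, scale = 4L) {
  pal <- rbind(B = c(1, 1, 1), X = c(0.7, 0.7, 0.7), T = c(0.85, 0.1, 0.1),
               S = c(0.2, 0.7, 0.2), I = c(0.1, 0.2, 0.9), L = c(0.1, 0.8, 0.9),
               N = c(0, 0, 0))
  idx <- matrix(match(tta$grid, rownames(pal)), nrow(tta$grid))
  img <- array(0, dim = c(nrow(idx) * scale, ncol(idx) * scale, 3L))
  big <- idx[rep(seq_len(nrow(idx)), each = scale),
             rep(seq_len(ncol(idx)), each = scale), drop = FALSE]
  for (ch in 1:3) img[, , ch] <- pal[cbind(as.vector(big), ch)]
  png::writePNG(img, path)
  invisible(path)
}
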