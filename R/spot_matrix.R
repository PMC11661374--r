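#' Spot expression matrix container
#'
#' Holds the sequencing side of the experiment: a sparse spots-by-genes count
#' matrix plus the barcoding-grid geometry. `spots` has one row per spot with
#' its channel indices `(a, b)` and center coordinates `(x, y)` in pixels of
#' the sequencing frame. `pixel_size` is the spot footprint side length (the
#' channel width); `pitch` is the center-to-center channel distance.
#'
#' @param counts Spots-by-genes matrix (coerced to sparse); rownames are spot
#'   ids, colnames gene names.
#' @param spots Data frame `spot_id, a, b, x, y`.
#' @param genes Character vector of gene names.
#' @param pixel_size,pitch,origin Grid geometry in pixels.
#' @param truth Optional simulator ground-truth list.
#' @return A `spot_matrix` object.
#' @export
new_spot_matrix <- function(counts, spots, genes, pixel_size, pitch,
                            origin = c(0, 0), truth = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  stopifnot(is.data.frame(spots),
            all(c("spot_id", "a", "b", "x", "y") %in% names(spots)),
            nrow(counts) == nrow(spots), ncol(counts) == length(genes))
  if (anyDuplicated(spots$spot_id)) stop("duplicate spot ids")
  if (anyDuplicated(genes)) stop("duplicate gene names")
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  if (pixel_size > pitch) stop("pixel_size (spot width) must be <= pitch")
  dimnames(counts) <- list(spots$spot_id, genes)
  structure(list(counts = counts, spots = spots, genes = genes,
                 pixel_size = as.numeric(pixel_size), pitch = as.numeric(pitch),
                 origin = as.numeric(origin), truth = truth),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot matrix: %d spots x %d genes, spot width %g px, pitch %g px\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size, x$pitch))
  invisible(x)
}

## Map coordinates to grid spot index (row of the a-major expand.grid spot
## table) using the half-open footprint rule shared by the simulator and
## assign_cells_to_spots: a point is inside spot (a, b) iff
## cx - w/2 <= x < cx + w/2 and likewise for y.
spot_index <- function(x, y, grid) {
  w <- grid$channel_width
  a <- floor((x - grid$origin[1] + grid$pitch / 2) / grid$pitch) + 1
  b <- floor((y - grid$origin[2] + grid$pitch / 2) / grid$pitch) + 1
  cx <- grid$origin[1] + (a - 1) * grid$pitch
  cy <- grid$origin[2] + (b - 1) * grid$pitch
  inside <- a >= 1 & a <= grid$n_channels_a & b >= 1 & b <= grid$n_channels_b &
    (x - cx) >= -w / 2 & (x - cx) < w / 2 &
    (y - cy) >= -w / 2 & (y - cy) < w / 2
  idx <- (b - 1) * grid$n_channels_a + a
  idx[!inside] <- NA_integer_
  as.integer(idx)
}

grid_of <- function(spot_matrix) {
  sp <- spot_matrix$spots
  grid_config(n_channels_a = max(sp$a), n_channels_b = max(sp$b),
              channel_width = spot_matrix$pixel_size,
              pitch = spot_matrix$pitch, origin = spot_matrix$origin)
}
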