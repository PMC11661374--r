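provenance_block <- function(seed = NULL, extra = NULL) {
  ## deliberately no timestamp: outputs must be bit-identical across reruns
  c(list(tool = "spotsplit",
         version = as.character(utils::packageVersion("spotsplit")),
         seed = seed), extra)
}

#' Write a spot matrix to a directory
#'
#' Writes `matrix.mtx` (Matrix Market, spots x genes), `spots.tsv`
#' (`spot_id, row_index, col_index, center_x, center_y`), `genes.tsv` and
#' `grid.json` (spot width, pitch, origin).
#'
#' @param spot_matrix A `spot_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(spot_matrix, dir) {
  stopifnot(inherits(spot_matrix, "spot_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(spot_matrix$counts, file.path(dir, "matrix.mtx"))
  sp <- spot_matrix$spots
  utils::write.table(
    data.frame(spot_id = sp$spot_id, row_index = sp$a, col_index = sp$b,
               center_x = sp$x, center_y = sp$y),
    file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(spot_matrix$genes, file.path(dir, "genes.tsv"))
  jsonlite::write_json(
    list(pixel_size = spot_matrix$pixel_size, pitch = spot_matrix$pitch,
         origin = spot_matrix$origin),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a spot matrix from a directory
#'
#' Counterpart of [write_spot_matrix()]. Validates that sidecar row/column
#' counts match the matrix dimensions, that entries are nonnegative and that
#' spot ids are unique; errors name the offending counts. When `grid.json`
#' is absent the pitch is inferred from the spot centers and `pixel_size`
#' must then be supplied (it defaults to the inferred pitch, i.e. gap-free
#' footprints).
#'
#' @param dir Directory containing `matrix.mtx`, `spots.tsv`, `genes.tsv`
#'   and optionally `grid.json`.
#' @param pixel_size Spot width override when no `grid.json` is present.
#' @return A `spot_matrix`.
#' @export
read_spot_matrix <- function(dir, pixel_size = NULL) {
  mtx <- file.path(dir, "matrix.mtx")
  for (f in c(mtx, file.path(dir, c("spots.tsv", "genes.tsv"))))
    if (!file.exists(f)) stop("missing input file: ", f)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  spots <- utils::read.delim(file.path(dir, "spots.tsv"),
                             stringsAsFactors = FALSE)
  genes <- readLines(file.path(dir, "genes.tsv"))
  if (nrow(spots) != nrow(counts))
    stop(sprintf("spots.tsv lists %d spots but matrix.mtx declares %d rows",
                 nrow(spots), nrow(counts)))
  if (length(genes) != ncol(counts))
    stop(sprintf("genes.tsv lists %d genes but matrix.mtx declares %d columns",
                 length(genes), ncol(counts)))
  if (anyDuplicated(spots$spot_id))
    stop("duplicate spot ids in spots.tsv: ",
         paste(utils::head(unique(spots$spot_id[duplicated(spots$spot_id)]), 5),
               collapse = ", "))
  if (any(counts@x < 0)) stop("matrix.mtx contains negative entries")
  names(spots)[names(spots) == "row_index"] <- "a"
  names(spots)[names(spots) == "col_index"] <- "b"
  names(spots)[names(spots) == "center_x"] <- "x"
  names(spots)[names(spots) == "center_y"] <- "y"

  gj <- file.path(dir, "grid.json")
  if (file.exists(gj)) {
    g <- jsonlite::read_json(gj, simplifyVector = TRUE)
    pitch <- g$pitch; px <- g$pixel_size; origin <- g$origin
  } else {
    ux <- sort(unique(spots$x)); uy <- sort(unique(spots$y))
    pitch <- min(c(diff(ux), diff(uy)))
    if (!is.finite(pitch) || pitch <= 0)
      stop("cannot infer grid pitch from spot centers; provide grid.json")
    px <- if (is.null(pixel_size)) pitch else pixel_size
    origin <- c(min(spots$x) - (min(spots$a) - 1) * pitch,
                min(spots$y) - (min(spots$b) - 1) * pitch)
  }
  new_spot_matrix(counts = counts, spots = spots, genes = genes,
                  pixel_size = px, pitch = pitch, origin = origin)
}

#' Write / read a cell table as CSV
#'
#' @param cells A cell table.
#' @param path CSV path.
#' @return `path` invisibly / the cell table.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @param markers Optional explicit marker column names (default: everything
#'   outside the reserved id/coordinate columns).
#' @export
read_cell_table <- function(path, markers = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cell_table(df, markers = markers)
}

#' Write / read a transform as JSON
#'
#' Similarity transforms store `{type, scale, rotation_deg, tx, ty, matrix}`;
#' affine transforms store the 2x2 linear part and translation. Optional
#' `loss`/`converged` fields carry registration diagnostics, and a
#' provenance block records tool version and seed.
#'
#' @param transform A transform object.
#' @param path JSON path.
#' @param loss,converged Optional registration diagnostics.
#' @param seed Optional seed to record.
#' @export
write_transform <- function(transform, path, loss = NULL, converged = NULL,
                            seed = NULL) {
  m <- transform_matrix(transform)
  obj <- if (inherits(transform, "similarity_transform")) {
    list(type = "similarity", scale = transform$scale,
         rotation_deg = transform$rotation,
         tx = transform$translation[1], ty = transform$translation[2],
         matrix = m)
  } else {
    list(type = "affine", A = transform$A,
         tx = transform$translation[1], ty = transform$translation[2],
         matrix = m)
  }
  obj$loss <- loss
  obj$converged <- converged
  obj$provenance <- provenance_block(seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "similarity")) {
    similarity_transform(scale = obj$scale, rotation = obj$rotation_deg,
                         translation = c(obj$tx, obj$ty))
  } else if (identical(obj$type, "affine")) {
    affine_transform(matrix(unlist(obj$A), 2, 2), c(obj$tx, obj$ty))
  } else stop("unknown transform type in ", path)
}

#' Write / read a cell-type signature matrix as CSV
#'
#' Rows are cell types (first column `type`), columns genes.
#' @param signatures Types-by-genes matrix.
#' @param path CSV path.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(type = rownames(signatures),
                   as.data.frame(signatures, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a sub-spot matrix to a directory
#'
#' Writes `subspots.mtx` (sub-spots x genes), `subspots.tsv`
#' (`spot_id, type, beta, n_cells`) and `genes.tsv`; the `"drop"` policy's
#' unassigned bucket, when present, goes to `unassigned.mtx`.
#'
#' @param subspots A `subspot_matrix` from [split_spots()].
#' @param dir Output directory.
#' @export
write_subspots <- function(subspots, dir) {
  stopifnot(inherits(subspots, "subspot_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(subspots$counts, sparse = TRUE),
                  file.path(dir, "subspots.mtx"))
  utils::write.table(subspots$keys, file.path(dir, "subspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(subspots$genes, file.path(dir, "genes.tsv"))
  if (!is.null(subspots$unassigned))
    Matrix::writeMM(Matrix::Matrix(subspots$unassigned, sparse = TRUE),
                    file.path(dir, "unassigned.mtx"))
  invisible(dir)
}

#' Read a TIFF channel stack or label mask
#'
#' Flat (non-pyramidal) TIFF only. Multi-page files become a
#' rows x cols x channels array; a single page stays a matrix. Label masks
#' read as integers (16-bit TIFFs are de-normalized back to integer labels).
#'
#' @param path TIFF path.
#' @return Numeric array/matrix.
#' @export
read_channel_stack <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 1L) return(pages[[1]])
  simplify2array(pages)
}

#' @rdname read_channel_stack
#' @export
read_label_mask <- function(path) {
  m <- read_channel_stack(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Library-size normalize counts (counts-per-scale, optionally log1p)
#'
#' Standard scRNA-seq style normalization used before signature aggregation
#' and cross-modality linkage: each profile is scaled to `scale_factor`
#' total counts; `log1p = TRUE` additionally log-transforms.
#'
#' @param counts Profiles-by-genes matrix.
#' @param scale_factor Target total per profile (default 1e4).
#' @param log1p Apply `log1p` after scaling (default TRUE).
#' @export
lognormalize_counts <- function(counts, scale_factor = 1e4, log1p = TRUE) {
  m <- as.matrix(counts)
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  m <- m / tot * scale_factor
  if (log1p) m <- log1p(m)
  m
}

#' Write a simulated dataset (both modalities plus ground truth)
#'
#' Writes the spot matrix directory, the raw imaging cell table, the
#' reference profiles and labels, and `truth.json` (seed, true transform if
#' any, true per-spot proportions) so a full pipeline run can be scored.
#'
#' @param dir Output directory.
#' @param tissue A `tissue`.
#' @param cells Rendered cell table (possibly perturbed).
#' @param spot_matrix Rendered `spot_matrix`.
#' @param reference Optional list from [render_reference()].
#' @param transform Optional true perturbation transform.
#' @export
write_simulation <- function(dir, tissue, cells, spot_matrix,
                             reference = NULL, transform = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spot_matrix(spot_matrix, file.path(dir, "spots"))
  write_cell_table(cells, file.path(dir, "cells.csv"))
  if (!is.null(reference)) {
    utils::write.csv(data.frame(id = rownames(reference$counts),
                                as.data.frame(reference$counts),
                                check.names = FALSE),
                     file.path(dir, "reference.csv"), row.names = FALSE)
    utils::write.csv(data.frame(id = names(reference$labels),
                                label = unname(reference$labels)),
                     file.path(dir, "reference_labels.csv"), row.names = FALSE)
  }
  truth <- list(seed = tissue$seed,
                field_size = tissue$field_size,
                types = tissue$types,
                true_beta = if (!is.null(spot_matrix$truth)) spot_matrix$truth$beta,
                n_cells = if (!is.null(spot_matrix$truth)) spot_matrix$truth$n_cells,
                transform = if (!is.null(transform))
                  list(scale = transform$scale, rotation_deg = transform$rotation,
                       tx = transform$translation[1], ty = transform$translation[2]),
                provenance = provenance_block(tissue$seed))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
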