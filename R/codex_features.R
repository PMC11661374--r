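#' Cell table helpers
#'
#' A cell table is a plain data frame with one row per segmented cell:
#' `cell_id`, centroid `x`, `y` (pixels), `area` (px^2), optionally `type`,
#' and one column per protein marker. The marker column names are carried in
#' the `markers` attribute; when absent, every column outside the reserved
#' set is treated as a marker.
#'
#' @param df Data frame with at least `cell_id`, `x`, `y`, `area`.
#' @param markers Character vector of marker column names.
#' @return The data frame with class `cell_table` and a `markers` attribute.
#' @export
as_cell_table <- function(df, markers = NULL) {
  stopifnot(is.data.frame(df), all(c("cell_id", "x", "y", "area") %in% names(df)))
  if (anyDuplicated(df$cell_id)) stop("cell_ids must be unique")
  if (is.null(markers)) markers <- guess_markers(df)
  if (!all(markers %in% names(df))) stop("marker columns missing from table")
  attr(df, "markers") <- markers
  class(df) <- unique(c("cell_table", class(df)))
  df
}

reserved_cell_cols <- c("cell_id", "x", "y", "area", "type", "label",
                        "is_pivot", "score", "spot_id")

guess_markers <- function(df) setdiff(names(df), reserved_cell_cols)

#' Marker column names of a cell table
#' @param cells A cell table.
#' @export
marker_names <- function(cells) {
  m <- attr(cells, "markers")
  if (is.null(m)) m <- guess_markers(cells)
  m
}

#' Marker columns of a cell table as a numeric matrix
#' @param cells A cell table.
#' @export
marker_matrix <- function(cells) {
  m <- marker_names(cells)
  out <- as.matrix(as.data.frame(cells)[, m, drop = FALSE])
  rownames(out) <- cells$cell_id
  out
}

#' Extract per-cell features from a label mask and channel stack
#'
#' For every nonzero label in the segmentation mask, sums each channel's
#' pixel intensities under the label (the raw per-cell signal), counts pixels
#' (area) and averages pixel coordinates (centroid). Label 0 is background.
#' Coordinates are 0-based pixel indices with x = column and y = row.
#'
#' @param label_mask Integer matrix; 0 = background, k > 0 = cell k.
#' @param channel_stack 3-D array `(rows, cols, channels)` or a list of
#'   matrices, each the same size as `label_mask`.
#' @param channel_names Character vector naming the channels.
#' @return A cell table with raw signal columns, one per channel.
#' @export
extract_cell_features <- function(label_mask, channel_stack, channel_names) {
  if (is.list(channel_stack))
    channel_stack <- simplify2array(channel_stack)
  if (length(dim(channel_stack)) == 2L)
    channel_stack <- array(channel_stack, c(dim(channel_stack), 1L))
  stopifnot(length(dim(channel_stack)) == 3L)
  if (!identical(dim(label_mask), dim(channel_stack)[1:2]))
    stop(sprintf("label mask is %dx%d but channels are %dx%d",
                 nrow(label_mask), ncol(label_mask),
                 dim(channel_stack)[1], dim(channel_stack)[2]))
  if (length(channel_names) != dim(channel_stack)[3])
    stop("channel_names length must match number of channels")
  if (any(channel_stack < 0)) stop("channel intensities must be nonnegative")

  lab <- as.integer(label_mask)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) {
    warning("label mask contains no cells; returning empty table")
    empty <- data.frame(cell_id = character(), x = numeric(), y = numeric(),
                        area = numeric(), stringsAsFactors = FALSE)
    for (nm in channel_names) empty[[nm]] <- numeric()
    return(as_cell_table(empty, markers = channel_names))
  }

  fg <- lab > 0L
  f <- factor(lab[fg], levels = ids)
  area <- as.numeric(table(f))
  rows <- (seq_along(lab) - 1L) %% nrow(label_mask)      # 0-based y
  cols <- (seq_along(lab) - 1L) %/% nrow(label_mask)     # 0-based x
  cx <- rowsum(cols[fg], f) / area
  cy <- rowsum(rows[fg], f) / area

  out <- data.frame(cell_id = as.character(ids), x = as.numeric(cx),
                    y = as.numeric(cy), area = area, stringsAsFactors = FALSE)
  for (ch in seq_along(channel_names)) {
    v <- channel_stack[, , ch]
    out[[channel_names[ch]]] <- as.numeric(rowsum(as.numeric(v)[fg], f))
  }
  as_cell_table(out, markers = channel_names)
}

#' Quality-filter cells on size and nuclear signal
#'
#' Retains cells whose area lies within the stated quantile range of the
#' observed areas (inclusive at both ends) and whose nuclear-stain raw signal
#' strictly exceeds its lower quantile threshold. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param cells A cell table.
#' @param size_quantile_range Lower and upper area quantiles (default
#'   `c(0.05, 0.95)`).
#' @param dapi_channel Name of the nuclear-stain marker column.
#' @param dapi_quantile Lower quantile of nuclear signal; cells at or below
#'   the threshold are dropped (default 0.1).
#' @return The filtered cell table, with attribute `filter_thresholds`
#'   recording the area bounds and nuclear threshold applied.
#' @export
filter_cells <- function(cells, size_quantile_range = c(0.05, 0.95),
                         dapi_channel = "DAPI", dapi_quantile = 0.1) {
  stopifnot(length(size_quantile_range) == 2L,
            size_quantile_range[1] <= size_quantile_range[2])
  if (!dapi_channel %in% names(cells))
    stop(sprintf("nuclear channel '%s' not found in cell table", dapi_channel))
  if (nrow(cells) == 0L) {
    warning("empty cell table; nothing to filter")
    return(cells)
  }
  qa <- stats::quantile(cells$area, size_quantile_range, names = FALSE, type = 7)
  qd <- stats::quantile(cells[[dapi_channel]], dapi_quantile, names = FALSE, type = 7)
  keep <- cells$area >= qa[1] & cells$area <= qa[2] & cells[[dapi_channel]] > qd
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- as_cell_table(out, markers = marker_names(cells))
  attr(out, "filter_thresholds") <- list(area_low = qa[1], area_high = qa[2],
                                         dapi = qd, dapi_channel = dapi_channel)
  out
}

#' Scale per-cell marker signals to [0, 1] by 5th/95th quantiles
#'
#' The working value is raw signal divided by cell area (per-pixel mean
#' intensity) when `area_normalize` is TRUE, else the raw sum. Per marker the
#' lower and upper quantiles (default 0.05 and 0.95) of the working values
#' are computed; values are mapped linearly so the lower quantile becomes 0
#' and the upper becomes 1, and clipped outside that range. A marker whose
#' two quantiles coincide carries no usable signal at this scaling and is set
#' to 0 for all cells, with a warning.
#'
#' @param cells A cell table with raw signals.
#' @param area_normalize Divide by area before scaling (default TRUE).
#' @param q Length-2 quantile pair used for the scaling window.
#' @return `list(cells = table with marker columns replaced by normalized
#'   values, record = normalization_record)` where the record stores per-
#'   marker `q_low`/`q_high`, the flags and the quantile method, sufficient
#'   to reproduce the mapping.
#' @export
normalize_features <- function(cells, area_normalize = TRUE, q = c(0.05, 0.95)) {
  stopifnot(length(q) == 2L, q[1] <= q[2])
  if (any(cells$area <= 0)) stop("cell areas must be positive")
  mk <- marker_names(cells)
  vals <- marker_matrix(cells)
  if (area_normalize) vals <- vals / cells$area

  q_low <- q_high <- stats::setNames(numeric(length(mk)), mk)
  out <- vals
  degenerate <- character()
  for (m in mk) {
    qq <- stats::quantile(vals[, m], q, names = FALSE, type = 7)
    q_low[m] <- qq[1]; q_high[m] <- qq[2]
    if (qq[2] == qq[1]) {
      out[, m] <- 0
      degenerate <- c(degenerate, m)
    } else {
      out[, m] <- pmin(pmax((vals[, m] - qq[1]) / (qq[2] - qq[1]), 0), 1)
    }
  }
  if (length(degenerate))
    warning(sprintf("constant marker(s) set to 0: %s",
                    paste(degenerate, collapse = ", ")))
  res <- as.data.frame(cells)
  res[, mk] <- out
  res <- as_cell_table(res, markers = mk)
  record <- structure(list(q_low = q_low, q_high = q_high,
                           quantiles = q, area_normalized = area_normalize,
                           quantile_method = "type7_linear_interpolation",
                           degenerate_markers = degenerate),
                      class = "normalization_record")
  list(cells = res, record = record)
}
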