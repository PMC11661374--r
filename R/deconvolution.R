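#' Assign registered cells to barcoded spots
#'
#' A cell belongs to spot `(a, b)` iff its centroid lies in the half-open
#' square `[cx - w/2, cx + w/2) x [cy - w/2, cy + w/2)` around the spot
#' center, where `w` is the spot width (`pixel_size`). Half-open footprints
#' are disjoint whenever `w <= pitch`, so each cell maps to at most one spot;
#' cells falling in inter-channel gaps or outside the grid are unassigned.
#' Cell coordinates must already be in the spot coordinate system
#' (post-registration).
#'
#' @param cells Cell table with `x`, `y` in the spot frame.
#' @param spot_matrix A `spot_matrix`.
#' @return Data frame `cell_id, spot_id` with `NA` spot_id for unassigned
#'   cells.
#' @export
assign_cells_to_spots <- function(cells, spot_matrix) {
  stopifnot(inherits(spot_matrix, "spot_matrix"))
  if (spot_matrix$pixel_size > spot_matrix$pitch)
    stop("spot footprints overlap (pixel_size > pitch); geometry is invalid")
  grid <- grid_of(spot_matrix)
  w <- grid$channel_width
  a <- floor((cells$x - grid$origin[1] + grid$pitch / 2) / grid$pitch) + 1
  b <- floor((cells$y - grid$origin[2] + grid$pitch / 2) / grid$pitch) + 1
  cx <- grid$origin[1] + (a - 1) * grid$pitch
  cy <- grid$origin[2] + (b - 1) * grid$pitch
  inside <- (cells$x - cx) >= -w / 2 & (cells$x - cx) < w / 2 &
    (cells$y - cy) >= -w / 2 & (cells$y - cy) < w / 2
  key <- paste(a, b)
  pos <- match(key, paste(spot_matrix$spots$a, spot_matrix$spots$b))
  spot_id <- spot_matrix$spots$spot_id[pos]
  spot_id[!inside | is.na(pos)] <- NA_character_
  data.frame(cell_id = cells$cell_id, spot_id = spot_id,
             stringsAsFactors = FALSE)
}

#' Cell-type proportions per spot from assigned, labeled cells
#'
#' The imaging-informed deconvolution prior: `beta[k, i]` is the fraction of
#' cells assigned to spot `i` that carry type label `k`. Spots with no
#' assigned cell get an all-zero column and are flagged empty.
#'
#' @param assignment Data frame `cell_id, spot_id` from
#'   [assign_cells_to_spots()].
#' @param cell_labels Named character vector (names = cell_id) or a cell
#'   table with a `type` column.
#' @param type_universe Character vector of all type names (defines row
#'   order); defaults to the sorted labels observed.
#' @param spot_ids All spot ids (column order); defaults to the assigned ones.
#' @return A `spot_proportions` object: `beta` (types x spots, columns of
#'   occupied spots sum to 1), `n_cells`, `empty`.
#' @export
compute_proportions <- function(assignment, cell_labels, type_universe = NULL,
                                spot_ids = NULL) {
  if (is.data.frame(cell_labels)) {
    if (!"type" %in% names(cell_labels))
      stop("cell table has no 'type' column")
    cell_labels <- stats::setNames(cell_labels$type, cell_labels$cell_id)
  }
  assigned <- assignment[!is.na(assignment$spot_id), , drop = FALSE]
  lab <- cell_labels[assigned$cell_id]
  bad <- assigned$cell_id[is.na(lab)]
  if (length(bad))
    stop(sprintf("assigned cells without a label: %s%s",
                 paste(utils::head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""))
  if (is.null(type_universe)) type_universe <- sort(unique(lab))
  if (!all(lab %in% type_universe))
    stop("labels outside type_universe: ",
         paste(setdiff(unique(lab), type_universe), collapse = ", "))
  if (is.null(spot_ids)) spot_ids <- sort(unique(assigned$spot_id))

  tab <- table(factor(lab, levels = type_universe),
               factor(assigned$spot_id, levels = spot_ids))
  counts <- matrix(as.numeric(tab), nrow = length(type_universe),
                   dimnames = list(type_universe, spot_ids))
  n_cells <- colSums(counts)
  beta <- sweep(counts, 2, pmax(n_cells, 1), "/")
  beta[, n_cells == 0] <- 0
  structure(list(beta = beta, n_cells = n_cells, empty = n_cells == 0),
            class = "spot_proportions")
}

#' @export
print.spot_proportions <- function(x, ...) {
  cat(sprintf("spot proportions: %d types x %d spots (%d occupied)\n",
              nrow(x$beta), ncol(x$beta), sum(!x$empty)))
  invisible(x)
}

#' Cell-type signature matrix from reference expression profiles
#'
#' `mu[k, j]` is the arithmetic mean expression of gene `j` over reference
#' profiles labeled type `k`, on whatever normalization scale the reference
#' is supplied in (no re-normalization is applied; per-gene scaling cancels
#' in the splitting formula anyway).
#'
#' @param reference_expression Profiles-by-genes matrix.
#' @param reference_labels Type label per profile (row).
#' @param types Types to include; default all observed. A requested type
#'   with no profiles is an error.
#' @return Types-by-genes numeric matrix.
#' @export
aggregate_signatures <- function(reference_expression, reference_labels,
                                 types = NULL) {
  m <- as.matrix(reference_expression)
  if (nrow(m) != length(reference_labels))
    stop("one label per reference profile is required")
  if (is.null(types)) types <- sort(unique(as.character(reference_labels)))
  missing <- setdiff(types, reference_labels)
  if (length(missing))
    stop("no reference profiles for type(s): ", paste(missing, collapse = ", "))
  f <- factor(as.character(reference_labels), levels = types)
  keep <- !is.na(f)
  mu <- rowsum(m[keep, , drop = FALSE], f[keep]) /
    as.numeric(table(f[keep]))
  mu <- as.matrix(mu)[types, , drop = FALSE]
  if (any(rowSums(mu) == 0)) stop("all-zero signature row; reference unusable")
  mu
}

#' Split spot counts into pure-cell-type sub-spots
#'
#' The core allocation: given spot counts `x[i, j]`, imaging-derived type
#' proportions `beta[k, i]` and reference signatures `mu[k, j]`, each spot's
#' counts are divided among its constituent types as
#'
#' \deqn{\hat X_{i,j,k} = x_{i,j} \frac{\beta_{k,i} \mu_{k,j}}
#'   {\sum_{k'} \beta_{k',i} \mu_{k',j}}}
#'
#' so that a type's share of gene `j` in spot `i` is proportional to its cell
#' fraction weighted by how strongly it expresses that gene. Summing over
#' types returns the original counts exactly (conservation). Genes absent
#' from `mu` are dropped (with a message); for a gene whose denominator is 0
#' in an occupied spot with nonzero counts, the `"beta"` policy (default)
#' splits by `beta` alone, preserving conservation, while `"drop"` routes
#' those counts to an `unassigned` bucket. Empty spots yield no sub-spots.
#'
#' @param spot_matrix A `spot_matrix`.
#' @param proportions A `spot_proportions` (types x spots).
#' @param signatures Types-by-genes signature matrix `mu`; type names must
#'   match `proportions`.
#' @param zero_denominator_policy `"beta"` or `"drop"`.
#' @return A `subspot_matrix`: `counts` (sub-spots x genes), `keys` (data
#'   frame `spot_id, type, beta, n_cells`, one row per (occupied spot, type
#'   with beta > 0)), `genes`, and `unassigned` (spots x genes matrix of
#'   dropped counts, only under the `"drop"` policy).
#' @export
split_spots <- function(spot_matrix, proportions, signatures,
                        zero_denominator_policy = c("beta", "drop")) {
  policy <- match.arg(zero_denominator_policy)
  stopifnot(inherits(spot_matrix, "spot_matrix"),
            inherits(proportions, "spot_proportions"))
  mu <- as.matrix(signatures)
  beta <- proportions$beta
  if (is.null(rownames(mu)) || is.null(rownames(beta)))
    stop("both beta and mu need type names")
  if (!setequal(rownames(mu), rownames(beta)))
    stop("type names of beta and mu do not match: beta has {",
         paste(setdiff(rownames(beta), rownames(mu)), collapse = ", "),
         "} not in mu")
  mu <- mu[rownames(beta), , drop = FALSE]
  if (any(mu < 0)) stop("signature matrix must be nonnegative")
  if (any(rowSums(mu) == 0)) stop("all-zero signature row in mu")

  genes <- intersect(colnames(spot_matrix$counts), colnames(mu))
  dropped <- ncol(spot_matrix$counts) - length(genes)
  if (length(genes) == 0L) stop("no genes shared between counts and mu")
  if (dropped > 0)
    message(sprintf("dropping %d gene(s) absent from the signature matrix", dropped))

  spot_ids <- intersect(colnames(beta), rownames(spot_matrix$counts))
  occ <- spot_ids[!proportions$empty[match(spot_ids, colnames(beta))]]
  x <- as.matrix(spot_matrix$counts[occ, genes, drop = FALSE])
  B <- beta[, occ, drop = FALSE]                    # K x S
  M <- mu[, genes, drop = FALSE]                    # K x G
  D <- t(B) %*% M                                   # S x G denominators

  zero_d <- D == 0 & x > 0
  keys <- NULL; rows <- list()
  unassigned <- NULL
  if (policy == "drop" && any(zero_d)) {
    unassigned <- matrix(0, length(occ), length(genes),
                         dimnames = list(occ, genes))
    unassigned[zero_d] <- x[zero_d]
  }
  Dsafe <- D; Dsafe[D == 0] <- 1
  for (k in rownames(B)) {
    sel <- B[k, ] > 0
    if (!any(sel)) next
    W <- outer(B[k, sel], M[k, ]) / Dsafe[sel, , drop = FALSE]
    Xk <- x[sel, , drop = FALSE] * W
    if (policy == "beta" && any(zero_d[sel, , drop = FALSE])) {
      zz <- zero_d[sel, , drop = FALSE]
      Xk[zz] <- (x[sel, , drop = FALSE] * B[k, sel])[zz]
    }
    rows[[k]] <- Xk
    keys <- rbind(keys, data.frame(spot_id = occ[sel], type = k,
                                   beta = unname(B[k, sel]),
                                   n_cells = unname(proportions$n_cells[occ[sel]]),
                                   stringsAsFactors = FALSE))
  }
  counts <- do.call(rbind, rows)
  ord <- order(keys$spot_id, keys$type)
  keys <- keys[ord, , drop = FALSE]; rownames(keys) <- NULL
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- paste(keys$spot_id, keys$type, sep = "|")
  structure(list(counts = counts, keys = keys, genes = genes,
                 unassigned = unassigned, policy = policy),
            class = "subspot_matrix")
}

#' @export
print.subspot_matrix <- function(x, ...) {
  cat(sprintf("sub-spot matrix: %d (spot, type) rows x %d genes [policy %s]\n",
              nrow(x$counts), length(x$genes), x$policy))
  invisible(x)
}

#' Aggregate imaging cells into pure-cell-type protein sub-spots
#'
#' The protein-side counterpart of [split_spots()]: for every (spot, type)
#' pair with at least one assigned cell, averages the normalized marker
#' signals of those cells. Row keys use the same `spot_id|type` scheme as the
#' RNA sub-spots, so when both are derived from the same assignment and
#' labels the two modalities join one-to-one.
#'
#' @param cells Normalized cell table.
#' @param assignment Data frame `cell_id, spot_id`.
#' @param labels Named label vector or cell table with `type`; defaults to
#'   `cells$type`.
#' @return `list(protein = (spot, type) x markers matrix of mean normalized
#'   signal, keys = data frame spot_id, type, n_cells)`.
#' @export
aggregate_codex_subspots <- function(cells, assignment, labels = NULL) {
  if (is.null(labels)) {
    if (!"type" %in% names(cells)) stop("no labels supplied and no 'type' column")
    labels <- stats::setNames(cells$type, cells$cell_id)
  } else if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$type, labels$cell_id)
  }
  spot <- assignment$spot_id[match(cells$cell_id, assignment$cell_id)]
  lab <- labels[cells$cell_id]
  keep <- !is.na(spot) & !is.na(lab)
  if (!any(keep)) stop("no assigned, labeled cells to aggregate")
  key <- paste(spot[keep], lab[keep], sep = "|")
  vals <- marker_matrix(cells)[keep, , drop = FALSE]
  f <- factor(key)
  n <- as.numeric(table(f))
  prot <- rowsum(vals, f) / n
  parts <- do.call(rbind, strsplit(levels(f), "|", fixed = TRUE))
  keys <- data.frame(spot_id = parts[, 1], type = parts[, 2], n_cells = n,
                     stringsAsFactors = FALSE)
  ord <- order(keys$spot_id, keys$type)
  list(protein = prot[ord, , drop = FALSE],
       keys = { k <- keys[ord, , drop = FALSE]; rownames(k) <- NULL; k })
}
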