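#' Cross-slice marker reproducibility via spatial binning
#'
#' Registers slice A into slice B's frame (optional transform), discretizes
#' both coordinate sets on a square raster of `bin_size` pixels
#' (`bin = floor(coordinate / bin_size)` per axis), averages each marker over
#' the cells of each bin, intersects the bin keys, and computes a Pearson
#' correlation per shared marker over the common bins. Markers constant in
#' either slice have undefined correlation and are reported as `NA`, not 0.
#'
#' @param cells_a,cells_b Cell tables sharing marker names.
#' @param transform_a_to_b Optional transform mapping A coordinates into B's
#'   frame.
#' @param bin_size Bin side length in pixels (default 100).
#' @return Data frame `marker, r, n_bins`, one row per shared marker, with
#'   attribute `n_common_bins`.
#' @export
binned_marker_correlation <- function(cells_a, cells_b, transform_a_to_b = NULL,
                                      bin_size = 100) {
  stopifnot(bin_size > 0)
  shared <- intersect(marker_names(cells_a), marker_names(cells_b))
  if (length(shared) == 0L) stop("no shared markers between the slices")
  if (!is.null(transform_a_to_b))
    cells_a <- apply_transform(transform_a_to_b, cells_a)

  bin_means <- function(cells) {
    key <- paste(floor(cells$x / bin_size), floor(cells$y / bin_size))
    f <- factor(key)
    m <- rowsum(as.matrix(as.data.frame(cells)[, shared, drop = FALSE]), f) /
      as.numeric(table(f))
    m
  }
  ma <- bin_means(cells_a)
  mb <- bin_means(cells_b)
  common <- intersect(rownames(ma), rownames(mb))
  if (length(common) < 3L)
    stop(sprintf("only %d common bins; need >= 3 for a meaningful correlation",
                 length(common)))
  ma <- ma[common, , drop = FALSE]
  mb <- mb[common, , drop = FALSE]
  r <- vapply(shared, function(m) {
    if (stats::sd(ma[, m]) == 0 || stats::sd(mb[, m]) == 0) return(NA_real_)
    stats::cor(ma[, m], mb[, m])
  }, numeric(1))
  out <- data.frame(marker = shared, r = unname(r),
                    n_bins = length(common), stringsAsFactors = FALSE)
  attr(out, "n_common_bins") <- length(common)
  out
}

#' Average silhouette width of a labeled embedding
#'
#' Mean silhouette over all points with Euclidean distances; points in
#' singleton clusters contribute 0 (the usual convention). Used to score how
#' well pure-cell-type sub-spots separate by type in a joint embedding.
#'
#' @param embedding Numeric matrix, points x dimensions.
#' @param labels Cluster/type label per point (>= 2 distinct labels).
#' @return The ASW, a number in `[-1, 1]`.
#' @export
average_silhouette_width <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(labels)) stop("one label per embedding row")
  if (nrow(embedding) < 3L) stop("need at least 3 points")
  if (length(unique(labels)) < 2L)
    stop("silhouette undefined for a single label")
  cl <- as.integer(factor(labels))
  sil <- cluster::silhouette(cl, stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions of the same items,
#' corrected for chance agreement; 1 for identical partitions (up to label
#' renaming), approximately 0 for independent random labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(labels_a), length(labels_b)))
  mclust::adjustedRandIndex(labels_a, labels_b)
}
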