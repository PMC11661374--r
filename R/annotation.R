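#' Identify linked gene/protein feature pairs across modalities
#'
#' Matches protein markers to genes by exact name, supplemented by an alias
#' map for the usual protein-vs-gene nomenclature differences (e.g. CD20 ->
#' MS4A1). Each candidate pair is screened on per-feature standard deviation
#' in both modalities: weakly varying features carry no cross-modal
#' information and are dropped (threshold 0.01 by default, applied to the
#' matrices as supplied).
#'
#' @param reference_matrix Profiles-by-genes matrix (normalized scRNA-seq
#'   reference).
#' @param codex_matrix Cells-by-markers matrix (normalized protein signal),
#'   or a cell table.
#' @param alias_map Named character vector or list, protein name -> gene
#'   name.
#' @param sd_min Standard-deviation screen threshold (default 0.01).
#' @return A `linked_features` data frame: `gene, protein, sd_rna,
#'   sd_protein, retained, reason`. At least one retained pair is required.
#' @export
link_features <- function(reference_matrix, codex_matrix, alias_map = NULL,
                          sd_min = 0.01) {
  if (is.data.frame(codex_matrix) && inherits(codex_matrix, "cell_table"))
    codex_matrix <- marker_matrix(codex_matrix)
  genes <- colnames(reference_matrix)
  prots <- colnames(codex_matrix)
  if (length(genes) == 0L || length(prots) == 0L)
    stop("both matrices need named feature columns")
  gene_of <- stats::setNames(ifelse(prots %in% genes, prots, NA_character_), prots)
  for (p in names(alias_map))
    if (p %in% prots && is.na(gene_of[p])) gene_of[p] <- alias_map[[p]]
  cand <- !is.na(gene_of) & gene_of %in% genes
  if (!any(cand)) stop("no linkable feature pairs between the modalities")

  prot_k <- prots[cand]; gene_k <- unname(gene_of[cand])
  sd_rna <- apply(reference_matrix[, gene_k, drop = FALSE], 2, stats::sd)
  sd_prot <- apply(codex_matrix[, prot_k, drop = FALSE], 2, stats::sd)
  retained <- sd_rna > sd_min & sd_prot > sd_min
  reason <- rep("", length(prot_k))
  reason[sd_rna <= sd_min] <- "rna_sd_below_threshold"
  reason[sd_prot <= sd_min] <-
    paste0(reason[sd_prot <= sd_min],
           ifelse(reason[sd_prot <= sd_min] == "", "", "+"),
           "protein_sd_below_threshold")
  out <- data.frame(gene = gene_k, protein = prot_k,
                    sd_rna = unname(sd_rna), sd_protein = unname(sd_prot),
                    retained = retained, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("linked_features", class(out))
  if (!any(out$retained))
    stop("all linked feature pairs fail the standard-deviation screen; integration impossible")
  out
}

## Row-standardize columns; constant columns become 0.
standardize_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

## k-NN averaged smoothing of `target` using neighborhoods computed on
## `space` (both rows = observations): (1-w) * self + w * neighbor mean.
knn_smooth <- function(target, space, k, w) {
  if (w == 0 || k == 0) return(target)
  n <- nrow(space)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(space))
  diag(d) <- Inf
  out <- target
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    out[i, ] <- (1 - w) * target[i, ] + w * colMeans(target[nb, , drop = FALSE])
  }
  out
}

#' Match cross-modality pivot cell pairs
#'
#' A linear, deterministic stand-in for iterative cross-modal matching
#' (MaxFuse-style) sufficient to seed label transfer: (1) within each
#' modality, each cell's linked-feature vector is smoothed toward the mean
#' of its k nearest neighbors in the full feature space,
#' `(1 - w) * self + w * neighbor mean`; (2) the smoothed, standardized
#' linked features of both modalities are stacked and reduced by a shared
#' SVD; (3) mutual nearest neighbors between reference profiles and imaging
#' cells in the reduced space become candidate pairs, scored by negative
#' match distance normalized by the cell's mean distance to its `k_match`
#' nearest reference profiles (a label-free local-contrast confidence, so
#' loose and tight expression clusters compete fairly); (4) the top
#' `pivot_fraction` of imaging cells by score are kept as pivots, each
#' paired with at most one reference profile.
#'
#' @param reference_matrix Profiles-by-genes matrix (normalized).
#' @param codex_matrix Cells-by-markers matrix (normalized) or cell table.
#' @param linked A `linked_features` table from [link_features()].
#' @param smoothing_weight Neighborhood smoothing weight `w` (default 0.3).
#' @param n_components Shared-SVD dimensionality; default is the smallest
#'   count explaining at least 80% of stacked variance, floored at 10 (or
#'   the number of retained linked features if fewer).
#' @param pivot_fraction Fraction of imaging cells to retain as pivots
#'   (default 0.10).
#' @param k_graph Neighbors for the smoothing graph (default 15).
#' @param k_match Neighborhood size for mutual-nearest matching (default 10).
#' @param seed Optional seed (the procedure is deterministic; the seed guards
#'   any downstream stochastic consumers and is recorded).
#' @return A `pivot_set` data frame: `cell_id, ref_id, score`, ordered by
#'   decreasing score, with attributes `n_components` and `seed`. Ties are
#'   broken by cell id order.
#' @export
match_pivots <- function(reference_matrix, codex_matrix, linked,
                         smoothing_weight = 0.3, n_components = NULL,
                         pivot_fraction = 0.10, k_graph = 15, k_match = 10,
                         seed = NULL) {
  cells_tab <- NULL
  if (is.data.frame(codex_matrix) && inherits(codex_matrix, "cell_table")) {
    cells_tab <- codex_matrix
    codex_matrix <- marker_matrix(codex_matrix)
  }
  stopifnot(inherits(linked, "linked_features"),
            smoothing_weight >= 0, smoothing_weight <= 1,
            pivot_fraction > 0, pivot_fraction <= 1)
  lk <- linked[linked$retained, , drop = FALSE]
  if (nrow(lk) == 0L) stop("no retained linked features")
  if (!is.null(n_components) && n_components > nrow(lk))
    stop("n_components exceeds the number of retained linked features")

  ref_full <- standardize_cols(as.matrix(reference_matrix))
  cdx_full <- standardize_cols(as.matrix(codex_matrix))
  ref_lk <- ref_full[, lk$gene, drop = FALSE]
  cdx_lk <- cdx_full[, lk$protein, drop = FALSE]

  ref_sm <- knn_smooth(ref_lk, ref_full, k_graph, smoothing_weight)
  cdx_sm <- knn_smooth(cdx_lk, cdx_full, k_graph, smoothing_weight)
  ref_sm <- standardize_cols(ref_sm)
  cdx_sm <- standardize_cols(cdx_sm)

  stacked <- rbind(ref_sm, cdx_sm)
  sv <- svd(scale(stacked, center = TRUE, scale = FALSE))
  var_expl <- cumsum(sv$d^2) / sum(sv$d^2)
  if (is.null(n_components))
    ## smallest count explaining >= 80% of stacked variance, floored at 10:
    ## smoothed linked features are highly collinear, so the variance rule
    ## alone can collapse to 2-3 components and blur minor populations
    n_components <- max(min(10L, nrow(lk)), which(var_expl >= 0.8)[1])
  n_components <- min(n_components, length(sv$d))
  proj <- sv$u[, seq_len(n_components), drop = FALSE] *
    rep(sv$d[seq_len(n_components)], each = nrow(stacked))
  nr <- nrow(ref_sm)
  ref_red <- proj[seq_len(nr), , drop = FALSE]
  cdx_red <- proj[-seq_len(nr), , drop = FALSE]

  ## Mutual k-nearest-neighbor candidate pairs across the modalities.
  cross <- outer(rowSums(ref_red^2), rowSums(cdx_red^2), "+") -
    2 * ref_red %*% t(cdx_red)
  cross[cross < 0] <- 0
  km <- min(k_match, nrow(ref_red), nrow(cdx_red))
  rank_ref <- t(apply(cross, 1, rank, ties.method = "first"))   # rank of codex per ref
  rank_cdx <- apply(cross, 2, rank, ties.method = "first")      # rank of ref per codex
  mutual <- rank_ref <= km & rank_cdx <= km

  ref_ids <- rownames(reference_matrix)
  if (is.null(ref_ids)) ref_ids <- sprintf("ref%05d", seq_len(nrow(cross)))
  cdx_ids <- rownames(codex_matrix)
  if (is.null(cdx_ids) && !is.null(cells_tab)) cdx_ids <- cells_tab$cell_id
  if (is.null(cdx_ids)) cdx_ids <- sprintf("cell%05d", seq_len(ncol(cross)))

  ## Best mutual reference per imaging cell; confidence = match distance
  ## relative to the cell's local cross-modal neighborhood scale.
  pairs <- lapply(seq_len(ncol(cross)), function(j) {
    cand <- which(mutual[, j])
    if (!length(cand)) return(NULL)
    best <- cand[which.min(cross[cand, j])]
    local_scale <- mean(sqrt(sort(cross[, j])[seq_len(km)]))
    if (local_scale == 0) local_scale <- 1
    data.frame(cell_id = cdx_ids[j], ref_id = ref_ids[best],
               score = -sqrt(cross[best, j]) / local_scale,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no mutual-nearest pivot candidates found")
  pairs <- pairs[order(-pairs$score, pairs$cell_id), , drop = FALSE]
  n_keep <- max(1L, min(nrow(pairs), ceiling(pivot_fraction * ncol(cross))))
  out <- pairs[seq_len(n_keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pivot_set", class(out))
  attr(out, "n_components") <- n_components
  attr(out, "seed") <- seed
  out
}

#' Transfer reference labels onto pivot cells
#'
#' @param pivots A `pivot_set` from [match_pivots()].
#' @param reference_labels Named character vector, reference profile id ->
#'   type label.
#' @return The pivot set with a `label` column.
#' @export
transfer_labels <- function(pivots, reference_labels) {
  lab <- reference_labels[pivots$ref_id]
  if (any(is.na(lab)))
    stop("reference profiles without labels: ",
         paste(utils::head(pivots$ref_id[is.na(lab)], 5), collapse = ", "))
  pivots$label <- unname(lab)
  pivots
}

#' Propagate pivot labels to all cells with a supervised classifier
#'
#' Trains a support vector machine (radial kernel, balanced class weights)
#' on the labeled pivot cells' normalized protein features, reports
#' per-class and macro F1 on a stratified held-out pivot split, then refits
#' on all pivots and predicts every non-pivot cell.
#'
#' @param labeled_pivots Pivot set with `label` (from [transfer_labels()]).
#' @param cells Normalized cell table covering all cells (pivot and not).
#' @param classifier Only `"svm"` is provided.
#' @param holdout_fraction Fraction of pivots held out per class for the F1
#'   estimate (default 0.2; at least 2 pivots per class are required).
#' @param seed Seed for the stratified split.
#' @return `list(labels = data frame cell_id, label, is_pivot, score;
#'   f1 = per-class F1 on the held-out split; macro_f1)`.
#' @export
propagate_labels <- function(labeled_pivots, cells, classifier = "svm",
                             holdout_fraction = 0.2, seed = 1) {
  classifier <- match.arg(classifier, "svm")
  if (!"label" %in% names(labeled_pivots))
    stop("pivots are unlabeled; run transfer_labels() first")
  classes <- unique(labeled_pivots$label)
  if (length(classes) < 2L) stop("at least 2 pivot classes are required")
  per_class <- table(labeled_pivots$label)
  if (any(per_class < 2L))
    stop("every class needs >= 2 pivots for the held-out split: ",
         paste(names(per_class)[per_class < 2], collapse = ", "))

  feats <- marker_matrix(cells)
  pidx <- match(labeled_pivots$cell_id, cells$cell_id)
  if (any(is.na(pidx))) stop("pivot cell ids missing from the cell table")
  X <- feats[pidx, , drop = FALSE]
  yf <- factor(labeled_pivots$label)

  split <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(yf), yf), function(ii) {
      n_hold <- max(1L, floor(holdout_fraction * length(ii)))
      sample(ii, n_hold)
    }))
  })
  wts <- length(yf) / (nlevels(yf) * table(yf))
  fit_holdout <- e1071::svm(X[-split, , drop = FALSE],
                            droplevels(yf[-split]),
                            kernel = "radial",
                            class.weights = wts[levels(droplevels(yf[-split]))])
  pred_hold <- predict(fit_holdout, X[split, , drop = FALSE])
  f1 <- per_class_f1(as.character(yf[split]), as.character(pred_hold),
                     levels(yf))

  fit <- e1071::svm(X, yf, kernel = "radial", class.weights = wts)
  is_pivot <- cells$cell_id %in% labeled_pivots$cell_id
  labels <- character(nrow(cells))
  labels[is_pivot] <- labeled_pivots$label[match(cells$cell_id[is_pivot],
                                                 labeled_pivots$cell_id)]
  if (any(!is_pivot))
    labels[!is_pivot] <- as.character(predict(fit, feats[!is_pivot, , drop = FALSE]))
  score <- rep(NA_real_, nrow(cells))
  score[is_pivot] <- labeled_pivots$score[match(cells$cell_id[is_pivot],
                                                labeled_pivots$cell_id)]
  list(labels = data.frame(cell_id = cells$cell_id, label = labels,
                           is_pivot = is_pivot, score = score,
                           stringsAsFactors = FALSE),
       f1 = f1, macro_f1 = mean(f1, na.rm = TRUE))
}

## Per-class F1; classes absent from both truth and prediction give NA.
per_class_f1 <- function(truth, pred, classes) {
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
}
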