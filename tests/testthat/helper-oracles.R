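# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and stats::quantile) so they can vouch
# for them.

# Linear-interpolation quantile between order statistics, written out by hand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# O(n^2) silhouette with the singleton-cluster-contributes-0 convention.
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    if (sum(same) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, same & seq_len(n) != i])
    b <- min(vapply(unique(labels[!same]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ARI by explicit enumeration of all item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- ss + sd_ + ds + dd
  expected <- (ss + sd_) * (ss + ds) / tot
  maxi <- ((ss + sd_) + (ss + ds)) / 2
  if (maxi == expected) return(1)
  (ss - expected) / (maxi - expected)
}

# Per-pixel accumulation of per-cell area/centroid/channel sums.
oracle_cell_features <- function(mask, stack, names) {
  ids <- sort(unique(mask[mask > 0]))
  out <- lapply(ids, function(id) {
    sums <- numeric(dim(stack)[3])
    area <- 0; sx <- 0; sy <- 0
    for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc] == id) {
        area <- area + 1
        sx <- sx + (cc - 1); sy <- sy + (r - 1)
        for (ch in seq_len(dim(stack)[3])) sums[ch] <- sums[ch] + stack[r, cc, ch]
      }
    }
    c(id = id, x = sx / area, y = sy / area, area = area, setNames(sums, names))
  })
  do.call(rbind, out)
}

# Small tissue + both modalities, shared by several tests.
make_small_dataset <- function(seed = 42, n_cells = 800, n_types = 3,
                               n_genes = 60, n_markers = 9,
                               field = c(500, 500)) {
  ts <- generate_tissue(n_cells = n_cells, n_types = n_types,
                        n_genes = n_genes, n_markers = n_markers,
                        field_size = field, seed = seed)
  grid <- grid_config(n_channels_a = 9, n_channels_b = 9,
                      channel_width = 50, pitch = 50, origin = c(50, 50))
  list(tissue = ts, grid = grid,
       spots = render_spots(ts, grid, seed = seed + 1),
       codex = render_codex(ts, seed = seed + 2))
}

# Hand-built single-cell "tissue" for closed-form spot expectation checks.
make_tiny_tissue <- function(mu = c(0.3, 0.7)) {
  structure(list(
    cells = data.frame(cell_id = "c1", x = 50, y = 50, area = 80, type = "A",
                       stringsAsFactors = FALSE),
    n_types = 1L, types = "A", genes = c("gA", "gB"),
    markers = c("DAPI", "P01"),
    rna_signatures = matrix(mu, 1, 2, dimnames = list("A", c("gA", "gB"))),
    protein_signatures = matrix(c(1, 2), 1, 2,
                                dimnames = list("A", c("DAPI", "P01"))),
    marker_genes = c(P01 = "gA"),
    field_size = c(100, 100), seed = 1L), class = "tissue")
}

# Nearest-neighbor warp of a binary mask under a similarity transform, used
# to build ground-truth registration instances.
warp_mask <- function(mask, tf, nr, nc) {
  inv <- invert_transform(tf)
  qx <- rep(seq_len(nc) - 0.5, each = nr)
  qy <- rep(seq_len(nr) - 0.5, times = nc)
  p <- apply_transform(inv, cbind(qx, qy))
  ci <- floor(p[, 1]) + 1
  ri <- floor(p[, 2]) + 1
  ok <- ci >= 1 & ci <= ncol(mask) & ri >= 1 & ri <= nrow(mask)
  v <- logical(nr * nc)
  v[ok] <- mask[(ci[ok] - 1) * nrow(mask) + ri[ok]]
  matrix(v, nr, nc)
}
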