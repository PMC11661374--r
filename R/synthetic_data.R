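#' Barcoding grid geometry
#'
#' Describes the deterministic-barcoding spot lattice: two orthogonal sets of
#' microfluidic channels whose intersections form the barcoded spots. Channel
#' set A runs along y (indexing x positions), set B along x (indexing y
#' positions). Spot centers sit at
#' `(origin[1] + (a-1)*pitch, origin[2] + (b-1)*pitch)`.
#'
#' @param n_channels_a,n_channels_b Number of channels in each direction
#'   (default 50, the common device layout).
#' @param channel_width Channel width in pixels; the spot footprint is a
#'   `channel_width`-sided square. Must not exceed `pitch`.
#' @param pitch Center-to-center channel distance in pixels.
#' @param origin Center of spot (a=1, b=1), pixels.
#' @return A `grid_config` list.
#' @export
grid_config <- function(n_channels_a = 50, n_channels_b = 50,
                        channel_width = 25, pitch = 50, origin = c(50, 50)) {
  stopifnot(n_channels_a >= 1, n_channels_b >= 1,
            channel_width > 0, pitch > 0, length(origin) == 2L)
  if (channel_width > pitch)
    stop("channel_width must be <= pitch (spot footprints must not overlap)")
  structure(list(n_channels_a = as.integer(n_channels_a),
                 n_channels_b = as.integer(n_channels_b),
                 channel_width = as.numeric(channel_width),
                 pitch = as.numeric(pitch),
                 origin = as.numeric(origin)),
            class = "grid_config")
}

#' Simulator noise configuration
#'
#' @param rna_depth Expected RNA counts contributed per cell (UMI-like).
#' @param protein_cv Coefficient of variation of the multiplicative lognormal
#'   imaging noise on per-cell protein signal. The factor is mean-calibrated
#'   (expectation exactly 1) so that noiseless averages match the signatures.
#' @param background Additive nonnegative offset on raw protein signal.
#' @export
noise_config <- function(rna_depth = 1e4, protein_cv = 0.2, background = 0) {
  stopifnot(rna_depth >= 0, protein_cv >= 0, background >= 0)
  structure(list(rna_depth = rna_depth, protein_cv = protein_cv,
                 background = background),
            class = "noise_config")
}

#' Generate a synthetic tissue with known ground truth
#'
#' Lays out `n_cells` cells in a rectangular field, assigns each a cell type,
#' and draws type-specific RNA and protein signatures. RNA signatures are
#' expression proportions (rows sum to 1); the first `n_markers` genes are
#' designated marker genes, assigned round-robin to types and enriched by
#' `separation`, and each protein marker measures one of them, so the two
#' modalities are genuinely linked. A DAPI-like nuclear channel with a
#' type-independent signature is always included as the first protein marker.
#'
#' The simulator is a validation device: its distributional choices (gamma
#' signature draws, Gaussian niches, lognormal areas) are package choices, not
#' measurements of any particular tissue.
#'
#' @param n_cells,n_types,n_genes,n_markers Dimensions; all must be positive
#'   and `n_markers <= n_genes`.
#' @param field_size `(width, height)` of the imaging field in pixels.
#' @param spatial_structure `"niches"` places cells in Gaussian blobs with
#'   type-biased mixing (one niche per type); `"uniform"` scatters them.
#' @param separation Fold-enrichment of a type's marker genes; larger values
#'   make types easier to distinguish.
#' @param seed Integer; the whole tissue is reproducible bit-for-bit from it.
#' @return A `tissue` object: `cells` (cell_id, x, y, area, type),
#'   `rna_signatures` (types x genes, rows sum to 1), `protein_signatures`
#'   (types x markers, per unit area), `marker_genes` (marker -> gene map for
#'   the non-DAPI markers), plus dimensions and the seed.
#' @export
generate_tissue <- function(n_cells = 2000, n_types = 4, n_genes = 200,
                            n_markers = 20, field_size = c(1000, 1000),
                            spatial_structure = c("niches", "uniform"),
                            separation = 8, seed = 1) {
  if (n_cells < 1 || n_types < 1 || n_genes < 1 || n_markers < 1)
    stop("all dimensions must be positive")
  if (n_markers > n_genes) stop("n_markers must not exceed n_genes")
  stopifnot(length(field_size) == 2L, all(field_size > 0), separation >= 1)
  spatial_structure <- match.arg(spatial_structure)

  withr::with_seed(as.integer(seed), {
    types <- sprintf("T%d", seq_len(n_types))
    genes <- sprintf("g%03d", seq_len(n_genes))
    markers <- c("DAPI", sprintf("P%02d", seq_len(n_markers)))

    ## RNA signatures: sparse gamma baseline + round-robin enriched marker
    ## genes + a few extra private genes per type, rows normalized to sum 1.
    sig <- matrix(stats::rgamma(n_types * n_genes, shape = 0.3, rate = 1),
                  n_types, n_genes, dimnames = list(types, genes))
    owner <- rep_len(seq_len(n_types), n_markers)
    for (m in seq_len(n_markers))
      sig[owner[m], m] <- (sig[owner[m], m] + 0.5) * separation
    if (n_genes > n_markers) {
      extra <- max(1L, round(0.03 * n_genes))
      pool <- setdiff(seq_len(n_genes), seq_len(n_markers))
      for (k in seq_len(n_types)) {
        pick <- sample(pool, min(extra, length(pool)))
        sig[k, pick] <- (sig[k, pick] + 0.5) * separation
        pool <- setdiff(pool, pick)
      }
    }
    rna <- sig / rowSums(sig)

    ## Protein signatures per unit area: DAPI near-constant, the rest
    ## proportional to their linked marker gene.
    prot_core <- rna[, seq_len(n_markers), drop = FALSE]
    prot_core <- 5 * prot_core / max(prot_core)
    dapi <- matrix(stats::runif(n_types, 0.9, 1.1), ncol = 1)
    prot <- cbind(dapi, prot_core)
    dimnames(prot) <- list(types, markers)

    ## Cell placement and typing.
    if (spatial_structure == "uniform") {
      x <- stats::runif(n_cells, 0, field_size[1])
      y <- stats::runif(n_cells, 0, field_size[2])
      type <- sample(types, n_cells, replace = TRUE)
    } else {
      centers <- cbind(stats::runif(n_types, 0.22, 0.78) * field_size[1],
                       stats::runif(n_types, 0.22, 0.78) * field_size[2])
      sd_niche <- min(field_size) / 8
      niche <- sample(seq_len(n_types), n_cells, replace = TRUE)
      x <- stats::rnorm(n_cells, centers[niche, 1], sd_niche)
      y <- stats::rnorm(n_cells, centers[niche, 2], sd_niche)
      x <- pmin(pmax(x, 0), field_size[1] - 1e-6)
      y <- pmin(pmax(y, 0), field_size[2] - 1e-6)
      own <- 0.65
      type <- vapply(niche, function(k) {
        p <- rep((1 - own) / max(1, n_types - 1), n_types)
        p[k] <- if (n_types == 1) 1 else own
        sample(types, 1, prob = p)
      }, character(1))
    }
    area <- stats::rlnorm(n_cells, meanlog = log(80), sdlog = 0.25)

    cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                        x = x, y = y, area = area, type = type,
                        stringsAsFactors = FALSE)
    marker_genes <- stats::setNames(genes[seq_len(n_markers)],
                                    markers[-1])

    structure(list(cells = cells, n_types = n_types, types = types,
                   genes = genes, markers = markers,
                   rna_signatures = rna, protein_signatures = prot,
                   marker_genes = marker_genes,
                   field_size = as.numeric(field_size), seed = as.integer(seed)),
              class = "tissue")
  })
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("synthetic tissue: %d cells, %d types, %d genes, %d protein markers, field %g x %g px\n",
              nrow(x$cells), x$n_types, length(x$genes),
              length(x$markers) - 1L, x$field_size[1], x$field_size[2]))
  invisible(x)
}

#' Render the imaging (CODEX-like) modality of a tissue
#'
#' Produces a per-cell raw marker signal table following the model
#' `raw = area * signature[type, marker] * lognormal(1, cv) + background`.
#' The lognormal factor is calibrated so its expectation is exactly 1; with
#' `protein_cv = 0` and `background = 0` the raw signal equals
#' `area * signature` exactly.
#'
#' @param tissue A `tissue` from [generate_tissue()].
#' @param noise A [noise_config()].
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return A cell table: `cell_id, x, y, area, type` plus one raw-signal
#'   column per marker, with attribute `markers`.
#' @export
render_codex <- function(tissue, noise = noise_config(), seed = NULL) {
  stopifnot(inherits(tissue, "tissue"), inherits(noise, "noise_config"))
  draw <- function() {
    n <- nrow(tissue$cells)
    M <- length(tissue$markers)
    sig <- tissue$protein_signatures[tissue$cells$type, , drop = FALSE]
    sdlog <- sqrt(log(1 + noise$protein_cv^2))
    fac <- matrix(stats::rlnorm(n * M, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, M)
    raw <- tissue$cells$area * sig * fac + noise$background
    out <- cbind(tissue$cells, as.data.frame(raw))
    names(out)[-(1:5)] <- tissue$markers
    rownames(out) <- NULL
    as_cell_table(out, markers = tissue$markers)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Render the sequencing (spot-grid) modality of a tissue
#'
#' Cells are assigned to spot footprints by the same half-open square rule
#' used in [assign_cells_to_spots()]; each spot's expected expression is
#' `rna_depth * sum over its cells of rna_signatures[type, ]` and observed
#' counts are Poisson draws (or the expectation itself with
#' `noise_free = TRUE`). The true assignment and true per-spot type
#' proportions are recorded in the result's `truth` field for validation.
#'
#' @param tissue A `tissue`.
#' @param grid A [grid_config()]; must fit inside the tissue field.
#' @param noise A [noise_config()] (only `rna_depth` is used here).
#' @param noise_free If TRUE, return expected counts instead of Poisson draws.
#' @param seed Optional integer seed for the Poisson draw.
#' @return A `spot_matrix` object (see [read_spot_matrix()] for the layout)
#'   with a `truth` list: `assignment`, `beta` (types x spots), `n_cells`.
#' @export
render_spots <- function(tissue, grid = grid_config(), noise = noise_config(),
                         noise_free = FALSE, seed = NULL) {
  stopifnot(inherits(tissue, "tissue"), inherits(grid, "grid_config"))
  w <- grid$channel_width
  lo <- grid$origin - w / 2
  hi <- grid$origin + c(grid$n_channels_a - 1, grid$n_channels_b - 1) * grid$pitch + w / 2
  if (any(lo < 0) || hi[1] > tissue$field_size[1] || hi[2] > tissue$field_size[2])
    stop("grid does not fit inside the tissue field")

  spots <- expand.grid(a = seq_len(grid$n_channels_a),
                       b = seq_len(grid$n_channels_b))
  spots <- data.frame(spot_id = sprintf("s%03dx%03d", spots$a, spots$b),
                      a = spots$a, b = spots$b,
                      x = grid$origin[1] + (spots$a - 1) * grid$pitch,
                      y = grid$origin[2] + (spots$b - 1) * grid$pitch,
                      stringsAsFactors = FALSE)

  idx <- spot_index(tissue$cells$x, tissue$cells$y, grid)
  spot_of_cell <- ifelse(is.na(idx), NA_character_, spots$spot_id[idx])
  assignment <- data.frame(cell_id = tissue$cells$cell_id,
                           spot_id = spot_of_cell, stringsAsFactors = FALSE)

  K <- tissue$n_types
  S <- nrow(spots)
  counts_kt <- matrix(0, S, K, dimnames = list(spots$spot_id, tissue$types))
  keep <- !is.na(idx)
  if (any(keep)) {
    tab <- table(factor(spots$spot_id[idx[keep]], levels = spots$spot_id),
                 factor(tissue$cells$type[keep], levels = tissue$types))
    counts_kt[] <- as.numeric(tab)
  }
  n_cells <- rowSums(counts_kt)
  beta <- t(counts_kt / pmax(n_cells, 1))
  beta[, n_cells == 0] <- 0

  lambda <- noise$rna_depth * (counts_kt %*% tissue$rna_signatures)
  draw <- function() {
    if (noise_free) lambda
    else matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda),
                dimnames = dimnames(lambda))
  }
  x <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  counts <- Matrix::Matrix(x, sparse = TRUE,
                           dimnames = list(spots$spot_id, tissue$genes))

  new_spot_matrix(counts = counts, spots = spots, genes = tissue$genes,
                  pixel_size = grid$channel_width, pitch = grid$pitch,
                  origin = grid$origin,
                  truth = list(assignment = assignment, beta = beta,
                               n_cells = n_cells))
}

#' Apply a known similarity perturbation to cell coordinates
#'
#' Creates the coordinate mismatch between the imaging and sequencing frames
#' that registration must undo, and returns the exact transform applied so
#' recovery can be scored against ground truth.
#'
#' @param cells A cell table (data frame with `x`, `y`).
#' @param scale Positive scale factor.
#' @param rotation_deg Rotation in degrees (counter-clockwise, y-up).
#' @param translation Length-2 translation in pixels.
#' @param center Point about which scale and rotation act (default origin).
#' @return `list(cells = transformed table, transform = similarity_transform)`
#'   where `transform` is in global form `T(p) = s R p + t`.
#' @export
perturb_coordinates <- function(cells, scale = 1, rotation_deg = 0,
                                translation = c(0, 0), center = c(0, 0)) {
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be > 0")
  stopifnot(length(translation) == 2L, length(center) == 2L)
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_global <- as.numeric(center + translation - scale * R %*% center)
  tf <- similarity_transform(scale = scale, rotation = rotation_deg,
                             translation = t_global)
  list(cells = apply_transform(tf, cells), transform = tf)
}

#' Rasterize point positions into a count image
#'
#' Bins points on a square raster: pixel `(row r, col c)` covers
#' `x in [(c-1)*resolution, c*resolution)`, `y` likewise with rows. Points
#' outside the field are dropped. Used to build the tissue images that mask
#' detection and registration consume; mask-frame coordinates are original
#' coordinates divided by `resolution`.
#'
#' @param points Matrix or data frame with `x`, `y`.
#' @param field_size `(width, height)` in original pixels.
#' @param resolution Original pixels per raster pixel (default 1).
#' @return Numeric matrix (rows = y, cols = x) of point counts, with
#'   attribute `resolution`.
#' @export
rasterize_points <- function(points, field_size, resolution = 1) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  stopifnot(ncol(points) == 2L, length(field_size) == 2L, resolution > 0)
  nc <- ceiling(field_size[1] / resolution)
  nr <- ceiling(field_size[2] / resolution)
  col <- floor(points[, 1] / resolution) + 1
  row <- floor(points[, 2] / resolution) + 1
  keep <- col >= 1 & col <= nc & row >= 1 & row <= nr & is.finite(col) & is.finite(row)
  img <- matrix(0, nr, nc)
  if (any(keep)) {
    lin <- (col[keep] - 1) * nr + row[keep]
    tab <- tabulate(lin, nbins = nr * nc)
    img[] <- tab
  }
  attr(img, "resolution") <- resolution
  img
}

#' Simulate reference expression profiles from a tissue's signatures
#'
#' Draws single-cell-like RNA profiles (Poisson counts at a per-profile depth)
#' from the tissue's ground-truth type signatures, to serve as the annotated
#' scRNA-seq reference in annotation and signature-aggregation stages.
#'
#' @param tissue A `tissue`.
#' @param n_profiles Number of reference cells.
#' @param depth Expected total counts per profile.
#' @param seed Optional seed.
#' @return `list(counts = profiles x genes integer matrix, labels = type per
#'   profile)`.
#' @export
render_reference <- function(tissue, n_profiles = 2000, depth = 5000, seed = NULL) {
  stopifnot(inherits(tissue, "tissue"), n_profiles >= 1, depth > 0)
  draw <- function() {
    k <- sample(seq_len(tissue$n_types), n_profiles, replace = TRUE)
    lam <- depth * tissue$rna_signatures[k, , drop = FALSE]
    counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    dimnames(counts) <- list(sprintf("r%05d", seq_len(n_profiles)), tissue$genes)
    list(counts = counts, labels = stats::setNames(tissue$types[k], rownames(counts)))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
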