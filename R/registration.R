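#' Detect the tissue foreground mask of an image
#'
#' Standard tissue-boundary pipeline for a single-channel image: Gaussian
#' smoothing, Otsu thresholding of the smoothed image, binary hole filling,
#' then retention of the largest 8-connected foreground component so that
#' debris and satellite fragments do not distort registration.
#'
#' @param image Nonnegative numeric matrix (rows = y, cols = x).
#' @param gaussian_sigma Smoothing sigma in pixels (default 2).
#' @return Logical matrix of the same size; attribute `threshold` records the
#'   Otsu cut on the rescaled smoothed image.
#' @export
detect_tissue_mask <- function(image, gaussian_sigma = 2) {
  image <- as.matrix(image)
  if (length(dim(image)) != 2L || !is.numeric(image))
    stop("'image' must be a 2-D numeric matrix")
  if (any(image < 0)) stop("'image' must be nonnegative")
  rng <- range(image)
  if (rng[1] == rng[2])
    stop("constant image: Otsu threshold undefined, no tissue detectable")
  img <- (image - rng[1]) / (rng[2] - rng[1])
  sm <- EBImage::gblur(img, sigma = gaussian_sigma)
  sm <- pmin(pmax(sm, 0), 1)
  th <- EBImage::otsu(sm, range = c(0, 1))
  bin <- sm > th
  if (!any(bin)) stop("no foreground after thresholding")
  filled <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0
  filled <- matrix(as.logical(filled), nrow(image), ncol(image))
  mask <- largest_component8(filled)
  attr(mask, "threshold") <- th
  mask
}

## Largest 8-connected foreground component, via a graph over foreground
## pixels (EBImage's labeling is 4-connected, which splits diagonal bridges).
largest_component8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- id_of[nb] > 0L
    edges[[length(edges) + 1L]] <-
      cbind(id_of[idx[ok][has]], id_of[nb[has]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(e) && nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  out <- matrix(FALSE, nr, nc)
  out[idx[comp$membership == big]] <- TRUE
  out
}

## Foreground centroid (x, y in pixel-center coordinates), area and principal
## axis angle (degrees) of a binary mask.
mask_moments <- function(mask) {
  idx <- which(mask)
  x <- (idx - 1L) %/% nrow(mask) + 0.5
  y <- (idx - 1L) %% nrow(mask) + 0.5
  cx <- mean(x); cy <- mean(y)
  cov <- stats::cov(cbind(x - cx, y - cy)) * (length(x) - 1) / length(x)
  ev <- eigen(cov, symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  list(centroid = c(cx, cy), area = length(idx), angle = ang,
       anisotropy = ev$values[1] / max(ev$values[2], .Machine$double.eps))
}

#' Estimate the similarity transform aligning one tissue mask onto another
#'
#' Finds the transform `T` minimizing the squared mismatch
#' `sum((T(moving) - fixed)^2)` over the fixed image grid, with
#' nearest-neighbor resampling of the moving mask and out-of-bounds pixels
#' treated as background. The search is moment-initialized (centroid
#' alignment, scale from the foreground area ratio, orientation from the
#' principal axes) and refined by Nelder-Mead simplex over
#' `(log scale, angle, tx, ty)`, with rotation expressed about the moving
#' centroid so rotation and translation stay decoupled. Because the principal
#' axis is only defined up to 180 degrees, both orientations are tried and
#' the lower-loss fit kept (ties broken toward the smaller absolute angle).
#'
#' @param mask_moving,mask_fixed Logical (or 0/1) matrices from
#'   [detect_tissue_mask()] or equivalent.
#' @param max_iter Simplex iteration cap per start (default 500).
#' @param tol Relative convergence tolerance on the loss (default 1e-4).
#' @return `list(transform = similarity_transform in global form
#'   T(p) = s R p + t, loss = final sum of squared mismatch, converged =
#'   logical, initial_loss = loss at the moment initialization)`. The
#'   returned loss never exceeds `initial_loss`. A non-converged refinement
#'   warns and returns the best transform found.
#' @export
estimate_similarity_transform <- function(mask_moving, mask_fixed,
                                          max_iter = 500, tol = 1e-4) {
  Mv <- as.logical(mask_moving); dim(Mv) <- dim(mask_moving)
  Fx <- as.logical(mask_fixed); dim(Fx) <- dim(mask_fixed)
  if (!any(Mv) || !any(Fx)) stop("both masks must be nonempty")
  mm <- mask_moments(Mv); mf <- mask_moments(Fx)

  nrF <- nrow(Fx); ncF <- ncol(Fx)
  nrM <- nrow(Mv); ncM <- ncol(Mv)
  ## Restrict the loss to a margin-dilated bounding window of the fixed
  ## foreground: pixels far outside it are background in both images for any
  ## near-optimal transform and contribute nothing to the squared mismatch.
  fidx <- which(Fx)
  frow <- (fidx - 1L) %% nrF + 1L
  fcol <- (fidx - 1L) %/% nrF + 1L
  margin <- ceiling(0.25 * max(diff(range(frow)), diff(range(fcol))) + 10)
  rwin <- max(1L, min(frow) - margin):min(nrF, max(frow) + margin)
  cwin <- max(1L, min(fcol) - margin):min(ncF, max(fcol) + margin)
  qx <- rep(cwin - 0.5, each = length(rwin))  # fixed-grid pixel centers
  qy <- rep(rwin - 0.5, times = length(cwin))
  fvec <- as.numeric(Fx[rwin, cwin])
  mvnum <- Mv * 1

  ## T(p) = s R (p - cM) + cF + t ; loss samples moving at T^{-1}(q).
  loss_fun <- function(par) {
    s <- exp(par[1]); th <- par[2] * pi / 180
    ct <- cos(th); st <- sin(th)
    dx <- qx - mf$centroid[1] - par[3]
    dy <- qy - mf$centroid[2] - par[4]
    px <- (ct * dx + st * dy) / s + mm$centroid[1]
    py <- (-st * dx + ct * dy) / s + mm$centroid[2]
    ci <- floor(px) + 1; ri <- floor(py) + 1
    ok <- ci >= 1 & ci <= ncM & ri >= 1 & ri <= nrM
    samp <- numeric(length(qx))
    samp[ok] <- mvnum[(ci[ok] - 1) * nrM + ri[ok]]
    sum((samp - fvec)^2)
  }

  s0 <- sqrt(mf$area / mm$area)
  th0 <- mf$angle - mm$angle
  ## The principal axis is 180-degree ambiguous always, and close to
  ## undefined for near-isotropic masks. A coarse angular scan (centroids
  ## aligned, scale from areas) locates the rotation basins cheaply; the
  ## simplex then starts from the axis candidates plus the best scan angles.
  scan <- seq(-180, 175, by = 5)
  scan_loss <- vapply(scan, function(th) loss_fun(c(log(s0), th, 0, 0)),
                      numeric(1))
  th_cands <- c(th0, th0 + 180, scan[order(scan_loss)][1:3])
  th_cands <- ((th_cands + 180) %% 360) - 180
  keep <- rep(TRUE, length(th_cands))
  for (i in seq_along(th_cands)[-1]) {
    d <- abs(((th_cands[seq_len(i - 1)][keep[seq_len(i - 1)]] -
                 th_cands[i] + 180) %% 360) - 180)
    if (any(d < 10)) keep[i] <- FALSE
  }
  th_cands <- th_cands[keep]
  fits <- lapply(th_cands, function(th0) {
    par0 <- c(log(s0), th0, 0, 0)
    init_loss <- loss_fun(par0)
    opt <- stats::optim(par0, loss_fun, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol))
    if (opt$value > init_loss) {           # refinement must never worsen
      opt$par <- par0; opt$value <- init_loss
    }
    list(par = opt$par, loss = opt$value, init_loss = init_loss,
         converged = opt$convergence == 0)
  })
  losses <- vapply(fits, `[[`, numeric(1), "loss")
  best <- which(losses <= min(losses) + 1e-12)
  if (length(best) > 1)
    best <- best[which.min(abs(((vapply(fits[best], function(f) f$par[2],
                                        numeric(1)) + 180) %% 360) - 180))]
  fit <- fits[[best]]

  s <- exp(fit$par[1])
  th <- ((fit$par[2] + 180) %% 360) - 180
  thr <- th * pi / 180
  R <- matrix(c(cos(thr), sin(thr), -sin(thr), cos(thr)), 2, 2)
  t_global <- as.numeric(mf$centroid + fit$par[3:4] - s * R %*% mm$centroid)
  if (!fit$converged)
    warning("similarity refinement hit the iteration cap; returning best transform found")
  list(transform = similarity_transform(scale = s, rotation = th,
                                        translation = t_global),
       loss = fit$loss, converged = fit$converged,
       initial_loss = fit$init_loss)
}

#' Least-squares affine transform from landmark pairs
#'
#' Estimates the affine transform minimizing the summed squared distance
#' between transformed source points and their paired destination points.
#' With at least three non-collinear pairs the normal equations have a unique
#' solution; on a consistent (noiseless) system the fit is exact.
#'
#' @param points_src,points_dst 2-column matrices or data frames of paired
#'   landmark coordinates (same row order).
#' @return An `affine_transform` with attribute `residuals`, the per-pair
#'   Euclidean residual distances.
#' @export
estimate_affine_from_landmarks <- function(points_src, points_dst) {
  src <- as.matrix(points_src); dst <- as.matrix(points_dst)
  if (is.data.frame(points_src)) src <- cbind(points_src$x, points_src$y)
  if (is.data.frame(points_dst)) dst <- cbind(points_dst$x, points_dst$y)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L)
  if (nrow(src) != nrow(dst)) stop("point sets must pair up row by row")
  if (nrow(src) < 3L) stop("at least 3 landmark pairs are required")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stop("source landmarks are collinear; affine transform is not identifiable")
  coef <- qr.solve(X, dst)                  # 3 x 2: rows = (x, y, 1) weights
  A <- t(coef[1:2, , drop = FALSE])
  tvec <- as.numeric(coef[3, ])
  tf <- affine_transform(A, tvec)
  pred <- apply_transform(tf, src)
  attr(tf, "residuals") <- sqrt(rowSums((pred - dst)^2))
  tf
}

#' Refine a similarity transform on intensity images
#'
#' Polishes a mask-derived similarity estimate by minimizing the squared
#' error between the transformed moving image and the fixed image, allowing
#' an optimal linear intensity map between the two (equivalent to maximizing
#' normalized cross-correlation), over the fixed-image tissue region. Both
#' images are Gaussian-smoothed to a common density scale first; when the
#' two modalities render tissue density differently (cell rasters vs
#' spot-count blocks), smoothing at roughly the spot pitch makes the
#' objective well-posed and recovers sub-pixel alignment that binary masks
#' cannot.
#'
#' @param image_moving,image_fixed Nonnegative intensity images.
#' @param init A `similarity_transform` starting point, in the pixel frame
#'   of the two images (e.g. from [estimate_similarity_transform()]).
#' @param smooth_sigma Gaussian sigma (pixels) applied to both images before
#'   matching.
#' @param roi Optional logical matrix (fixed frame) of pixels to score;
#'   default is the fixed tissue support (smoothed intensity above 1% of
#'   max).
#' @param max_iter,tol Simplex iteration cap and relative tolerance.
#' @return `list(transform, loss, converged)`; `loss` is `1 - r^2` of the
#'   final intensity correlation.
#' @export
refine_similarity_intensity <- function(image_moving, image_fixed, init,
                                        smooth_sigma, roi = NULL,
                                        max_iter = 800, tol = 1e-8) {
  stopifnot(inherits(init, "similarity_transform"))
  Msm <- as.matrix(EBImage::gblur(image_moving / max(image_moving), smooth_sigma))
  Fsm <- as.matrix(EBImage::gblur(image_fixed / max(image_fixed), smooth_sigma))
  nrF <- nrow(Fsm); ncF <- ncol(Fsm); nrM <- nrow(Msm); ncM <- ncol(Msm)
  qx <- rep(seq_len(ncF) - 0.5, each = nrF)
  qy <- rep(seq_len(nrF) - 0.5, times = ncF)
  fvec <- as.numeric(Fsm)
  if (is.null(roi)) roi <- fvec > 0.01 * max(fvec) else roi <- as.logical(roi)
  if (sum(roi) < 16) stop("refinement region is (almost) empty")
  b <- fvec[roi]

  ## bilinear sampling of the smoothed moving image: sub-pixel sensitivity
  ## matters because the raster may be several original pixels per cell
  loss_fun <- function(par) {
    s <- exp(par[1]); th <- par[2] * pi / 180
    ct <- cos(th); st <- sin(th)
    dx <- qx - par[3]; dy <- qy - par[4]
    px <- (ct * dx + st * dy) / s - 0.5
    py <- (-st * dx + ct * dy) / s - 0.5
    c0 <- floor(px); r0 <- floor(py)
    fx <- px - c0; fy <- py - r0
    ok <- c0 >= 0 & c0 <= ncM - 2 & r0 >= 0 & r0 <= nrM - 2
    samp <- numeric(length(qx))
    i00 <- c0[ok] * nrM + r0[ok] + 1
    samp[ok] <- (1 - fx[ok]) * ((1 - fy[ok]) * Msm[i00] + fy[ok] * Msm[i00 + 1]) +
      fx[ok] * ((1 - fy[ok]) * Msm[i00 + nrM] + fy[ok] * Msm[i00 + nrM + 1])
    a <- samp[roi]
    r <- suppressWarnings(stats::cor(a, b))
    if (!is.finite(r)) return(1)
    1 - r^2
  }
  par <- c(log(init$scale), init$rotation, init$translation)
  best <- loss_fun(par)
  converged <- TRUE
  ## iterated simplex restarts: a fresh simplex escapes the degenerate ones
  ## Nelder-Mead collapses into on these flat correlation surfaces
  for (round in 1:6) {
    opt <- stats::optim(par, loss_fun, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol))
    converged <- opt$convergence == 0
    if (opt$value >= best * (1 - 1e-6) && round > 1) { break }
    if (opt$value < best) { best <- opt$value; par <- opt$par }
  }
  init_loss <- loss_fun(c(log(init$scale), init$rotation, init$translation))
  if (best > init_loss) par <- c(log(init$scale), init$rotation, init$translation)
  list(transform = similarity_transform(exp(par[1]),
                                        ((par[2] + 180) %% 360) - 180,
                                        par[3:4]),
       loss = min(best, init_loss), converged = converged)
}

#' Polish a similarity transform against observed spot totals
#'
#' Final registration stage for the cell-to-spot setting: maps cell
#' centroids through the candidate transform, soft-assigns each cell to the
#' barcoding grid (linear ramps of width `boundary_softness` pixels at the
#' footprint boundaries keep the objective smooth), and maximizes the
#' correlation between predicted per-spot cell counts and the observed
#' per-spot total counts. This uses the grid's own geometry rather than a
#' rasterized image, so it is free of raster quantization and lattice
#' artifacts and typically reaches ~1 px accuracy where image-based
#' matching plateaus.
#'
#' @param cells Cell table (or 2-column matrix) in the moving frame.
#' @param spot_matrix A `spot_matrix` with observed counts.
#' @param init Starting `similarity_transform` mapping the moving frame into
#'   the spot frame (e.g. the image-based estimate).
#' @param boundary_softness Ramp width in pixels at spot boundaries
#'   (default 10).
#' @param max_iter Simplex iteration cap per restart.
#' @return `list(transform, loss, converged)`; `loss` is `1 - r^2` between
#'   predicted and observed spot totals.
#' @export
refine_similarity_spot_counts <- function(cells, spot_matrix, init,
                                          boundary_softness = 10,
                                          max_iter = 600) {
  stopifnot(inherits(spot_matrix, "spot_matrix"),
            inherits(init, "similarity_transform"))
  p <- if (is.data.frame(cells)) cbind(cells$x, cells$y) else as.matrix(cells)
  tot <- Matrix::rowSums(spot_matrix$counts)
  sp <- spot_matrix$spots
  g <- grid_of(spot_matrix)
  na <- g$n_channels_a; nb <- g$n_channels_b
  obs <- numeric(na * nb)
  obs[(sp$b - 1) * na + sp$a] <- tot
  d <- boundary_softness / g$pitch

  loss_fun <- function(par) {
    s <- exp(par[1]); th <- par[2] * pi / 180
    ct <- cos(th); st <- sin(th)
    X <- s * (ct * p[, 1] - st * p[, 2]) + par[3]
    Y <- s * (st * p[, 1] + ct * p[, 2]) + par[4]
    ua <- (X - g$origin[1]) / g$pitch + 1
    ub <- (Y - g$origin[2]) / g$pitch + 1
    ia <- round(ua); ib <- round(ub)
    wa <- pmin(1, pmax(0, (0.5 - abs(ua - ia)) / d + 0.5))
    wb <- pmin(1, pmax(0, (0.5 - abs(ub - ib)) / d + 0.5))
    ia2 <- ia + sign(ua - ia); ib2 <- ib + sign(ub - ib)
    acc <- function(i, j, w) {
      ok <- i >= 1 & i <= na & j >= 1 & j <= nb & w > 0
      v <- numeric(na * nb)
      if (any(ok)) {
        tv <- rowsum(w[ok], (j[ok] - 1) * na + i[ok])
        v[as.integer(rownames(tv))] <- tv
      }
      v
    }
    pred <- acc(ia, ib, wa * wb) + acc(ia2, ib, (1 - wa) * wb) +
      acc(ia, ib2, wa * (1 - wb)) + acc(ia2, ib2, (1 - wa) * (1 - wb))
    keep <- obs > 0 | pred > 1e-9
    if (sum(keep) < 8) return(1)
    r <- suppressWarnings(stats::cor(pred[keep], obs[keep]))
    if (!is.finite(r)) return(1)
    1 - r^2
  }

  par <- c(log(init$scale), init$rotation, init$translation)
  init_loss <- loss_fun(par)
  best <- init_loss
  converged <- TRUE
  for (round in 1:6) {
    opt <- stats::optim(par, loss_fun, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-9))
    converged <- opt$convergence == 0
    if (opt$value < best) { best <- opt$value; par <- opt$par }
    else if (round > 1) break
  }
  if (best > init_loss) par <- c(log(init$scale), init$rotation, init$translation)
  list(transform = similarity_transform(exp(par[1]),
                                        ((par[2] + 180) %% 360) - 180,
                                        par[3:4]),
       loss = min(best, init_loss), converged = converged)
}
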