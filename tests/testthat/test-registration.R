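disk_image <- function(n = 80, cx = 40, cy = 40, r = 22, value = 100) {
  img <- matrix(0, n, n)
  for (row in 1:n) for (col in 1:n)
    if ((col - cx)^2 + (row - cy)^2 <= r^2) img[row, col] <- value
  img
}

test_that("mask detection recovers a disk, fills holes and keeps the largest blob", {
  img <- disk_image()
  mask <- detect_tissue_mask(img, gaussian_sigma = 2)
  truth <- disk_image(value = 1) > 0
  # agreement up to a thin smoothing band around the boundary
  band <- disk_image(r = 25, value = 1) > 0 & !(disk_image(r = 19, value = 1) > 0)
  expect_true(all(mask[!band] == truth[!band]))

  holed <- img
  holed[35:45, 35:45] <- 0
  mask2 <- detect_tissue_mask(holed, gaussian_sigma = 1)
  expect_true(all(mask2[38:42, 38:42]))  # hole filled

  two <- matrix(0, 60, 60)
  two[10:35, 10:35] <- 100   # ~676 px
  two[50:56, 50:56] <- 100   # ~49 px
  mask3 <- detect_tissue_mask(two, gaussian_sigma = 1)
  expect_true(any(mask3[15:30, 15:30]))
  expect_false(any(mask3[48:58, 48:58]))

  expect_error(detect_tissue_mask(matrix(5, 10, 10)), "constant")
})

test_that("similarity estimation recovers identity and known perturbations", {
  ts <- generate_tissue(n_cells = 3000, n_types = 3, n_genes = 30, n_markers = 6,
                        field_size = c(400, 400), seed = 51)
  img <- rasterize_points(ts$cells, c(400, 400), resolution = 2)
  mask <- detect_tissue_mask(img, 2)

  fit_id <- estimate_similarity_transform(mask, mask)
  expect_lt(abs(fit_id$transform$scale - 1), 0.02)
  expect_lt(abs(fit_id$transform$rotation), 1)
  ctr <- colMeans(which(mask, arr.ind = TRUE))
  shift <- sqrt(sum((apply_transform(fit_id$transform, rbind(rev(ctr))) - rev(ctr))^2))
  expect_lt(shift, 1)
  expect_lte(fit_id$loss, fit_id$initial_loss)

  # known similarity transform of the mask, recovered within (2%, 1 deg, 2 px)
  cm <- rbind(rev(ctr))
  truth <- perturb_coordinates(data.frame(x = 0, y = 0), scale = 1.15,
                               rotation_deg = 20, translation = c(30, -12),
                               center = as.numeric(cm))$transform
  mask2 <- warp_mask(mask, truth, 300, 300)
  fit <- estimate_similarity_transform(mask, mask2)
  est <- fit$transform
  expect_lt(abs(est$scale / 1.15 - 1), 0.02)
  expect_lt(abs(est$rotation - 20), 1)
  expect_lt(sqrt(sum((apply_transform(est, cm) -
                        apply_transform(truth, cm))^2)), 2)

  # pure translation of the same asymmetric blob, recovered within 1 px
  truth2 <- similarity_transform(translation = c(10, -5))
  fit2 <- estimate_similarity_transform(mask, warp_mask(mask, truth2, 250, 250))
  expect_lt(sqrt(sum((apply_transform(fit2$transform, cm) -
                        apply_transform(truth2, cm))^2)), 1)
})

test_that("landmark affine is exact on consistent pairs and localizes noise", {
  src <- cbind(c(0, 10, 0), c(0, 0, 10))
  tf_id <- estimate_affine_from_landmarks(src, src)
  expect_equal(tf_id$A, diag(2), tolerance = 1e-12)
  expect_lt(max(attr(tf_id, "residuals")), 1e-9)

  A <- matrix(c(1.1, -0.02, 0.05, 0.95), 2, 2)
  tvec <- c(12, -7)
  set.seed(52)
  src6 <- matrix(runif(12, 0, 100), ncol = 2)
  dst6 <- src6 %*% t(A) + rep(tvec, each = 6)
  fit <- estimate_affine_from_landmarks(src6, dst6)
  expect_equal(fit$A, A, tolerance = 1e-9)
  expect_equal(fit$translation, tvec, tolerance = 1e-9)
  expect_lt(max(attr(fit, "residuals")), 1e-9)

  # adding pairs consistent with the same affine leaves the estimate unchanged
  more <- matrix(runif(8, 0, 100), ncol = 2)
  fit2 <- estimate_affine_from_landmarks(rbind(src6, more),
                                         rbind(dst6, more %*% t(A) +
                                                 rep(tvec, each = 4)))
  expect_equal(fit2$A, fit$A, tolerance = 1e-9)

  # a perturbed pair concentrates the residual on itself
  dst_bad <- dst6
  dst_bad[4, ] <- dst_bad[4, ] + c(5, 5)
  fit3 <- estimate_affine_from_landmarks(src6, dst_bad)
  res <- attr(fit3, "residuals")
  expect_equal(which.max(res), 4L)
  expect_gt(res[4], max(res[-4]))

  expect_error(estimate_affine_from_landmarks(src[1:2, ], src[1:2, ]), "3")
  coll <- cbind(1:4, 2 * (1:4))
  expect_error(estimate_affine_from_landmarks(coll, coll), "collinear")
})

test_that("intensity refinement never worsens the starting loss", {
  ts <- generate_tissue(n_cells = 2500, n_types = 3, n_genes = 30, n_markers = 6,
                        field_size = c(400, 400), seed = 53)
  img <- rasterize_points(ts$cells, c(400, 400), resolution = 2)
  pp <- perturb_coordinates(ts$cells, scale = 1.05, rotation_deg = 5,
                            translation = c(8, -4), center = c(200, 200))
  img2 <- rasterize_points(pp$cells, c(500, 500), resolution = 2)
  init <- estimate_similarity_transform(detect_tissue_mask(img, 2),
                                        detect_tissue_mask(img2, 2))
  ref <- refine_similarity_intensity(img, img2, init$transform, smooth_sigma = 8)
  expect_lte(ref$loss, 1)
  est <- rescale_transform(ref$transform, 2)
  cmov <- rbind(colMeans(cbind(ts$cells$x, ts$cells$y)))
  expect_lt(sqrt(sum((apply_transform(est, cmov) -
                        apply_transform(pp$transform, cmov))^2)), 2)
})

test_that("spot-count polish recovers a small residual misalignment", {
  d <- make_small_dataset(seed = 54, n_cells = 3000)
  truth <- invert_transform(
    perturb_coordinates(d$tissue$cells, scale = 1.02, rotation_deg = 2,
                        translation = c(6, -4), center = c(250, 250))$transform)
  cells_moving <- perturb_coordinates(d$tissue$cells, scale = 1.02,
                                      rotation_deg = 2, translation = c(6, -4),
                                      center = c(250, 250))$cells
  # start a few pixels off the true inverse
  init <- similarity_transform(truth$scale * 1.01, truth$rotation + 1,
                               truth$translation + c(4, -3))
  rf <- refine_similarity_spot_counts(cells_moving, d$spots, init)
  pts <- cbind(cells_moving$x, cells_moving$y)
  disp <- mean(sqrt(rowSums((apply_transform(rf$transform, pts) -
                               apply_transform(truth, pts))^2)))
  expect_lt(disp, 1.5)
  expect_lte(rf$loss, 1)
})
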