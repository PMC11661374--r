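#' Planar similarity transform
#'
#' A similarity transform is a rotation plus uniform scaling plus translation,
#' `T(p) = s * R(theta) * p + t`, with four free parameters in 2-D. The
#' rotation convention is mathematical: counter-clockwise positive with the y
#' axis increasing upward in the abstract coordinate plane. When coordinates
#' come from image arrays (y = row index, increasing downward) the caller is
#' responsible for the sign flip; all functions in this package keep a single
#' consistent (x, y) plane so the convention only matters when interpreting
#' the angle.
#'
#' @param scale Positive uniform scale factor.
#' @param rotation Rotation angle in degrees, counter-clockwise.
#' @param translation Numeric length-2, `(tx, ty)` in the same units as the
#'   points the transform will be applied to (pixels throughout this package).
#' @return An object of class `similarity_transform`.
#' @examples
#' tf <- similarity_transform(scale = 2, rotation = 0, translation = c(1, 1))
#' apply_transform(tf, cbind(3, 4)) # (7, 9)
#' @export
similarity_transform <- function(scale = 1, rotation = 0, translation = c(0, 0)) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale <= 0) stop("'scale' must be > 0")
  stopifnot(length(rotation) == 1L, is.finite(rotation), length(translation) == 2L)
  structure(
    list(scale = as.numeric(scale), rotation = as.numeric(rotation),
         translation = as.numeric(translation)),
    class = "similarity_transform"
  )
}

#' General planar affine transform
#'
#' `T(p) = A %*% p + t` with an arbitrary 2x2 linear part.
#'
#' @param A 2x2 numeric matrix (linear part).
#' @param translation Numeric length-2 translation.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A, translation = c(0, 0)) {
  A <- as.matrix(A)
  stopifnot(identical(dim(A), c(2L, 2L)), all(is.finite(A)), length(translation) == 2L)
  structure(list(A = A, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' Homogeneous 3x3 matrix form of a transform
#'
#' Parameter form and matrix form round-trip within 1e-9.
#'
#' @param transform A `similarity_transform` or `affine_transform`.
#' @return A 3x3 numeric matrix acting on column vectors `(x, y, 1)`.
#' @export
transform_matrix <- function(transform) {
  A <- linear_part(transform)
  t <- transform$translation
  rbind(cbind(A, t), c(0, 0, 1))
}

linear_part <- function(transform) {
  if (inherits(transform, "similarity_transform")) {
    th <- transform$rotation * pi / 180
    transform$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else if (inherits(transform, "affine_transform")) {
    transform$A
  } else {
    stop("not a transform object")
  }
}

#' Build a similarity transform from a 3x3 or 2x3 matrix
#'
#' Fails if the linear part is not (numerically) a rotation times a positive
#' scale.
#'
#' @param m Matrix with linear part in `m[1:2, 1:2]` and translation in
#'   `m[1:2, 3]`.
#' @export
similarity_from_matrix <- function(m) {
  A <- m[1:2, 1:2]
  s <- sqrt(abs(det(A)))
  if (s <= 0) stop("singular linear part")
  R <- A / s
  if (max(abs(crossprod(R) - diag(2))) > 1e-6 || det(R) < 0)
    stop("linear part is not a rotation times positive scale")
  similarity_transform(scale = s,
                       rotation = atan2(R[2, 1], R[1, 1]) * 180 / pi,
                       translation = m[1:2, 3])
}

#' Apply a transform to points
#'
#' @param transform A `similarity_transform` or `affine_transform`.
#' @param points A 2-column matrix, or a data frame with `x` and `y` columns
#'   (other columns pass through untouched).
#' @return Points in the same container shape as the input.
#' @export
apply_transform <- function(transform, points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    xy <- apply_transform(transform, cbind(points$x, points$y))
    points$x <- xy[, 1]
    points$y <- xy[, 2]
    return(points)
  }
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2L)
  out <- p %*% t(linear_part(transform))
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  dimnames(out) <- dimnames(p)
  out
}

#' Invert a transform
#'
#' @param transform A `similarity_transform` or `affine_transform` with a
#'   nonsingular linear part.
#' @return The inverse transform of the same class; round-trip error is at
#'   machine precision (well under 1e-9).
#' @export
invert_transform <- function(transform) {
  if (inherits(transform, "similarity_transform")) {
    th <- -transform$rotation * pi / 180
    s <- 1 / transform$scale
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    similarity_transform(scale = s, rotation = -transform$rotation,
                         translation = as.numeric(-s * R %*% transform$translation))
  } else if (inherits(transform, "affine_transform")) {
    d <- det(transform$A)
    if (abs(d) < .Machine$double.eps * 100)
      stop("affine transform is singular; no inverse")
    Ai <- solve(transform$A)
    affine_transform(Ai, as.numeric(-Ai %*% transform$translation))
  } else stop("not a transform object")
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#' The result is a `similarity_transform` when both arguments are, and an
#' `affine_transform` otherwise.
#' @param second,first Transform objects.
#' @export
compose_transforms <- function(second, first) {
  A <- linear_part(second) %*% linear_part(first)
  t <- as.numeric(linear_part(second) %*% first$translation) + second$translation
  if (inherits(second, "similarity_transform") && inherits(first, "similarity_transform")) {
    similarity_transform(scale = second$scale * first$scale,
                         rotation = second$rotation + first$rotation,
                         translation = t)
  } else {
    affine_transform(A, t)
  }
}

#' Rescale a transform between raster resolutions
#'
#' A transform estimated on masks rasterized at `factor` original pixels per
#' mask pixel acts on down-scaled coordinates; the equivalent transform on
#' original coordinates keeps scale and rotation and multiplies the
#' translation by `factor`.
#'
#' @param transform A `similarity_transform`.
#' @param factor Positive resolution factor.
#' @export
rescale_transform <- function(transform, factor) {
  stopifnot(inherits(transform, "similarity_transform"), factor > 0)
  similarity_transform(scale = transform$scale, rotation = transform$rotation,
                       translation = transform$translation * factor)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.4f, rotation %.3f deg, t = (%.3f, %.3f)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine transform\n  A:\n")
  print(x$A)
  cat(sprintf("  t = (%.4f, %.4f)\n", x$translation[1], x$translation[2]))
  invisible(x)
}
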