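#' 3D scalar volume with world geometry
#'
#' The basic image container: a 3D numeric array plus voxel spacing (mm),
#' world origin (mm) and an orthonormal direction matrix. Voxel indices are
#' 0-based and node-centered: the world position of index `i = (i1,i2,i3)`
#' is `origin + orientation %*% (spacing * i)`. All world coordinates in the
#' package live in a single fixed RAS frame (right/anterior/superior
#' positive).
#'
#' @param data numeric 3D array with at least 2 samples per axis.
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param orientation 3x3 orthonormal direction matrix with determinant +1.
#' @return An object of class `us_volume`.
#' @seealso [us_mask()], [read_volume()]
#' @export
us_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 2L))
    stop("volume data must be a 3D array with >= 2 samples per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite world coordinates (mm)")
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      det(orientation) < 0)
    stop("orientation must be orthonormal with determinant +1")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "us_volume")
}

#' Binary or probability mask congruent to a volume
#'
#' A mask shares the exact geometry of its source volume. Binary masks
#' contain only 0/1; probability masks take values in \[0, 1\].
#'
#' @param data numeric 3D array of values in \[0, 1\].
#' @inheritParams us_volume
#' @param kind `"binary"` or `"probability"`.
#' @return An object of class `us_mask` (also inheriting `us_volume`).
#' @export
us_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    orientation = diag(3),
                    kind = c("binary", "probability")) {
  kind <- match.arg(kind)
  v <- us_volume(data, spacing, origin, orientation)
  rng <- range(v$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("mask values must lie in [0, 1]")
  if (kind == "binary" && !all(v$data %in% c(0, 1)))
    stop("binary mask may contain only 0 and 1")
  v$kind <- kind
  class(v) <- c("us_mask", "us_volume")
  v
}

#' Derive a mask that shares a volume's geometry
#'
#' @param v a `us_volume` providing the geometry.
#' @param data mask array (defaults to thresholding `v` at `threshold`).
#' @param kind mask kind, `"binary"` or `"probability"`.
#' @param threshold binarization threshold when `data` is missing.
#' @return A `us_mask`.
#' @export
mask_like <- function(v, data = NULL, kind = "binary", threshold = 0.5) {
  stopifnot(inherits(v, "us_volume"))
  if (is.null(data)) data <- (v$data >= threshold) * 1
  us_mask(data, v$spacing, v$origin, v$orientation, kind = kind)
}

#' @export
print.us_volume <- function(x, ...) {
  kind <- if (inherits(x, "us_mask")) paste0("mask (", x$kind, ")") else "volume"
  cat(sprintf("<us_%s> %s voxels, spacing %s mm, origin %s mm\n",
              if (inherits(x, "us_mask")) "mask" else "volume",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  %s, intensity range [%.4g, %.4g]\n", kind,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Geometry of a volume or mask
#'
#' @param x a `us_volume` or `us_mask`.
#' @return list with `dim`, `spacing`, `origin`, `orientation`.
#' @export
geometry <- function(x) {
  stopifnot(inherits(x, "us_volume"))
  list(dim = dim(x$data), spacing = x$spacing, origin = x$origin,
       orientation = x$orientation)
}

#' Do two grids share the same geometry?
#'
#' @param a,b `us_volume`s (or geometry lists from [geometry()]).
#' @param tol absolute tolerance on spacing/origin (mm) and direction cosines.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "us_volume")) geometry(a) else a
  gb <- if (inherits(b, "us_volume")) geometry(b) else b
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$orientation - gb$orientation)) <= tol
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("geometry mismatch: grids differ in dimensions, spacing, origin or orientation")
  invisible(TRUE)
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param x a `us_volume` or geometry list.
#' @param idx numeric matrix (n x 3) of 0-based (possibly fractional) indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(x, idx) {
  g <- if (inherits(x, "us_volume")) geometry(x) else x
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx %*% diag(g$spacing) %*% t(g$orientation), 2, g$origin, "+")
}

#' Convert world coordinates (mm) to 0-based voxel indices
#'
#' Inverse of [voxel_to_world()]; returned indices are continuous.
#'
#' @inheritParams voxel_to_world
#' @param pts numeric matrix (n x 3) of world coordinates in mm.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(x, pts) {
  g <- if (inherits(x, "us_volume")) geometry(x) else x
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts, 2, g$origin, "-") %*% g$orientation %*% diag(1 / g$spacing)
}

#' World coordinates of every grid node
#'
#' @param x a `us_volume` or geometry list.
#' @return (prod(dim) x 3) matrix of node positions in mm, in array order.
#' @export
grid_points <- function(x) {
  g <- if (inherits(x, "us_volume")) geometry(x) else x
  d <- g$dim
  idx <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(g, idx)
}

#' World center of a volume (mm)
#' @param x a `us_volume` or geometry list.
#' @return length-3 numeric.
#' @export
volume_center <- function(x) {
  g <- if (inherits(x, "us_volume")) geometry(x) else x
  drop(voxel_to_world(g, matrix((g$dim - 1) / 2, 1)))
}

#' Ordered set of world-coordinate landmarks
#'
#' Point order is the correspondence key: two landmark sets paired by equal
#' ordering define point correspondences for registration evaluation.
#'
#' @param points numeric matrix (n x 3) of world coordinates in mm.
#' @param labels optional character vector of per-point identifiers.
#' @return An object of class `landmark_set` (an n x 3 matrix with a
#'   `labels` attribute).
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(points)))
  if (length(labels) != nrow(points))
    stop("labels must match the number of points")
  structure(points, labels = as.character(labels),
            class = c("landmark_set", class(points)))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (mm)\n", nrow(x)))
  print(head(cbind(label = attr(x, "labels"),
                   as.data.frame(unclass(x))), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
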