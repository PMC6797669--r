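#' Rigid transform (translation + rotation about a center)
#'
#' Maps world points `p` to `R %*% (p - center) + center + translation`,
#' with `R` built from intrinsic XYZ Euler angles:
#' `R = Rx(rotation[1]) %*% Ry(rotation[2]) %*% Rz(rotation[3])`.
#' Rotating about the (reference volume's) world center decouples the
#' translation and rotation parameters during optimization.
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, Euler angles in radians.
#' @param center length-3 numeric, world rotation center in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation); rotation <- as.numeric(rotation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(center) == 3, all(is.finite(c(translation, rotation, center))))
  structure(list(translation = translation, rotation = rotation,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, angles = (%s) rad, center = (%s) mm\n",
              paste(signif(x$translation, 4), collapse = ", "),
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

euler_to_matrix <- function(rot) {
  ca <- cos(rot[1]); sa <- sin(rot[1])
  cb <- cos(rot[2]); sb <- sin(rot[2])
  cc <- cos(rot[3]); sc <- sin(rot[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

matrix_to_euler <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(b)) < 1e-12) {  # gimbal-locked; pick c = 0
    c(atan2(R[2, 1], R[2, 2]), b, 0)
  } else {
    c(atan2(-R[2, 3], R[3, 3]), b, atan2(-R[1, 2], R[1, 1]))
  }
}

#' Invert a rigid transform
#'
#' @param x a `rigid_transform`.
#' @return The `rigid_transform` such that composing the two is the
#'   identity (to machine precision).
#' @export
rigid_invert <- function(x) {
  R <- euler_to_matrix(x$rotation)
  rigid_transform(translation = as.numeric(-t(R) %*% x$translation),
                  rotation = matrix_to_euler(t(R)),
                  center = x$center)
}

#' Dense displacement field on a regular grid
#'
#' Displacements are stored in mm on a node-centered grid with its own
#' geometry (typically a pyramid level of the reference volume). Applying
#' the field maps `p` to `p + u(p)`, with `u` trilinearly interpolated and
#' extrapolated by the nearest-border displacement.
#'
#' @param displacements numeric array of dim `c(nx, ny, nz, 3)`, mm.
#' @param spacing,origin,orientation grid geometry, as in [us_volume()].
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), orientation = diag(3)) {
  displacements <- as.array(displacements)
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacements must be an (nx, ny, nz, 3) array")
  if (any(!is.finite(displacements)))
    stop("displacements must be finite everywhere")
  structure(list(disp = displacements, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 orientation = matrix(as.numeric(orientation), 3, 3)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mags <- sqrt(rowSums(matrix(x$disp, ncol = 3)^2))
  cat(sprintf("<deformation_field> grid %s, spacing %s mm, |u| max %.3g mm\n",
              paste(dim(x$disp)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), max(mags)))
  invisible(x)
}

field_geometry <- function(f)
  list(dim = dim(f$disp)[1:3], spacing = f$spacing, origin = f$origin,
       orientation = f$orientation)

#' Ordered chain of transforms
#'
#' A chain applies its entries (rigid transforms and/or deformation fields)
#' in sequence; an empty chain is the identity map.
#'
#' @param ... `rigid_transform` and/or `deformation_field` objects (or a
#'   single list of them).
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && is.list(steps[[1]]) &&
      !inherits(steps[[1]], c("rigid_transform", "deformation_field")))
    steps <- steps[[1]]
  ok <- vapply(steps, inherits, TRUE, c("rigid_transform", "deformation_field"))
  if (length(steps) && !all(ok))
    stop("chain entries must be rigid transforms or deformation fields")
  structure(steps, class = "transform_chain")
}

#' @export
c.transform_chain <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (inherits(x, "transform_chain")) unclass(x) else list(x)
  })
  transform_chain(do.call(c, parts))
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> %d step(s)\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' Apply a transform or chain to world points
#'
#' Entries are applied in order; each point is mapped independently.
#' Deformation fields extrapolate by their nearest-border displacement.
#'
#' @param transform a `rigid_transform`, `deformation_field` or
#'   `transform_chain`.
#' @param pts n x 3 matrix of world coordinates (mm), or a `landmark_set`.
#' @return Transformed points; a `landmark_set` input keeps its labels.
#' @export
apply_transform <- function(transform, pts) {
  labs <- if (inherits(pts, "landmark_set")) attr(pts, "labels") else NULL
  p <- matrix(as.numeric(pts), ncol = 3)
  out <- if (inherits(transform, "rigid_transform")) {
    R <- euler_to_matrix(transform$rotation)
    sweep(sweep(p, 2, transform$center, "-") %*% t(R), 2,
          transform$center + transform$translation, "+")
  } else if (inherits(transform, "deformation_field")) {
    g <- field_geometry(transform)
    vox <- world_to_voxel(g, p)
    u <- vapply(1:3, function(a) {
      cpp_interp3(as.numeric(transform$disp[, , , a]), as.integer(g$dim),
                  vox, FALSE, TRUE)$value
    }, numeric(nrow(p)))
    p + matrix(u, ncol = 3)
  } else if (inherits(transform, "transform_chain")) {
    for (s in transform) p <- apply_transform(s, p)
    p
  } else stop("unsupported transform type")
  if (!is.null(labs)) landmark_set(out, labs) else out
}
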