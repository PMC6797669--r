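#' Gaussian-soften a binary mask for gradient-based registration
#'
#' Hard 0/1 masks have zero intensity gradient almost everywhere, which
#' stalls gradient-driven SSD optimization; registration therefore consumes
#' Gaussian-smoothed masks (or the network's probability output directly).
#'
#' @param m a [us_mask()].
#' @param sigma_vox smoothing bandwidth in voxels (isotropic in index
#'   space); default 1.
#' @return A probability-kind `us_mask`.
#' @export
soften_mask <- function(m, sigma_vox = 1) {
  stopifnot(inherits(m, "us_mask"))
  sm <- cpp_gauss3(as.numeric(m$data), as.integer(dim(m$data)), sigma_vox)
  sm <- pmin(pmax(sm, 0), 1)
  us_mask(array(sm, dim(m$data)), m$spacing, m$origin, m$orientation,
          kind = "probability")
}

#' Multilevel image pyramid (smooth, then subsample by 2)
#'
#' Each step applies a mass-preserving Gaussian (sigma = 1 fine voxel,
#' replicate borders) and keeps every second node starting at index 0, so
#' the origin is preserved and spacing doubles per level.
#'
#' @param x a [us_volume()] or [us_mask()].
#' @param levels number of coarsening steps (result has `levels + 1`
#'   entries; entry 1 is `x` unchanged, entry `L + 1` is level `L`).
#' @return List of volumes/masks, one per level.
#' @export
build_pyramid <- function(x, levels) {
  stopifnot(inherits(x, "us_volume"), levels >= 0)
  if (any(dim(x$data) < 2^levels + 1))
    stop("volume too small for ", levels, " pyramid levels (need >= ",
         2^levels + 1, " samples per axis)")
  out <- vector("list", levels + 1)
  out[[1]] <- x
  cur <- x
  for (L in seq_len(levels)) {
    d <- dim(cur$data)
    sm <- array(cpp_gauss3(as.numeric(cur$data), as.integer(d), 1.0), d)
    ix <- seq(1, d[1], by = 2); iy <- seq(1, d[2], by = 2); iz <- seq(1, d[3], by = 2)
    sub <- sm[ix, iy, iz, drop = FALSE]
    cur <- if (inherits(x, "us_mask")) {
      us_mask(pmin(pmax(sub, 0), 1), cur$spacing * 2, cur$origin,
              cur$orientation, kind = "probability")
    } else {
      us_volume(sub, cur$spacing * 2, cur$origin, cur$orientation)
    }
    out[[L + 1]] <- cur
  }
  out
}

#' Resample a volume or mask through a transform chain (pull-back)
#'
#' Produces `out(p) = x(map(p))` on the target grid with trilinear
#' interpolation; reads outside `x`'s domain return 0 (background).
#'
#' @param x a [us_volume()] or [us_mask()] (the template).
#' @param map a [transform_chain()] (or single transform) mapping target
#'   (reference) world coordinates to `x`'s (template) world coordinates.
#' @param target target geometry: a `us_volume`/`us_mask` or a [geometry()]
#'   list. Defaults to `x`'s own geometry.
#' @return Same kind as `x`, on the target grid. Masks come back as
#'   probability kind (interpolation mixes 0 and 1); re-binarize with
#'   [mask_like()] if needed.
#' @export
resample <- function(x, map, target = NULL) {
  stopifnot(inherits(x, "us_volume"))
  g <- if (is.null(target)) geometry(x)
       else if (inherits(target, "us_volume")) geometry(target) else target
  pts <- grid_points(g)
  if (!inherits(map, "transform_chain")) map <- transform_chain(map)
  warped <- apply_transform(map, pts)
  vox <- world_to_voxel(x, warped)
  vals <- cpp_interp3(as.numeric(x$data), as.integer(dim(x$data)), vox,
                      FALSE, FALSE)$value
  arr <- array(vals, g$dim)
  if (inherits(x, "us_mask"))
    us_mask(pmin(pmax(arr, 0), 1), g$spacing, g$origin, g$orientation,
            kind = "probability")
  else
    us_volume(arr, g$spacing, g$origin, g$orientation)
}

#' Sum of squared differences between two congruent grids
#'
#' `D = 1/2 * sum((template - reference)^2) * voxel_volume` (mm^3), the
#' mono-modal distance used to compare the deformed template mask with the
#' reference mask.
#'
#' @param ref reference mask/volume.
#' @param def_tmpl deformed template mask/volume on the same grid.
#' @return Scalar SSD (intensity^2 * mm^3).
#' @export
ssd <- function(ref, def_tmpl) {
  stop_if_geometry_mismatch(ref, def_tmpl)
  0.5 * sum((def_tmpl$data - ref$data)^2) * prod(ref$spacing)
}

#' Linear-elastic regularization energy of a displacement field
#'
#' Discretized elastic potential
#' `S(u) = integral of mu/4 * sum_jk (d_j u_k + d_k u_j)^2 +
#'  lambda/2 * (div u)^2`,
#' using central finite differences in the grid interior and one-sided
#' differences at the borders (Neumann handling). Rigid displacements have
#' zero energy in the continuous limit.
#'
#' @param u a [deformation_field()].
#' @param mu,lambda Lame parameters (defaults 1 and 0).
#' @return Scalar energy (mm^3 * strain^2).
#' @export
elastic_energy <- function(u, mu = 1, lambda = 0) {
  stopifnot(inherits(u, "deformation_field"))
  d <- dim(u$disp)[1:3]
  cpp_elastic3(matrix(u$disp, ncol = 3), as.integer(d), u$spacing,
               mu, lambda, FALSE)$value
}
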