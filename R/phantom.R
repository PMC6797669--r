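#' Specification of a synthetic ultrasound phantom
#'
#' The phantom emulates the appearance that drives the registration method:
#' thin, curved, bright (hyperechogenic) sheets -- stand-ins for sulci and
#' the falx cerebri -- over a darker speckled background. Sheets are level
#' sets of smooth random low-order height functions swept through the
#' volume and thickened to `sheet_thickness`; intensities are the two mean
#' levels modulated by multiplicative, right-skewed speckle.
#'
#' @param shape voxel counts per axis (default `c(64, 64, 64)`).
#' @param spacing voxel size in mm (default 0.5 mm isotropic, the scale of
#'   high-resolution 3D ultrasound reconstructions).
#' @param n_sheets number of bright sheets (>= 1; default 4, alternating
#'   sweep axes so that sheets intersect).
#' @param sheet_thickness sheet thickness in mm (default 1.5).
#' @param sheet_intensity_mean,background_intensity_mean mean intensity of
#'   sheet and background tissue, arbitrary units (defaults 180 and 60 on a
#'   0--255 B-mode-like scale).
#' @param speckle_scale blending weight of the multiplicative speckle in
#'   \[0, 1\] (default 0.3).
#' @param n_landmarks number of landmarks placed on the sheets (>= 4,
#'   default 15, the order of magnitude annotated per clinical case).
#' @param seed RNG seed making the phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(0.5, 0.5, 0.5),
                         n_sheets = 4, sheet_thickness = 1.5,
                         sheet_intensity_mean = 180,
                         background_intensity_mean = 60,
                         speckle_scale = 0.3, n_landmarks = 15, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8), length(spacing) == 3,
            all(spacing > 0))
  if (n_sheets < 1) stop("n_sheets must be >= 1")
  if (sheet_intensity_mean <= background_intensity_mean)
    stop("sheet_intensity_mean must exceed background_intensity_mean")
  if (n_landmarks < 4) stop("n_landmarks must be >= 4")
  if (speckle_scale < 0 || speckle_scale > 1)
    stop("speckle_scale must be in [0, 1]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_sheets = as.integer(n_sheets),
                 sheet_thickness = sheet_thickness,
                 sheet_intensity_mean = sheet_intensity_mean,
                 background_intensity_mean = background_intensity_mean,
                 speckle_scale = speckle_scale,
                 n_landmarks = as.integer(n_landmarks),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @importFrom stats quantile
NULL

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Multiplicative speckle factor: squared magnitude of a complex Gaussian
# (unit mean, exponential-tailed, right-skewed), blended with 1 by `scale`.
speckle_factor <- function(n, scale) {
  e <- (rnorm(n)^2 + rnorm(n)^2) / 2
  (1 - scale) + scale * e
}

#' Generate a synthetic phantom case
#'
#' Deterministic given `spec$seed`. Returns the intensity volume, the exact
#' ground-truth sheet mask (1 exactly on the thickened sheets) and
#' `spec$n_landmarks` landmarks sampled on mask voxels without replacement,
#' weighted toward high-curvature mask points (sheet rims, corners and
#' intersections) the way clinical landmarks favour deep grooves and
#' corners of sulci.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case`: list with `volume`
#'   ([us_volume()]), `mask` ([us_mask()]), `landmarks` ([landmark_set()])
#'   and the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape; sp <- spec$spacing
    ext <- (d - 1) * sp
    ax <- list(seq(0, ext[1], length.out = d[1]),
               seq(0, ext[2], length.out = d[2]),
               seq(0, ext[3], length.out = d[3]))
    mask <- array(FALSE, d)
    half <- spec$sheet_thickness / 2
    for (s in seq_len(spec$n_sheets)) {
      a <- ((s - 1) %% 3) + 1              # sweep axis cycles x, y, z
      uv <- setdiff(1:3, a)
      # smooth random low-order height function over the two in-sheet axes
      c0 <- runif(1, 0.25, 0.75) * ext[a]
      sl <- runif(2, -0.25, 0.25)
      amp <- runif(2, 0.06, 0.16) * ext[a]
      om <- sample(1:3, 2, replace = TRUE)
      ph <- runif(2, 0, 2 * pi)
      U <- ax[[uv[1]]]; V <- ax[[uv[2]]]
      fU <- sl[1] * (U - ext[uv[1]] / 2) + amp[1] * sin(2 * pi * om[1] * U / ext[uv[1]] + ph[1])
      fV <- sl[2] * (V - ext[uv[2]] / 2) + amp[2] * sin(2 * pi * om[2] * V / ext[uv[2]] + ph[2])
      fUV <- c0 + outer(fU, fV, "+")       # height along axis a
      # patchy coverage: sulci segments, not unbroken surfaces -- the gaps
      # create rims and corners that anchor in-sheet (tangential) motion
      gU <- sin(2 * pi * sample(1:2, 1) * U / ext[uv[1]] + runif(1, 0, 2 * pi))
      gV <- sin(2 * pi * sample(1:2, 1) * V / ext[uv[2]] + runif(1, 0, 2 * pi))
      keepUV <- outer(gU, gV, "+") > stats::quantile(outer(gU, gV, "+"), 0.3)
      W <- ax[[a]]
      # |w - f(u,v)| <= half, broadcast to the full grid in array order
      hitf <- function(w, f) abs(w - f) <= half
      hit <- switch(a,
        outer(W, fUV, hitf),                                           # a = 1
        aperm(outer(fUV, W, function(f, w) hitf(w, f)), c(1, 3, 2)),   # a = 2
        outer(fUV, W, function(f, w) hitf(w, f)))                      # a = 3
      keep3 <- switch(a,
        outer(rep(TRUE, d[1]), keepUV),
        aperm(outer(keepUV, rep(TRUE, d[2])), c(1, 3, 2)),
        outer(keepUV, rep(TRUE, d[3])))
      mask <- mask | (hit & keep3)
    }
    n_vox <- prod(d)
    base <- ifelse(mask, spec$sheet_intensity_mean, spec$background_intensity_mean)
    vol <- base * speckle_factor(n_vox, spec$speckle_scale)
    vol <- pmax(array(vol, d), 0)

    volume <- us_volume(vol, sp)
    gt <- us_mask(mask * 1, sp)

    midx <- which(mask)
    if (spec$n_landmarks > length(midx))
      stop("capacity error: ", spec$n_landmarks, " landmarks requested but the mask has only ",
           length(midx), " voxels")
    # curvature proxy: fewer mask neighbours = rim/corner/intersection voxel
    frac <- cpp_boxsum3(as.numeric(mask), as.integer(d))[midx] / 27
    w <- (1 - frac) + 0.05
    pick <- sample(length(midx), spec$n_landmarks, prob = w)
    sel <- arrayInd(midx[pick], d) - 1L
    lms <- landmark_set(voxel_to_world(volume, sel))

    structure(list(volume = volume, mask = gt, landmarks = lms, spec = spec),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case>\n  ")
  print(x$volume)
  cat(sprintf("  mask: %d voxels on (%.1f%%), %d landmarks\n",
              sum(x$mask$data), 100 * mean(x$mask$data), nrow(x$landmarks)))
  invisible(x)
}

#' Random smooth displacement field over a volume's domain
#'
#' A brain-shift-like deformation: a random bulk (constant) displacement
#' plus a superposition of low-frequency sinusoidal modes per component,
#' globally rescaled so the largest displacement magnitude equals
#' `max_mm`. Intraoperative brain shift is predominantly a bulk settling
#' of the exposed tissue with a smoother elastic residual on top, which is
#' exactly this two-part structure. Used as ground-truth deformation for
#' registration testing.
#'
#' @param x a `us_volume` (or geometry list) whose grid the field lives on.
#' @param max_mm peak displacement magnitude in mm (default 4).
#' @param seed RNG seed.
#' @param n_modes sinusoidal modes per component on top of the bulk mode
#'   (default 3).
#' @return A [deformation_field()] on `x`'s grid.
#' @export
random_smooth_field <- function(x, max_mm = 4, seed = 1L, n_modes = 3) {
  g <- if (inherits(x, "us_volume")) geometry(x) else x
  with_seed(seed, {
    pts <- grid_points(g)
    ext <- pmax((g$dim - 1) * g$spacing, 1e-6)
    u <- matrix(0, nrow(pts), 3)
    for (k in 1:3) {
      u[, k] <- runif(1, -1, 1)                  # bulk (DC) mode
      for (m in seq_len(n_modes)) {
        w <- sample(0:1, 3, replace = TRUE)      # low spatial frequency
        if (all(w == 0)) w[sample(3, 1)] <- 1
        ph <- runif(1, 0, 2 * pi)
        amp <- runif(1, 0.2, 0.6)
        u[, k] <- u[, k] + amp * sin(2 * pi * (pts %*% (w / ext)) + ph)
      }
    }
    mags <- sqrt(rowSums(u^2))
    u <- u * (max_mm / max(mags))
    deformation_field(array(u, c(g$dim, 3)), g$spacing, g$origin, g$orientation)
  })
}

# Invert a displacement field by fixed-point iteration: find q(p) with
# q + u(q) = p. Converges for the moderate, smooth deformations the
# phantom uses (contraction when max |grad u| < 1).
invert_field <- function(f, iters = 20) {
  g <- field_geometry(f)
  pts <- grid_points(g)
  q <- pts
  for (it in seq_len(iters)) q <- pts - (apply_transform(f, q) - q)
  deformation_field(array(q - pts, c(g$dim, 3)), g$spacing, g$origin,
                    g$orientation)
}

#' Deform a phantom case under a known motion
#'
#' `motion` is the forward motion of material points: returned landmarks
#' are exactly `motion(landmarks)`, and the volume and mask are resampled
#' so the imaged structures move accordingly (the pull-back map is the
#' motion's inverse -- exact for rigid motions, fixed-point-inverted for
#' displacement fields). The returned landmark set is therefore the
#' ground-truth correspondence of the input set, which makes
#' (case, deformed case) a registration test pair with known answer.
#'
#' @param case a [generate_phantom()] result.
#' @param motion a [rigid_transform()] or [deformation_field()].
#' @return A new `phantom_case` (mask re-binarized at 0.5).
#' @export
deform_phantom <- function(case, motion) {
  stopifnot(inherits(case, "phantom_case"))
  inv <- if (inherits(motion, "rigid_transform")) rigid_invert(motion)
         else if (inherits(motion, "deformation_field")) invert_field(motion)
         else stop("motion must be a rigid transform or a deformation field")
  chain <- transform_chain(inv)
  vol <- resample(case$volume, chain)
  msk <- resample(case$mask, chain)
  msk <- mask_like(vol, (msk$data >= 0.5) * 1)
  kept <- sum(msk$data) / max(sum(case$mask$data), 1)
  if (kept < 0.5)
    stop("coverage error: motion moves ", round(100 * (1 - kept)),
         "% of the mask mass outside the field of view")
  lms <- apply_transform(motion, case$landmarks)
  structure(list(volume = vol, mask = msk, landmarks = lms, spec = case$spec),
            class = "phantom_case")
}

#' Specification of a simulated resection cavity
#'
#' @param center cavity center in world mm.
#' @param radius cavity radius in mm (> 0).
#' @param rim_intensity_mean mean intensity of the bright rim around the
#'   cavity (resection cavities appear hyperechogenic, as bright as sulci,
#'   which is exactly why they confound mask-based registration).
#' @param rim_thickness rim shell thickness in mm (default 1.5).
#' @return An object of class `cavity_spec`.
#' @export
cavity_spec <- function(center, radius, rim_intensity_mean = 180,
                        rim_thickness = 1.5) {
  if (radius <= 0) stop("cavity radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 rim_intensity_mean = rim_intensity_mean,
                 rim_thickness = rim_thickness),
            class = "cavity_spec")
}

#' Simulate a resection cavity in a phantom case
#'
#' Intensities inside the cavity sphere drop to the background level and a
#' thin shell around it turns bright (`rim_intensity_mean`), mimicking the
#' hyperechogenic cavity wall. Ground-truth mask voxels inside the sphere
#' are removed; the rim is deliberately NOT added to the ground truth -- it
#' is a confounder with no counterpart at earlier surgical stages.
#'
#' @param case a `phantom_case`.
#' @param cavity a [cavity_spec()].
#' @return A new `phantom_case`.
#' @export
simulate_resection <- function(case, cavity) {
  stopifnot(inherits(case, "phantom_case"), inherits(cavity, "cavity_spec"))
  g <- geometry(case$volume)
  c0 <- drop(voxel_to_world(g, matrix(0, 1, 3)))
  c1 <- drop(voxel_to_world(g, matrix(g$dim - 1, 1)))
  lo <- pmin(c0, c1); hi <- pmax(c0, c1)
  nearest <- pmin(pmax(cavity$center, lo), hi)
  if (sqrt(sum((nearest - cavity$center)^2)) > cavity$radius)
    stop("cavity sphere does not intersect the volume")
  pts <- grid_points(g)
  dist <- sqrt(rowSums(sweep(pts, 2, cavity$center, "-")^2))
  inside <- dist <= cavity$radius
  rim <- dist > cavity$radius & dist <= cavity$radius + cavity$rim_thickness
  sp <- case$spec
  vol <- case$volume$data
  with_seed(sp$seed + 104729L, {  # independent speckle draw for the cavity
    if (any(inside))
      vol[inside] <- pmax(sp$background_intensity_mean *
                            speckle_factor(sum(inside), sp$speckle_scale), 0)
    if (any(rim))
      vol[rim] <- pmax(cavity$rim_intensity_mean *
                         speckle_factor(sum(rim), sp$speckle_scale), 0)
  })
  msk <- case$mask$data
  msk[inside] <- 0
  structure(list(volume = us_volume(array(vol, g$dim), g$spacing, g$origin,
                                    g$orientation),
                 mask = us_mask(array(msk, g$dim), g$spacing, g$origin,
                                g$orientation),
                 landmarks = case$landmarks, spec = sp),
            class = "phantom_case")
}
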