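#' Registration configuration
#'
#' Collects the tunable parameters of the mask-driven variational
#' registration. The objective is `J(u) = D + alpha * S` with `D` the SSD
#' between the (softened) reference mask and deformed template mask and
#' `S` the linear-elastic energy of the nonparametric displacement
#' relative to the rigid initializer (bulk rigid motion is not penalized).
#'
#' @param alpha weight of the elastic regularizer (default 0.01,
#'   calibrated on the synthetic-field recovery study: large enough to keep
#'   the displacement smooth, small enough that the data term can pull the
#'   mask sheets onto their counterparts).
#' @param mu,lambda Lame parameters of the elastic potential (defaults 1
#'   and 0: pure shear penalty, no extra volumetric term).
#' @param sigma_soften Gaussian bandwidth (voxels) used to soften binary
#'   masks before registration (default 1.5; widens the capture basin of
#'   the SSD gradient). Probability masks are used as-is.
#' @param parametric_level pyramid level of the translation/rigid stage
#'   (default 1, one level coarser than native).
#' @param nonparametric_levels pyramid levels of the elastic stage, coarse
#'   to fine (default `c(3, 2, 1)`, third- to one-level coarser).
#' @param stopping a [stopping_criteria()], shared by all stages.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(alpha = 0.01, mu = 1, lambda = 0, sigma_soften = 1.5,
                       parametric_level = 1,
                       nonparametric_levels = c(3, 2, 1),
                       stopping = stopping_criteria()) {
  stopifnot(alpha >= 0, mu > 0, lambda >= 0, sigma_soften >= 0,
            parametric_level >= 0, all(diff(nonparametric_levels) < 0),
            inherits(stopping, "stopping_criteria"))
  structure(list(alpha = alpha, mu = mu, lambda = lambda,
                 sigma_soften = sigma_soften,
                 parametric_level = as.integer(parametric_level),
                 nonparametric_levels = as.integer(nonparametric_levels),
                 stopping = stopping),
            class = "reg_config")
}

# Soften a mask for gradient-based SSD; probability masks pass through.
reg_soften <- function(m, sigma) {
  if (identical(m$kind, "binary") && sigma > 0) soften_mask(m, sigma) else m
}

# Re-express a rigid transform about a different rotation center.
rigid_recenter <- function(x, center) {
  R <- euler_to_matrix(x$rotation)
  t_new <- as.numeric(R %*% (center - x$center)) + x$center + x$translation - center
  rigid_transform(t_new, x$rotation, center)
}

# dR/d(angle_i) for R = Rx Ry Rz
euler_derivatives <- function(rot) {
  ca <- cos(rot[1]); sa <- sin(rot[1])
  cb <- cos(rot[2]); sb <- sin(rot[2])
  cc <- cos(rot[3]); sc <- sin(rot[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  dx <- matrix(c(0, 0, 0, 0, -sa, ca, 0, -ca, -sa), 3, 3)
  dy <- matrix(c(-sb, 0, -cb, 0, 0, 0, cb, 0, -sb), 3, 3)
  dz <- matrix(c(-sc, cc, 0, -cc, -sc, 0, 0, 0, 0), 3, 3)
  list(dx %*% ry %*% rz, rx %*% dy %*% rz, rx %*% ry %*% dz)
}

# Shared pieces of an SSD objective on one pyramid level.
ssd_level_env <- function(refL, tmplL) {
  list(pts = grid_points(refL),
       refvals = as.numeric(refL$data),
       h3 = prod(refL$spacing),
       tvals = as.numeric(tmplL$data),
       tdim = as.integer(dim(tmplL$data)),
       torigin = tmplL$origin,
       tA = tmplL$orientation %*% diag(1 / tmplL$spacing),  # world -> voxel
       tG = diag(1 / tmplL$spacing) %*% t(tmplL$orientation)) # voxel grad -> world grad
}

# SSD value and gradient w.r.t. the warped world positions.
ssd_at <- function(env, warped) {
  vox <- sweep(warped, 2, env$torigin) %*% env$tA
  ip <- cpp_interp3(env$tvals, env$tdim, vox, TRUE, FALSE)
  r <- ip$value - env$refvals
  list(D = 0.5 * env$h3 * sum(r^2),
       Gw = (ip$grad %*% env$tG) * (env$h3 * r))
}

#' Parametric (translation, then rigid) mask registration
#'
#' Optimizes SSD between softened masks at a resolution one level coarser
#' than native: stage 1 fits a pure translation starting from the tracker
#' initial guess, stage 2 refines all 6 rigid parameters from the stage-1
#' result. The translation stage itself is warm-started one further level
#' coarser (when the grid allows), which keeps the stage out of the false
#' minima created by near-parallel neighbouring sheets under larger
#' initial misalignments. No regularizer is applied (parametric maps need
#' none). The rotation center is the reference volume's world center.
#'
#' @param ref,tmpl reference and template [us_mask()]s.
#' @param init optional [rigid_transform()] initial guess (e.g. from the
#'   optical tracker); identity by default.
#' @param config a [reg_config()].
#' @return List with `transform` (the fitted [rigid_transform()] at native
#'   resolution), `log` (per-stage optimizer logs) and `converged`.
#' @export
register_parametric <- function(ref, tmpl, init = NULL,
                                config = reg_config()) {
  stopifnot(inherits(ref, "us_mask"), inherits(tmpl, "us_mask"))
  refS <- reg_soften(ref, config$sigma_soften)
  tmplS <- reg_soften(tmpl, config$sigma_soften)
  if (sum(refS$data) == 0 || sum(tmplS$data) == 0)
    stop("degenerate input: empty mask cannot drive registration")
  L <- config$parametric_level
  Lw <- L + 1L                           # warm-start level for the translation
  warm <- all(dim(refS$data) >= 2^Lw + 1) && all(dim(tmplS$data) >= 2^Lw + 1)
  depth <- if (warm) Lw else L
  refP <- build_pyramid(refS, depth)
  tmplP <- build_pyramid(tmplS, depth)
  center <- volume_center(ref)
  init <- if (is.null(init)) rigid_transform(center = center)
          else rigid_recenter(init, center)

  mkobj <- function(lev) {
    env <- ssd_level_env(refP[[lev + 1]], tmplP[[lev + 1]])
    pc <- sweep(env$pts, 2, center)
    function(theta, rot_fixed = NULL) {
      tr <- theta[1:3]
      rot <- rot_fixed %||% theta[4:6]
      R <- euler_to_matrix(rot)
      warped <- pc %*% t(R) + matrix(center + tr, nrow(pc), 3, byrow = TRUE)
      s <- ssd_at(env, warped)
      gt <- colSums(s$Gw)
      if (is.null(rot_fixed)) {
        dR <- euler_derivatives(rot)
        ga <- vapply(dR, function(D) sum((pc %*% t(D)) * s$Gw), 0)
        list(value = s$D, grad = c(gt, ga), extra = c(D = s$D))
      } else {
        list(value = s$D, grad = gt, extra = c(D = s$D))
      }
    }
  }

  objL <- mkobj(L)
  t0 <- init$translation
  log_warm <- NULL
  if (warm) {
    objW <- mkobj(Lw)
    stw <- lbfgs_optimize(function(x) objW(x, rot_fixed = init$rotation),
                          t0, config$stopping)
    t0 <- stw$x
    log_warm <- stw$log
  }
  st1 <- lbfgs_optimize(function(x) objL(x, rot_fixed = init$rotation),
                        t0, config$stopping)
  st2 <- lbfgs_optimize(objL, c(st1$x, init$rotation), config$stopping)
  logs <- list(translation = st1$log, rigid = st2$log)
  if (!is.null(log_warm)) logs <- c(list(translation_warmstart = log_warm), logs)
  list(transform = rigid_transform(st2$x[1:3], st2$x[4:6], center),
       log = logs,
       converged = st1$converged && st2$converged)
}

#' Nonparametric (elastic) mask registration
#'
#' Solves `min_u SSD(ref, tmpl(phi_init + u)) + alpha * S(u)` by l-BFGS on
#' a coarse-to-fine pyramid (levels `config$nonparametric_levels`),
#' prolongating the displacement between levels by trilinear
#' interpolation (displacements are stored in mm, so no rescaling is
#' needed across levels). The regularizer acts on `u` only, leaving the
#' rigid bulk motion of the initializer unpenalized.
#'
#' @inheritParams register_parametric
#' @param init [rigid_transform()] initializer, normally the
#'   [register_parametric()] result.
#' @return List with `field` (a [deformation_field()] on the native grid
#'   holding the TOTAL displacement, rigid initializer folded in, so that
#'   the registration map is `p -> p + field(p)`), `log` (per-level
#'   optimizer logs) and `converged`.
#' @export
register_nonparametric <- function(ref, tmpl, init = NULL,
                                   config = reg_config()) {
  stopifnot(inherits(ref, "us_mask"), inherits(tmpl, "us_mask"))
  refS <- reg_soften(ref, config$sigma_soften)
  tmplS <- reg_soften(tmpl, config$sigma_soften)
  if (sum(refS$data) == 0 || sum(tmplS$data) == 0)
    stop("degenerate input: empty mask cannot drive registration")
  levels <- config$nonparametric_levels
  maxL <- max(levels)
  refP <- build_pyramid(refS, maxL)
  tmplP <- build_pyramid(tmplS, maxL)
  init <- init %||% rigid_transform(center = volume_center(ref))

  logs <- list()
  converged <- TRUE
  u <- NULL; prev_geom <- NULL
  for (L in levels) {
    refL <- refP[[L + 1]]; tmplL <- tmplP[[L + 1]]
    g <- geometry(refL)
    env <- ssd_level_env(refL, tmplL)
    warped0 <- apply_transform(init, env$pts)
    n <- nrow(env$pts)
    u <- if (is.null(u)) {
      matrix(0, n, 3)
    } else {                     # prolongate from the previous (coarser) level
      vox <- world_to_voxel(prev_geom, env$pts)
      vapply(1:3, function(k) {
        cpp_interp3(u[, k], as.integer(prev_geom$dim), vox, FALSE, TRUE)$value
      }, numeric(n))
    }
    obj <- function(uvec) {
      um <- matrix(uvec, ncol = 3)
      s <- ssd_at(env, warped0 + um)
      el <- cpp_elastic3(um, as.integer(g$dim), g$spacing,
                         config$mu, config$lambda, TRUE)
      list(value = s$D + config$alpha * el$value,
           grad = as.numeric(s$Gw + config$alpha * el$grad),
           extra = c(D = s$D, S = el$value))
    }
    res <- lbfgs_optimize(obj, as.numeric(u), config$stopping)
    u <- matrix(res$x, ncol = 3)
    logs[[paste0("level", L)]] <- res$log
    converged <- converged && res$converged
    prev_geom <- g
  }

  # total displacement on the native grid: p -> init(p) + u(p)
  gn <- geometry(ref)
  pts_nat <- grid_points(gn)
  vox <- world_to_voxel(prev_geom, pts_nat)
  u_nat <- vapply(1:3, function(k) {
    cpp_interp3(u[, k], as.integer(prev_geom$dim), vox, FALSE, TRUE)$value
  }, numeric(nrow(pts_nat)))
  total <- apply_transform(init, pts_nat) + u_nat - pts_nat
  field <- deformation_field(array(total, c(gn$dim, 3)), gn$spacing,
                             gn$origin, gn$orientation)
  list(field = field, log = logs, converged = converged)
}

#' Full mask-driven registration (parametric, then nonparametric)
#'
#' The standard two-stage pipeline: translation/rigid pre-alignment one
#' pyramid level coarse, then the three-level elastic stage initialized
#' with the parametric result. Outputs the transform chain (reference
#' coordinates to template coordinates) and the deformed template.
#'
#' @inheritParams register_parametric
#' @param deform in addition to the chain, resample this object (defaults
#'   to `tmpl`) onto `ref`'s grid to produce the deformed template.
#' @return An object of class `registration_result`: list with
#'   `chain` (full, elastic), `chain_parametric` (rigid only),
#'   `parametric` (the [rigid_transform()]), `field`, `deformed_template`,
#'   `log` and `converged`.
#' @export
register_masks <- function(ref, tmpl, init = NULL, config = reg_config(),
                           deform = NULL) {
  par <- register_parametric(ref, tmpl, init, config)
  nonpar <- register_nonparametric(ref, tmpl, par$transform, config)
  chain <- transform_chain(nonpar$field)
  structure(list(chain = chain,
                 chain_parametric = transform_chain(par$transform),
                 parametric = par$transform,
                 field = nonpar$field,
                 deformed_template = resample(deform %||% tmpl, chain,
                                              geometry(ref)),
                 log = c(list(parametric = par$log), nonpar$log),
                 converged = par$converged && nonpar$converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  print(x$parametric)
  print(x$field)
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}
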