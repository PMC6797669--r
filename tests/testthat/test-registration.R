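test_that("pyramid levels keep constants, geometry and intensity mass", {
  v <- us_volume(array(7, c(17, 17, 17)), spacing = c(0.5, 0.5, 0.5))
  pyr <- build_pyramid(v, 3)
  expect_identical(pyr[[1]], v)                 # level 0 is the input
  for (L in 1:3) {
    expect_true(all(abs(pyr[[L + 1]]$data - 7) < 1e-12))
    expect_equal(pyr[[L + 1]]$spacing, v$spacing * 2^L)
  }
  # mass preservation on a structured volume (brute-force sums)
  case <- small_case(seed = 30, shape = 32)
  pyr <- build_pyramid(case$volume, 3)
  m0 <- sum(case$volume$data) * prod(case$volume$spacing)
  for (L in 1:3) {
    mL <- sum(pyr[[L + 1]]$data) * prod(pyr[[L + 1]]$spacing)
    expect_lt(abs(mL - m0) / m0, 0.02)
  }
  expect_error(build_pyramid(v, 5), "small")
})

test_that("resampling through the identity and whole-voxel shifts is exact", {
  case <- small_case(seed = 31, shape = 16)
  v <- case$volume
  out <- resample(v, transform_chain())
  expect_identical(out$data, v$data)
  # translation by exactly one voxel spacing: interior voxels bit-equal
  shift <- rigid_transform(translation = c(v$spacing[1], 0, 0))
  out <- resample(v, transform_chain(shift))
  expect_identical(out$data[1:15, , ], v$data[2:16, , ])
})

test_that("rigid resampling matches an independent per-voxel oracle", {
  set.seed(32)
  v <- us_volume(array(rnorm(10^3), c(10, 10, 10)), spacing = c(0.8, 1, 1.2),
                 origin = c(2, -1, 0))
  rig <- rigid_transform(c(0.7, -0.4, 0.3), c(0.05, -0.08, 0.1), c(5, 4, 5))
  out <- resample(v, transform_chain(rig))
  # oracle: loop voxels, manual trilinear interpolation
  interp1 <- function(arr, x) {                # x: 0-based voxel coords
    i0 <- floor(x); f <- x - i0
    acc <- 0
    for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
      ii <- i0 + c(di, dj, dk)
      w <- prod(ifelse(c(di, dj, dk) == 1, f, 1 - f))
      val <- if (all(ii >= 0) && all(ii <= dim(arr) - 1))
        arr[ii[1] + 1, ii[2] + 1, ii[3] + 1] else 0
      acc <- acc + w * val
    }
    acc
  }
  idx <- rbind(c(0, 0, 0), c(3, 4, 5), c(9, 9, 9), c(1, 7, 2), c(5, 5, 5))
  for (r in seq_len(nrow(idx))) {
    p <- voxel_to_world(v, matrix(idx[r, ], 1))
    q <- apply_transform(rig, p)
    expected <- interp1(v$data, drop(world_to_voxel(v, q)))
    got <- out$data[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1]
    expect_lt(abs(got - expected), 1e-6)
  }
})

test_that("SSD has its closed-form values and matches the triple-loop oracle", {
  z <- us_mask(array(0, c(4, 4, 4)))
  expect_equal(ssd(z, z), 0)
  one <- array(0, c(4, 4, 4)); one[2, 3, 1] <- 1
  expect_equal(ssd(us_mask(one), z), 0.5)       # 1/2 * 1^2 * 1 mm^3
  set.seed(33)
  pr <- random_mask_pair(c(6, 5, 7))
  expect_equal(ssd(pr$a, pr$b), oracle_ssd(pr$a, pr$b), tolerance = 1e-12)
  bad <- us_mask(array(0, c(6, 5, 7)), spacing = c(2, 2, 2))
  expect_error(ssd(pr$a, bad), "geometry")
})

test_that("elastic energy: zero for rigid-limit fields, closed-form shear", {
  g <- list(dim = c(8L, 8L, 8L), spacing = c(1, 1, 1), origin = c(0, 0, 0),
            orientation = diag(3))
  zero <- deformation_field(array(0, c(8, 8, 8, 3)), g$spacing)
  expect_equal(elastic_energy(zero, 1, 1), 0)
  const <- deformation_field(array(2.5, c(8, 8, 8, 3)), g$spacing)
  expect_equal(elastic_energy(const, 1, 1), 0)
  # u = (gamma * x, 0, 0), mu = 1, lambda = 0 -> gamma^2 * volume,
  # approached under grid refinement
  gamma <- 0.3
  err <- sapply(c(9, 17, 33), function(n) {
    sp <- rep(8 / (n - 1), 3)
    pts <- grid_points(list(dim = rep(n, 3L), spacing = sp,
                            origin = c(0, 0, 0), orientation = diag(3)))
    u <- array(cbind(gamma * pts[, 1], 0, 0), c(n, n, n, 3))
    S <- elastic_energy(deformation_field(u, sp), mu = 1, lambda = 0)
    abs(S - gamma^2 * 8^3)
  })
  expect_true(all(diff(err) < 0))               # converges monotonically
  expect_lt(err[3] / (gamma^2 * 8^3), 0.11)
})

test_that("parametric registration recovers pure translations and rotations", {
  case <- small_case(seed = 34, shape = 48)
  ctr <- volume_center(case$volume)
  # translation
  def <- deform_phantom(case, rigid_transform(c(2, -3, 1), center = ctr))
  par <- register_parametric(def$mask, case$mask)
  expect_lt(max(abs(par$transform$translation - c(-2, 3, -1))),
            0.5 * case$volume$spacing[1])
  expect_descent(par)
  # identity
  par0 <- register_parametric(case$mask, case$mask)
  expect_lt(max(abs(par0$transform$translation)), 1e-3)
  expect_lt(max(abs(par0$transform$rotation)), 1e-3)
  # 5 degree rotation about the center
  ang <- 5 * pi / 180
  def2 <- deform_phantom(case, rigid_transform(c(0, 0, 0), c(0, 0, ang),
                                               center = ctr))
  par2 <- register_parametric(def2$mask, case$mask)
  expect_lt(abs(par2$transform$rotation[3] + ang), 0.5 * pi / 180)
})

test_that("parametric registration rejects empty masks", {
  case <- small_case(seed = 35, shape = 16)
  empty <- mask_like(case$volume, array(0, dim(case$volume$data)))
  expect_error(register_parametric(empty, case$mask), "empty mask")
})

test_that("nonparametric self-registration returns a near-zero field", {
  case <- small_case(seed = 36, shape = 32)
  res <- register_nonparametric(case$mask, case$mask,
                                rigid_transform(center = volume_center(case$mask)))
  mags <- sqrt(rowSums(matrix(res$field$disp, ncol = 3)^2))
  expect_lt(max(mags), 0.1 * case$mask$spacing[1])
})

test_that("elastic energy of the solution is monotone in alpha", {
  case <- small_case(seed = 37, shape = 32)
  f <- random_smooth_field(case$volume, max_mm = 3, seed = 370)
  def <- deform_phantom(case, f)
  S_end <- sapply(c(0.003, 0.03, 0.3), function(a) {
    res <- register_nonparametric(def$mask, case$mask,
                                  rigid_transform(center = volume_center(def$mask)),
                                  reg_config(alpha = a,
                                             nonparametric_levels = c(2, 1)))
    finest <- res$log[[length(res$log)]]
    finest$S[nrow(finest)]
  })
  expect_true(all(diff(S_end) < 0))
})

test_that("nonparametric stage improves on the parametric stage (field case)", {
  case <- small_case(seed = 38, shape = 64, n_landmarks = 12)
  f <- random_smooth_field(case$volume, max_mm = 4, seed = 380)
  def <- deform_phantom(case, f)
  res <- register_masks(def$mask, case$mask)
  before <- tre(def$landmarks, case$landmarks)$mean
  par <- tre(def$landmarks, case$landmarks, res$chain_parametric)$mean
  nonpar <- tre(def$landmarks, case$landmarks, res$chain)$mean
  expect_lt(nonpar, 0.4 * before)
  expect_lte(nonpar, par + 1e-6)
  expect_descent(res)
  # chain consistency: re-applying the stored chain reproduces the
  # deformed template bit-for-bit
  again <- resample(case$mask, res$chain, geometry(def$mask))
  expect_identical(again$data, res$deformed_template$data)
})
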