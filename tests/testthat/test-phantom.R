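test_that("phantom generation is deterministic and respects its spec", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 9, n_landmarks = 10)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(unclass(a$landmarks), unclass(b$landmarks))
  expect_equal(nrow(a$landmarks), 10)
  # every landmark's nearest voxel lies inside the mask
  vox <- round(world_to_voxel(a$volume, a$landmarks)) + 1
  expect_true(all(a$mask$data[vox] == 1))
})

test_that("sheet voxels are brighter than background (brute-force means)", {
  case <- generate_phantom(phantom_spec(shape = c(24, 24, 24), seed = 2,
                                        sheet_intensity_mean = 180,
                                        background_intensity_mean = 60,
                                        speckle_scale = 0.3))
  d <- dim(case$volume$data)
  s_in <- 0; n_in <- 0; s_out <- 0; n_out <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (case$mask$data[i, j, k] == 1) {
      s_in <- s_in + case$volume$data[i, j, k]; n_in <- n_in + 1
    } else {
      s_out <- s_out + case$volume$data[i, j, k]; n_out <- n_out + 1
    }
  }
  expect_gt(s_in / n_in, s_out / n_out)
  st <- mask_stats(case$volume, case$mask)
  expect_equal(st$mean_inside, s_in / n_in, tolerance = 1e-12)
  expect_equal(st$mean_outside, s_out / n_out, tolerance = 1e-12)
})

test_that("landmark capacity errors when the mask cannot hold them", {
  spec <- phantom_spec(shape = c(16, 16, 16), seed = 1, n_sheets = 1,
                       sheet_thickness = 0.5, n_landmarks = 10000)
  expect_error(generate_phantom(spec), "capacity")
})

test_that("identity deformation reproduces the case exactly", {
  case <- small_case(seed = 4, shape = 24)
  idm <- deform_phantom(case, rigid_transform(center = volume_center(case$volume)))
  expect_lt(max(abs(idm$volume$data - case$volume$data)), 1e-9)
  expect_identical(unclass(idm$landmarks), unclass(case$landmarks))
})

test_that("a (3,4,0) mm translation moves every landmark by 5 mm", {
  case <- small_case(seed = 5, shape = 32)
  mot <- rigid_transform(c(3, 4, 0), center = volume_center(case$volume))
  def <- deform_phantom(case, mot)
  d <- sqrt(rowSums((unclass(def$landmarks) - unclass(case$landmarks))^2))
  expect_equal(d, rep(5, length(d)), tolerance = 1e-12)
})

test_that("field-deformed landmarks equal per-point evaluation of the motion", {
  case <- small_case(seed = 6, shape = 32)
  f <- random_smooth_field(case$volume, max_mm = 3, seed = 60)
  def <- deform_phantom(case, f)
  for (i in seq_len(nrow(case$landmarks))) {
    p <- matrix(unclass(case$landmarks)[i, ], 1)
    expect_equal(unclass(def$landmarks)[i, ],
                 drop(apply_transform(f, p)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("rigid deform-then-inverse returns landmarks within 1e-6 mm", {
  case <- small_case(seed = 7, shape = 24)
  mot <- rigid_transform(c(1, -2, 0.5), c(0.03, 0.02, -0.04),
                         center = volume_center(case$volume))
  back <- deform_phantom(deform_phantom(case, mot), rigid_invert(mot))
  expect_lt(max(abs(unclass(back$landmarks) - unclass(case$landmarks))), 1e-6)
})

test_that("contrast separation persists after deformation", {
  case <- small_case(seed = 8, shape = 32)
  f <- random_smooth_field(case$volume, max_mm = 4, seed = 80)
  def <- deform_phantom(case, f)
  st <- mask_stats(def$volume, def$mask)
  expect_gt(st$mean_inside, st$mean_outside)
})

test_that("motions that evict most of the mask raise a coverage error", {
  case <- small_case(seed = 9, shape = 24)
  mot <- rigid_transform(c(100, 0, 0), center = volume_center(case$volume))
  expect_error(deform_phantom(case, mot), "coverage")
})

test_that("simulated resection removes mask inside the cavity, leaves rest", {
  case <- small_case(seed = 10, shape = 32)
  ctr <- volume_center(case$volume)
  cav <- cavity_spec(ctr, radius = 4, rim_intensity_mean = 180,
                     rim_thickness = 1.5)
  res <- simulate_resection(case, cav)
  expect_lt(sum(res$mask$data), sum(case$mask$data))
  # outside cavity + rim: untouched
  pts <- grid_points(geometry(case$volume))
  dist <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  outside <- dist > cav$radius + cav$rim_thickness
  expect_identical(res$volume$data[outside], case$volume$data[outside])
  expect_identical(res$mask$data[outside], case$mask$data[outside])
  # rim intensity ~ sheet intensity (brute-force shell mean), within 10%
  shell <- which(dist > cav$radius & dist <= cav$radius + cav$rim_thickness)
  s <- 0
  for (i in shell) s <- s + res$volume$data[i]
  expect_lt(abs(s / length(shell) - case$spec$sheet_intensity_mean) /
              case$spec$sheet_intensity_mean, 0.1)
})

test_that("a cavity missing the mask leaves the mask unchanged", {
  case <- small_case(seed = 11, shape = 32)
  # center on a corner region far from any mask voxel if possible;
  # construct one guaranteed empty by using a tiny radius at a non-mask voxel
  bg <- which(case$mask$data == 0)[1]
  ctr <- voxel_to_world(case$volume, matrix(arrayInd(bg, dim(case$mask$data)) - 1, 1))
  cav <- cavity_spec(drop(ctr), radius = 0.2)
  res <- simulate_resection(case, cav)
  expect_identical(res$mask$data, case$mask$data)
  # but a sphere fully outside the volume is rejected
  expect_error(simulate_resection(case, cavity_spec(c(1e4, 1e4, 1e4), 1)),
               "intersect")
})
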