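test_that("TRE has its closed-form values and checks correspondence", {
  lm <- landmark_set(matrix(rnorm(30), 10, 3))
  r0 <- tre(lm, lm)
  expect_equal(r0$distances, rep(0, 10))
  expect_equal(r0$n_landmarks, 10)
  shifted <- landmark_set(sweep(unclass(lm), 2, c(3, 4, 0), "+"))
  r1 <- tre(lm, shifted)
  expect_equal(r1$mean, 5)
  expect_equal(r1$sd, 0)
  expect_equal(r1$min, 5)
  expect_equal(r1$max, 5)
  expect_error(tre(lm, landmark_set(matrix(0, 4, 3))), "correspondence")
})

test_that("TRE through a rigid chain matches the per-point oracle", {
  set.seed(50)
  a <- landmark_set(matrix(rnorm(24, sd = 10), 8, 3))
  b <- landmark_set(matrix(rnorm(24, sd = 10), 8, 3))
  chain <- transform_chain(rigid_transform(c(1, 2, -1), c(0.1, -0.05, 0.2),
                                           c(3, 0, 1)))
  expect_equal(tre(a, b, chain)$distances, oracle_tre(a, b, chain),
               tolerance = 1e-12)
})

test_that("TRE is invariant under conjugation by a global rigid motion", {
  set.seed(51)
  a <- landmark_set(matrix(rnorm(24, sd = 10), 8, 3))
  b <- landmark_set(matrix(rnorm(24, sd = 10), 8, 3))
  chain <- transform_chain(rigid_transform(c(1, 0, 2), c(0.05, 0.1, 0), c(0, 0, 0)))
  g <- rigid_transform(c(-4, 2, 7), c(0.3, -0.2, 0.15), c(1, 5, -2))
  # move both landmark sets by g and conjugate the chain: g o chain o g^-1
  conj <- transform_chain(rigid_invert(g), chain[[1]], g)
  r1 <- tre(a, b, chain)
  r2 <- tre(apply_transform(g, a), apply_transform(g, b), conj)
  expect_equal(r1$distances, r2$distances, tolerance = 1e-9)
})

test_that("dice has its closed-form values", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1
  b <- array(0, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1
  ma <- us_mask(a); mb <- us_mask(b)
  expect_equal(dice(ma, ma), 1)
  expect_equal(dice(ma, mb), 0.5)                 # 2*4 / (8+8)
  empty <- mask_like(ma, array(0, c(4, 4, 4)))
  expect_equal(dice(empty, empty), 1)
})

test_that("correspondence-restricted dice discards unmatched components", {
  manual <- array(0, c(12, 12, 12)); manual[2:4, 2:4, 2:4] <- 1
  pred <- manual
  pred[8:10, 8:10, 8:10] <- 1                     # far disjoint blob
  mm <- us_mask(manual); mp <- us_mask(pred)
  expect_lt(dice(mp, mm), 1)
  expect_equal(dice_correspondence_restricted(mp, mm), 1)
  # no component touching the manual mask -> 0
  off <- array(0, c(12, 12, 12)); off[8:10, 8:10, 8:10] <- 1
  expect_equal(dice_correspondence_restricted(us_mask(off), mm), 0)
  # mixed case equals dice after manual component bookkeeping
  pred2 <- array(0, c(12, 12, 12))
  pred2[2:4, 2:5, 2:4] <- 1                       # overlaps manual, extra slab
  pred2[10:11, 2:3, 2:3] <- 1                     # disjoint
  kept <- array(0, c(12, 12, 12)); kept[2:4, 2:5, 2:4] <- 1
  expect_equal(dice_correspondence_restricted(us_mask(pred2), mm),
               dice(us_mask(kept), mm))
})

test_that("restricted dice is never below plain dice (random masks)", {
  set.seed(52)
  for (i in 1:10) {
    pr <- random_mask_pair(c(8, 8, 8), p = 0.2)
    expect_gte(dice_correspondence_restricted(pr$a, pr$b) + 1e-12,
               dice(pr$a, pr$b))
  }
})

test_that("mask_stats handles constants, checkerboards and empty masks", {
  const <- us_volume(array(3.5, c(4, 4, 4)))
  half <- array(0, c(4, 4, 4)); half[1:2, , ] <- 1
  st <- mask_stats(const, mask_like(const, half))
  expect_equal(st$mean_inside, 3.5)
  expect_equal(st$mean_outside, 3.5)
  chk <- array((outer(1:4, outer(1:4, 1:4, "+"), "+")) %% 2, c(4, 4, 4))
  v <- us_volume(chk, spacing = c(0.5, 0.5, 0.5))
  st2 <- mask_stats(v, mask_like(v, chk))
  expect_equal(st2$mean_inside, 1)
  expect_equal(st2$mean_outside, 0)
  expect_equal(st2$volume_mm3, sum(chk) * 0.125)
  st3 <- mask_stats(const, mask_like(const, array(0, c(4, 4, 4))))
  expect_true(is.na(st3$mean_inside))
})

test_that("pearson is exact on lines and matches the long-hand formula", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(53)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("capture range follows first-failure semantics on success tables", {
  r <- capture_range_from_table(c(1, 2, 3), c(5, 5, 3), 5, required = 0.8)
  expect_equal(as.numeric(r), 2)
  expect_false(attr(r, "censored"))
  r2 <- capture_range_from_table(c(1, 2, 3), c(5, 5, 5), 5)
  expect_equal(as.numeric(r2), 3)
  expect_true(attr(r2, "censored"))
  r3 <- capture_range_from_table(c(1, 2), c(0, 2), 5)
  expect_equal(as.numeric(r3), 0)
  # a later recovery does not extend the range past the first failure
  r4 <- capture_range_from_table(c(1, 2, 3), c(5, 3, 5), 5)
  expect_equal(as.numeric(r4), 1)
})

test_that("capture range is monotone in the required success fraction", {
  succ <- c(10, 9, 7, 5, 1)
  offs <- 1:5
  rng <- sapply(c(1, 0.9, 0.7, 0.5, 0.1),
                function(q) as.numeric(capture_range_from_table(offs, succ, 10, q)))
  expect_true(all(diff(rng) >= 0))
})
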