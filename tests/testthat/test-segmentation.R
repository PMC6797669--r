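test_that("patch tiles have the configured core and context shapes", {
  cfg <- unet_config(patch_size = c(12, 12, 12), padding = c(2, 2, 2))
  case <- small_case(seed = 40, shape = 24)
  pts <- sample_patches(case, cfg, 5, seed = 1)
  tg <- usreg:::tile_geometry(cfg)
  expect_equal(tg$input, c(16, 16, 16))          # 12 + 2*2, already /4
  for (p in pts) {
    expect_equal(dim(p$input), c(16, 16, 16))
    expect_equal(dim(p$label), c(12, 12, 12))
  }
  # the stated (30, 30, 30) + (8, 8, 8) setup resolves to a 48^3 tile
  tg30 <- usreg:::tile_geometry(unet_config())
  expect_equal(tg30$input, c(48, 48, 48))
  expect_equal(tg30$core, c(30, 30, 30))
})

test_that("patch sampling is seed-deterministic and labels match the core", {
  cfg <- unet_config(patch_size = c(8, 8, 8), padding = c(2, 2, 2),
                     balanced_sampling = TRUE)
  case <- small_case(seed = 41, shape = 24)
  a <- sample_patches(case, cfg, 15, seed = 7)
  b <- sample_patches(case, cfg, 15, seed = 7)
  expect_identical(lapply(a, `[[`, "start"), lapply(b, `[[`, "start"))
  expect_identical(lapply(a, `[[`, "input"), lapply(b, `[[`, "input"))
  # labels are the mask core at the sampled origin
  for (p in a) {
    s <- p$start
    expect_identical(p$label,
                     case$mask$data[s[1] + 1:8, s[2] + 1:8, s[3] + 1:8])
  }
  expect_error(sample_patches(case, cfg, 0), "> 0")
})

test_that("unbalanced sampling in a mask-free region yields empty labels", {
  vol <- us_volume(array(runif(24^3), c(24, 24, 24)))
  msk <- mask_like(vol, array(0, c(24, 24, 24)))
  cfg <- unet_config(patch_size = c(8, 8, 8), padding = c(0, 0, 0),
                     balanced_sampling = FALSE)
  pts <- sample_patches(list(volume = vol, mask = msk), cfg, 5, seed = 3)
  for (p in pts) expect_true(all(p$label == 0))
})

test_that("network gradients match finite differences", {
  set.seed(42)
  cfg <- unet_config(resolution_steps = 1, base_channels = 2,
                     patch_size = c(6, 6, 6), padding = c(1, 1, 1),
                     dropout_rate = 0)
  tg <- usreg:::tile_geometry(cfg)
  params <- usreg:::unet_init_params(cfg$base_channels, cfg$resolution_steps)
  cidx <- usreg:::core_indices(tg)
  X <- matrix(rnorm(prod(tg$input)), ncol = 1)
  y <- as.numeric(runif(length(cidx)) < 0.3)
  loss_of <- function(p) {
    out <- usreg:::unet_fwd(p, X, tg$input, 0, FALSE)
    usreg:::tile_loss(out$logits[cidx], y, "bce")$value
  }
  out <- usreg:::unet_fwd(params, X, tg$input, 0, FALSE)
  lo <- usreg:::tile_loss(out$logits[cidx], y, "bce")
  dlog <- numeric(length(out$logits)); dlog[cidx] <- lo$dlogits
  grads <- usreg:::unet_bwd(params, out$caches, dlog)

  get_leaf <- function(tree, path) { for (k in path) tree <- tree[[k]]; tree }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) tree[[path[[1]]]] <- val
    else tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  h <- 1e-5
  probe <- list(list("enc", 1L, "c1", "W"), list("enc", 1L, "c2", "gamma"),
                list("bottom", "c1", "b"), list("dec", 1L, "c1", "W"),
                list("dec", 1L, "up", "b"), list("final", "W"))
  for (path in probe) {
    g_an <- get_leaf(grads, path)
    leaf <- get_leaf(params, path)
    i <- sample(length(leaf), 1)
    lp <- leaf; lp[i] <- lp[i] + h
    lm <- leaf; lm[i] <- lm[i] - h
    num <- (loss_of(set_leaf(params, path, lp)) -
              loss_of(set_leaf(params, path, lm))) / (2 * h)
    expect_equal(g_an[i], num, tolerance = 1e-4,
                 label = paste("grad", paste(unlist(path), collapse = "/")))
  }
})

test_that("training bookkeeping: history length, checkpoint, determinism", {
  case <- small_case(seed = 43, shape = 24)
  cfg <- unet_config(patch_size = c(8, 8, 8), padding = c(2, 2, 2),
                     base_channels = 4, batch_size = 2, val_samples = 4,
                     val_interval = 5, max_iterations = 15, seed = 5)
  split <- dataset_split(train = list(case), validation = list(case))
  m1 <- train_unet(split, cfg)
  expect_equal(nrow(m1$history), 15 %/% 5)
  expect_equal(m1$best_val_jaccard, max(m1$history$val_jaccard))
  expect_equal(m1$selected_checkpoint,
               m1$history$iteration[which.max(m1$history$val_jaccard)])
  m2 <- train_unet(split, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$selected_checkpoint, m2$selected_checkpoint)
})

test_that("dataset splits must be disjoint when named", {
  a <- small_case(seed = 44, shape = 16)
  expect_error(dataset_split(train = list(v1 = a), validation = list(v1 = a)),
               "disjoint")
  expect_silent(dataset_split(train = list(v1 = a), validation = list(v2 = a)))
})

test_that("prediction outputs probabilities on the input grid and stitching is consistent", {
  case <- small_case(seed = 45, shape = 16)
  cfg <- unet_config(patch_size = c(16, 16, 16), padding = c(2, 2, 2),
                     base_channels = 4, batch_size = 2, val_samples = 2,
                     val_interval = 5, max_iterations = 5, seed = 6)
  split <- dataset_split(train = list(case), validation = list(case))
  model <- train_unet(split, cfg)
  pred <- predict_mask(model, case$volume)
  expect_equal(dim(pred$probability$data), dim(case$volume$data))
  expect_true(all(pred$probability$data >= 0 & pred$probability$data <= 1))
  expect_true(all(pred$binary$data %in% c(0, 1)))
  expect_true(same_geometry(pred$binary, case$volume))
  # a volume that fits a single tile: stitched output equals one forward pass
  tgm <- usreg:::tile_geometry(cfg)
  tile <- usreg:::extract_tile(usreg:::standardize_volume(case$volume),
                               c(0L, 0L, 0L) - tgm$pad_lo, tgm$input)
  out <- usreg:::unet_fwd(model$params, matrix(as.numeric(tile), ncol = 1),
                          tgm$input, 0, FALSE)
  p_core <- 1 / (1 + exp(-out$logits[usreg:::core_indices(tgm)]))
  expect_equal(as.numeric(pred$probability$data), as.numeric(p_core),
               tolerance = 1e-12)
  # volumes smaller than a core tile are rejected
  tiny <- us_volume(array(0, c(8, 8, 8)))
  expect_error(predict_mask(model, tiny), "smaller")
})

test_that("jaccard has its closed-form values", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1   # 8 voxels
  b <- array(0, c(4, 4, 4)); b[2:3, 1:2, 1:2] <- 1   # 8 voxels, overlap 4
  ma <- us_mask(a); mb <- us_mask(b)
  expect_equal(jaccard(ma, ma), 1)
  expect_equal(jaccard(ma, mask_like(ma, 1 - a)), 0)
  expect_equal(jaccard(ma, mb), 4 / 12)
  empty <- mask_like(ma, array(0, c(4, 4, 4)))
  expect_equal(jaccard(empty, empty), 1)
  expect_error(jaccard(ma, us_mask(a, spacing = c(2, 2, 2))), "geometry")
})
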