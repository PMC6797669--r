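#' Configuration of the 3D U-Net segmenter
#'
#' Defaults follow the training setup used for intraoperative ultrasound:
#' analysis and synthesis paths with two resolution steps, dropout 0.4 on
#' the synthesis path only, patch size (30,30,30) with a context padding of
#' (8,8,8) per side, batches of 15 samples, learning rate 0.001, and model
#' selection by the best validation Jaccard index computed on
#' `val_samples` patches every `val_interval` iterations.
#'
#' The network input tile is `patch_size + 2 * padding`, mirror-extended to
#' the next multiple of `2^resolution_steps` per axis so that the pooling
#' arithmetic closes; predictions are stitched from the `patch_size` cores
#' only.
#'
#' @param resolution_steps pooling steps in each path (default 2).
#' @param dropout_rate dropout before each synthesis-path convolution
#'   (default 0.4).
#' @param base_channels channels at the finest level, doubling per step
#'   (default 16).
#' @param patch_size predicted core size in voxels (default `c(30,30,30)`).
#' @param padding per-side context border in voxels (default `c(8,8,8)`).
#' @param batch_size patches per training iteration (default 15).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param val_samples validation patches per evaluation (default 75).
#' @param val_interval iterations between validation evaluations
#'   (default 100).
#' @param max_iterations total training iterations (default 1000).
#' @param loss `"bce"` (voxel-wise binary cross-entropy, default) or
#'   `"soft_dice"`.
#' @param balanced_sampling draw 50% of patch centers from mask voxels
#'   (default TRUE; the sheets cover only a few percent of the volume and
#'   unbalanced sampling stalls training).
#' @param threshold binarization threshold for predictions (default 0.5).
#' @param early_stop_val_jaccard optionally stop training once the
#'   validation Jaccard reaches this value (NULL = never).
#' @param seed RNG seed covering initialization, sampling and dropout.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(resolution_steps = 2, dropout_rate = 0.4,
                        base_channels = 16, patch_size = c(30, 30, 30),
                        padding = c(8, 8, 8), batch_size = 15,
                        learning_rate = 0.001, val_samples = 75,
                        val_interval = 100, max_iterations = 1000,
                        loss = c("bce", "soft_dice"),
                        balanced_sampling = TRUE, threshold = 0.5,
                        early_stop_val_jaccard = NULL, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(resolution_steps >= 1, dropout_rate >= 0, dropout_rate < 1,
            base_channels >= 1, length(patch_size) == 3, all(patch_size >= 4),
            length(padding) == 3, all(padding >= 0), batch_size >= 1,
            learning_rate > 0, val_samples >= 1, val_interval >= 1,
            max_iterations >= 1)
  structure(list(resolution_steps = as.integer(resolution_steps),
                 dropout_rate = dropout_rate,
                 base_channels = as.integer(base_channels),
                 patch_size = as.integer(patch_size),
                 padding = as.integer(padding),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_samples = as.integer(val_samples),
                 val_interval = as.integer(val_interval),
                 max_iterations = as.integer(max_iterations),
                 loss = loss, balanced_sampling = balanced_sampling,
                 threshold = threshold,
                 early_stop_val_jaccard = early_stop_val_jaccard,
                 seed = as.integer(seed)),
            class = "unet_config")
}

# Resolve core/padding into the actual network tile: input = core + 2*pad,
# mirror-extended up to the next multiple of 2^steps (split low/high).
tile_geometry <- function(cfg) {
  core <- cfg$patch_size
  raw <- core + 2L * cfg$padding
  mult <- 2L^cfg$resolution_steps
  extra <- (mult - raw %% mult) %% mult
  lo <- cfg$padding + extra %/% 2L
  hi <- cfg$padding + extra - extra %/% 2L
  list(core = core, pad_lo = lo, pad_hi = hi, input = core + lo + hi)
}

# Mirror-reflect 0-based indices into [0, n-1] (reflection about end nodes).
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

# Extract a tile [start, start+size) per axis with mirror extension.
extract_tile <- function(arr, start, size) {
  d <- dim(arr)
  ix <- mirror_index(start[1] + seq_len(size[1]) - 1L, d[1]) + 1L
  iy <- mirror_index(start[2] + seq_len(size[2]) - 1L, d[2]) + 1L
  iz <- mirror_index(start[3] + seq_len(size[3]) - 1L, d[3]) + 1L
  arr[ix, iy, iz, drop = FALSE]
}

standardize_volume <- function(v) {
  x <- v$data
  s <- stats::sd(x)
  (x - mean(x)) / if (s > 0) s else 1
}

#' Sample training patches from a volume/mask pair
#'
#' Each input tile is the `patch_size` core plus the per-side context
#' border (mirror-extended at volume boundaries); the label tile is the
#' core of the mask. With balanced sampling, half of the patch centers are
#' drawn from mask voxels. Deterministic given `seed`.
#'
#' @param case a `phantom_case`, or a list with elements `volume`
#'   ([us_volume()]) and `mask` ([us_mask()]).
#' @param cfg a [unet_config()].
#' @param n number of patches (> 0).
#' @param seed optional seed; by default the caller's RNG stream is used.
#' @return List of `n` lists with `input` (standardized intensity tile),
#'   `label` (core mask tile) and `start` (0-based core origin).
#' @export
sample_patches <- function(case, cfg, n, seed = NULL) {
  if (n <= 0) stop("n must be > 0")
  run <- function() {
    vol <- standardize_volume(case$volume)
    msk <- case$mask$data
    d <- dim(vol)
    tg <- tile_geometry(cfg)
    if (any(d < tg$core))
      stop("volume smaller than one patch core on some axis")
    midx <- which(msk > 0)
    lapply(seq_len(n), function(i) {
      balanced <- cfg$balanced_sampling && length(midx) > 0 &&
        runif(1) < 0.5
      center <- if (balanced) {
        arrayInd(midx[sample.int(length(midx), 1L)], d) - 1L
      } else {
        cbind(sample.int(d[1], 1L), sample.int(d[2], 1L),
              sample.int(d[3], 1L)) - 1L
      }
      start <- pmin(pmax(as.integer(center) - tg$core %/% 2L, 0L), d - tg$core)
      list(input = extract_tile(vol, start - tg$pad_lo, tg$input),
           label = extract_tile(msk, start, tg$core),
           start = start)
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# linear indices of the core voxels inside the network input tile
core_indices <- function(tg) {
  inp <- tg$input
  ix <- tg$pad_lo[1] + seq_len(tg$core[1])
  iy <- tg$pad_lo[2] + seq_len(tg$core[2])
  iz <- tg$pad_lo[3] + seq_len(tg$core[3])
  idx <- array(seq_len(prod(inp)), inp)
  as.integer(idx[ix, iy, iz])
}

# loss value and d(loss)/d(logits) on the core voxels; mean-per-voxel scale
tile_loss <- function(logits_core, label_core, loss) {
  p <- 1 / (1 + exp(-logits_core))
  y <- as.numeric(label_core)
  n <- length(y)
  if (loss == "bce") {
    eps <- 1e-12
    value <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    dlog <- (p - y) / n
  } else {                               # soft Dice
    eps <- 1
    num <- 2 * sum(p * y) + eps
    den <- sum(p) + sum(y) + eps
    value <- 1 - num / den
    dnum_dp <- 2 * y
    dp <- -(dnum_dp * den - num) / den^2
    dlog <- dp * p * (1 - p)
  }
  list(value = value, dlogits = dlog)
}

#' Split a dataset into train/validation/test case lists
#'
#' @param train,validation,test lists of cases (each a `phantom_case` or a
#'   `list(volume, mask)`); when named, names must be pairwise disjoint.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train, validation, test = list()) {
  nm <- c(names(train), names(validation), names(test))
  if (!is.null(nm) && length(nm) && anyDuplicated(nm[nzchar(nm)]))
    stop("dataset split sets must be pairwise disjoint (duplicated case names)")
  structure(list(train = train, validation = validation, test = test),
            class = "dataset_split")
}

#' Train the 3D U-Net on a dataset split
#'
#' Optimizes the voxel-wise segmentation loss with Adam over patches
#' sampled from the training cases. Every `cfg$val_interval` iterations the
#' mean Jaccard index over a fixed set of `cfg$val_samples` validation
#' patches is recorded and the parameters are checkpointed; the returned
#' model carries the checkpoint with the best validation Jaccard.
#'
#' @param split a [dataset_split()] with non-empty train and validation.
#' @param cfg a [unet_config()].
#' @return An object of class `trained_unet`: list with `params` (best
#'   checkpoint), `config`, `history` (data.frame: iteration, loss,
#'   val_jaccard) and `selected_checkpoint` (iteration of the best
#'   validation Jaccard).
#' @export
train_unet <- function(split, cfg) {
  stopifnot(inherits(split, "dataset_split"), inherits(cfg, "unet_config"))
  if (!length(split$train) || !length(split$validation))
    stop("train and validation sets must be non-empty")
  with_seed(cfg$seed, {
    tg <- tile_geometry(cfg)
    cidx <- core_indices(tg)
    params <- unet_init_params(cfg$base_channels, cfg$resolution_steps)
    opt <- adam_init(params)

    # fixed validation patches: comparable across checkpoints
    val_patches <- unlist(lapply(seq_along(split$validation), function(i) {
      k <- cfg$val_samples %/% length(split$validation) +
        (i <= cfg$val_samples %% length(split$validation))
      if (k > 0) sample_patches(split$validation[[i]], cfg, k) else list()
    }), recursive = FALSE)

    val_jaccard <- function(p) {
      js <- vapply(val_patches, function(pt) {
        out <- unet_fwd(p, matrix(as.numeric(pt$input), ncol = 1),
                        tg$input, 0, FALSE)
        pred <- out$logits[cidx] > log(cfg$threshold / (1 - cfg$threshold))
        truth <- as.numeric(pt$label) > 0.5
        uni <- sum(pred | truth)
        if (uni == 0) 1 else sum(pred & truth) / uni
      }, 0)
      mean(js)
    }

    history <- data.frame(iteration = integer(), loss = numeric(),
                          val_jaccard = numeric())
    best <- list(jaccard = -Inf, params = params, iteration = 0L)
    loss_acc <- numeric()

    for (it in seq_len(cfg$max_iterations)) {
      gsum <- NULL
      lsum <- 0
      for (s in seq_len(cfg$batch_size)) {
        case <- split$train[[sample.int(length(split$train), 1L)]]
        pt <- sample_patches(case, cfg, 1L)[[1]]
        fwd <- unet_fwd(params, matrix(as.numeric(pt$input), ncol = 1),
                        tg$input, cfg$dropout_rate, TRUE)
        lo <- tile_loss(fwd$logits[cidx], pt$label, cfg$loss)
        if (!is.finite(lo$value))
          stop("training error: non-finite loss at iteration ", it)
        lsum <- lsum + lo$value
        dlogits <- numeric(length(fwd$logits))
        dlogits[cidx] <- lo$dlogits
        g <- unet_bwd(params, fwd$caches, dlogits)
        gsum <- if (is.null(gsum)) g else tree_map2(`+`, gsum, g)
      }
      gmean <- tree_map(function(x) x / cfg$batch_size, gsum)
      st <- adam_step(params, gmean, opt, cfg$learning_rate)
      params <- st$params; opt <- st$state
      loss_acc <- c(loss_acc, lsum / cfg$batch_size)

      if (it %% cfg$val_interval == 0) {
        vj <- val_jaccard(params)
        history <- rbind(history,
                         data.frame(iteration = it, loss = mean(loss_acc),
                                    val_jaccard = vj))
        loss_acc <- numeric()
        if (vj > best$jaccard)
          best <- list(jaccard = vj, params = params, iteration = it)
        if (!is.null(cfg$early_stop_val_jaccard) &&
            vj >= cfg$early_stop_val_jaccard) break
      }
    }
    structure(list(params = best$params, config = cfg, history = history,
                   selected_checkpoint = best$iteration,
                   best_val_jaccard = best$jaccard),
              class = "trained_unet")
  })
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("<trained_unet> %d-channel, %d steps; best val Jaccard %.3f at iteration %d\n",
              x$config$base_channels, x$config$resolution_steps,
              x$best_val_jaccard, x$selected_checkpoint))
  invisible(x)
}

#' Segment a volume with a trained U-Net
#'
#' Tiles the volume into `patch_size` cores with mirror-extended context,
#' stitches the core predictions (no overlap except where a final partial
#' tile is shifted inward to fit) and returns both the probability output
#' and its binarization.
#'
#' @param model a [train_unet()] result.
#' @param v a [us_volume()].
#' @param threshold binarization threshold (default from the config).
#' @return List with `probability` and `binary` [us_mask()]s, both on
#'   `v`'s grid.
#' @export
predict_mask <- function(model, v, threshold = NULL) {
  stopifnot(inherits(model, "trained_unet"), inherits(v, "us_volume"))
  cfg <- model$config
  threshold <- threshold %||% cfg$threshold
  tg <- tile_geometry(cfg)
  cidx <- core_indices(tg)
  d <- dim(v$data)
  if (any(d < tg$core))
    stop("volume smaller than one patch core: ", paste(d, collapse = "x"))
  vol <- standardize_volume(v)
  starts <- lapply(1:3, function(a) {
    s <- seq(0L, d[a] - tg$core[a], by = tg$core[a])
    unique(c(s, d[a] - tg$core[a]))
  })
  prob <- array(0, d)
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    st <- c(sx, sy, sz)
    tile <- extract_tile(vol, st - tg$pad_lo, tg$input)
    out <- unet_fwd(model$params, matrix(as.numeric(tile), ncol = 1),
                    tg$input, 0, FALSE)
    p_core <- array(1 / (1 + exp(-out$logits[cidx])), tg$core)
    prob[st[1] + seq_len(tg$core[1]), st[2] + seq_len(tg$core[2]),
         st[3] + seq_len(tg$core[3])] <- p_core
  }
  list(probability = us_mask(prob, v$spacing, v$origin, v$orientation,
                             kind = "probability"),
       binary = us_mask((prob >= threshold) * 1, v$spacing, v$origin,
                        v$orientation, kind = "binary"))
}

#' Jaccard index between two binary masks
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are empty.
#'
#' @param a,b binary [us_mask()]s on the same grid.
#' @return Fraction in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  A <- a$data > 0.5; B <- b$data > 0.5
  uni <- sum(A | B)
  if (uni == 0) return(1)
  sum(A & B) / uni
}
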