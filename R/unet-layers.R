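# Internal layer primitives of the 3D U-Net. Activations are stored as
# (#voxels x #channels) matrices in R-array voxel order; the spatial dims
# travel alongside. Convolutions are 3x3x3 'same' (zero padded), pooling is
# 2x2x2 max, upsampling is a 2x2x2 stride-2 transposed convolution.
# Forward passes return a cache consumed by the matching backward pass.

he_init <- function(n_out, n_in_eff, n_cols) {
  matrix(rnorm(n_out * n_cols, sd = sqrt(2 / n_in_eff)), n_out, n_cols)
}

new_conv <- function(cin, cout) {
  list(W = he_init(cout, 27 * cin, 27 * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

new_upconv <- function(cin, cout) {
  list(W = lapply(1:8, function(d) he_init(cout, cin, cin)), b = numeric(cout))
}

new_final <- function(cin) {
  list(W = matrix(rnorm(cin, sd = sqrt(1 / cin)), 1, cin), b = 0)
}

IN_EPS <- 1e-5

# conv 3^3 -> instance norm -> ReLU (one "block" of a level)
conv_block_fwd <- function(p, X, dims, drop_p = 0, train = FALSE) {
  cache <- list(dims = dims)
  if (train && drop_p > 0) {
    keep <- matrix(runif(length(X)) >= drop_p, nrow(X), ncol(X)) / (1 - drop_p)
    X <- X * keep
    cache$drop <- keep
  }
  cache$X <- X
  Z <- cpp_conv3_fwd(X, as.integer(dims), p$W, p$b)
  mu <- colMeans(Z)
  zc <- sweep(Z, 2, mu)
  v <- colMeans(zc^2)
  xhat <- sweep(zc, 2, sqrt(v + IN_EPS), "/")
  A <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  relu <- A > 0
  cache$xhat <- xhat; cache$v <- v; cache$relu <- relu
  list(Y = A * relu, cache = cache)
}

conv_block_bwd <- function(p, cache, dY) {
  dA <- dY * cache$relu
  xhat <- cache$xhat
  dgamma <- colSums(dA * xhat)
  dbeta <- colSums(dA)
  dxhat <- sweep(dA, 2, p$gamma, "*")
  inv_sd <- 1 / sqrt(cache$v + IN_EPS)
  dZ <- sweep(dxhat, 2, colMeans(dxhat)) -
    sweep(xhat, 2, colMeans(dxhat * xhat), "*")
  dZ <- sweep(dZ, 2, inv_sd, "*")
  g <- cpp_conv3_bwd(cache$X, as.integer(cache$dims), p$W, dZ)
  dX <- g$dX
  if (!is.null(cache$drop)) dX <- dX * cache$drop
  list(dX = dX, grads = list(W = g$dW, b = as.numeric(g$db),
                             gamma = dgamma, beta = dbeta))
}

# 1-based output linear indices of each of the 8 stride-2 offsets
upconv_pos <- function(dims_in) {
  mx <- dims_in[1]; my <- dims_in[2]; mz <- dims_in[3]
  i <- rep.int(seq_len(mx) - 1L, my * mz)
  j <- rep.int(rep(seq_len(my) - 1L, each = mx), mz)
  k <- rep(seq_len(mz) - 1L, each = mx * my)
  out <- matrix(0L, mx * my * mz, 8)
  d <- 0L
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    d <- d + 1L
    out[, d] <- (2L * i + di) + 2L * mx * (2L * j + dj) +
      4L * mx * my * (2L * k + dk) + 1L
  }
  out
}

upconv_fwd <- function(p, X, dims_in) {
  pos <- upconv_pos(dims_in)
  cout <- length(p$b)
  Y <- matrix(0, 8 * nrow(X), cout)
  for (d in 1:8) Y[pos[, d], ] <- X %*% t(p$W[[d]])
  Y <- sweep(Y, 2, p$b, "+")
  list(Y = Y, cache = list(X = X, pos = pos, dims_out = dims_in * 2L))
}

upconv_bwd <- function(p, cache, dY) {
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  dW <- vector("list", 8)
  for (d in 1:8) {
    dYd <- dY[cache$pos[, d], , drop = FALSE]
    dW[[d]] <- t(dYd) %*% cache$X
    dX <- dX + dYd %*% p$W[[d]]
  }
  list(dX = dX, grads = list(W = dW, b = colSums(dY)))
}

# Build all parameters of a U-Net with `steps` resolution steps.
unet_init_params <- function(base_channels, steps) {
  ch <- base_channels * 2^(0:steps)
  enc <- lapply(seq_len(steps), function(l) {
    cin <- if (l == 1) 1 else ch[l - 1]
    list(c1 = new_conv(cin, ch[l]), c2 = new_conv(ch[l], ch[l]))
  })
  bottom <- list(c1 = new_conv(ch[steps], ch[steps + 1]),
                 c2 = new_conv(ch[steps + 1], ch[steps + 1]))
  dec <- lapply(rev(seq_len(steps)), function(l) {
    list(up = new_upconv(ch[l + 1], ch[l]),
         c1 = new_conv(2 * ch[l], ch[l]), c2 = new_conv(ch[l], ch[l]))
  })
  list(enc = enc, bottom = bottom, dec = dec,
       final = new_final(ch[1]), steps = steps)
}

# Forward pass on one tile. X: (#voxels x 1) standardized intensities.
unet_fwd <- function(params, X, dims, drop_p = 0, train = FALSE) {
  S <- params$steps
  caches <- list(enc = vector("list", S), dec = vector("list", S))
  skips <- vector("list", S)
  cur <- X; cd <- dims
  for (l in seq_len(S)) {
    b1 <- conv_block_fwd(params$enc[[l]]$c1, cur, cd, 0, train)
    b2 <- conv_block_fwd(params$enc[[l]]$c2, b1$Y, cd, 0, train)
    skips[[l]] <- b2$Y
    pl <- cpp_maxpool3_fwd(b2$Y, as.integer(cd))
    caches$enc[[l]] <- list(b1 = b1$cache, b2 = b2$cache, idx = pl$idx,
                            n_in = nrow(b2$Y), dims = cd)
    cur <- pl$Y; cd <- cd %/% 2L
  }
  b1 <- conv_block_fwd(params$bottom$c1, cur, cd, 0, train)
  b2 <- conv_block_fwd(params$bottom$c2, b1$Y, cd, 0, train)
  caches$bottom <- list(b1 = b1$cache, b2 = b2$cache)
  cur <- b2$Y
  for (i in seq_len(S)) {
    l <- S - i + 1                       # decoder level, coarse to fine
    up <- upconv_fwd(params$dec[[i]]$up, cur, cd)
    cd <- cd * 2L
    cat_in <- cbind(up$Y, skips[[l]])
    b1 <- conv_block_fwd(params$dec[[i]]$c1, cat_in, cd, drop_p, train)
    b2 <- conv_block_fwd(params$dec[[i]]$c2, b1$Y, cd, drop_p, train)
    caches$dec[[i]] <- list(up = up$cache, b1 = b1$cache, b2 = b2$cache,
                            n_up = ncol(up$Y))
    cur <- b2$Y
  }
  logits <- as.numeric(cur %*% t(params$final$W) + params$final$b)
  caches$final_in <- cur
  list(logits = logits, caches = caches)
}

# Backward pass; dlogits is a vector over tile voxels.
unet_bwd <- function(params, caches, dlogits) {
  S <- params$steps
  grads <- list(enc = vector("list", S), dec = vector("list", S))
  dlog <- matrix(dlogits, ncol = 1)
  grads$final <- list(W = t(dlog) %*% caches$final_in, b = sum(dlog))
  dcur <- dlog %*% params$final$W
  for (i in rev(seq_len(S))) {
    cc <- caches$dec[[i]]
    g2 <- conv_block_bwd(params$dec[[i]]$c2, cc$b2, dcur)
    g1 <- conv_block_bwd(params$dec[[i]]$c1, cc$b1, g2$dX)
    dup <- g1$dX[, seq_len(cc$n_up), drop = FALSE]
    dskip <- g1$dX[, -seq_len(cc$n_up), drop = FALSE]
    gu <- upconv_bwd(params$dec[[i]]$up, cc$up, dup)
    grads$dec[[i]] <- list(up = gu$grads, c1 = g1$grads, c2 = g2$grads)
    # stash skip gradient for the matching encoder level
    grads$dec[[i]]$dskip <- dskip
    dcur <- gu$dX
  }
  g2 <- conv_block_bwd(params$bottom$c2, caches$bottom$b2, dcur)
  g1 <- conv_block_bwd(params$bottom$c1, caches$bottom$b1, g2$dX)
  grads$bottom <- list(c1 = g1$grads, c2 = g2$grads)
  dcur <- g1$dX
  for (l in rev(seq_len(S))) {
    cc <- caches$enc[[l]]
    dpool <- cpp_maxpool3_bwd(cc$idx, dcur, cc$n_in)
    i <- S - l + 1                       # decoder slot holding this skip
    dpool <- dpool + grads$dec[[i]]$dskip
    g2 <- conv_block_bwd(params$enc[[l]]$c2, cc$b2, dpool)
    g1 <- conv_block_bwd(params$enc[[l]]$c1, cc$b1, g2$dX)
    grads$enc[[l]] <- list(c1 = g1$grads, c2 = g2$grads)
    dcur <- g1$dX
  }
  for (i in seq_len(S)) grads$dec[[i]]$dskip <- NULL
  grads
}

# --- parameter-tree utilities (used by the Adam update) -------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (n in keys) out[[n]] <- tree_map2(f, a[[n]], b[[n]])
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (n in seq_along(a)) out[[n]] <- tree_map(f, a[[n]])
    out
  } else f(a)
}

# numeric leaves only (skips the `steps` scalar bookkeeping field)
param_tree <- function(p) p[setdiff(names(p), "steps")]

adam_init <- function(params) {
  z <- tree_map(function(x) x * 0, param_tree(params))
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  gt <- grads
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, gt)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, gt)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  pt <- tree_map2(function(p, u) p - lr * u, param_tree(params), upd)
  params[names(pt)] <- pt
  list(params = params, state = state)
}
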