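# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as explicit loops over voxels/points, independent of
# the package's vectorized/C++ code paths they check.

small_case <- function(seed = 1, shape = 32, n_landmarks = 8) {
  generate_phantom(phantom_spec(shape = rep(shape, 3), seed = seed,
                                n_landmarks = n_landmarks))
}

random_mask_pair <- function(dim3, p = 0.3) {
  a <- array(as.numeric(runif(prod(dim3)) < p), dim3)
  b <- array(as.numeric(runif(prod(dim3)) < p), dim3)
  sp <- runif(3, 0.3, 1.2)
  list(a = us_mask(a, sp), b = us_mask(b, sp))
}

oracle_ssd <- function(ref, tmpl) {
  acc <- 0
  d <- dim(ref$data)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    acc <- acc + (tmpl$data[i, j, k] - ref$data[i, j, k])^2
  0.5 * acc * ref$spacing[1] * ref$spacing[2] * ref$spacing[3]
}

oracle_counts <- function(a, b) {
  d <- dim(a$data); ii <- 0; na <- 0; nb <- 0; nu <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    av <- a$data[i, j, k] > 0.5; bv <- b$data[i, j, k] > 0.5
    if (av) na <- na + 1
    if (bv) nb <- nb + 1
    if (av && bv) ii <- ii + 1
    if (av || bv) nu <- nu + 1
  }
  list(inter = ii, na = na, nb = nb, uni = nu)
}

oracle_dice <- function(a, b) {
  cn <- oracle_counts(a, b)
  if (cn$na + cn$nb == 0) 1 else 2 * cn$inter / (cn$na + cn$nb)
}

oracle_jaccard <- function(a, b) {
  cn <- oracle_counts(a, b)
  if (cn$uni == 0) 1 else cn$inter / cn$uni
}

oracle_tre <- function(ref_lm, other_lm, chain = transform_chain()) {
  n <- nrow(ref_lm)
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- apply_transform(chain, matrix(unclass(ref_lm)[i, ], 1))
    d[i] <- sqrt(sum((p - unclass(other_lm)[i, ])^2))
  }
  d
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Discretized elastic potential, re-derived with explicit loops: central
# differences in the interior, one-sided at the borders.
oracle_elastic <- function(u_arr, spacing, mu, lambda) {
  d <- dim(u_arr)[1:3]
  h3 <- prod(spacing)
  diffa <- function(a, b, i, j, k) {    # D_a u_b at (i, j, k), 1-based
    c0 <- c(i, j, k)
    if (d[a] == 1) return(0)
    if (c0[a] == 1) {
      cp <- c0; cp[a] <- cp[a] + 1
      (u_arr[cp[1], cp[2], cp[3], b] - u_arr[c0[1], c0[2], c0[3], b]) / spacing[a]
    } else if (c0[a] == d[a]) {
      cm <- c0; cm[a] <- cm[a] - 1
      (u_arr[c0[1], c0[2], c0[3], b] - u_arr[cm[1], cm[2], cm[3], b]) / spacing[a]
    } else {
      cp <- c0; cp[a] <- cp[a] + 1
      cm <- c0; cm[a] <- cm[a] - 1
      (u_arr[cp[1], cp[2], cp[3], b] - u_arr[cm[1], cm[2], cm[3], b]) / (2 * spacing[a])
    }
  }
  acc <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    D <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) D[a, b] <- diffa(a, b, i, j, k)
    e <- 0
    for (a in 1:3) for (b in 1:3) e <- e + 0.25 * mu * (D[a, b] + D[b, a])^2
    e <- e + 0.5 * lambda * (D[1, 1] + D[2, 2] + D[3, 3])^2
    acc <- acc + h3 * e
  }
  acc
}

# all per-stage/per-level optimizer logs of a registration result
all_logs <- function(res) {
  flat <- function(x) {
    if (is.data.frame(x)) return(list(x))
    if (is.list(x)) return(unlist(lapply(x, flat), recursive = FALSE))
    list()
  }
  flat(res$log)
}

expect_descent <- function(res) {
  for (lg in all_logs(res))
    expect_true(all(diff(lg$J) <= 1e-9 * (1 + abs(lg$J[1]))))
}
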