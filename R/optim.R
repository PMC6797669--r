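#' Stopping criteria for the registration optimizer
#'
#' All four tolerances default to 0.001 and the iteration cap to 100, the
#' empirically chosen settings for mask-driven ultrasound registration.
#' Following standard practice in variational registration, the first
#' three rules indicate convergence only when they fire *jointly* --
#' stopping on any one alone (e.g. a single slow iteration crossing the
#' progress threshold) halts the optimization far from a minimum.
#' Semantics (J = objective, g = gradient, x = parameters, k = iteration):
#' \itemize{
#'   \item converged when all three hold:
#'     `|J_k - J_(k-1)| < min_progress * (1 + |J_0|)`,
#'     `||x_k - x_(k-1)|| < min_step * (1 + ||x_k||)`,
#'     `||g_k|| < min_gradient * (1 + |J_0|)`
#'   \item or on the relative gradient alone:
#'     `||g_k|| / ||g_0|| < rel_gradient`
#'   \item or when the line search cannot find any descent step
#'   \item or at `k = max_iterations`
#' }
#'
#' @param min_progress,min_gradient,rel_gradient,min_step positive
#'   tolerances (default 0.001 each).
#' @param max_iterations iteration cap (default 100).
#' @return An object of class `stopping_criteria`.
#' @export
stopping_criteria <- function(min_progress = 0.001, min_gradient = 0.001,
                              rel_gradient = 0.001, min_step = 0.001,
                              max_iterations = 100) {
  stopifnot(min_progress > 0, min_gradient > 0, rel_gradient > 0,
            min_step > 0, max_iterations >= 1)
  structure(list(min_progress = min_progress, min_gradient = min_gradient,
                 rel_gradient = rel_gradient, min_step = min_step,
                 max_iterations = as.integer(max_iterations)),
            class = "stopping_criteria")
}

#' Limited-memory BFGS minimization with registration stopping rules
#'
#' Quasi-Newton iterations with two-loop recursion (memory `memory`) and
#' Armijo backtracking line search; the line search guarantees a
#' non-increasing objective log. Terminates on whichever stopping rule of
#' [stopping_criteria()] fires first.
#'
#' @param objective function of the parameter vector returning a list with
#'   `value`, `grad`, and optionally `extra` (named numerics appended to
#'   the log, e.g. the distance and regularizer terms).
#' @param x0 initial parameter vector (objective must be finite there).
#' @param stop a [stopping_criteria()].
#' @param memory number of curvature pairs kept (default 10).
#' @return List with `x` (minimizer found), `value`, `log` (data.frame
#'   with one row per iteration: `iter`, `J`, `grad_norm`, `step`, extras),
#'   `converged` (TRUE unless stopped on the iteration cap) and `reason`.
#' @export
lbfgs_optimize <- function(objective, x0, stop = stopping_criteria(),
                           memory = 10) {
  ev <- objective(x0)
  if (!is.finite(ev$value) || any(!is.finite(ev$grad)))
    stop("objective not finite at the starting point")
  x <- x0; f <- ev$value; g <- ev$grad
  J0 <- f
  g0n <- sqrt(sum(g^2))
  mk_row <- function(k, f, gn, step, extra) {
    as.data.frame(c(list(iter = k, J = f, grad_norm = gn, step = step),
                    as.list(extra %||% numeric())))
  }
  log <- mk_row(0L, f, g0n, NA_real_, ev$extra)
  S <- list(); Y <- list(); rho <- numeric()
  reason <- "max_iterations"

  if (g0n < stop$min_gradient * (1 + abs(J0))) {
    return(list(x = x, value = f, log = log, converged = TRUE,
                reason = "gradient"))
  }

  for (k in seq_len(stop$max_iterations)) {
    # two-loop recursion
    q <- g
    m <- length(S)
    a <- numeric(m)
    if (m > 0) {
      for (i in m:1) {
        a[i] <- rho[i] * sum(S[[i]] * q)
        q <- q - a[i] * Y[[i]]
      }
      gamma <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]]^2)
      q <- q * gamma
      for (i in 1:m) {
        b <- rho[i] * sum(Y[[i]] * q)
        q <- q + (a[i] - b) * S[[i]]
      }
      d <- -q
    } else {
      d <- -g / max(g0n, 1e-12)          # first step ~ unit length
    }
    gd <- sum(g * d)
    if (!is.finite(gd) || gd >= 0) {     # safeguard: fall back to steepest descent
      d <- -g / max(sqrt(sum(g^2)), 1e-12)
      gd <- sum(g * d)
    }

    t <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + t * d
      en <- objective(xn)
      if (is.finite(en$value) && all(is.finite(en$grad)) &&
          en$value <= f + 1e-4 * t * gd) { accepted <- TRUE; break }
      t <- t / 2
      if (t * sqrt(sum(d^2)) < .Machine$double.eps * (1 + sqrt(sum(x^2))))
        break
    }
    if (!accepted) { reason <- "step"; break }
    step_len <- t * sqrt(sum(d^2))

    s <- xn - x; yv <- en$grad - g
    sy <- sum(s * yv)
    if (is.finite(sy) && sy > 1e-12) {
      S <- c(S, list(s)); Y <- c(Y, list(yv)); rho <- c(rho, 1 / sy)
      if (length(S) > memory) { S <- S[-1]; Y <- Y[-1]; rho <- rho[-1] }
    }
    f_prev <- f
    x <- xn; f <- en$value; g <- en$grad
    gn <- sqrt(sum(g^2))
    log <- rbind(log, mk_row(k, f, gn, step_len, en$extra))

    small_progress <- abs(f - f_prev) < stop$min_progress * (1 + abs(J0))
    small_step <- step_len < stop$min_step * (1 + sqrt(sum(x^2)))
    small_grad <- gn < stop$min_gradient * (1 + abs(J0))
    if (small_progress && small_step && small_grad) { reason <- "tolerances"; break }
    if (gn / max(g0n, 1e-300) < stop$rel_gradient) { reason <- "rel_gradient"; break }
  }
  list(x = x, value = f, log = log,
       converged = reason != "max_iterations", reason = reason)
}
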