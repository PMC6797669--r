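#' Target registration error between corresponding landmark sets
#'
#' Maps the reference landmarks through `chain` and measures the Euclidean
#' distance to the corresponding landmarks of the other set (matched by
#' order), in mm.
#'
#' @param ref_lm reference-volume [landmark_set()].
#' @param other_lm corresponding [landmark_set()] (equal size, same order).
#' @param chain a [transform_chain()] (default: empty = initial error).
#' @return An object of class `tre_report`: list with `distances`, `mean`,
#'   `sd`, `min`, `max`, `n_landmarks`.
#' @export
tre <- function(ref_lm, other_lm, chain = transform_chain()) {
  if (nrow(ref_lm) != nrow(other_lm))
    stop("correspondence error: landmark sets have ", nrow(ref_lm), " vs ",
         nrow(other_lm), " points")
  warped <- apply_transform(chain, ref_lm)
  d <- sqrt(rowSums((unclass(warped) - unclass(other_lm))^2))
  structure(list(distances = d, mean = mean(d),
                 sd = if (length(d) > 1) stats::sd(d) else 0,
                 min = min(d), max = max(d), n_landmarks = length(d)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report> n = %d, mean %.2f mm (sd %.2f, range %.2f-%.2f)\n",
              x$n_landmarks, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both are empty.
#'
#' @param a,b binary [us_mask()]s on the same grid.
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  A <- a$data > 0.5; B <- b$data > 0.5
  tot <- sum(A) + sum(B)
  if (tot == 0) return(1)
  2 * sum(A & B) / tot
}

#' Correspondence-restricted Dice coefficient
#'
#' When the manual annotation is sparse, automatically segmented structures
#' without any manual counterpart should not count against the overlap.
#' Connected components (26-neighbourhood) of `pred` that do not overlap
#' `manual` by at least one voxel are discarded before computing the Dice
#' coefficient. Always >= the plain [dice()] of the same pair.
#'
#' @param pred automatically segmented binary [us_mask()].
#' @param manual manually annotated binary [us_mask()].
#' @return Fraction in \[0, 1\].
#' @export
dice_correspondence_restricted <- function(pred, manual) {
  stop_if_geometry_mismatch(pred, manual)
  P <- pred$data > 0.5; M <- manual$data > 0.5
  lab <- cpp_label26(P, as.integer(dim(pred$data)))
  keep <- unique(lab[M & lab > 0])
  kept <- array(as.numeric(lab %in% keep & P), dim(pred$data))
  kp <- mask_like(pred, kept)
  dice(kp, manual)
}

#' Mean intensity inside and outside a mask
#'
#' The hyperechogenic structures the method segments should be markedly
#' brighter than the excluded background; this is the per-volume statistic
#' behind that check, plus the physical mask volume.
#'
#' @param v a [us_volume()].
#' @param m a congruent [us_mask()].
#' @return List with `mean_inside` (NA when the mask is empty),
#'   `mean_outside`, `volume_mm3`.
#' @export
mask_stats <- function(v, m) {
  stop_if_geometry_mismatch(v, m)
  inside <- m$data > 0.5
  list(mean_inside = if (any(inside)) mean(v$data[inside]) else NA_real_,
       mean_outside = if (all(inside)) NA_real_ else mean(v$data[!inside]),
       volume_mm3 = sum(inside) * prod(v$spacing))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation, used to compare the volume extents of masks
#' segmented at different surgical stages across cases.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearson requires two equal-length vectors with >= 3 entries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined statistic: zero variance in input")
  stats::cor(x, y, method = "pearson")
}

#' Capture-range protocol
#'
#' @param offsets strictly increasing initial misalignment magnitudes (mm).
#' @param trials registrations per offset (default 10).
#' @param required success fraction required (default 0.80).
#' @param success_mm optional fixed success threshold on the final mTRE;
#'   by default `max(1 voxel, 1.5 * baseline mTRE)` where the baseline is
#'   the final mTRE of an unperturbed registration of the same pair.
#' @return An object of class `capture_protocol`.
#' @export
capture_protocol <- function(offsets, trials = 10, required = 0.8,
                             success_mm = NULL) {
  offsets <- as.numeric(offsets)
  if (any(diff(offsets) <= 0)) stop("offsets must be strictly increasing")
  if (required <= 0 || required > 1) stop("required fraction must be in (0, 1]")
  structure(list(offsets = offsets, trials = as.integer(trials),
                 required = required, success_mm = success_mm),
            class = "capture_protocol")
}

#' Capture range from a success table
#'
#' The capture range is the largest initial misalignment at which the
#' registration still converges for at least the required fraction of
#' trials, with every smaller misalignment also passing (first-failure
#' cut). Returns 0 mm (with a diagnostic attribute) when no offset passes;
#' when every offset passes, the largest tested offset is returned and
#' flagged as censored.
#'
#' @param offsets tested misalignment magnitudes (mm), increasing.
#' @param successes successful trials per offset.
#' @param trials total trials per offset (recycled if scalar).
#' @param required required success fraction (default 0.8).
#' @return The capture range in mm, with attributes `censored` (logical)
#'   and `table` (data.frame of offsets and success fractions).
#' @export
capture_range_from_table <- function(offsets, successes, trials,
                                     required = 0.8) {
  trials <- rep_len(trials, length(offsets))
  frac <- successes / trials
  pass <- frac >= required
  first_fail <- match(FALSE, pass, nomatch = length(offsets) + 1L)
  rng <- if (first_fail == 1L) 0 else offsets[first_fail - 1L]
  structure(rng, censored = first_fail > length(offsets),
            table = data.frame(offset_mm = offsets, successes = successes,
                               trials = trials, fraction = frac))
}

#' Estimate the capture range of the registration on a case pair
#'
#' For each offset magnitude, `protocol$trials` registrations are started
#' from random initial rigid translations of that magnitude (uniformly
#' random directions); a trial succeeds when the final mean TRE on the
#' pair's landmarks stays within the protocol's success rule. The returned
#' range follows [capture_range_from_table()] semantics.
#'
#' @param ref_mask,tmpl_mask the masks driving registration.
#' @param ref_lm,tmpl_lm paired landmark sets of the two volumes.
#' @param protocol a [capture_protocol()].
#' @param config a [reg_config()].
#' @param seed RNG seed for the random misalignment directions.
#' @return As [capture_range_from_table()], plus attribute `success_mm`.
#' @export
capture_range <- function(ref_mask, tmpl_mask, ref_lm, tmpl_lm,
                          protocol, config = reg_config(), seed = 1L) {
  stopifnot(inherits(protocol, "capture_protocol"))
  if (nrow(ref_lm) != nrow(tmpl_lm))
    stop("correspondence error: landmark sets differ in size")
  center <- volume_center(ref_mask)
  run_final_mtre <- function(init) {
    res <- register_masks(ref_mask, tmpl_mask, init, config)
    tre(ref_lm, tmpl_lm, res$chain)$mean
  }
  success_mm <- protocol$success_mm
  if (is.null(success_mm)) {
    baseline <- run_final_mtre(NULL)
    success_mm <- max(mean(ref_mask$spacing), 1.5 * baseline)
  }
  with_seed(seed, {
    successes <- vapply(protocol$offsets, function(off) {
      ok <- 0L
      for (t in seq_len(protocol$trials)) {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        init <- rigid_transform(translation = off * dir, center = center)
        final <- tryCatch(run_final_mtre(init), error = function(e) Inf)
        if (final <= success_mm) ok <- ok + 1L
      }
      ok
    }, 0L)
    out <- capture_range_from_table(protocol$offsets, successes,
                                    protocol$trials, protocol$required)
    attr(out, "success_mm") <- success_mm
    out
  })
}
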