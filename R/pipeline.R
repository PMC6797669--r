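#' Case pair for registration
#'
#' Bundles the two volumes of successive surgical stages with optional
#' landmarks, masks and tracker initial guess. Role convention: the
#' later-stage volume is the *reference* and the earlier-stage (higher
#' quality) volume is the *template* that gets deformed onto it.
#'
#' @param reference_volume,template_volume [us_volume()]s.
#' @param reference_landmarks,template_landmarks optional paired
#'   [landmark_set()]s (equal sizes, matched order).
#' @param reference_mask,template_mask optional precomputed [us_mask()]s;
#'   when absent, [run_pair()] segments the volumes with its model.
#' @param init optional [rigid_transform()] tracker initial guess.
#' @return An object of class `case_pair`.
#' @export
case_pair <- function(reference_volume, template_volume,
                      reference_landmarks = NULL, template_landmarks = NULL,
                      reference_mask = NULL, template_mask = NULL,
                      init = NULL) {
  stopifnot(inherits(reference_volume, "us_volume"),
            inherits(template_volume, "us_volume"))
  if (!is.null(reference_landmarks) && !is.null(template_landmarks) &&
      nrow(reference_landmarks) != nrow(template_landmarks))
    stop("correspondence error: paired landmark sets differ in size")
  structure(list(reference_volume = reference_volume,
                 template_volume = template_volume,
                 reference_landmarks = reference_landmarks,
                 template_landmarks = template_landmarks,
                 reference_mask = reference_mask,
                 template_mask = template_mask,
                 init = init),
            class = "case_pair")
}

#' Turn a phantom pair into a case pair
#'
#' Convenience wrapper: the deformed (later-stage) case becomes the
#' reference, the original case the template, with the ground-truth masks
#' and landmark correspondences attached.
#'
#' @param reference_case,template_case `phantom_case`s.
#' @param init optional tracker initial guess.
#' @return A [case_pair()].
#' @export
phantom_pair <- function(reference_case, template_case, init = NULL) {
  case_pair(reference_case$volume, template_case$volume,
            reference_case$landmarks, template_case$landmarks,
            reference_case$mask, template_case$mask, init = init)
}

pair_masks <- function(pair, model) {
  get_mask <- function(mask, vol, what) {
    if (!is.null(mask)) return(mask)
    if (is.null(model))
      stop("pipeline stage 'segmentation' failed: no ", what,
           " mask supplied and no model given")
    predict_mask(model, vol)$binary
  }
  list(ref = get_mask(pair$reference_mask, pair$reference_volume, "reference"),
       tmpl = get_mask(pair$template_mask, pair$template_volume, "template"))
}

pair_tre <- function(pair, chain) {
  if (is.null(pair$reference_landmarks) || is.null(pair$template_landmarks))
    return(NULL)
  tre(pair$reference_landmarks, pair$template_landmarks, chain)
}

#' Run the full pipeline on one case pair
#'
#' Segments both volumes (unless masks are supplied), registers the masks
#' (parametric, then nonparametric), warps the landmarks and reports the
#' three-column TRE summary: initial error, error after the parametric
#' stage and error after the nonparametric stage.
#'
#' @param pair a [case_pair()].
#' @param model a [train_unet()] result (may be NULL when both masks are
#'   supplied in `pair`).
#' @param config a [reg_config()].
#' @param out_dir optional directory to write artifacts to (masks, chain
#'   YAML, deformed template, warped landmarks, report YAML).
#' @return An object of class `pipeline_report`: list with `tre_initial`,
#'   `tre_parametric`, `tre_nonparametric` ([tre()] reports or NULL when
#'   the pair carries no landmarks), `registration`
#'   (the [register_masks()] result), `timings` (seconds per stage,
#'   logged but never asserted -- hardware-dependent), `config` and
#'   `artifacts` (paths written, if any).
#' @export
run_pair <- function(pair, model = NULL, config = reg_config(),
                     out_dir = NULL) {
  stopifnot(inherits(pair, "case_pair"))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }
  masks <- tick("segmentation", pair_masks(pair, model))
  reg <- tick("registration", tryCatch(
    register_masks(masks$ref, masks$tmpl, pair$init, config),
    error = function(e) stop("pipeline stage 'registration' failed: ",
                             conditionMessage(e))))
  init_chain <- if (is.null(pair$init)) transform_chain()
                else transform_chain(pair$init)
  report <- structure(list(
    tre_initial = pair_tre(pair, init_chain),
    tre_parametric = pair_tre(pair, reg$chain_parametric),
    tre_nonparametric = pair_tre(pair, reg$chain),
    registration = reg, timings = timings, config = config,
    artifacts = character()), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(ref_mask = file.path(out_dir, "reference_mask.nii.gz"),
               tmpl_mask = file.path(out_dir, "template_mask.nii.gz"),
               deformed = file.path(out_dir, "deformed_template.nii.gz"),
               chain = file.path(out_dir, "chain.yaml"))
    write_volume(masks$ref, paths[["ref_mask"]])
    write_volume(masks$tmpl, paths[["tmpl_mask"]])
    write_volume(reg$deformed_template, paths[["deformed"]])
    write_transform_chain(reg$chain, paths[["chain"]])
    if (!is.null(pair$reference_landmarks)) {
      paths[["warped_landmarks"]] <- file.path(out_dir, "warped_landmarks.csv")
      write_landmarks(apply_transform(reg$chain, pair$reference_landmarks),
                      paths[["warped_landmarks"]])
    }
    summarize <- function(r) if (is.null(r)) NULL else
      list(mean = r$mean, sd = r$sd, min = r$min, max = r$max,
           n = r$n_landmarks)
    yaml::write_yaml(list(
      tre_initial = summarize(report$tre_initial),
      tre_parametric = summarize(report$tre_parametric),
      tre_nonparametric = summarize(report$tre_nonparametric),
      converged = reg$converged,
      timings_s = as.list(timings)), file.path(out_dir, "report.yaml"))
    paths[["report"]] <- file.path(out_dir, "report.yaml")
    report$artifacts <- paths
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  row <- function(name, r) if (!is.null(r))
    cat(sprintf("  %-28s %.2f mm (sd %.2f, range %.2f-%.2f, n=%d)\n",
                name, r$mean, r$sd, r$min, r$max, r$n_landmarks))
  row("mean initial distance:", x$tre_initial)
  row("after parametric:", x$tre_parametric)
  row("after nonparametric:", x$tre_nonparametric)
  cat(sprintf("  converged: %s\n", x$registration$converged))
  invisible(x)
}

#' Run two stage pairs and chain the transforms
#'
#' Instead of registering the first and last stage directly, registers
#' A -> B and B -> C through the shared middle volume and concatenates the
#' two transform chains, then evaluates A's landmarks against C's. `pair_ab`
#' must have the middle volume as its reference and `pair_bc` must have it
#' as its template.
#'
#' @param pair_ab [case_pair()] of the earlier stage pair (template = A,
#'   reference = B).
#' @param pair_bc [case_pair()] of the later stage pair (template = B,
#'   reference = C).
#' @inheritParams run_pair
#' @return A `pipeline_report` whose TRE columns evaluate the composed
#'   C -> A map on `pair_bc`'s reference landmarks vs `pair_ab`'s template
#'   landmarks; carries both stage reports as `stage_ab` / `stage_bc`.
#' @export
run_chained <- function(pair_ab, pair_bc, model = NULL,
                        config = reg_config()) {
  stopifnot(inherits(pair_ab, "case_pair"), inherits(pair_bc, "case_pair"))
  if (!same_geometry(pair_ab$reference_volume, pair_bc$template_volume))
    stop("chaining error: pair_ab's reference and pair_bc's template must be the same middle volume")
  rep_ab <- run_pair(pair_ab, model, config)
  rep_bc <- run_pair(pair_bc, model, config)
  lm_c <- pair_bc$reference_landmarks
  lm_a <- pair_ab$template_landmarks
  chain_of <- function(ab, bc) c(bc, ab)     # C -> B, then B -> A
  tre_or_null <- function(chain)
    if (is.null(lm_c) || is.null(lm_a)) NULL else tre(lm_c, lm_a, chain)
  init_ab <- if (is.null(pair_ab$init)) transform_chain() else transform_chain(pair_ab$init)
  init_bc <- if (is.null(pair_bc$init)) transform_chain() else transform_chain(pair_bc$init)
  structure(list(
    tre_initial = tre_or_null(chain_of(init_ab, init_bc)),
    tre_parametric = tre_or_null(chain_of(rep_ab$registration$chain_parametric,
                                          rep_bc$registration$chain_parametric)),
    tre_nonparametric = tre_or_null(chain_of(rep_ab$registration$chain,
                                             rep_bc$registration$chain)),
    registration = rep_ab$registration,
    chain = chain_of(rep_ab$registration$chain, rep_bc$registration$chain),
    stage_ab = rep_ab, stage_bc = rep_bc,
    timings = c(rep_ab$timings, rep_bc$timings),
    config = config, artifacts = character()),
    class = "pipeline_report")
}
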