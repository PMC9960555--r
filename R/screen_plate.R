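# Plate-level orchestration: calibration -> per-well screening ->
# replicate consensus, for one plate in one or both polarities.

#' Screen a whole plate
#'
#' Runs the full screening workflow on one plate: fits per-well calibration
#' models from the calibrant wells ([plate_calibration()]), applies them,
#' screens every sample well against the database with blank thresholds
#' from the plate's own (calibrated) blanks, and reduces per-well matches
#' to per-sample detections by replicate consensus.
#'
#' @param x A `plate_bundle` (from [simulate_plate()] or
#'   [read_plate_bundle()]), or a list of per-polarity named spectrum
#'   lists as in a bundle's `$spectra`.
#' @param manifest A `plate_manifest`; taken from the bundle if `x` is
#'   one.
#' @param db A `compound_db` (default the bundled database).
#' @param criteria A `screening_criteria`.
#' @param refs Reference ions for calibration (default bundled PFSA list).
#' @param calibration `"linear"`, `"quadratic"` or `"identity"`.
#' @param policy Calibrant-assignment policy (see [plate_calibration()]).
#' @param resolution,prune Isotope-pattern parameters.
#' @return A `screen_result` list: `detections` (consensus table),
#'   `matches` (all per-well match rows, pass and fail, for audit),
#'   `calibration` (per polarity: model kind, rms residual in Da, number
#'   of references, between-calibrant reference-intensity RSD), `criteria`
#'   and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- screen_plate(simulate_plate(plate_design(seed = 1)))
#' subset(res$detections, validated)
#' }
screen_plate <- function(x, manifest = NULL, db = read_database(),
                         criteria = screening_criteria(),
                         refs = reference_ions(),
                         calibration = c("linear", "quadratic", "identity"),
                         policy = c("average", "nearest", "first"),
                         resolution = 25000, prune = 1e-4) {
  calibration <- match.arg(calibration)
  policy <- match.arg(policy)
  if (inherits(x, "plate_bundle")) {
    manifest <- x$manifest
    spectra <- x$spectra
  } else spectra <- x
  if (is.null(manifest)) stop("manifest is required", call. = FALSE)

  all_matches <- list()
  cal_info <- list()
  for (pol in names(spectra)) {
    wells <- spectra[[pol]]
    models <- plate_calibration(wells, manifest, refs, policy = policy,
                                kind = calibration)
    calibrated <- stats::setNames(
      lapply(names(wells), function(w) apply_calibration(wells[[w]],
                                                         models[[w]])),
      names(wells))
    cal_models <- attr(models, "calibrant_models")
    cal_info[[pol]] <- list(
      kind = if (length(cal_models)) cal_models[[1L]]$kind else "identity",
      rms_residual = if (length(cal_models))
        mean(vapply(cal_models, `[[`, numeric(1), "rms_residual")) else NA,
      n_refs = if (length(cal_models))
        min(vapply(cal_models, `[[`, integer(1), "n_refs_used")) else 0L,
      reference_intensity_rsd = attr(models, "reference_intensity_rsd"))

    blank_ids <- manifest$well_id[manifest$role == "blank"]
    blanks <- calibrated[intersect(blank_ids, names(calibrated))]
    sample_ids <- manifest$well_id[manifest$role == "sample"]
    species_tab <- expand_database(db, pol)
    for (w in intersect(sample_ids, names(calibrated)))
      all_matches[[length(all_matches) + 1L]] <-
        screen_well(calibrated[[w]], species_tab, criteria, blanks,
                    resolution = resolution, prune = prune)
  }
  matches <- do.call(rbind, all_matches)
  if (is.null(matches)) matches <- .empty_match_results()
  detections <- consensus(matches, manifest, criteria)
  structure(list(detections = detections, matches = matches,
                 calibration = cal_info, criteria = criteria,
                 manifest = manifest),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  nv <- sum(x$detections$validated)
  cat("<screen result> ", nrow(x$detections),
      " candidate detections, ", nv, " validated (level 4)\n", sep = "")
  for (pol in names(x$calibration)) {
    ci <- x$calibration[[pol]]
    cat(sprintf("  %s calibration: %s, %d refs, rms %.3g Da\n",
                pol, ci$kind, ci$n_refs, ci$rms_residual))
  }
  invisible(x)
}
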