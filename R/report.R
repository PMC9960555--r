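# Report writers: a detections TSV in the times-detected / times-measured
# style and a machine-readable JSON audit trail, plus a structural
# validator for the JSON report.

#' Write screening reports
#'
#' [write_detections_tsv()] writes the consensus table as TSV, one row per
#' sample x compound x species with the `n/m` detection string, mean mass
#' error (mDa), mean isotope-fit score, quality band, confidence level and
#' isobar group. [write_audit_json()] writes the full audit trail: every
#' per-well match (passing or not) with its per-criterion flags, the
#' calibration summary, the criteria used, the package version and, for
#' synthetic plates, the seed -- every reported number traces back to these
#' stored match rows. Report generation is deterministic.
#'
#' @param result A `screen_result` from [screen_plate()].
#' @param path Output file path.
#' @param seed Optional generator seed to record (synthetic plates).
#' @return `path`, invisibly.
#' @export
write_detections_tsv <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  det <- result$detections
  num <- vapply(det, is.numeric, logical(1))
  det[num] <- lapply(det[num], function(x) round(x, 6))
  utils::write.table(det, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_detections_tsv
#' @export
write_audit_json <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "screen_result"))
  report <- list(
    software = list(
      package = "maldiscreen",
      version = as.character(utils::packageVersion("maldiscreen"))),
    seed = seed,
    criteria = unclass(result$criteria)[c("mass_tol", "sigma_max",
                                          "blank_factor",
                                          "replicate_rule")],
    calibration = result$calibration,
    detections = result$detections,
    matches = result$matches)
  jsonlite::write_json(report, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Validate a JSON audit report
#'
#' Structural validation of a report written by [write_audit_json()]
#' against the schema shipped in `inst/extdata/report-schema.json`:
#' required top-level members, required fields on every detection and
#' match row, and the traceability invariant that each validated detection
#' is supported by at least `n_measured` passing match rows.
#'
#' @param path Path to the JSON report.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "maldiscreen",
                mustWork = TRUE))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  miss <- setdiff(unlist(schema$required), names(rep))
  if (length(miss))
    stop("report missing members: ", paste(miss, collapse = ", "),
         call. = FALSE)
  det <- rep$detections
  if (length(det) && nrow(det)) {
    miss <- setdiff(unlist(schema$detection_fields), names(det))
    if (length(miss))
      stop("detections missing fields: ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- rep$matches
    miss <- setdiff(unlist(schema$match_fields), names(m))
    if (length(miss))
      stop("matches missing fields: ", paste(miss, collapse = ", "),
           call. = FALSE)
    for (i in which(det$validated)) {
      n_pass <- sum(m$name == det$name[i] & m$species == det$species[i] &
                      m$polarity == det$polarity[i] & m$passed_all)
      if (n_pass < det$n_measured[i])
        stop("validated detection not traceable to enough passing ",
             "matches: ", det$name[i], " [", det$species[i], "]",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}
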