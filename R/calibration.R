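# Internal recalibration of well spectra against PFSA reference ions
# measured in the plate's calibrant wells: match references coarsely, fit a
# low-order polynomial observed -> corrected m/z, apply per well.

#' PFSA reference-ion list
#'
#' Loads a reference-ion configuration: a TSV with columns `label`,
#' `polarity`, `formula` and `species` (species grammar). Theoretical m/z
#' values are computed from the bundled isotope table at load time so the
#' configuration stays consistent with the rest of the package. The shipped
#' default covers the C4/C6/C8 perfluoroalkyl sulfonic acid calibration
#' mixture: `[M-H]-` monomers and proton-bound dimers in negative mode
#' (about m/z 299-1000) and a dipotassium series in positive mode (about
#' m/z 377-1077); the positive-mode species are a package convention (see
#' the file header).
#'
#' @param path TSV config path; default is the bundled PFSA list.
#' @return A `reference_ions` data frame: `label`, `polarity`, `mz`
#'   (ascending within polarity), with the source path as an attribute.
#' @export
#' @examples
#' reference_ions()
reference_ions <- function(path = default_reference_ions()) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character", strip.white = TRUE)
  need <- c("label", "polarity", "formula", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference-ion config missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$mz <- vapply(seq_len(nrow(df)), function(i) {
    theoretical_mz(parse_formula(df$formula[i]),
                   parse_species(df$species[i], df$polarity[i]))
  }, numeric(1))
  out <- df[order(df$polarity, df$mz),
            c("label", "polarity", "mz"), drop = FALSE]
  rownames(out) <- NULL
  for (pol in unique(out$polarity))
    if (sum(out$polarity == pol) < 2L)
      warning("fewer than 2 reference ions for ", pol, " mode",
              call. = FALSE)
  structure(out, source = path,
            class = c("reference_ions", "data.frame"))
}

#' @rdname reference_ions
#' @return `default_reference_ions()`: path to the bundled PFSA config.
#' @export
default_reference_ions <- function() {
  system.file("extdata", "pfsa_reference_ions.tsv", package = "maldiscreen",
              mustWork = TRUE)
}

.model_min_refs <- c(identity = 0L, linear = 2L, quadratic = 3L)

.new_calibration <- function(kind, coefficients, n_refs, rms) {
  structure(list(kind = kind, coefficients = coefficients,
                 n_refs_used = n_refs, rms_residual = rms),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration model> ", x$kind, ", coefficients (",
      paste(signif(x$coefficients, 8), collapse = ", "), "), ",
      x$n_refs_used, " refs, rms residual ",
      sprintf("%.3g", x$rms_residual), " Da\n", sep = "")
  invisible(x)
}

#' Fit a recalibration model to a calibrant-well spectrum
#'
#' Each reference ion of the spectrum's polarity is matched to its nearest
#' peak within `coarse_tol`; the corrected m/z is then modelled as a
#' polynomial in the observed m/z by least squares. If fewer references
#' match than the requested model needs (linear: 2, quadratic: 3) the model
#' degrades (quadratic to linear to identity) with a warning; if nothing
#' matches, the identity model is returned with a warning and screening
#' proceeds uncalibrated (flagged in reports through `n_refs_used = 0`).
#'
#' @param cal_spectrum `centroid_spectrum` of a calibrant well.
#' @param refs A `reference_ions` table.
#' @param coarse_tol Match tolerance in Da (default 0.05, wide enough for
#'   raw TOF drift).
#' @param kind `"linear"` (default), `"quadratic"` or `"identity"`.
#' @return A `calibration_model` with `kind`, `coefficients` (ascending
#'   powers of observed m/z), `n_refs_used` and `rms_residual` (Da, over
#'   matched references).
#' @export
fit_calibration <- function(cal_spectrum, refs,
                            coarse_tol = 0.05,
                            kind = c("linear", "quadratic", "identity")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cal_spectrum, "centroid_spectrum"), coarse_tol > 0)
  refs <- refs[refs$polarity == cal_spectrum$polarity, , drop = FALSE]
  obs <- theo <- numeric(0)
  for (i in seq_len(nrow(refs))) {
    hit <- nearest_peak(cal_spectrum, refs$mz[i], coarse_tol)
    if (!is.null(hit)) {
      obs <- c(obs, hit$mz)
      theo <- c(theo, refs$mz[i])
    }
  }
  n <- length(obs)
  if (kind == "identity")
    return(.new_calibration("identity", c(0, 1), n,
                            if (n) sqrt(mean((theo - obs)^2)) else 0))
  degraded <- kind
  while (n < .model_min_refs[[degraded]] && degraded != "identity")
    degraded <- switch(degraded, quadratic = "linear", linear = "identity")
  if (degraded != kind)
    warning("only ", n, " reference ions matched; degrading ", kind,
            " calibration to ", degraded, call. = FALSE)
  if (degraded == "identity")
    return(.new_calibration("identity", c(0, 1), n, 0))
  deg <- if (degraded == "linear") 1L else 2L
  fit <- stats::lm(theo ~ stats::poly(obs, deg, raw = TRUE))
  coef <- unname(stats::coef(fit))
  rms <- sqrt(mean(stats::resid(fit)^2))
  .new_calibration(degraded, coef, n, rms)
}

.eval_calibration <- function(m, mz) {
  out <- numeric(length(mz))
  for (k in seq_along(m$coefficients))
    out <- out + m$coefficients[k] * mz^(k - 1L)
  out
}

#' Apply a calibration model to a spectrum
#'
#' Maps every m/z through the model polynomial, leaving intensities
#' untouched. The correction must be monotone over the spectrum's m/z range
#' so that peak order is preserved; a non-monotone model (possible for a
#' badly conditioned quadratic) is an error.
#'
#' @param s A `centroid_spectrum`.
#' @param m A `calibration_model`.
#' @return The corrected `centroid_spectrum`.
#' @export
apply_calibration <- function(s, m) {
  stopifnot(inherits(s, "centroid_spectrum"),
            inherits(m, "calibration_model"))
  if (length(s$mz) == 0L) return(s)
  mz2 <- .eval_calibration(m, s$mz)
  if (length(mz2) > 1L && any(diff(mz2) <= 0))
    stop("calibration model is non-monotone over the spectrum range",
         call. = FALSE)
  s$mz <- mz2
  s
}

#' Per-well calibration models for a plate
#'
#' Fits one model per calibrant well of the requested polarity and assigns a
#' model to every well according to `policy`: `"average"` (default; mean of
#' the calibrant-well models, the natural choice for calibrants in the first
#' and last well), `"nearest"` (each well uses the model of the closest
#' calibrant well by position, for drift that varies across the run) or
#' `"first"`. With no calibrant wells all wells get the identity model with
#' a warning.
#'
#' Also computes the between-calibrant reference-intensity RSDs used to
#' report plate/run reproducibility: for each reference ion matched in at
#' least two calibrant wells, the RSD of its matched intensity, summarised
#' by the mean (attribute `reference_intensity_rsd`).
#'
#' @param spectra Named list of `centroid_spectrum` (names = well ids) of
#'   one polarity.
#' @param manifest A `plate_manifest`.
#' @param refs A `reference_ions` table.
#' @param policy `"average"`, `"nearest"` or `"first"`.
#' @param coarse_tol,kind Passed to [fit_calibration()].
#' @return Named list of `calibration_model`, one per well in `spectra`,
#'   with attributes `calibrant_models` and `reference_intensity_rsd`.
#' @export
plate_calibration <- function(spectra, manifest, refs,
                              policy = c("average", "nearest", "first"),
                              coarse_tol = 0.05,
                              kind = c("linear", "quadratic", "identity")) {
  policy <- match.arg(policy)
  kind <- match.arg(kind)
  cal_wells <- manifest$well_id[manifest$role == "calibrant"]
  cal_wells <- cal_wells[cal_wells %in% names(spectra)]
  if (length(cal_wells) == 0L) {
    warning("no calibrant wells; all spectra left uncalibrated",
            call. = FALSE)
    id <- .new_calibration("identity", c(0, 1), 0L, 0)
    out <- stats::setNames(rep(list(id), length(spectra)), names(spectra))
    attr(out, "calibrant_models") <- list()
    attr(out, "reference_intensity_rsd") <- NA_real_
    return(out)
  }
  models <- lapply(cal_wells, function(w)
    fit_calibration(spectra[[w]], refs, coarse_tol, kind))
  names(models) <- cal_wells

  pick <- switch(policy,
    first = function(well) models[[1L]],
    nearest = function(well) {
      pos <- match(well, manifest$well_id)
      cal_pos <- match(cal_wells, manifest$well_id)
      models[[which.min(abs(cal_pos - pos))]]
    },
    average = local({
      maxlen <- max(lengths(lapply(models, `[[`, "coefficients")))
      coefs <- sapply(models, function(m)
        c(m$coefficients, rep(0, maxlen - length(m$coefficients))))
      avg <- .new_calibration(
        if (maxlen >= 3L) "quadratic" else if (maxlen == 2L) "linear"
        else "identity",
        rowMeans(as.matrix(coefs)),
        as.integer(round(mean(vapply(models, `[[`, integer(1),
                                     "n_refs_used")))),
        mean(vapply(models, `[[`, numeric(1), "rms_residual")))
      function(well) avg
    }))

  out <- lapply(names(spectra), pick)
  names(out) <- names(spectra)
  attr(out, "calibrant_models") <- models
  attr(out, "reference_intensity_rsd") <-
    .reference_intensity_rsd(spectra[cal_wells], refs, coarse_tol)
  out
}

# mean over reference ions of the between-calibrant intensity RSD
.reference_intensity_rsd <- function(cal_spectra, refs, coarse_tol) {
  if (length(cal_spectra) < 2L) return(NA_real_)
  pol <- cal_spectra[[1L]]$polarity
  refs <- refs[refs$polarity == pol, , drop = FALSE]
  rsds <- numeric(0)
  for (i in seq_len(nrow(refs))) {
    h <- vapply(cal_spectra, function(s) {
      hit <- nearest_peak(s, refs$mz[i], coarse_tol)
      if (is.null(hit)) NA_real_ else hit$intensity
    }, numeric(1))
    h <- h[!is.na(h)]
    if (length(h) >= 2L && mean(h) > 0)
      rsds <- c(rsds, 100 * stats::sd(h) / mean(h))
  }
  if (length(rsds)) mean(rsds) else NA_real_
}
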