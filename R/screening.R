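# The suspect-screening stage: expand compounds to ion species, match by
# exact mass against calibrated spectra, score the isotope-pattern fit,
# apply blank and replicate-consensus criteria, assign confidence level 4.

#' Screening criteria
#'
#' The three identification criteria applied to every candidate match, with
#' their standard defaults: isotope-fit score below `sigma_max` (100; bands
#' below 25 are labelled excellent, below 50 good, below 100 acceptable),
#' absolute mass deviation at most `mass_tol` (0.005 Da = 5 mDa), and peak
#' height strictly greater than `blank_factor` (3) times the highest signal
#' for that m/z across the plate's blanks. A detection is only validated
#' when every replicate measurement of the sample passes all three criteria
#' (`replicate_rule = "all"`).
#'
#' @param mass_tol Mass tolerance in Da.
#' @param sigma_max Maximum acceptable isotope-fit score.
#' @param blank_factor Blank multiplier (strict inequality).
#' @param replicate_rule Only `"all"` (all-of-n) is defined.
#' @param quality_bands Named numeric upper bounds for the score quality
#'   labels.
#' @return A `screening_criteria` list.
#' @export
screening_criteria <- function(mass_tol = 0.005, sigma_max = 100,
                               blank_factor = 3, replicate_rule = "all",
                               quality_bands = c(excellent = 25, good = 50,
                                                 acceptable = 100)) {
  stopifnot(mass_tol > 0, sigma_max > 0, blank_factor > 0,
            identical(replicate_rule, "all"), all(quality_bands > 0))
  structure(list(mass_tol = mass_tol, sigma_max = sigma_max,
                 blank_factor = blank_factor,
                 replicate_rule = replicate_rule,
                 quality_bands = sort(quality_bands)),
            class = "screening_criteria")
}

.quality_band <- function(score, bands) {
  i <- which(score < bands)[1L]
  if (is.na(i)) "poor" else names(bands)[i]
}

#' Isotope-pattern goodness-of-fit score
#'
#' An open sigma-style score between a theoretical isotope pattern and the
#' measured peaks around an anchored match. The theoretical pattern is
#' restricted to its most intense peaks covering at least 99% cumulative
#' intensity; each is paired with the nearest measured peak within `tol`
#' (missing peaks count as intensity 0); both intensity vectors are
#' normalised to sum 1 over this set; the score is `1000 * sqrt(mean((t -
#' m)^2))`. Perfect agreement scores 0; the conventional quality bands
#' (below 25 excellent, 50 good, 100 acceptable) are interpreted on this
#' scale. The score is a package-defined analogue of vendor isotope-fit
#' statistics, calibrated only in that 0 means a perfect pattern match; no
#' numeric equivalence with any vendor score is claimed.
#'
#' @param theoretical An `isotope_pattern`.
#' @param s A `centroid_spectrum`.
#' @param anchor_mz Observed m/z of the species' matched (monoisotopic)
#'   peak; the theoretical pattern is shifted so its first peak aligns with
#'   the anchor before pairing, making the score insensitive to residual
#'   mass offset.
#' @param tol Pairing tolerance in Da.
#' @return Non-negative score.
#' @export
#' @examples
#' pat <- isotope_pattern(parse_formula("C6H2Br3O"))
#' s <- centroid_spectrum(pat$mz, pat$intensity * 1e4, "negative")
#' iso_fit_score(pat, s, anchor_mz = pat$mz[1], tol = 0.005) # 0
iso_fit_score <- function(theoretical, s, anchor_mz, tol = 0.005) {
  stopifnot(nrow(theoretical) > 0, tol > 0)
  ord <- order(theoretical$intensity, decreasing = TRUE)
  csum <- cumsum(theoretical$intensity[ord])
  keep <- sort(ord[seq_len(which(csum >= 0.99)[1L])])
  t_mz <- theoretical$mz[keep] + (anchor_mz - theoretical$mz[1L])
  t_int <- theoretical$intensity[keep]
  m_int <- vapply(t_mz, function(mz) {
    hit <- nearest_peak(s, mz, tol)
    if (is.null(hit)) 0 else hit$intensity
  }, numeric(1))
  t_int <- t_int / sum(t_int)
  if (sum(m_int) > 0) m_int <- m_int / sum(m_int)
  1000 * sqrt(mean((t_int - m_int)^2))
}

#' Blank-based detection threshold
#'
#' The intensity a sample peak must strictly exceed: `factor` times the
#' highest signal for the target m/z across the plate's blank wells. A blank
#' with no peak inside the tolerance window contributes its noise floor (the
#' median of its peak intensities; 0 for an empty blank) instead, so the
#' threshold never collapses to 0 merely because the blank is clean at that
#' exact mass. Blanks must come from the same plate as the sample.
#'
#' @param blank_spectra List of blank `centroid_spectrum` (same plate,
#'   same polarity).
#' @param target_mz Target m/z in Da.
#' @param tol Tolerance in Da.
#' @param factor Multiplier (default 3).
#' @return Threshold intensity.
#' @export
blank_threshold <- function(blank_spectra, target_mz, tol = 0.005,
                            factor = 3) {
  stopifnot(length(blank_spectra) >= 1L, tol > 0, factor > 0)
  per_blank <- vapply(blank_spectra, function(b) {
    hit <- nearest_peak(b, target_mz, tol)
    if (!is.null(hit)) hit$intensity
    else if (length(b$mz)) stats::median(b$intensity)
    else 0
  }, numeric(1))
  factor * max(per_blank)
}

#' Screen one well spectrum against a compound database
#'
#' For every compound x applicable species of the spectrum's polarity:
#' match the species' theoretical monoisotopic m/z to the nearest peak
#' within `criteria$mass_tol`; on a match, compute the isotope-fit score
#' (anchored on the matched peak) and the blank threshold, and set the
#' per-criterion pass flags. All matches are returned, passing or not, so
#' that consensus and audit can see why a candidate failed; screen
#' positives are the rows with `passed_all`. One measured peak may support
#' several species or compounds: ambiguity is surfaced later through isobar
#' groups, never resolved winner-take-all.
#'
#' @param s A calibrated `centroid_spectrum`.
#' @param db A `compound_db`, or a pre-expanded species table from
#'   [expand_database()] (matching `s`'s polarity).
#' @param criteria A `screening_criteria`.
#' @param blanks List of calibrated blank spectra from the same plate; an
#'   empty list sets all blank thresholds to 0 (everything passes the blank
#'   criterion).
#' @param resolution,prune Isotope-pattern parameters (see
#'   [isotope_pattern()]).
#' @return Data frame of match results: compound, species, theoretical and
#'   observed m/z, signed mass error in mDa, peak height, `iso_fit_score`,
#'   `quality`, `blank_threshold`, the three pass flags and `passed_all`.
#' @export
screen_well <- function(s, db, criteria = screening_criteria(),
                        blanks = list(), resolution = 25000, prune = 1e-4) {
  stopifnot(inherits(s, "centroid_spectrum"))
  species_tab <- if (inherits(db, "compound_db"))
    expand_database(db, s$polarity) else db
  pattern_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(species_tab))
  for (i in seq_len(nrow(species_tab))) {
    mz_theo <- species_tab$mz[i]
    hit <- nearest_peak(s, mz_theo, criteria$mass_tol)
    if (is.null(hit)) next
    key <- species_tab$ion_formula[i]
    pat <- pattern_cache[[key]]
    if (is.null(pat)) {
      pat <- isotope_pattern(parse_formula(key), prune = prune,
                             resolution = resolution)
      pattern_cache[[key]] <- pat
    }
    score <- iso_fit_score(pat, s, anchor_mz = hit$mz,
                           tol = criteria$mass_tol)
    thr <- if (length(blanks))
      blank_threshold(blanks, mz_theo, criteria$mass_tol,
                      criteria$blank_factor) else 0
    pass_mass <- TRUE  # matched within mass_tol by construction
    pass_sigma <- score < criteria$sigma_max
    pass_blank <- hit$intensity > thr
    rows[[i]] <- data.frame(
      well_id = s$well_id, polarity = s$polarity,
      name = species_tab$name[i], cas = species_tab$cas[i],
      class = species_tab$class[i], species = species_tab$species[i],
      ion_formula = species_tab$ion_formula[i],
      isobar_group = species_tab$isobar_group[i],
      mz_theoretical = mz_theo, mz_observed = hit$mz,
      mass_error_mda = (hit$mz - mz_theo) * 1000,
      peak_height = hit$intensity, iso_fit_score = score,
      quality = .quality_band(score, criteria$quality_bands),
      blank_threshold = thr,
      pass_mass = pass_mass, pass_sigma = pass_sigma,
      pass_blank = pass_blank,
      passed_all = pass_mass && pass_sigma && pass_blank,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_match_results())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_match_results <- function() {
  data.frame(well_id = character(0), polarity = character(0),
             name = character(0), cas = character(0), class = character(0),
             species = character(0), ion_formula = character(0),
             isobar_group = character(0), mz_theoretical = numeric(0),
             mz_observed = numeric(0), mass_error_mda = numeric(0),
             peak_height = numeric(0), iso_fit_score = numeric(0),
             quality = character(0), blank_threshold = numeric(0),
             pass_mass = logical(0), pass_sigma = logical(0),
             pass_blank = logical(0), passed_all = logical(0),
             stringsAsFactors = FALSE)
}

#' Replicate consensus and confidence assignment
#'
#' Combines per-well match results into per-sample detections. For each
#' sample x compound x species, `n_detected` counts replicate wells whose
#' match passed all criteria and `n_measured` counts the sample's replicate
#' wells; a detection is validated only when the compound was detected in
#' every measurement (`n_detected == n_measured`), reported in the
#' `n/3` / `n/9` style (triplicate spots, or triplicate extracts times
#' triplicate spots). Validated detections carry confidence level 4
#' (identification by exact mass and isotope pattern only). Compounds whose
#' ion formulas coincide (isobars, indistinguishable at this confidence
#' level) share an isobar group id and are all reported.
#'
#' @param results Data frame of match results from [screen_well()] over the
#'   plate's sample wells (row-bound), or a list of such data frames.
#' @param manifest A `plate_manifest`; every screened sample well must
#'   appear in it.
#' @param criteria A `screening_criteria`.
#' @return A `detection` data frame: `sample_id`, `polarity`, compound
#'   fields, `n_detected`, `n_measured`, `detected` ("n/m"), `validated`,
#'   `mean_mass_error_mda`, `mean_score`, `quality`, `confidence_level`
#'   (4 for validated detections, `NA` otherwise) and `isobar_group`.
#' @export
consensus <- function(results, manifest, criteria = screening_criteria()) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  if (is.null(results) || nrow(results) == 0L)
    results <- .empty_match_results()
  sample_rows <- manifest[manifest$role == "sample", , drop = FALSE]
  unknown <- setdiff(unique(results$well_id), manifest$well_id)
  if (length(unknown))
    stop("screened wells missing from manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- list()
  for (sid in unique(sample_rows$sample_id)) {
    wells <- sample_rows$well_id[sample_rows$sample_id == sid]
    res <- results[results$well_id %in% wells, , drop = FALSE]
    for (pol in unique(res$polarity)) {
      n_measured <- length(wells)  # every replicate well was measured
      rp <- res[res$polarity == pol, , drop = FALSE]
      for (key in unique(paste(rp$name, rp$species, sep = "\r"))) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
        rk <- rp[rp$name == parts[1L] & rp$species == parts[2L], ,
                 drop = FALSE]
        det <- rk[rk$passed_all, , drop = FALSE]
        n_det <- length(unique(det$well_id))
        validated <- n_det == n_measured && n_measured > 0L
        mean_err <- if (nrow(det)) mean(det$mass_error_mda)
                    else mean(rk$mass_error_mda)
        mean_score <- if (nrow(det)) mean(det$iso_fit_score)
                      else mean(rk$iso_fit_score)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, polarity = pol,
          name = rk$name[1L], cas = rk$cas[1L], class = rk$class[1L],
          species = rk$species[1L], ion_formula = rk$ion_formula[1L],
          n_detected = n_det, n_measured = n_measured,
          detected = paste0(n_det, "/", n_measured),
          validated = validated,
          mean_mass_error_mda = mean_err, mean_score = mean_score,
          quality = .quality_band(mean_score, criteria$quality_bands),
          confidence_level = if (validated) 4L else NA_integer_,
          isobar_group = rk$isobar_group[1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(0), polarity = character(0),
                      name = character(0), cas = character(0),
                      class = character(0), species = character(0),
                      ion_formula = character(0), n_detected = integer(0),
                      n_measured = integer(0), detected = character(0),
                      validated = logical(0),
                      mean_mass_error_mda = numeric(0),
                      mean_score = numeric(0), quality = character(0),
                      confidence_level = integer(0),
                      isobar_group = character(0),
                      stringsAsFactors = FALSE))
  det <- do.call(rbind, out)
  rownames(det) <- NULL
  det[order(det$sample_id, det$polarity, -det$validated, det$name,
            det$species), , drop = FALSE]
}
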