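# Synthetic plate acquisitions: seeded generation of complete 48-well
# plates (spectra + manifest + ground truth) with the statistical structure
# the analysis assumes -- full isotope envelopes for spiked compounds,
# systematic + random mass error, two-level lognormal intensity noise
# (extract x spot), PFSA peaks in the calibrant wells, and exponential
# background noise.

#' Synthetic plate design
#'
#' Describes one synthetic 48-well acquisition. The default layout mirrors
#' standard practice: calibrant wells in the first and last position, three
#' blanks, and the remaining wells filled with samples measured as
#' triplicate spots (leftover wells become extra spots of the last sample).
#' Explicitly requested samples (e.g. triplicate extracts x triplicate
#' spots) are allocated first.
#'
#' Noise structure: every generated peak's m/z is passed through the
#' systematic drift model `mz_obs = (1 + slope) * mz + offset` plus
#' `N(0, sigma_mz)`; spiked-species envelopes are scaled by the spike's
#' base height times a per-extract and a per-spot lognormal factor;
#' background peaks are drawn uniformly in m/z with exponential
#' intensities. Defaults (`sigma_spot = 0.15`, `sigma_extract = 0.12`,
#' about 15% and 12% coefficients of variation) sit inside the 6-48%
#' spot-to-spot and 1-46% extract-to-extract RSD ranges observed for
#' replicate well measurements of consumer-product extracts; `sigma_mz` of
#' 1 mDa and a drift of 10 ppm + 2 mDa are typical raw TOF accuracy before
#' internal recalibration.
#'
#' @param n_wells Plate size (default 48).
#' @param calibrant_wells Positions of the calibrant wells (default first
#'   and last).
#' @param blank_wells Positions of the blank wells (default 3 spread over
#'   the plate).
#' @param samples Optional data frame (`sample_id`, `extracts`, `spots`)
#'   allocated before the auto-filled triplicate samples.
#' @param spikes Data frame (`sample_id`, `compound`, `base_height`,
#'   optional `species` as semicolon-separated labels, `NA` = every
#'   database species of the compound). `base_height` is the height of the
#'   species' monoisotopic peak before intensity noise.
#' @param database A `compound_db` (default the bundled database).
#' @param refs A `reference_ions` table (default the bundled PFSA list).
#' @param polarity Modes to acquire: `"both"` (default), `"positive"` or
#'   `"negative"`.
#' @param drift List `slope`, `offset` (Da), `sigma` (Da).
#' @param intensity_noise List `sigma_spot`, `sigma_extract` (lognormal
#'   sigmas) and `sigma_calibrant` (per-reference intensity spread in the
#'   calibrant wells).
#' @param noise List `n_peaks`, `intensity_scale` (exponential mean),
#'   `mz_range`.
#' @param contamination Optional data frame (`mz`, `height`) of peaks
#'   present in every blank (and only there).
#' @param calibrant_height Base intensity of reference-ion peaks.
#' @param height_ceiling Per-peak intensity ceiling approximating detector
#'   saturation (default `Inf`).
#' @param resolution,prune Isotope-pattern / centroid-merging parameters.
#' @param seed Integer seed fixing all randomness of [simulate_plate()].
#' @return A `plate_design` list, with the generated `plate_manifest` in
#'   `$manifest`.
#' @export
#' @examples
#' d <- plate_design(seed = 1)
#' head(d$manifest)
plate_design <- function(n_wells = 48,
                         calibrant_wells = c(1, n_wells),
                         blank_wells = c(2, 25, 47),
                         samples = NULL,
                         spikes = default_spikes(),
                         database = read_database(),
                         refs = reference_ions(),
                         polarity = c("both", "positive", "negative"),
                         drift = list(slope = 1e-5, offset = 0.002,
                                      sigma = 0.001),
                         intensity_noise = list(sigma_spot = 0.15,
                                                sigma_extract = 0.12,
                                                sigma_calibrant = 0.2),
                         noise = list(n_peaks = 150, intensity_scale = 30,
                                      mz_range = c(100, 1100)),
                         contamination = NULL,
                         calibrant_height = 1e4,
                         height_ceiling = Inf,
                         resolution = 25000, prune = 1e-4,
                         seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(n_wells >= length(calibrant_wells) + length(blank_wells) + 1,
            !anyDuplicated(c(calibrant_wells, blank_wells)))
  if (!is.null(spikes)) {
    stopifnot(all(c("sample_id", "compound", "base_height") %in%
                    names(spikes)),
              all(spikes$base_height > 0),
              all(spikes$compound %in% database$name))
    if (!"species" %in% names(spikes)) spikes$species <- NA_character_
  }
  layout <- .build_layout(n_wells, calibrant_wells, blank_wells, samples)
  if (!is.null(spikes)) {
    missing_samples <- setdiff(spikes$sample_id, layout$sample_id)
    if (length(missing_samples))
      stop("spiked sample(s) not in layout: ",
           paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  structure(list(n_wells = n_wells, manifest = layout, spikes = spikes,
                 database = database, refs = refs, polarity = polarity,
                 drift = drift, intensity_noise = intensity_noise,
                 noise = noise, contamination = contamination,
                 calibrant_height = calibrant_height,
                 height_ceiling = height_ceiling, resolution = resolution,
                 prune = prune, seed = as.integer(seed)),
            class = "plate_design")
}

.build_layout <- function(n_wells, calibrant_wells, blank_wells, samples) {
  well_id <- sprintf("W%02d", seq_len(n_wells))
  role <- rep("sample", n_wells)
  role[calibrant_wells] <- "calibrant"
  role[blank_wells] <- "blank"
  sample_id <- rep("", n_wells)
  extract <- replicate_idx <- rep(NA_integer_, n_wells)
  free <- which(role == "sample")
  if (!is.null(samples)) {
    for (i in seq_len(nrow(samples))) {
      need <- samples$extracts[i] * samples$spots[i]
      if (need > length(free))
        stop("not enough wells for sample ", samples$sample_id[i],
             call. = FALSE)
      take <- free[seq_len(need)]
      free <- free[-seq_len(need)]
      sample_id[take] <- samples$sample_id[i]
      extract[take] <- rep(seq_len(samples$extracts[i]),
                           each = samples$spots[i])
      replicate_idx[take] <- rep(seq_len(samples$spots[i]),
                                 samples$extracts[i])
    }
  }
  # auto-fill the rest with triplicate-spot samples; leftovers become extra
  # spots of the last auto sample
  auto <- 0L
  while (length(free) >= 3L) {
    auto <- auto + 1L
    take <- free[1:3]
    free <- free[-(1:3)]
    sample_id[take] <- sprintf("S%02d", auto)
    extract[take] <- 1L
    replicate_idx[take] <- 1:3
  }
  if (length(free) && auto > 0L) {
    last <- sprintf("S%02d", auto)
    extra <- seq_along(free) + 3L
    sample_id[free] <- last
    extract[free] <- 1L
    replicate_idx[free] <- extra
  } else if (length(free)) {
    sample_id[free] <- "S01"
    extract[free] <- 1L
    replicate_idx[free] <- seq_along(free)
  }
  as_plate_manifest(data.frame(well_id = well_id, role = role,
                               sample_id = sample_id, extract = extract,
                               replicate = replicate_idx,
                               stringsAsFactors = FALSE),
                    plate_id = "synthetic")
}

#' @rdname plate_design
#' @return `default_spikes()`: the default spike table -- an
#'   organophosphate flame retardant (TPhP), a brominated one (TBBPA), a
#'   phthalate plasticizer (DEHP) and a bromophenol (2,4,6-TBP) spiked into
#'   sample S01 at 5000 counts, roughly 50-fold above the blank-derived
#'   detection thresholds the default noise level produces.
#' @export
default_spikes <- function() {
  data.frame(sample_id = "S01",
             compound = c("TPhP", "TBBPA", "DEHP", "2,4,6-TBP"),
             base_height = 5000,
             species = NA_character_,
             stringsAsFactors = FALSE)
}

.design_polarity <- function(design)
  switch(design$polarity, both = c("positive", "negative"),
         design$polarity)

# expanded species table for one spike row, in one polarity
.spike_species <- function(design, spike, pol) {
  db <- design$database
  row <- db[db$name == spike$compound, , drop = FALSE]
  tab <- expand_database(row, pol)
  if (!is.na(spike$species)) {
    labs <- vapply(.split_species(spike$species), function(l)
      parse_species(l, pol)$label, character(1))
    tab <- tab[tab$species %in% labs, , drop = FALSE]
  }
  tab
}

.apply_drift <- function(mz, drift, jitter = TRUE) {
  out <- (1 + drift$slope) * mz + drift$offset
  if (jitter && drift$sigma > 0)
    out <- out + stats::rnorm(length(out), 0, drift$sigma)
  out
}

#' Simulate one well spectrum
#'
#' Generates the centroided spectrum of a single well under a design, using
#' the current RNG state (callers wanting reproducibility seed the RNG, as
#' [simulate_plate()] does). Sample wells receive the full merged isotope
#' envelope of every spiked species scaled by `base_height` times the
#' extract and spot lognormal factors; blank wells contain only the
#' design's contamination peaks; calibrant wells contain the reference
#' ions. Every well receives background noise peaks, all m/z values pass
#' through the drift model, and peaks closer than the centroiding
#' resolution allows are merged.
#'
#' @param design A `plate_design`.
#' @param role `"sample"`, `"blank"` or `"calibrant"`.
#' @param pol `"positive"` or `"negative"`.
#' @param well_id Well identifier for the spectrum.
#' @param sample_id Sample the well belongs to (sample wells only).
#' @param extract_factors Named numeric vector of per-extract lognormal
#'   factors, names `"<sample_id>:<extract>:<compound>"`; missing entries
#'   default to 1.
#' @param extract Extract index of the well.
#' @return List with `spectrum` (a `centroid_spectrum`) and `truth` (data
#'   frame of spiked species in this well: compound, species, theoretical
#'   m/z and true anchor height).
#' @export
simulate_well <- function(design, role, pol, well_id = "",
                          sample_id = NULL, extract = 1L,
                          extract_factors = NULL) {
  mz <- inten <- numeric(0)
  truth <- list()
  noise <- design$noise
  if (role == "sample" && !is.null(design$spikes) && !is.null(sample_id)) {
    spikes <- design$spikes[design$spikes$sample_id == sample_id, ,
                            drop = FALSE]
    for (i in seq_len(nrow(spikes))) {
      spike <- spikes[i, ]
      tab <- .spike_species(design, spike, pol)
      key <- paste(sample_id, extract, spike$compound, sep = ":")
      ef <- if (!is.null(extract_factors) && key %in% names(extract_factors))
        extract_factors[[key]] else 1
      sf <- stats::rlnorm(1, 0, design$intensity_noise$sigma_spot)
      for (j in seq_len(nrow(tab))) {
        pat <- .cached_pattern(tab$ion_formula[j], design)
        height <- spike$base_height * ef * sf
        peak_h <- pmin(pat$intensity / pat$intensity[1L] * height,
                       design$height_ceiling)
        mz <- c(mz, .apply_drift(pat$mz, design$drift))
        inten <- c(inten, peak_h)
        truth[[length(truth) + 1L]] <- data.frame(
          well_id = well_id, compound = spike$compound,
          species = tab$species[j], polarity = pol,
          mz_theoretical = tab$mz[j], true_height = height,
          stringsAsFactors = FALSE)
      }
    }
  } else if (role == "blank" && !is.null(design$contamination)) {
    mz <- c(mz, .apply_drift(design$contamination$mz, design$drift))
    inten <- c(inten, design$contamination$height)
  } else if (role == "calibrant") {
    refs <- design$refs[design$refs$polarity == pol, , drop = FALSE]
    h <- design$calibrant_height *
      stats::rlnorm(nrow(refs), 0, design$intensity_noise$sigma_calibrant)
    mz <- c(mz, .apply_drift(refs$mz, design$drift))
    inten <- c(inten, h)
  }
  if (noise$n_peaks > 0) {
    mz <- c(mz, stats::runif(noise$n_peaks, noise$mz_range[1L],
                             noise$mz_range[2L]))
    inten <- c(inten, stats::rexp(noise$n_peaks,
                                  1 / noise$intensity_scale))
  }
  ord <- order(mz)
  merged <- .merge_peaks(mz[ord], inten[ord], design$resolution)
  list(spectrum = centroid_spectrum(merged$mz, merged$intensity, pol,
                                    well_id),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

.cached_pattern <- function(ion_formula, design) {
  cache <- design$.pattern_cache
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  pat <- cache[[ion_formula]]
  if (is.null(pat)) {
    pat <- isotope_pattern(parse_formula(ion_formula),
                           prune = design$prune,
                           resolution = design$resolution)
    cache[[ion_formula]] <- pat
  }
  pat
}

#' Simulate a complete plate
#'
#' Deterministically (given `design$seed`) generates every well spectrum of
#' the plate in each acquired polarity, together with the manifest and the
#' ground truth: which species were spiked where, at which theoretical m/z
#' and true height, and which compounds should validate for each sample
#' under default screening criteria. The caller's RNG state is left
#' untouched.
#'
#' @param design A `plate_design`.
#' @return A `plate_bundle` list: `manifest` (a `plate_manifest`),
#'   `spectra` (per polarity, a named list of `centroid_spectrum` by well
#'   id), `truth` (list with `wells`, `expected`, `seed`) and `design`.
#' @export
#' @examples
#' bundle <- simulate_plate(plate_design(seed = 7))
#' bundle$spectra$positive[["W05"]]
simulate_plate <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)

  design$.pattern_cache <- new.env(parent = emptyenv())
  manifest <- design$manifest
  pols <- .design_polarity(design)

  # per-extract lognormal factors, drawn in a fixed order
  extract_factors <- numeric(0)
  if (!is.null(design$spikes)) {
    sm <- manifest[manifest$role == "sample", , drop = FALSE]
    for (i in seq_len(nrow(design$spikes))) {
      sp <- design$spikes[i, ]
      for (ex in sort(unique(sm$extract[sm$sample_id == sp$sample_id]))) {
        key <- paste(sp$sample_id, ex, sp$compound, sep = ":")
        extract_factors[key] <-
          stats::rlnorm(1, 0, design$intensity_noise$sigma_extract)
      }
    }
  }

  spectra <- stats::setNames(vector("list", length(pols)), pols)
  truth_rows <- list()
  for (pol in pols) {
    wells <- stats::setNames(vector("list", nrow(manifest)),
                             manifest$well_id)
    for (i in seq_len(nrow(manifest))) {
      w <- manifest[i, ]
      sim <- simulate_well(design, w$role, pol, w$well_id,
                           sample_id = if (w$role == "sample") w$sample_id,
                           extract = w$extract,
                           extract_factors = extract_factors)
      wells[[w$well_id]] <- sim$spectrum
      if (!is.null(sim$truth))
        truth_rows[[length(truth_rows) + 1L]] <- sim$truth
    }
    spectra[[pol]] <- wells
  }
  wells_truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
                 else NULL
  expected <- if (!is.null(design$spikes))
    unique(design$spikes[, c("sample_id", "compound")]) else
    data.frame(sample_id = character(0), compound = character(0))
  rownames(expected) <- NULL
  structure(list(manifest = manifest, spectra = spectra,
                 truth = list(wells = wells_truth, expected = expected,
                              seed = design$seed),
                 design = design),
            class = "plate_bundle")
}

#' @export
print.plate_bundle <- function(x, ...) {
  cat("<plate bundle> ", nrow(x$manifest), " wells (",
      paste(names(x$spectra), collapse = "/"), "), seed ",
      x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a plate bundle on disk
#'
#' [write_plate_bundle()] writes `manifest.csv`, one TSV peak list per well
#' and polarity under `spectra/`, and the ground truth as `truth.json`.
#' [read_plate_bundle()] reads the same structure back. Output is plain
#' text and, for a fixed design, byte-identical across runs.
#'
#' @param bundle A `plate_bundle` from [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @return The directory ([write_plate_bundle()]) or a `plate_bundle`
#'   without the `design` element ([read_plate_bundle()]).
#' @export
write_plate_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  m <- as.data.frame(bundle$manifest)
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = TRUE, na = "")
  for (pol in names(bundle$spectra))
    for (w in names(bundle$spectra[[pol]]))
      write_spectrum(bundle$spectra[[pol]][[w]],
                     file.path(dir, "spectra",
                               sprintf("%s_%s.tsv", w, substr(pol, 1, 3))))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_plate_bundle
#' @export
read_plate_bundle <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"),
                            plate_id = basename(dir))
  files <- list.files(file.path(dir, "spectra"), pattern = "\\.tsv$",
                      full.names = TRUE)
  spectra <- list()
  for (f in files) {
    base <- tools::file_path_sans_ext(basename(f))
    pol <- if (grepl("_pos$", base)) "positive" else "negative"
    well <- sub("_(pos|neg)$", "", base)
    spectra[[pol]][[well]] <- read_spectrum(f, "tsv", pol, well)
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(manifest = manifest, spectra = spectra, truth = truth),
            class = "plate_bundle")
}

#' Flame-retarded housing plate design
#'
#' A design emulating the screening ground truth of a flame-retarded
#' electronics housing extract measured as triplicate extracts times
#' triplicate spots (9 wells): BDP, TPhP, TTBP-TAZ and 2,4,6-TBP present,
#' while TCEP, TCP, TBBPA and BDE209 -- compounds screened by the same
#' database -- are absent. Screening this plate should report 9/9 for the
#' four spiked additives and 0/9 for the absent ones.
#'
#' @param seed Seed for [simulate_plate()].
#' @param base_height Spike anchor height.
#' @param ... Further arguments to [plate_design()].
#' @return A `plate_design`.
#' @export
design_tv_housing <- function(seed = 1L, base_height = 5000, ...) {
  plate_design(
    samples = data.frame(sample_id = "tv_housing", extracts = 3L,
                         spots = 3L, stringsAsFactors = FALSE),
    spikes = data.frame(sample_id = "tv_housing",
                        compound = c("BDP", "TPhP", "TTBP-TAZ",
                                     "2,4,6-TBP"),
                        base_height = base_height,
                        species = NA_character_,
                        stringsAsFactors = FALSE),
    seed = seed, ...)
}
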