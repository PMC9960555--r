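# Spot-to-spot and extract-to-extract relative standard deviations of peak
# heights, the two variance levels of replicate MALDI well measurements.

#' Replicate peak-height matrix
#'
#' Peak heights for one compound x species in one sample, indexed extract x
#' spot. `NA` marks a non-detect; non-detects are excluded from the RSD
#' calculations (never zero-filled), with the effective n reported
#' alongside.
#'
#' @param heights Numeric matrix (rows = extracts, columns = spots) or
#'   something coercible; values must be positive where present.
#' @return A `replicate_heights` matrix.
#' @export
#' @examples
#' h <- replicate_heights(rbind(c(80, 100, 120), c(100, 100, 100)))
#' spot_to_spot_rsd(h)
replicate_heights <- function(heights) {
  m <- as.matrix(heights)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("need at least one extract and one spot", call. = FALSE)
  if (any(m[!is.na(m)] <= 0))
    stop("detected heights must be positive (use NA for non-detects)",
         call. = FALSE)
  structure(m, class = c("replicate_heights", "matrix", "array"))
}

.rsd <- function(x) 100 * stats::sd(x) / mean(x)

#' Extract-to-extract RSD
#'
#' The relative standard deviation (sample sd / mean x 100, n-1
#' denominator) over the per-extract mean peak heights: each extract's
#' detected spots are averaged first, then the RSD is taken across
#' extracts. Undefined (`NA`, reported as n/a) with fewer than two extracts
#' that have at least one detected spot.
#'
#' @param h A `replicate_heights` matrix.
#' @return List with `rsd` (percent, `NA` if undefined), `n` (number of
#'   extracts used) and `n_total` (number of extracts).
#' @export
extract_to_extract_rsd <- function(h) {
  stopifnot(inherits(h, "replicate_heights"))
  means <- apply(h, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) mean(r) else NA_real_
  })
  used <- means[!is.na(means)]
  if (length(used) < 2L)
    return(list(rsd = NA_real_, n = length(used), n_total = nrow(h)))
  list(rsd = .rsd(used), n = length(used), n_total = nrow(h))
}

#' Spot-to-spot RSD
#'
#' The mean over extracts of the within-extract RSD across detected spots.
#' Extracts with fewer than two detected spots cannot contribute a
#' within-extract RSD and are dropped with a note; the effective number of
#' detected spots in the used extracts is reported alongside (so one
#' non-detect among 3 x 3 spots yields n = 8, flagged `reduced_n`).
#'
#' @param h A `replicate_heights` matrix.
#' @return List with `rsd` (percent, `NA` if no extract has two detected
#'   spots), `n` (detected spots in the extracts used), `n_total` (total
#'   cells), `extracts_used` and `reduced_n` (`TRUE` when any cell was
#'   excluded).
#' @export
spot_to_spot_rsd <- function(h) {
  stopifnot(inherits(h, "replicate_heights"))
  per_extract <- apply(h, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2L) .rsd(r) else NA_real_
  })
  usable <- !is.na(per_extract)
  n_spots <- sum(!is.na(h[usable, , drop = FALSE]))
  if (!any(usable))
    return(list(rsd = NA_real_, n = 0L, n_total = length(h),
                extracts_used = 0L, reduced_n = TRUE))
  if (!all(usable))
    message(sum(!usable), " extract(s) dropped from spot-to-spot RSD ",
            "(fewer than 2 detected spots)")
  list(rsd = mean(per_extract[usable]), n = n_spots, n_total = length(h),
       extracts_used = sum(usable), reduced_n = n_spots < length(h))
}

#' Replicate RSD table from screening heights
#'
#' Computes spot-to-spot and extract-to-extract RSDs for every sample x
#' compound x species present in a set of match results, using the plate
#' manifest's extract/replicate structure. Wells where the species did not
#' pass all screening criteria count as non-detects.
#'
#' @param results Match results from [screen_well()] over sample wells
#'   (data frame or list of data frames).
#' @param manifest A `plate_manifest` with `extract` and `replicate`
#'   columns.
#' @return Data frame with one row per sample x compound x species:
#'   RSDs in percent, effective n, and `reduced_n` flags.
#' @export
rsd_table <- function(results, manifest) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  sm <- manifest[manifest$role == "sample", , drop = FALSE]
  out <- list()
  for (sid in unique(sm$sample_id)) {
    wells <- sm[sm$sample_id == sid, , drop = FALSE]
    extracts <- sort(unique(wells$extract))
    spots <- sort(unique(wells$replicate))
    res <- results[results$well_id %in% wells$well_id, , drop = FALSE]
    keys <- unique(res[, c("polarity", "name", "species")])
    for (k in seq_len(nrow(keys))) {
      rk <- res[res$polarity == keys$polarity[k] &
                res$name == keys$name[k] &
                res$species == keys$species[k] & res$passed_all, ,
                drop = FALSE]
      m <- matrix(NA_real_, length(extracts), length(spots))
      for (j in seq_len(nrow(rk))) {
        w <- wells[wells$well_id == rk$well_id[j], , drop = FALSE]
        m[match(w$extract, extracts), match(w$replicate, spots)] <-
          rk$peak_height[j]
      }
      if (all(is.na(m))) next
      h <- replicate_heights(m)
      ss <- suppressMessages(spot_to_spot_rsd(h))
      ee <- extract_to_extract_rsd(h)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, polarity = keys$polarity[k], name = keys$name[k],
        species = keys$species[k],
        spot_to_spot_rsd = ss$rsd, spot_n = ss$n,
        spot_n_total = ss$n_total, spot_reduced_n = ss$reduced_n,
        extract_to_extract_rsd = ee$rsd, extract_n = ee$n,
        extract_n_total = ee$n_total, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(0), polarity = character(0),
                      name = character(0), species = character(0),
                      spot_to_spot_rsd = numeric(0), spot_n = integer(0),
                      spot_n_total = integer(0),
                      spot_reduced_n = logical(0),
                      extract_to_extract_rsd = numeric(0),
                      extract_n = integer(0), extract_n_total = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
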