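# Plate manifest and suspect-database IO. Both are plain CSV so that plate
# layouts and compound lists can be maintained in a spreadsheet.

#' Read a plate manifest
#'
#' The manifest maps wells of one target plate to their roles. Required
#' columns: `well_id`, `role` (`blank`, `calibrant` or `sample`),
#' `sample_id` (empty for blanks/calibrants) and `replicate` (spot index
#' within a sample). An optional `extract` column distinguishes replicate
#' extracts of the same sample (defaults to 1), so a sample measured as
#' triplicate extracts times triplicate spots has 9 rows. The standard plate
#' has 48 wells with calibrant wells in the first and last position and 3
#' blanks.
#'
#' @param path CSV file path.
#' @param plate_id Plate identifier; defaults to the file base name.
#' @return A `plate_manifest`: data frame with columns `well_id`, `role`,
#'   `sample_id`, `extract`, `replicate` and attribute `plate_id`.
#' @export
read_manifest <- function(path, plate_id = NULL) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("well_id", "role", "sample_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(plate_id)) plate_id <- tools::file_path_sans_ext(basename(path))
  if (!"extract" %in% names(df)) df$extract <- "1"
  as_plate_manifest(df, plate_id)
}

#' @param df Data frame with the manifest columns.
#' @rdname read_manifest
#' @export
as_plate_manifest <- function(df, plate_id = "plate") {
  bad <- setdiff(unique(df$role), c("blank", "calibrant", "sample"))
  if (length(bad))
    stop("unknown well roles: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$well_id))
    stop("duplicate well_id in manifest", call. = FALSE)
  if (!"extract" %in% names(df)) df$extract <- 1L
  as_int <- function(x) {
    x[is.na(x) | x %in% c("", "NA")] <- NA
    as.integer(x)
  }
  out <- data.frame(well_id = as.character(df$well_id),
                    role = as.character(df$role),
                    sample_id = as.character(df$sample_id),
                    extract = as_int(df$extract),
                    replicate = as_int(df$replicate),
                    stringsAsFactors = FALSE)
  out$extract[out$role != "sample"] <- NA_integer_
  out$replicate[out$role != "sample"] <- NA_integer_
  structure(out, plate_id = plate_id,
            class = c("plate_manifest", "data.frame"))
}

#' Read a suspect-compound database
#'
#' Required columns: `name`, `cas`, `formula` (Hill notation), `class`, and
#' per-mode species lists `pos_species` / `neg_species` as semicolon-
#' separated labels in the species grammar (see [parse_species()]). Formulas
#' and species labels are parsed eagerly so malformed rows fail at load time
#' with their line number. An empty species cell means the compound is
#' screened with the mode-wide default set ([default_species()]) in that
#' mode only.
#'
#' @param path CSV file path; default is the database bundled with the
#'   package (a compact suspect list of plastic additives: organophosphate
#'   and brominated flame retardants, phthalate and non-phthalate
#'   plasticizers, antioxidants, UV stabilizers and common background fatty
#'   acids, with their literature adduct/fragment chemistry).
#' @return A `compound_db` data frame with columns `name`, `cas`, `formula`,
#'   `class`, `pos_species`, `neg_species` plus a parsed-formula list column
#'   `formula_parsed`.
#' @export
#' @examples
#' db <- read_database()
#' head(db$name)
read_database <- function(path = default_database()) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("name", "cas", "formula", "class", "pos_species", "neg_species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("database is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$formula_parsed <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header line
    df$formula_parsed[[i]] <- tryCatch(parse_formula(df$formula[i]),
      error = function(e) stop("database line ", line, " (", df$name[i],
                               "): ", conditionMessage(e), call. = FALSE))
    for (col in c("pos_species", "neg_species")) {
      pol <- if (col == "pos_species") "positive" else "negative"
      for (lab in .split_species(df[[col]][i]))
        tryCatch(parse_species(lab, pol),
          error = function(e) stop("database line ", line, " (", df$name[i],
                                   "): ", conditionMessage(e), call. = FALSE))
    }
  }
  structure(df, class = c("compound_db", "data.frame"))
}

.split_species <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
  trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
}

#' @rdname read_database
#' @return `default_database()`: path to the bundled database CSV.
#' @export
default_database <- function() {
  system.file("extdata", "default_database.csv", package = "maldiscreen",
              mustWork = TRUE)
}

#' Expand a compound database into screenable ion species
#'
#' For one polarity, turns every compound into its list of applicable ion
#' species with theoretical m/z: the compound's own species list for that
#' mode, or the mode-wide default set when the list is empty. Species whose
#' losses are not applicable to the compound's formula (negative element
#' counts) are skipped with a message. Compounds whose post-species ion
#' formulas coincide are isobars and cannot be distinguished by exact mass
#' and isotope pattern; they share an `isobar_group` identifier.
#'
#' @param db A `compound_db` from [read_database()].
#' @param polarity `"positive"` or `"negative"`.
#' @return Data frame with one row per compound x species: `name`, `cas`,
#'   `class`, `species`, `ion_formula`, `mz`, `isobar_group`.
#' @export
expand_database <- function(db, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  col <- if (polarity == "positive") "pos_species" else "neg_species"
  rows <- list()
  for (i in seq_len(nrow(db))) {
    labels <- .split_species(db[[col]][i])
    use_default <- length(labels) == 0L
    specs <- if (use_default) default_species(polarity)
             else lapply(labels, parse_species, polarity = polarity)
    base <- db$formula_parsed[[i]]
    for (s in specs) {
      if (!species_applicable(base, s)) {
        message("skipping inapplicable species [", s$label, "] for ",
                db$name[i])
        next
      }
      ion <- apply_species(base, s)
      rows[[length(rows) + 1L]] <- data.frame(
        name = db$name[i], cas = db$cas[i], class = db$class[i],
        species = s$label, ion_formula = format_formula(ion),
        mz = monoisotopic_mass(ion), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(name = character(0), cas = character(0),
                      class = character(0), species = character(0),
                      ion_formula = character(0), mz = numeric(0),
                      isobar_group = character(0)))
  out$isobar_group <- paste0(polarity, ":", out$ion_formula)
  out
}
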