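# Ion-species grammar: "M" followed by signed formula deltas, e.g. "M+H",
# "M+O+K", "M-C6H2Br3-H". Adducts, in-source fragments and oxidation are all
# expressed as formula deltas; screening only needs the resulting mass.

#' Parse an ion-species label
#'
#' An ion species describes how a neutral compound `M` is turned into a
#' singly charged screenable ion: a sequence of signed elemental deltas
#' applied to the base formula, plus a polarity. Examples from screening
#' practice: the protonated molecule `"M+H"` (positive), the potassium adduct
#' `"M+K"`, the oxidised potassium adduct `"M+O+K"` of phosphites, the
#' deprotonated molecule `"M-H"` (negative), and in-source fragments such as
#' `"M-C6H5"` for aryl phosphates or `"M-C6H2Br3-H"` for brominated
#' triazines. The ASCII hyphen and the Unicode minus are both accepted.
#'
#' @param label Species label string; `"M"` alone is the intact (molecular)
#'   ion.
#' @param polarity `"positive"` or `"negative"`.
#' @return An `ion_species` object: list with `label` (canonical form),
#'   `deltas` (list of `(sign, formula)` pairs in written order) and
#'   `polarity`. The charge magnitude is fixed at 1.
#' @export
#' @examples
#' parse_species("M+O+K", "positive")
#' parse_species("M-C6H2Br3-H", "negative")
parse_species <- function(label, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  lab <- gsub("[[:space:]]", "", label)
  lab <- gsub("−|–", "-", lab)  # unicode minus/en-dash
  if (!grepl("^M([+-][A-Za-z0-9]+)*$", lab))
    stop("malformed species label: '", label, "'", call. = FALSE)
  deltas <- list()
  if (nchar(lab) > 1L) {
    body <- substring(lab, 2L)
    m <- gregexpr("[+-][A-Za-z0-9]+", body)[[1L]]
    groups <- regmatches(body, list(m))[[1L]]
    deltas <- lapply(groups, function(g) {
      list(sign = if (substring(g, 1L, 1L) == "+") +1L else -1L,
           formula = parse_formula(substring(g, 2L)))
    })
  }
  structure(list(label = .format_species_deltas(deltas),
                 deltas = deltas, polarity = polarity, charge = 1L),
            class = "ion_species")
}

.format_species_deltas <- function(deltas) {
  if (length(deltas) == 0L) return("M")
  paste0("M", paste0(vapply(deltas, function(d) {
    paste0(if (d$sign > 0L) "+" else "-", format_formula(d$formula))
  }, character(1)), collapse = ""))
}

#' @param s An `ion_species`.
#' @return `format_species()`: the canonical label, round-tripping through
#'   [parse_species()].
#' @rdname parse_species
#' @export
format_species <- function(s) s$label

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion species> [", x$label, "]",
      if (x$polarity == "positive") "+" else "-", "\n", sep = "")
  invisible(x)
}

#' Apply an ion species to a base formula
#'
#' Element-wise applies the species' signed deltas to the compound formula,
#' giving the elemental composition of the ion. A species whose losses exceed
#' the available atoms (e.g. `"M-C6H5"` on ethane) is *inapplicable* to that
#' compound: `apply_species()` raises an error, and [species_applicable()]
#' provides the corresponding predicate so database expansion can skip the
#' species with a note instead of failing.
#'
#' @param base `molecular_formula` of the neutral compound.
#' @param s `ion_species`.
#' @return The ion's `molecular_formula`.
#' @export
#' @examples
#' tbbpa <- parse_formula("C15H12Br4O2")
#' apply_species(tbbpa, parse_species("M-H", "negative"))
apply_species <- function(base, s) {
  stopifnot(inherits(s, "ion_species"))
  out <- as.integer(base)
  names(out) <- names(base)
  for (d in s$deltas)
    out <- .formula_combine(out, d$formula, d$sign)
  if (any(out < 0L))
    stop("species [", s$label, "] is inapplicable to ",
         format_formula(base), " (negative element count)", call. = FALSE)
  .new_formula(out)
}

#' @rdname apply_species
#' @return `species_applicable()`: `TRUE` if all element counts stay
#'   non-negative.
#' @export
species_applicable <- function(base, s) {
  out <- as.integer(base)
  names(out) <- names(base)
  for (d in s$deltas)
    out <- .formula_combine(out, d$formula, d$sign)
  all(out >= 0L)
}

#' Theoretical m/z of a compound ion
#'
#' Monoisotopic mass of the species-transformed formula. The charge
#' magnitude is 1, so m/z equals the ion mass. By default no electron-mass
#' correction is applied: singly charged screening m/z values are quoted as
#' neutral-fragment monoisotopic masses, the convention used by common
#' screening software for annotated spectra (the difference, one electron
#' mass of about 0.55 mDa, is well inside the 5 mDa matching tolerance).
#' Set `electron_correction = TRUE` to subtract (positive mode) or add
#' (negative mode) the electron mass.
#'
#' @inheritParams apply_species
#' @param electron_correction Apply the +/- 0.000548579909 u electron-mass
#'   term (default `FALSE`).
#' @return m/z in Da.
#' @export
#' @examples
#' tphp <- parse_formula("C18H15O4P")
#' theoretical_mz(tphp, parse_species("M-C6H5", "negative")) # 249.0317
theoretical_mz <- function(base, s, electron_correction = FALSE) {
  mass <- monoisotopic_mass(apply_species(base, s))
  if (electron_correction) {
    me <- 0.000548579909
    mass <- mass + if (s$polarity == "positive") -me else me
  }
  mass
}

#' Mode-wide default species sets
#'
#' The species screened for every compound that has no compound-specific
#' species list: protonated, potassium and sodium adducts in positive mode
#' (potassium adducts dominate when extracts are salted with KCl), and the
#' deprotonated molecule in negative mode. Compound-specific extras (chloride
#' adducts of chlorinated paraffins, bromide/oxide exchange for brominated
#' analytes, diagnostic in-source fragments) belong in the database's species
#' columns.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return List of `ion_species`.
#' @export
default_species <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  labels <- if (polarity == "positive") c("M+H", "M+K", "M+Na") else "M-H"
  lapply(labels, parse_species, polarity = polarity)
}
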