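# Bundled isotope table: one pinned reference set for all mass arithmetic.

.maldiscreen_env <- new.env(parent = emptyenv())

#' Bundled isotope table
#'
#' Returns the isotope masses and natural abundances bundled with the package
#' (see `inst/extdata/isotopes.tsv` for provenance). All monoisotopic masses
#' and isotope patterns computed by the package derive from this single table,
#' so results are reproducible across installations.
#'
#' @return A data frame with columns `element`, `nominal`, `mass` (u) and
#'   `abundance` (mole fraction, summing to 1 within each element). Rows are
#'   ordered by element and descending abundance, so the first row of each
#'   element is its most abundant (monoisotopic-defining) isotope.
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function() {
  tab <- .maldiscreen_env$isotopes
  if (is.null(tab)) {
    path <- system.file("extdata", "isotopes.tsv", package = "maldiscreen",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, comment.char = "#",
                             colClasses = c("character", "integer",
                                            "numeric", "numeric"))
    tab <- tab[order(tab$element, -tab$abundance), , drop = FALSE]
    rownames(tab) <- NULL
    .maldiscreen_env$isotopes <- tab
  }
  tab
}

#' @return `supported_elements()`: character vector of element symbols with a
#'   bundled isotope record.
#' @rdname isotope_table
#' @export
supported_elements <- function() unique(isotope_table()$element)

# isotopes of one element, most abundant first
.element_isotopes <- function(symbol) {
  tab <- isotope_table()
  rows <- tab[tab$element == symbol, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  rows
}

# mass of the most abundant isotope
.monoisotope_mass <- function(symbol) .element_isotopes(symbol)$mass[[1L]]
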