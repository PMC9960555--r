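# Molecular-formula arithmetic. A formula is a named integer vector of
# element counts ("molecular_formula" S3 class); the empty formula is legal
# and has mass 0.

.new_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts)) {
    # Hill order: C, H, then alphabetical
    els <- names(counts)
    hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
    counts <- counts[hill]
  }
  structure(as.integer(counts), names = names(counts),
            class = "molecular_formula")
}

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string such as `"C18H15O4P"` into a named
#' integer vector of element counts. Only elements present in the bundled
#' isotope table (see [isotope_table()]) are accepted; two-letter symbols
#' (`Cl`, `Br`, `Na`, ...) are recognised greedily, so `"NaCl"` is sodium
#' chloride, not nitrogen + aluminium + chlorine.
#'
#' @param text A single formula string, e.g. `"C6H2Br3O"`. The empty string
#'   yields the empty formula (mass 0).
#' @return A `molecular_formula`: named integer vector of counts in Hill
#'   order.
#' @export
#' @examples
#' parse_formula("C18H15O4P")
#' monoisotopic_mass(parse_formula("C6H2Br3O"))
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("[[:space:]]", "", text)
  if (text == "" || text == "0") return(.new_formula(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(tokens) == 0L)
    stop("malformed formula string: '", text, "'", call. = FALSE)
  counts <- integer(0)
  known <- supported_elements()
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% known)
      stop("unknown element symbol: '", el, "' in '", text, "'",
           call. = FALSE)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  .new_formula(counts)
}

#' @param f,a,b Formulas as returned by [parse_formula()].
#' @return `format_formula()`: the canonical Hill-order string.
#' @rdname parse_formula
#' @export
format_formula <- function(f) {
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<formula> ", if (length(x)) format_formula(x) else "(empty)",
      "  monoisotopic mass ", sprintf("%.6f", monoisotopic_mass(x)),
      "\n", sep = "")
  invisible(x)
}

# element-wise sum/difference; negative counts are allowed here and must be
# checked by the caller (species applicability)
.formula_combine <- function(a, b, sign = 1L) {
  els <- union(names(a), names(b))
  va <- ifelse(els %in% names(a), as.integer(a)[match(els, names(a))], 0L)
  vb <- ifelse(els %in% names(b), as.integer(b)[match(els, names(b))], 0L)
  out <- va + sign * vb
  names(out) <- els
  out
}

#' @rdname parse_formula
#' @export
formula_add <- function(a, b) {
  .new_formula(.formula_combine(a, b, 1L))
}

#' @rdname parse_formula
#' @export
formula_subtract <- function(a, b) {
  out <- .formula_combine(a, b, -1L)
  if (any(out < 0L))
    stop("formula subtraction yields negative counts: ",
         paste0(names(out)[out < 0L], collapse = ", "), call. = FALSE)
  .new_formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope, from the bundled isotope table. The empty formula has mass 0.
#' No electron-mass correction is applied here; see [theoretical_mz()].
#'
#' @param f A `molecular_formula`.
#' @return Mass in Da (u).
#' @export
monoisotopic_mass <- function(f) {
  if (length(f) == 0L) return(0)
  sum(vapply(names(f), .monoisotope_mass, numeric(1)) * as.numeric(f))
}
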