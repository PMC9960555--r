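# Exact isotope-distribution computation: per-element multinomial
# distributions convolved across elements, then pruned and merged to the
# instrument's resolving power. Probabilities below .CONV_EPS are dropped
# during convolution; this is far below every comparison tolerance used
# downstream.

.CONV_EPS <- 1e-16

# exact distribution of n atoms of one element: enumerate all isotope
# compositions (k1..kj), n = sum k, p = multinomial(n; k) * prod(a_i^k_i)
.element_distribution <- function(symbol, n) {
  iso <- .element_isotopes(symbol)
  k <- nrow(iso)
  if (n == 0L) return(list(mass = 0, p = 1))
  if (k == 1L) return(list(mass = n * iso$mass, p = 1))
  comps <- .compositions(n, k)  # one composition per row
  logp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) +
    comps %*% log(iso$abundance)
  p <- exp(as.numeric(logp))
  mass <- as.numeric(comps %*% iso$mass)
  keep <- p >= .CONV_EPS
  ord <- order(mass[keep])
  list(mass = mass[keep][ord], p = p[keep][ord])
}

# all length-k non-negative integer vectors summing to n
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- NULL
  for (i in 0:n) {
    sub <- .compositions(n - i, k - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# convolve two (mass, p) distributions, aggregate numerically equal masses
.convolve_dist <- function(a, b) {
  mass <- outer(a$mass, b$mass, "+")
  p <- outer(a$p, b$p)
  keep <- p >= .CONV_EPS
  mass <- mass[keep]
  p <- p[keep]
  key <- round(mass * 1e9)  # isotopologues identical to < 1 nDa collapse
  agg_p <- rowsum(p, key, reorder = TRUE)
  agg_m <- rowsum(mass * p, key, reorder = TRUE) / agg_p
  ord <- order(agg_m)
  list(mass = as.numeric(agg_m)[ord], p = as.numeric(agg_p)[ord])
}

#' Exact isotopologue distribution of a formula
#'
#' The unmerged fine distribution: every isotopic composition of the formula
#' with probability above the internal floor (`1e-16`), computed by exact
#' per-element multinomial enumeration and cross-element convolution. Used
#' internally by [isotope_pattern()] and directly by tests that compare
#' against exhaustive enumeration.
#'
#' @param f A `molecular_formula`.
#' @return Data frame with columns `mz` (ascending) and `prob`
#'   (absolute probabilities, summing to 1 up to the pruning floor).
#' @export
#' @examples
#' isotopologue_distribution(parse_formula("Br2"))
isotopologue_distribution <- function(f) {
  dist <- list(mass = 0, p = 1)
  for (el in names(f))
    dist <- .convolve_dist(dist, .element_distribution(el, f[[el]]))
  data.frame(mz = dist$mass, prob = dist$p)
}

#' Resolution-merged isotope pattern
#'
#' Computes the theoretical isotope pattern a centroiding instrument of the
#' given resolving power would report for a formula: the exact isotopologue
#' distribution is pruned (relative probability below `prune` dropped),
#' peaks closer than half a peak width `(m/z / resolution) / 2` are merged
#' into their intensity-weighted centroid, and intensities are renormalised
#' to sum to 1.
#'
#' @param f A `molecular_formula` (typically of an ion, via
#'   [apply_species()]).
#' @param prune Relative probability threshold in `(0, 0.01]`; isotopologues
#'   below `prune` times the most probable one are dropped. Default `1e-4`
#'   keeps heavily brominated envelopes (Br4 and beyond) complete while
#'   bounding pattern size.
#' @param resolution Resolving power (FWHM, dimensionless), assumed constant
#'   across m/z as is approximately true for TOF analysers. Default 25000.
#' @return An `isotope_pattern`: data frame with columns `mz` (ascending Da)
#'   and `intensity` (fractions summing to 1), with the formula, `prune` and
#'   `resolution` stored as attributes. The first row is the monoisotopic
#'   peak for CHNOPS/halogen chemistry.
#' @export
#' @examples
#' isotope_pattern(parse_formula("C6H2Br3O"))
isotope_pattern <- function(f, prune = 1e-4, resolution = 25000) {
  stopifnot(prune > 0, prune <= 0.01, resolution > 0)
  fine <- isotopologue_distribution(f)
  if (nrow(fine) == 0L)
    stop("empty isotopologue distribution", call. = FALSE)
  fine <- fine[fine$prob >= prune * max(fine$prob), , drop = FALSE]
  merged <- .merge_peaks(fine$mz, fine$prob, resolution)
  out <- data.frame(mz = merged$mz,
                    intensity = merged$intensity / sum(merged$intensity))
  structure(out, class = c("isotope_pattern", "data.frame"),
            formula = format_formula(f), prune = prune,
            resolution = resolution)
}

# greedy ascending clustering: a peak joins the current cluster when its gap
# to the previous peak is below half the local peak width
.merge_peaks <- function(mz, intensity, resolution) {
  if (length(mz) <= 1L) return(list(mz = mz, intensity = intensity))
  gap <- diff(mz)
  width <- (mz[-1L] / resolution) / 2
  cluster <- cumsum(c(1L, as.integer(gap >= width)))
  inten <- as.numeric(rowsum(intensity, cluster))
  cent <- as.numeric(rowsum(mz * intensity, cluster)) / inten
  list(mz = cent, intensity = inten)
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope pattern> ", attr(x, "formula"), ", ", nrow(x),
      " peaks (R = ", attr(x, "resolution"), ", prune = ",
      attr(x, "prune"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 10)
  invisible(x)
}
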