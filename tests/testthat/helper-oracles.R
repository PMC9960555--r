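# Independent oracles and small fixture builders shared across test files.

# Exhaustive multinomial enumeration of a formula's isotopologues,
# independent of the package's convolution: per-element compositions via
# expand.grid, probabilities via dmultinom, aggregation by rounded mass.
enumerate_isotopologues <- function(formula_text) {
  tab <- isotope_table()
  f <- parse_formula(formula_text)
  grids <- list()
  for (el in names(f)) {
    iso <- tab[tab$element == el, , drop = FALSE]
    n <- f[[el]]
    if (nrow(iso) == 1L) {
      grids[[el]] <- data.frame(mass = n * iso$mass, p = 1)
    } else {
      comp <- expand.grid(rep(list(0:n), nrow(iso)))
      comp <- comp[rowSums(comp) == n, , drop = FALSE]
      grids[[el]] <- data.frame(
        mass = as.numeric(as.matrix(comp) %*% iso$mass),
        p = apply(comp, 1L, function(k)
          stats::dmultinom(k, prob = iso$abundance)))
    }
  }
  out <- data.frame(mass = 0, p = 1)
  for (g in grids) {
    out <- data.frame(mass = as.numeric(outer(out$mass, g$mass, "+")),
                      p = as.numeric(outer(out$p, g$p)))
  }
  key <- round(out$mass * 1e9)
  agg <- data.frame(
    mass = as.numeric(rowsum(out$mass * out$p, key) / rowsum(out$p, key)),
    p = as.numeric(rowsum(out$p, key)))
  agg[order(agg$mass), , drop = FALSE]
}

# linear-scan nearest peak, the brute-force counterpart of nearest_peak()
brute_nearest <- function(s, target, tol) {
  best <- NULL
  for (i in seq_along(s$mz)) {
    d <- abs(s$mz[i] - target)
    if (d > tol) next
    if (is.null(best)) { best <- i; next }
    db <- abs(s$mz[best] - target)
    if (d < db ||
        (d == db && s$intensity[i] > s$intensity[best]) ||
        (d == db && s$intensity[i] == s$intensity[best] &&
           s$mz[i] < s$mz[best]))
      best <- i
  }
  if (is.null(best)) NULL
  else list(mz = s$mz[best], intensity = s$intensity[best], index = best)
}

# an isotope_pattern-shaped object with given peaks (for score tests)
fake_pattern <- function(mz, intensity) {
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("isotope_pattern", "data.frame"),
            formula = "fake", prune = 1e-4, resolution = 25000)
}

# a minimal 5-well manifest: one triplicate sample, one blank, one calibrant
tiny_manifest <- function() {
  as_plate_manifest(data.frame(
    well_id = c("C1", "B1", "S1a", "S1b", "S1c"),
    role = c("calibrant", "blank", "sample", "sample", "sample"),
    sample_id = c("", "", "SMP", "SMP", "SMP"),
    extract = c(NA, NA, 1L, 1L, 1L),
    replicate = c(NA, NA, 1L, 2L, 3L)), plate_id = "tiny")
}

# small random formula (<= 4 elements) for property tests
.rand_formula <- function(els) {
  picked <- sample(els, sample(1:4, 1))
  parse_formula(paste0(picked, sample(1:20, length(picked),
                                      replace = TRUE), collapse = ""))
}

# quiet wrappers
quiet_screen_plate <- function(...) suppressMessages(screen_plate(...))
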