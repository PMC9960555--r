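# helpers to fabricate calibrant spectra under a known drift model
.drifted_cal_spectrum <- function(refs, pol, slope = 0, offset = 0,
                                  well = "C1") {
  r <- refs[refs$polarity == pol, ]
  centroid_spectrum((1 + slope) * r$mz + offset,
                    rep(1000, nrow(r)), pol, well)
}

# intercept-equivalent offset of a near-identity linear model
.eval_cal_offset <- function(m) m$coefficients[1L] / m$coefficients[2L]

test_that("reference-ion config loads with computed m/z in range", {
  refs <- reference_ions()
  expect_true(all(c("label", "polarity", "mz") %in% names(refs)))
  neg <- refs[refs$polarity == "negative", ]
  pos <- refs[refs$polarity == "positive", ]
  expect_gte(nrow(neg), 2L)
  expect_gte(nrow(pos), 2L)
  expect_true(all(neg$mz > 298 & neg$mz < 1038))
  expect_true(all(pos$mz > 376 & pos$mz < 1116))
  # PFBS [M-H]- anchor value
  expect_equal(round(min(neg$mz), 3), 298.942)
})

test_that("a constant offset is exactly removed by a linear fit", {
  refs <- reference_ions()
  s <- .drifted_cal_spectrum(refs, "negative", offset = 0.010)
  m <- fit_calibration(s, refs, kind = "linear")
  expect_equal(m$kind, "linear")
  corrected <- apply_calibration(s, m)
  resid <- corrected$mz - refs$mz[refs$polarity == "negative"]
  expect_true(all(abs(resid) < 1e-9))
})

test_that("error-free references give an identity-equivalent model", {
  refs <- reference_ions()
  s <- .drifted_cal_spectrum(refs, "positive")
  m <- fit_calibration(s, refs, kind = "linear")
  expect_lt(m$rms_residual, 1e-12)
  expect_equal(m$coefficients[2L], 1, tolerance = 1e-10)
  expect_equal(m$coefficients[1L], 0, tolerance = 1e-7)
})

test_that("linear drift parameters are recovered to solver precision", {
  refs <- reference_ions()
  slope <- 1e-5
  offset <- 0.002
  s <- .drifted_cal_spectrum(refs, "negative", slope = slope,
                             offset = offset)
  m <- fit_calibration(s, refs, kind = "linear")
  # fitted model is the analytic inverse of mz_obs = 1.00001 mz + 0.002
  expect_equal(m$coefficients[2L], 1 / (1 + slope), tolerance = 1e-7)
  expect_equal(m$coefficients[1L], -offset / (1 + slope),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(m$n_refs_used,
               sum(refs$polarity == "negative"))
})

test_that("models degrade gracefully when references go missing", {
  refs <- reference_ions()
  neg <- refs[refs$polarity == "negative", ]
  # only two reference peaks present -> quadratic degrades to linear
  s2 <- centroid_spectrum(neg$mz[1:2], c(10, 10), "negative")
  expect_warning(m2 <- fit_calibration(s2, refs, kind = "quadratic"),
                 "degrading")
  expect_equal(m2$kind, "linear")
  # nothing matches -> identity with warning
  s0 <- centroid_spectrum(c(150.1), c(10), "negative")
  expect_warning(m0 <- fit_calibration(s0, refs, kind = "linear"),
                 "degrading")
  expect_equal(m0$kind, "identity")
  expect_identical(m0$coefficients, c(0, 1))
})

test_that("applying models preserves intensities and peak order", {
  s <- centroid_spectrum(c(100, 200, 300), c(1, 2, 3), "positive")
  id <- fit_calibration(centroid_spectrum(numeric(0), numeric(0),
                                          "positive"),
                        reference_ions(), kind = "identity")
  expect_equal(apply_calibration(s, id)$mz, s$mz)
  shift <- structure(list(kind = "linear", coefficients = c(0.002, 1),
                          n_refs_used = 2L, rms_residual = 0),
                     class = "calibration_model")
  expect_equal(apply_calibration(s, shift)$mz, s$mz + 0.002)
  expect_equal(apply_calibration(s, shift)$intensity, s$intensity)
  bad <- structure(list(kind = "quadratic",
                        coefficients = c(0, -1, 0.001),
                        n_refs_used = 3L, rms_residual = 0),
                   class = "calibration_model")
  expect_error(apply_calibration(s, bad), "non-monotone")
})

test_that("plate calibration policies combine calibrant wells correctly", {
  refs <- reference_ions()
  man <- as_plate_manifest(data.frame(
    well_id = c("W1", "W2", "W3", "W4", "W5"),
    role = c("calibrant", "sample", "sample", "sample", "calibrant"),
    sample_id = c("", "A", "A", "A", ""),
    replicate = c(NA, 1L, 2L, 3L, NA)))
  mk <- function(offset, w) .drifted_cal_spectrum(refs, "negative",
                                                  offset = offset, well = w)
  spectra <- list(W1 = mk(0.002, "W1"), W2 = mk(0.0025, "W2"),
                  W3 = mk(0.003, "W3"), W4 = mk(0.0035, "W4"),
                  W5 = mk(0.004, "W5"))
  # identical drift in both calibrants: average equals either
  same <- list(W1 = mk(0.002, "W1"), W2 = mk(0.0025, "W2"),
               W3 = mk(0.003, "W3"), W4 = mk(0.0035, "W4"),
               W5 = mk(0.002, "W5"))
  avg_same <- plate_calibration(same, man, refs, policy = "average")
  cal1 <- attr(avg_same, "calibrant_models")[["W1"]]
  expect_equal(avg_same$W3$coefficients, cal1$coefficients,
               tolerance = 1e-10)
  # +0.002 / +0.004 offsets average to an effective +0.003
  avg <- plate_calibration(spectra, man, refs, policy = "average")
  expect_equal(.eval_cal_offset(avg$W3), -0.003, tolerance = 1e-6)
  # nearest beats first on drift that grows across the plate
  near <- plate_calibration(spectra, man, refs, policy = "nearest")
  first <- plate_calibration(spectra, man, refs, policy = "first")
  resid <- function(models) {
    vapply(c("W2", "W3", "W4"), function(w) {
      corr <- apply_calibration(spectra[[w]], models[[w]])
      median(abs(corr$mz - refs$mz[refs$polarity == "negative"]))
    }, numeric(1))
  }
  expect_lt(median(resid(near)), median(resid(first)))
  # no calibrant wells at all -> identity models with warning
  man_nc <- as_plate_manifest(data.frame(
    well_id = "W2", role = "sample", sample_id = "A", replicate = 1L))
  expect_warning(nc <- plate_calibration(spectra["W2"], man_nc, refs),
                 "no calibrant")
  expect_equal(nc$W2$kind, "identity")
})

test_that("between-calibrant reference-intensity RSD is reported", {
  refs <- reference_ions()
  man <- as_plate_manifest(data.frame(
    well_id = c("W1", "W2"), role = c("calibrant", "calibrant"),
    sample_id = c("", ""), replicate = c(NA, NA)))
  r <- refs[refs$polarity == "negative", ]
  sp <- list(
    W1 = centroid_spectrum(r$mz, rep(100, nrow(r)), "negative", "W1"),
    W2 = centroid_spectrum(r$mz, rep(150, nrow(r)), "negative", "W2"))
  models <- plate_calibration(sp, man, refs)
  # each reference: heights 100/150 -> RSD = sd/mean*100
  expect_equal(attr(models, "reference_intensity_rsd"),
               100 * sd(c(100, 150)) / 125, tolerance = 1e-9)
})
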