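# a small noiseless design used by several tests: no background peaks, no
# intensity noise, no drift
.noiseless_design <- function(seed = 1) {
  plate_design(
    drift = list(slope = 0, offset = 0, sigma = 0),
    intensity_noise = list(sigma_spot = 0, sigma_extract = 0,
                           sigma_calibrant = 0),
    noise = list(n_peaks = 0, intensity_scale = 30,
                 mz_range = c(100, 1100)),
    seed = seed)
}

test_that("the noiseless limit reproduces theoretical patterns exactly", {
  b <- simulate_plate(.noiseless_design())
  tw <- b$truth$wells
  w <- tw$well_id[tw$compound == "TBBPA" & tw$polarity == "negative"][1L]
  s <- b$spectra$negative[[w]]
  pat <- isotope_pattern(parse_formula("C15H11Br4O2"))
  for (k in seq_len(nrow(pat))) {
    hit <- nearest_peak(s, pat$mz[k], 1e-6)
    expect_false(is.null(hit))
    expect_equal(hit$mz, pat$mz[k], tolerance = 1e-12)
  }
  hit1 <- nearest_peak(s, pat$mz[1L], 1e-6)
  expect_equal(hit1$intensity, 5000)  # anchor height = base height
  # envelope intensity ratios are exactly the theoretical ones
  h <- vapply(seq_len(nrow(pat)),
              function(k) nearest_peak(s, pat$mz[k], 1e-6)$intensity,
              numeric(1))
  expect_equal(h / sum(h), pat$intensity, tolerance = 1e-12)
})

test_that("pipeline on a noiseless plate recovers spikes with zero error
           and zero score", {
  b <- simulate_plate(.noiseless_design())
  res <- quiet_screen_plate(b)
  v <- subset(res$detections, validated)
  expect_true(all(b$truth$expected$compound %in% v$name))
  spiked <- subset(res$matches,
                   name %in% b$truth$expected$compound & passed_all)
  expect_lt(max(abs(spiked$mass_error_mda)), 1e-6)
  expect_lt(max(spiked$iso_fit_score), 1e-9)
})

test_that("blank wells contain only noise peaks", {
  d <- plate_design(seed = 2, contamination = NULL)
  b <- simulate_plate(d)
  blank_ids <- b$manifest$well_id[b$manifest$role == "blank"]
  s <- b$spectra$positive[[blank_ids[1L]]]
  expect_lte(length(s$mz), d$noise$n_peaks)
  expect_true(all(s$intensity < 60 * d$noise$intensity_scale))
  # with zero noise peaks a contamination-free blank is empty
  d0 <- .noiseless_design()
  b0 <- simulate_plate(d0)
  expect_equal(length(b0$spectra$positive[[blank_ids[1L]]]$mz), 0L)
})

test_that("the same seed reproduces a plate byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_plate_bundle(simulate_plate(plate_design(seed = 17)), d1)
  write_plate_bundle(simulate_plate(plate_design(seed = 17)), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  # and a different seed differs
  d3 <- withr::local_tempdir()
  write_plate_bundle(simulate_plate(plate_design(seed = 18)), d3)
  sp <- grep("W05", f1, value = TRUE)[1L]
  expect_false(identical(readLines(file.path(d1, sp), warn = FALSE),
                         readLines(file.path(d3, sp), warn = FALSE)))
})

test_that("simulating a plate leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_plate(plate_design(seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("raw anchor mass errors follow the drift + jitter model", {
  db <- read_database()
  refs <- reference_ions()
  errs <- c()
  for (seed in 1:6) {
    d <- plate_design(seed = seed, database = db, refs = refs)
    b <- simulate_plate(d)
    tw <- b$truth$wells
    for (i in seq_len(nrow(tw))) {
      s <- b$spectra[[tw$polarity[i]]][[tw$well_id[i]]]
      drifted <- (1 + d$drift$slope) * tw$mz_theoretical[i] +
        d$drift$offset
      hit <- nearest_peak(s, drifted, 0.02)
      if (!is.null(hit)) errs <- c(errs, hit$mz - drifted)
    }
  }
  n <- length(errs)
  expect_gt(n, 250)
  sigma <- 0.001
  # moment comparison within 3 standard errors of the generating model
  expect_lt(abs(mean(errs)), 3 * sigma / sqrt(n) + 1e-5)
  expect_lt(abs(sd(errs) - sigma), 3 * sigma / sqrt(2 * n) + 1e-5)
})

test_that("validation turns on monotonically as spike height crosses the
           blank threshold", {
  db <- read_database()
  refs <- reference_ions()
  heights <- c(20, 60, 400, 4000)
  frac <- sapply(heights, function(h) {
    hits <- 0; total <- 0
    for (seed in 1:3) {
      spikes <- data.frame(sample_id = "S01", compound = "TBBPA",
                           base_height = h, species = NA_character_)
      d <- plate_design(seed = seed, spikes = spikes, database = db,
                        refs = refs, polarity = "negative")
      res <- quiet_screen_plate(simulate_plate(d), db = db, refs = refs)
      v <- subset(res$detections,
                  validated & sample_id == "S01" & name == "TBBPA")
      hits <- hits + (nrow(v) > 0)
      total <- total + 1
    }
    hits / total
  })
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[1L], 0)
  expect_equal(frac[length(frac)], 1)
})
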