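test_that("TSV peak lists read faithfully in both separators", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "100.0\t5.0", "200.0\t7.0"), p)
  s <- read_spectrum(p, polarity = "positive")
  expect_s3_class(s, "centroid_spectrum")
  expect_equal(s$mz, c(100, 200))
  expect_equal(s$intensity, c(5, 7))

  writeLines(c("100.0,5.0", "100.0,3.0", "200.0,7.0"), p)
  s2 <- read_spectrum(p, polarity = "negative")
  # duplicate m/z rows are kept, not merged
  expect_equal(s2$mz, c(100, 100, 200))
  expect_equal(s2$polarity, "negative")

  writeLines(c("200.0\t7.0", "100.0\t5.0"), p)
  expect_warning(s3 <- read_spectrum(p, polarity = "positive"), "unsorted")
  expect_equal(s3$mz, c(100, 200))

  writeLines("100.0\tabc", p)
  expect_error(read_spectrum(p, polarity = "positive"), "non-numeric")
  expect_error(read_spectrum(file.path(tempdir(), "nope.tsv")),
               "not found")
})

test_that("spectra round-trip through TSV and mzML writers", {
  s <- centroid_spectrum(c(104.34567891, 249.0317, 998.87),
                         c(12.5, 5000.25, 3.75),
                         "negative", "W07")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, tsv)
  s_tsv <- read_spectrum(tsv, polarity = "negative")
  expect_equal(s_tsv$mz, s$mz, tolerance = 1e-6 / 100)
  expect_equal(s_tsv$intensity, s$intensity, tolerance = 1e-6)

  mzml <- withr::local_tempfile(fileext = ".mzML")
  write_spectrum(s, mzml)
  s_mzml <- read_spectrum(mzml)
  expect_equal(s_mzml$mz, s$mz, tolerance = 1e-6 / 100)
  expect_equal(s_mzml$intensity, s$intensity, tolerance = 1e-6)
  expect_equal(s_mzml$polarity, "negative")
})

test_that("nearest_peak agrees with a linear scan and breaks ties as
           documented", {
  s <- centroid_spectrum(c(249.0320), c(10), "negative")
  hit <- nearest_peak(s, 249.0317, 0.005)
  expect_equal(hit$mz, 249.0320)
  expect_null(nearest_peak(centroid_spectrum(249.0380, 10, "negative"),
                           249.0317, 0.005))
  expect_null(nearest_peak(centroid_spectrum(numeric(0), numeric(0),
                                             "negative"), 100, 0.01))
  # equidistant peaks: higher intensity wins, then lower m/z
  tie <- centroid_spectrum(c(99.99, 100.01), c(5, 9), "positive")
  expect_equal(nearest_peak(tie, 100, 0.05)$mz, 100.01)
  tie2 <- centroid_spectrum(c(99.99, 100.01), c(9, 9), "positive")
  expect_equal(nearest_peak(tie2, 100, 0.05)$mz, 99.99)
  # brute-force equivalence on random spectra
  set.seed(41)
  for (i in 1:20) {
    mz <- sort(runif(80, 100, 1000))
    sp <- centroid_spectrum(mz, rexp(80, 1 / 50), "positive")
    target <- runif(1, 100, 1000)
    tol <- runif(1, 0.001, 2)
    expect_identical(nearest_peak(sp, target, tol),
                     brute_nearest(sp, target, tol))
  }
})

test_that("manifests validate roles and the default plate layout", {
  d <- plate_design(seed = 1)
  m <- d$manifest
  expect_s3_class(m, "plate_manifest")
  expect_equal(nrow(m), 48L)
  expect_equal(m$role[c(1L, 48L)], c("calibrant", "calibrant"))
  expect_equal(sum(m$role == "blank"), 3L)
  # round-trip through CSV
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(m), p, row.names = FALSE, na = "")
  m2 <- read_manifest(p)
  for (col in names(m)) expect_equal(m2[[col]], m[[col]])
  expect_error(as_plate_manifest(data.frame(
    well_id = "W1", role = "mystery", sample_id = "", replicate = NA)),
    "unknown well roles")
})

test_that("the compound database loads with parsed chemistry", {
  db <- read_database()
  expect_s3_class(db, "compound_db")
  tphp <- db[db$name == "TPhP", ]
  expect_equal(tphp$formula, "C18H15O4P")
  pos <- expand_database(db[db$name == "TPhP", ], "positive")
  neg <- expand_database(db[db$name == "TPhP", ], "negative")
  expect_setequal(pos$species, c("M+H", "M+K", "M+Na"))
  expect_identical(neg$species, "M-C6H5")
  expect_equal(round(neg$mz, 4), 249.0317)
  # empty species cell -> mode-wide defaults
  dehp_neg <- expand_database(db[db$name == "DEHP", ], "negative")
  expect_identical(dehp_neg$species, "M-H")
  # row-level errors carry the line number
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,cas,formula,class,pos_species,neg_species",
               "Good,1-1-1,C6H6,x,,",
               "Bad,2-2-2,C6Qq6,x,,"), p)
  expect_error(read_database(p), "line 3")
  writeLines(c("name,cas,formula,class,pos_species,neg_species",
               "Bad,2-2-2,C6H6,x,M++H,"), p)
  expect_error(read_database(p), "line 2")
  writeLines(c("name,cas,formula", "x,y,C6H6"), p)
  expect_error(read_database(p), "missing columns")
})

test_that("inapplicable species are skipped during expansion", {
  db_row <- read_database()[read_database()$name == "BPA", ]
  db_row$pos_species <- "M-CH3;M-C20H5"  # second loss impossible
  expect_message(tab <- expand_database(db_row, "positive"),
                 "inapplicable")
  expect_identical(tab$species, "M-CH3")
})
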