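test_that("iso_fit_score is 0 on perfect agreement and matches the
           hand-computed two-peak case", {
  pat <- isotope_pattern(parse_formula("C15H11Br4O2"))
  s <- centroid_spectrum(pat$mz, pat$intensity * 5e4, "negative")
  expect_equal(iso_fit_score(pat, s, anchor_mz = pat$mz[1L]), 0,
               tolerance = 1e-12)
  # theoretical (0.5, 0.5) vs measured (1, 0):
  # 1000 * sqrt((0.25 + 0.25) / 2) = 500
  two <- fake_pattern(c(100, 101), c(0.5, 0.5))
  s2 <- centroid_spectrum(100, 1, "positive")
  expect_equal(iso_fit_score(two, s2, anchor_mz = 100), 500)
})

test_that("iso_fit_score grows monotonically as one measured isotope
           intensity is perturbed away from theory", {
  pat <- isotope_pattern(parse_formula("C24H39O4"))
  set.seed(5)
  for (rep in 1:5) {
    j <- sample(seq_len(min(3, nrow(pat))), 1)
    scores <- vapply(c(1, 1.5, 2.5, 5, 10), function(fac) {
      inten <- pat$intensity
      inten[j] <- inten[j] * fac
      s <- centroid_spectrum(pat$mz, inten * 1e4, "positive")
      iso_fit_score(pat, s, anchor_mz = pat$mz[1L])
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-12))
  }
})

test_that("iso_fit_score tolerates residual mass offset via anchoring", {
  pat <- isotope_pattern(parse_formula("C6H2Br3O"))
  s <- centroid_spectrum(pat$mz + 0.003, pat$intensity * 1e4, "negative")
  expect_lt(iso_fit_score(pat, s, anchor_mz = pat$mz[1L] + 0.003), 1)
})

test_that("blank thresholds follow the strict 3x-highest-blank rule", {
  mk_blank <- function(h) centroid_spectrum(500, h, "positive", "B")
  blanks <- lapply(c(10, 20, 15), mk_blank)
  expect_equal(blank_threshold(blanks, 500, tol = 0.005, factor = 3), 60)
  # empty blanks -> threshold 0, any positive peak passes
  empty <- list(centroid_spectrum(numeric(0), numeric(0), "positive"))
  expect_equal(blank_threshold(empty, 500), 0)
  # blank peaks elsewhere -> that blank contributes its noise floor
  busy <- list(centroid_spectrum(c(100, 200, 300), c(4, 8, 40),
                                 "positive"))
  expect_equal(blank_threshold(busy, 500), 3 * 8)
})

test_that("screen_well matches, scores and flags candidates", {
  db <- read_database()
  crit <- screening_criteria()
  tbbpa_ion <- parse_formula("C15H11Br4O2")
  pat <- isotope_pattern(tbbpa_ion)
  blank <- centroid_spectrum(c(400, 600), c(30, 30), "negative", "B1")
  # blank noise floor 30 -> threshold 90; spike at 10x that
  s <- centroid_spectrum(pat$mz, pat$intensity / pat$intensity[1L] * 900,
                         "negative", "S1a")
  res <- screen_well(s, db, crit, blanks = list(blank))
  hit <- res[res$name == "TBBPA", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$species, "M-H")
  expect_true(hit$passed_all)
  expect_lt(abs(hit$mass_error_mda), 1e-6)
  expect_lt(hit$iso_fit_score, 1e-9)
  # no other brominated compound matches this envelope
  expect_false(any(res$name == "BDE209"))
  # a spike at exactly the blank threshold fails the strict inequality
  s_eq <- centroid_spectrum(pat$mz, pat$intensity / pat$intensity[1L] * 90,
                            "negative", "S1a")
  res_eq <- screen_well(s_eq, db, crit, blanks = list(blank))
  hit_eq <- res_eq[res_eq$name == "TBBPA", ]
  expect_equal(hit_eq$peak_height, hit_eq$blank_threshold)
  expect_false(hit_eq$pass_blank)
  expect_false(hit_eq$passed_all)
  # just above the threshold passes
  s_gt <- centroid_spectrum(pat$mz,
                            pat$intensity / pat$intensity[1L] * 90.01,
                            "negative", "S1a")
  res_gt <- screen_well(s_gt, db, crit, blanks = list(blank))
  expect_true(res_gt[res_gt$name == "TBBPA", "pass_blank"])
  # empty spectrum -> empty result
  empty <- centroid_spectrum(numeric(0), numeric(0), "negative", "S1a")
  expect_equal(nrow(screen_well(empty, db, crit)), 0L)
})

test_that("screening a fixed plate twice is deterministic", {
  b <- simulate_plate(plate_design(seed = 19))
  r1 <- quiet_screen_plate(b)
  r2 <- quiet_screen_plate(b)
  expect_identical(r1$detections, r2$detections)
  expect_identical(r1$matches, r2$matches)
})

test_that("tightening any criterion never adds detections", {
  b <- simulate_plate(plate_design(seed = 4))
  key <- function(res) with(subset(res$detections, validated),
                            paste(sample_id, name, species, polarity))
  base <- key(quiet_screen_plate(b))
  tighter <- list(screening_criteria(mass_tol = 0.002),
                  screening_criteria(sigma_max = 10),
                  screening_criteria(blank_factor = 10))
  for (crit in tighter)
    expect_true(all(key(quiet_screen_plate(b, criteria = crit)) %in% base))
})
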