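test_that("write-then-read of a simulated signal is lossless", {
  x <- gen_flm(500, H = 0.4, alpha = 1, seed = 81)
  f <- withr::local_tempfile(fileext = ".txt")
  write_signal(x, f)
  y <- read_segment(f)
  expect_identical(as.vector(y), as.vector(as.double(x)))
})

test_that("the segment reader tolerates blanks and names the offending line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.5", "", "  2.25 ", "3", "4", "5", "oops", "8"), f)
  expect_error(read_segment(f), "line 7")
  writeLines(c("1.5", "", "  2.25 ", "3,"), f)
  y <- read_segment(f)
  expect_equal(as.vector(y), c(1.5, 2.25, 3))
  expect_error(read_segment(file.path(tempdir(), "absent.txt")), "not found")
})

test_that("fixtures are complete, described, and byte-identical per seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- make_fixtures(d1, seed = 5)
  expect_gte(nrow(man), 10)
  expect_true(all(file.exists(file.path(d1, man$file))))
  expect_true(file.exists(file.path(d1, "fixtures_manifest.json")))

  # EEG-dialect fixture: 4097 integer samples, read back at full length
  eeg <- read_segment(file.path(d1, "synthetic_eeg_C.txt"))
  expect_length(eeg, 4097)
  expect_true(all(eeg == round(eeg)))

  # the nonstationary-gain fixture has its block boundaries at 200/400/600/800
  x1 <- read_segment(file.path(d1, "x1_n1000.txt"))
  x3 <- read_segment(file.path(d1, "x3_n1000.txt"))
  expect_identical(x3[201:400], 3 * x1[201:400])
  expect_identical(x3[401:600], 10 * x1[401:600])

  make_fixtures(d2, seed = 5)
  for (f in man$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("experiment configs validate ids and fields", {
  expect_error(experiment_config("nope"), "arg")
  expect_error(experiment_config("r_sweep", bogus = 1), "unknown config field")
  cfg <- experiment_config("hurst_sweep_fbm", reduced = TRUE)
  expect_equal(cfg$h_grid, seq(0.1, 0.9, 0.1))
  expect_equal(cfg$r_grid, seq(0.1, 1, 0.1))
  expect_error(run_experiment(list(id = "r_sweep")), "experiment_config")
})

test_that("the length sweep writes deterministic tidy results and conserves undefined counts", {
  d <- withr::local_tempdir()
  cfg <- experiment_config("length_sweep", outdir = d, seed = 3,
                           lengths = c(50L, 100L), n_realisations = 5L,
                           kinds = "white")
  out1 <- run_experiment(cfg)
  expect_true(all(file.exists(out1$files)))
  res <- out1$results
  expect_setequal(unique(res$measure), c("ApEn", "SampEn", "RangeEnA", "RangeEnB"))
  # undefined counts conserved between raw rows and summary
  s <- out1$summary
  expect_true(all(s$n_defined + s$n_undefined == 5L))
  raw_undef <- sum(res$undefined)
  expect_equal(sum(s$n_undefined), raw_undef)
  # undefined values are blank cells in the CSV, not zeros
  csv <- utils::read.csv(file.path(d, "length_sweep_results.csv"))
  expect_equal(sum(is.na(csv$value)), raw_undef)
  # re-running the same config reproduces identical results
  out2 <- run_experiment(cfg)
  expect_identical(out1$results$value, out2$results$value)
})

test_that("the amplitude experiment shows RangeEn invariance and ApEn/SampEn divergence", {
  d <- withr::local_tempdir()
  cfg <- experiment_config("amplitude_test", outdir = d, seed = 11,
                           n = 500L, r_grid = seq(0.2, 1, 0.2))
  res <- run_experiment(cfg)$results
  pick <- function(sig, msr, sdc) {
    res$value[res$signal == sig & res$measure == msr & res$sd_correction == sdc]
  }
  for (msr in c("RangeEnA", "RangeEnB")) {
    expect_equal(pick("x2", msr, FALSE), pick("x1", msr, FALSE), tolerance = 1e-12)
  }
  expect_gt(max(abs(pick("x2", "SampEn", FALSE) - pick("x1", "SampEn", FALSE)),
                na.rm = TRUE), 0.1)
  # the SD-corrected arm exists for ApEn/SampEn only
  expect_setequal(unique(res$measure[res$sd_correction]), c("ApEn", "SampEn"))
})

test_that("the covariance-scaling experiment records matched-seed profiles per D", {
  d <- withr::local_tempdir()
  cfg <- experiment_config("cov_scaling", outdir = d, seed = 2, n = 300L,
                           d_grid = c(0.01, 1), r_grid = c(0.25, 0.5, 1))
  res <- run_experiment(cfg)$results
  expect_setequal(unique(res$D), c(0.01, 1))
  rb <- function(D) res$value[res$D == D & res$measure == "RangeEnB"]
  expect_equal(rb(0.01), rb(1), tolerance = 1e-12)
})

test_that("EEG-style segment profiling runs on dialect files and reports Hurst", {
  d <- withr::local_tempdir()
  f <- file.path(d, "seg_a.txt")
  write_signal(round(50 * gen_noise(800, "pink", seed = 13)), f)
  cfg <- experiment_config("eeg_profiles", outdir = d, eeg_paths = f,
                           r_grid = c(0.2, 0.6, 1))
  res <- run_experiment(cfg)$results
  expect_setequal(unique(res$measure), c("ApEn", "SampEn", "RangeEnA", "RangeEnB"))
  expect_true(all(is.finite(res$hurst)))
  # range-entropy rows are never SD-corrected
  expect_true(all(!res$sd_correction[res$measure %in% c("RangeEnA", "RangeEnB")]))
  expect_error(run_experiment(experiment_config("eeg_profiles", outdir = d)),
               "eeg_paths")
})
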