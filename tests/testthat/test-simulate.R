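panel <- bundled_panel()

test_that("noise-free full-detection spectra equal the visible mass set", {
  for (taxon in c("Osphranter robustus", "Tachyglossus aculeatus",
                  "Vombatus ursinus")) {
    pk <- simulate_spectrum(panel, taxon, noise_free_params(), seed = 1)
    want <- emission_masses <- sort(unique(with(
      panel$alleles[panel$alleles$taxon == taxon &
                      panel$alleles$visibility == "maldi_visible" &
                      !is.na(panel$alleles$nominal_mz), ],
      ifelse(is.na(computed_mz), nominal_mz, computed_mz))))
    expect_equal(pk$mz, want, tolerance = 1e-9)
  }
})

test_that("markers reported only from LC-MS/MS are never emitted", {
  # O. rufus F' 2913 is MS/MS-only; its F base 2897 is visible
  pk <- simulate_spectrum(panel, "Osphranter rufus", noise_free_params(),
                          seed = 3)
  expect_true(any(abs(pk$mz - 2897.44) < 0.1))
  expect_false(any(abs(pk$mz - 2913.43) < 0.1))
})

test_that("state spectra contain only what the state allows", {
  pk <- simulate_spectrum(panel, "collagen_only",
                          sim_params(mass_sd = 0, noise_peaks = 0), seed = 2)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 1162.6), 0.1)
  pk2 <- simulate_spectrum(panel, "non_collagen",
                           sim_params(noise_peaks = 7), seed = 2)
  expect_identical(nrow(pk2), 7L)
  expect_true(all(pk2$mz >= 800 & pk2$mz <= 3200))
  expect_error(simulate_spectrum(panel, "Homo sapiens"), "Unknown taxon")
})

test_that("identical seeds give identical spectra", {
  p <- sim_params(mass_sd = 0.1, detection = 0.7, noise_peaks = 5)
  a <- simulate_spectrum(panel, "Isoodon macrourus", p, seed = 77)
  b <- simulate_spectrum(panel, "Isoodon macrourus", p, seed = 77)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_spectrum(panel, "Isoodon macrourus", p, seed = 78)
  expect_false(identical(a$mz, c$mz))
})

test_that("mean absolute mass error matches the half-normal mean", {
  p <- sim_params(mass_sd = 0.1, detection = 1, noise_peaks = 0)
  errs <- c()
  taxa <- unique(panel$alleles$taxon)
  i <- 0
  while (length(errs) < 10000) {
    i <- i + 1
    taxon <- taxa[(i %% length(taxa)) + 1]
    pk <- simulate_spectrum(panel, taxon, p, seed = 1000 + i)
    want <- sort(unique(with(
      panel$alleles[panel$alleles$taxon == taxon &
                      panel$alleles$visibility == "maldi_visible" &
                      !is.na(panel$alleles$nominal_mz), ],
      ifelse(is.na(computed_mz), nominal_mz, computed_mz))))
    # nearest-truth assignment of each emitted peak
    errs <- c(errs, vapply(pk$mz, function(m) min(abs(m - want)),
                           numeric(1)))
  }
  # E|X| for X ~ N(0, 0.1) is 0.1 * sqrt(2/pi) = 0.0798
  expect_lt(abs(mean(errs) - 0.0798) / 0.0798, 0.1)
})

test_that("lowering detection never adds peaks at a fixed seed", {
  for (seed in 1:10) {
    hi <- simulate_spectrum(panel, "Perameles nasuta",
                            sim_params(mass_sd = 0.05, detection = 0.9,
                                       noise_peaks = 0), seed = seed)
    lo <- simulate_spectrum(panel, "Perameles nasuta",
                            sim_params(mass_sd = 0.05, detection = 0.4,
                                       noise_peaks = 0), seed = seed)
    expect_true(all(lo$mz %in% hi$mz))
  }
})

test_that("assemblages carry one truth row per sample and are reproducible", {
  comp <- c("Osphranter robustus" = 3, "Isoodon macrourus" = 2,
            "collagen_only" = 1)
  dir1 <- withr::local_tempdir()
  a1 <- simulate_assemblage(panel, comp, sim_params(), seed = 9,
                            out_dir = dir1)
  expect_identical(nrow(a1), 6L)
  expect_identical(sum(a1$truth == "Osphranter robustus"), 3L)
  expect_true(file.exists(file.path(dir1, "truth.tsv")))
  expect_identical(length(list.files(dir1, pattern = "\\.txt$")), 6L)
  dir2 <- withr::local_tempdir()
  a2 <- simulate_assemblage(panel, comp, sim_params(), seed = 9,
                            out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_error(simulate_assemblage(panel, c("Osphranter robustus" = 0)),
               "positive")
  expect_error(simulate_assemblage(panel, integer(0)), "named")
})

test_that("sim config files parse into parameters", {
  f <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("# simulation settings", "[simulation]",
               "mass_sd = 0.1", "detection = 0.6", "noise_peaks = 3"), f)
  p <- read_sim_config(f)
  expect_equal(p$mass_sd, 0.1)
  expect_equal(p$detection, 0.6)
  expect_identical(p$noise_peaks, 3L)
  writeLines("bogus_knob = 1", f)
  expect_error(read_sim_config(f), "bogus_knob")
})
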