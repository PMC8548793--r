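panel <- bundled_panel()

test_that("peaks match alleles within tolerance, with collision flags", {
  m <- match_peaks(peaklist(1162.60, 100), panel)
  expect_true(all(m$matches$marker == "P1"))
  expect_true(all(abs(m$matches$deviation) <= 0.3))
  expect_false(any(m$matches$taxon == "Tachyglossus aculeatus"))
  # 2975 is ambiguous between the G' oxidation state and COL1A2 10-42
  m2 <- match_peaks(peaklist(2975.4, 50), panel)
  expect_setequal(unique(m2$matches$marker), c("G", "COL1A2 10-42"))
  expect_true(all(m2$matches$collision))
  # empty input gives empty results, not an error
  m3 <- match_peaks(peaklist(numeric(0)), panel)
  expect_identical(nrow(m3$matches), 0L)
  expect_identical(nrow(m3$loci), 0L)
})

test_that("match counts never decrease with tolerance", {
  pk <- simulate_spectrum(panel, "Phascolarctos cinereus",
                          sim_params(mass_sd = 0.15, noise_peaks = 10),
                          seed = 4)
  tols <- c(0.05, 0.1, 0.2, 0.3, 0.5, 1.0)
  counts <- vapply(tols, function(tol) {
    nrow(match_peaks(pk, panel, match_params(tolerance = tol))$matches)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("noise-free spectra classify to the known candidate sets", {
  cl <- classify_spectrum(
    simulate_spectrum(panel, "Osphranter robustus", noise_free_params(),
                      seed = 1), panel)
  expect_identical(cl$status, "identified")
  expect_setequal(cl$candidates, c(
    "Lagorchestes conspicillatus", "Osphranter robustus", "Osphranter rufus",
    "Notamacropus agilis", "Notamacropus parma", "Notamacropus rufogriseus"))
  expect_identical(cl$label, "Macropodidae")
  expect_identical(cl$rank, "family")

  cl2 <- classify_spectrum(
    simulate_spectrum(panel, "Macropus giganteus", noise_free_params(),
                      seed = 1), panel)
  expect_setequal(cl2$candidates,
                  c("Macropus giganteus", "Macropus fuliginosus"))
  expect_identical(cl2$label, "Macropus")

  cl3 <- classify_spectrum(
    simulate_spectrum(panel, "Notamacropus eugenii", noise_free_params(),
                      seed = 1), panel)
  expect_setequal(cl3$candidates,
                  c("Notamacropus eugenii", "Wallabia bicolor"))

  cl4 <- classify_spectrum(
    simulate_spectrum(panel, "Tachyglossus aculeatus", noise_free_params(),
                      seed = 1), panel)
  expect_identical(cl4$candidates, "Tachyglossus aculeatus")
  expect_identical(cl4$rank, "species")
})

test_that("a complete F/F' pair excludes the banded hare wallaby", {
  # macropod pair 2897/2913 conflicts with the 2881/2897 pair; a lone 2897
  # never does (oxidation-ladder overlap)
  full <- classify_spectrum(
    simulate_spectrum(panel, "Osphranter robustus", noise_free_params(),
                      seed = 1), panel)
  expect_false("Lagostrophus fasciatus" %in% full$candidates)
  lone <- consistent_taxa(
    peaklist(c(1162.5963, 1150.6327, 1166.6276, 1453.7433, 2145.1298,
               2897.4387, 1652.8390)), panel)
  expect_true("Lagostrophus fasciatus" %in% lone)
  expect_true("Osphranter robustus" %in% lone)
})

test_that("P1-only and P1-less spectra take the right outcome statuses", {
  only_p1 <- classify_spectrum(peaklist(1162.60, 100), panel)
  expect_identical(only_p1$status, "collagen_unidentifiable")
  expect_identical(length(only_p1$candidates), 0L)
  # collagen-like series without the P1 marker
  no_p1 <- classify_spectrum(
    peaklist(c(1453.74, 2145.13, 2897.44), c(50, 40, 30)), panel)
  expect_identical(no_p1$status, "tentative_fish_or_bird")
  # nothing matching at all
  none <- classify_spectrum(peaklist(c(900.1, 2500.9), c(5, 5)), panel)
  expect_identical(none$status, "failed")
})

test_that("candidate sets never shrink when peaks are removed", {
  set.seed(31)
  for (i in 1:8) {
    taxon <- sample(unique(panel$alleles$taxon), 1)
    pk <- simulate_spectrum(panel, taxon,
                            sim_params(mass_sd = 0.05, noise_peaks = 3),
                            seed = 300 + i)
    full <- consistent_taxa(pk, panel)
    keep <- sort(sample(nrow(pk), max(1, nrow(pk) - 3)))
    sub <- peaklist(pk$mz[keep], pk$intensity[keep])
    expect_true(all(full %in% consistent_taxa(sub, panel)))
  }
})

test_that("classification equals the brute-force oracle across taxa", {
  taxa <- sort(unique(panel$alleles$taxon))
  for (taxon in taxa) {
    for (seed in 1:3) {
      pk <- simulate_spectrum(panel, taxon,
                              sim_params(mass_sd = 0.05, detection = 0.9,
                                         noise_peaks = 3), seed = seed)
      expect_identical(consistent_taxa(pk, panel),
                       oracle_candidates(pk$mz, panel),
                       info = sprintf("%s seed %d", taxon, seed))
    }
  }
})

test_that("truth is contained and equals the class for noise-free spectra", {
  eq <- equivalence_classes(panel, "maldi_visible_only")
  for (taxon in sort(unique(panel$alleles$taxon))) {
    cl <- classify_spectrum(
      simulate_spectrum(panel, taxon, noise_free_params(), seed = 6), panel)
    expect_true(taxon %in% cl$candidates)
    members <- strsplit(eq$class_members[eq$taxon == taxon], ";")[[1]]
    expect_true(all(members %in% cl$candidates))
  }
})

test_that("D-locus 2161/2177 oxidation states never mutually exclude", {
  # an observed 2161 peak must not exclude taxa whose D is reported at 2177
  cand <- consistent_taxa(peaklist(c(1162.5963, 2161.1247)), panel)
  expect_true("Sarcophilus harrisii" %in% cand)   # D reported at 2177
  expect_true("Pseudocheirus peregrinus" %in% cand) # D reported at 2161
  expect_false("Osphranter robustus" %in% cand)   # D at 2145, no +16 state
  # and the reverse: 2177 must not exclude the taxon reported at 2161
  cand2 <- consistent_taxa(peaklist(c(1162.5963, 2177.1196)), panel)
  expect_true("Pseudocheirus peregrinus" %in% cand2)
  expect_true("Isoodon macrourus" %in% cand2)
})

test_that("classification glance/tidy/report produce tabular summaries", {
  comp <- c("Osphranter robustus" = 36, "Isoodon macrourus" = 3,
            "Trichosurus vulpecula" = 1)
  asm <- simulate_assemblage(panel, comp, noise_free_params(), seed = 12)
  res <- classify_assemblage(asm, panel)
  expect_identical(nrow(res), 40L)
  expect_true(all(res$status == "identified"))
  rep <- zooms_report(res)
  expect_identical(rep$id_table$nisp[rep$id_table$label == "Macropodidae"],
                   36L)
  expect_identical(rep$id_table$nisp[rep$id_table$label == "Isoodon macrourus"],
                   3L)
  expect_identical(
    rep$id_table$nisp[rep$id_table$label == "Trichosurus vulpecula"], 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f)
  expect_true(file.exists(f))
  g <- glance(res$classification[[1]])
  expect_identical(g$status, "identified")
  expect_s3_class(tidy(res$classification[[1]]), "tbl_df")
})

test_that("an all-failed assemblage reports an empty identification table", {
  asm <- simulate_assemblage(panel, c(non_collagen = 4),
                             sim_params(noise_peaks = 3), seed = 21)
  res <- classify_assemblage(asm, panel)
  rep <- zooms_report(res)
  expect_identical(nrow(rep$id_table), 0L)
  expect_identical(rep$status_tally$n[rep$status_tally$status == "failed"], 4L)
})

test_that("plots build without error", {
  pk <- simulate_spectrum(panel, "Vombatus ursinus", sim_params(), seed = 2)
  expect_s3_class(plot_spectrum(pk, panel), "ggplot")
  expect_s3_class(plot_panel(panel), "ggplot")
  cl <- classify_spectrum(pk, panel)
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
})
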