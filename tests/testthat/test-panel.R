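panel <- bundled_panel()

test_that("the bundled panel covers the 24 reference taxa", {
  expect_identical(length(unique(panel$alleles$taxon)), 24L)
  expect_identical(nrow(panel$loci), 11L)
  # monotreme P1 allele
  p1 <- panel$alleles[panel$alleles$taxon == "Tachyglossus aculeatus" &
                        panel$alleles$marker == "P1", ]
  expect_identical(p1$nominal_mz, 1120)
  expect_true(p1$diagnostic)
  # unreported cells are wildcards without a stored mass
  lasA <- panel$alleles[panel$alleles$taxon == "Lasiorhinus sp." &
                          panel$alleles$marker == "A", ]
  expect_true(all(lasA$visibility == "unreported"))
  expect_true(all(is.na(lasA$nominal_mz)))
})

test_that("panel TSV round trip is stable and preserves unknown columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  p2 <- panel
  p2$alleles$curator_note <- paste0("n", seq_len(nrow(p2$alleles)))
  write_panel(p2, f)
  p3 <- read_panel(f)
  expect_identical(dim(p3$alleles), dim(p2$alleles))
  expect_equal(p3$alleles$nominal_mz, p2$alleles$nominal_mz)
  expect_equal(p3$alleles$computed_mz, p2$alleles$computed_mz)
  expect_identical(p3$alleles$visibility, p2$alleles$visibility)
  expect_identical(p3$alleles$curator_note, p2$alleles$curator_note)
  expect_identical(p3$collisions$nominal_mz, p2$collisions$nominal_mz)
  # load . save . load == load
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p3, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the installed panel TSV equals the in-code panel", {
  f <- system.file("extdata", "marsupial_panel.tsv", package = "ozzooms")
  skip_if(f == "", "extdata not installed")
  p2 <- read_panel(f)
  expect_equal(p2$alleles$nominal_mz, panel$alleles$nominal_mz)
  expect_identical(p2$alleles$taxon, panel$alleles$taxon)
})

test_that("panel reading rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("", f)
  expect_error(read_panel(f), "empty|missing")
  df <- readr::read_tsv(system.file("extdata", "marsupial_panel.tsv",
                                    package = "ozzooms"),
                        col_types = readr::cols(.default = "c"))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df[, setdiff(names(df), "visibility")], f3)
  expect_error(read_panel(f3), "visibility")
  df$span[5] <- "12..40"
  f4 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df, f4)
  expect_error(read_panel(f4), "span '12\\.\\.40' at line 6")
})

test_that("the bundled panel validates with zero inconsistencies", {
  v <- validate_panel(panel)
  expect_identical(sum(!v$sequence_checks$consistent), 0L)
  expect_identical(sum(!v$pair_checks$consistent), 0L)
  expect_identical(nrow(v$flags), 0L)
  # all sequence-bearing alleles carry an inferred hydroxylation count
  expect_false(any(is.na(v$sequence_checks$inferred_k)))
  # oxidation pairs computed from sequence differ by 15.99 +/- 0.02
  seq_pairs <- v$pair_checks[v$pair_checks$kind %in% "oxpair", ]
  expect_true(all(abs(seq_pairs$offset - 15.99) <= 0.02 |
                    abs(seq_pairs$offset - 16) <= 1))
})

test_that("a corrupted allele mass is flagged exactly once", {
  broken <- panel
  i <- which(broken$alleles$taxon == "Osphranter robustus" &
               broken$alleles$marker == "B")
  broken$alleles$nominal_mz[i] <- broken$alleles$nominal_mz[i] + 7
  v <- validate_panel(broken)
  expect_identical(sum(!v$sequence_checks$consistent), 1L)
  expect_identical(v$flags$taxon, "Osphranter robustus")
})

test_that("cross-locus and base/+16 collisions are registered", {
  cc <- panel$collisions$nominal_mz
  expect_true(all(c(2975, 2945, 2959) %in% cc))
  # 2975 is both the common COL1A2 10-42 mass and a G' oxidation state
  expect_match(panel$collisions$reason[panel$collisions$nominal_mz == 2975],
               "multiple_loci")
})

test_that("monotreme diagnostic masses sit far from all marsupial alleles", {
  a <- panel$alleles
  mono <- a[a$taxon == "Tachyglossus aculeatus", ]
  for (mk in c("P1", "C", "E")) {
    m_mono <- mono$nominal_mz[mono$marker == mk]
    m_mars <- a$nominal_mz[a$taxon != "Tachyglossus aculeatus" &
                             a$marker == mk & !is.na(a$nominal_mz)]
    expect_true(all(abs(outer(m_mono, m_mars, "-")) > 2))
  }
})

test_that("the monotreme E peptide is four residues longer (KP fusion)", {
  seqs <- marker_sequences()
  e <- seqs[seqs$marker == "E", ]
  expect_identical(nchar(e$sequence[e$nominal == 2848]) -
                     nchar(e$sequence[e$nominal == 2335]), 4L)
  # the monotreme peptide contains the K-P motif that blocks cleavage
  expect_match(e$sequence[e$nominal == 2848], "KP")
})

test_that("equivalence classes group known indistinguishable taxa", {
  eq <- equivalence_classes(panel, "maldi_visible_only")
  cls <- function(t) eq$class[eq$taxon == t]
  expect_identical(cls("Notamacropus eugenii"), cls("Wallabia bicolor"))
  expect_identical(cls("Macropus giganteus"), cls("Macropus fuliginosus"))
  six <- c("Lagorchestes conspicillatus", "Osphranter robustus",
           "Osphranter rufus", "Notamacropus agilis", "Notamacropus parma",
           "Notamacropus rufogriseus")
  expect_identical(length(unique(eq$class[eq$taxon %in% six])), 1L)
  # the monotreme is always alone
  expect_identical(sum(eq$class == cls("Tachyglossus aculeatus")), 1L)
})

test_that("equivalence classes are invariant to taxon input order", {
  eq1 <- equivalence_classes(panel)
  shuffled <- panel
  set.seed(99)
  shuffled$alleles <- shuffled$alleles[sample(nrow(shuffled$alleles)), ]
  eq2 <- equivalence_classes(shuffled)
  expect_identical(eq1$taxon, eq2$taxon)
  expect_identical(eq1$class_members, eq2$class_members)
})

test_that("a single-taxon panel yields a single class", {
  solo <- zooms_panel(panel$alleles[panel$alleles$taxon == "Vombatus ursinus", ],
                      loci = panel$loci)
  eq <- equivalence_classes(solo)
  expect_identical(nrow(eq), 1L)
  expect_identical(eq$class, 1L)
})
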