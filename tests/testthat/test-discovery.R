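# helper: wrap marker peptides into equal-length toy chains flanked by
# constant tryptic linkers
wrap_chain <- function(core, prefix = "GPR", suffix = "GAAR") {
  paste0(prefix, core, suffix)
}

test_that("a single substitution inside a tryptic peptide is discovered", {
  chains <- tibble::tibble(
    chain = "COL1A2",
    taxon = c("taxonA", "taxonB"),
    sequence = c(wrap_chain("GPTGPAGPR"), wrap_chain("GPFGPAGPR"))
  )
  cand <- discover_markers(chains, min_gap = 2)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, 4L)
  expect_false(cand$span_shifted)
  # mass(F) - mass(T) = 46.02073
  expect_equal(cand$pairs[[1]]$gap, 46.02073, tolerance = 1e-4)
})

test_that("identical chains yield no candidates", {
  chains <- tibble::tibble(
    chain = "COL1A2", taxon = c("a", "b"),
    sequence = rep(wrap_chain("GPTGPAGPR"), 2)
  )
  expect_identical(nrow(discover_markers(chains)), 0L)
})

test_that("a K->KP context change yields a span-shifted candidate", {
  # marsupial-type chain cleaves after ...GEGGK; the monotreme-type chain
  # has a proline after the lysine, fusing four extra residues
  mars <- paste0("GPR", "GEQGPAGPPGFQGLPGPSGPAGEGGK", "AGERGAAR")
  mono <- paste0("GPR", "GEQGPAGPPGFQGLPGPSGPAGEVGK", "PGERGAAR")
  expect_identical(nchar(mars), nchar(mono))
  chains <- tibble::tibble(chain = "COL1A2",
                           taxon = c("marsupial", "monotreme"),
                           sequence = c(mars, mono))
  cand <- discover_markers(chains, min_gap = 2)
  hit <- cand[cand$start == 4, ]
  expect_identical(nrow(hit), 1L)
  expect_true(hit$span_shifted)
  expect_identical(hit$length_diff, 4L)
  peps <- hit$peptides[[1]]
  expect_identical(nchar(peps$peptide[peps$taxon == "monotreme"]) -
                     nchar(peps$peptide[peps$taxon == "marsupial"]), 4L)
})

test_that("discovery rejects unequal or empty chain sets", {
  expect_error(discover_markers(tibble::tibble(
    chain = "c", taxon = c("a", "b"), sequence = c("GGK", "GGKA"))),
    "equal")
  expect_error(discover_markers(tibble::tibble(chain = character(0),
                                               taxon = character(0),
                                               sequence = character(0))),
               "empty")
})

test_that("discovery is invariant to taxon row order", {
  chains <- tibble::tibble(
    chain = "COL1A2", taxon = c("a", "b", "c"),
    sequence = c(wrap_chain("GPTGPAGPR"), wrap_chain("GPFGPAGPR"),
                 wrap_chain("GPSGPAGPR"))
  )
  c1 <- discover_markers(chains)
  c2 <- discover_markers(chains[c(3, 1, 2), ])
  expect_identical(c1$start, c2$start)
  expect_identical(c1$peptides[[1]]$taxon, c2$peptides[[1]]$taxon)
  expect_equal(c1$peptides[[1]]$base_mhplus, c2$peptides[[1]]$base_mhplus)
})

test_that("the COL1A2 889-906 scaffold reproduces the printed mass ladder", {
  seqs <- marker_sequences()
  h <- seqs[seqs$marker == "COL1A2 889-906", ]
  chains <- tibble::tibble(
    chain = "COL1A2",
    taxon = c("monotreme", "possum_group", "macropod_group"),
    sequence = wrap_chain(h$sequence[match(c(1606, 1624, 1652), h$nominal)])
  )
  cand <- discover_markers(chains, min_gap = 2)
  hit <- cand[cand$start == 4, ]
  expect_identical(nrow(hit), 1L)
  peps <- hit$peptides[[1]]
  # at one hydroxylation, each taxon's ladder reproduces its printed mass
  printed <- c(monotreme = 1606, possum_group = 1624, macropod_group = 1652)
  for (t in names(printed)) {
    ladder <- peps$ladder[[which(peps$taxon == t)]]
    expect_lt(min(abs(ladder - printed[[t]])), 1.0)
  }
  # all three groups are mutually separated
  expect_identical(nrow(hit$pairs[[1]]), 3L)
  expect_true(all(hit$pairs[[1]]$gap >= 17))
})

test_that("candidates project into a mergeable panel fragment", {
  chains <- tibble::tibble(
    chain = "COL1A2", taxon = c("a", "b"),
    sequence = c(wrap_chain("GPTGPAGPR"), wrap_chain("GPFGPAGPR"))
  )
  cand <- discover_markers(chains)
  frag <- project_panel(cand)
  expect_s3_class(frag, "zooms_panel")
  expect_identical(nrow(frag$alleles), 2L)
  expect_identical(nrow(frag$loci), 1L)
  expect_error(project_panel(cand[integer(0), ]), "non-empty")
  expect_error(project_panel(rbind(cand, cand)), "duplicate")
})
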