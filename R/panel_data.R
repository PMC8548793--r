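# Bundled reference panel content: the 24-taxon marsupial/monotreme marker
# matrix, the marker-locus metadata, the taxonomic lineage, and the marker
# peptide sequences. Cell tokens: plain number = MALDI-visible mass; prefix
# "i" = reported from LC-MS/MS only (not visible in MALDI fingerprints);
# prefix "b" = flagged as diagnostic in the source table; "x" = unreported
# (wildcard). Column order: P1, A, A', B, C, P2, D, E, F, F', G, G',
# COL1A2 10-42, COL1A2 889-906.

.panel_loci <- tibble::tribble(
  ~marker,            ~chain,   ~span_start, ~span_end, ~paired, ~alias,
  "P1",               "COL1A1", 508L, 519L, FALSE, NA_character_,
  "A",                "COL1A2", 978L, 990L, TRUE,  NA_character_,
  "B",                "COL1A2", 484L, 498L, FALSE, NA_character_,
  "C",                "COL1A2", 502L, 519L, FALSE, NA_character_,
  "P2",               "COL1A2", 292L, 309L, FALSE, NA_character_,
  "D",                "COL1A2", 793L, 816L, FALSE, NA_character_,
  "E",                "COL1A2", 454L, 483L, FALSE, NA_character_,
  "F",                "COL1A1", 586L, 618L, TRUE,  NA_character_,
  "G",                "COL1A2", 757L, 789L, TRUE,  NA_character_,
  "COL1A2 10-42",     "COL1A2", 10L,  42L,  FALSE, "2T3",
  "COL1A2 889-906",   "COL1A2", 889L, 906L, FALSE, NA_character_
)

.panel_lineage <- tibble::tribble(
  ~taxon,                       ~genus,          ~family,            ~order,             ~clade,
  "Tachyglossus aculeatus",     "Tachyglossus",  "Tachyglossidae",   "Monotremata",      "Monotremata",
  "Phascogale tapoatafa",       "Phascogale",    "Dasyuridae",       "Dasyuromorphia",   "Marsupialia",
  "Sarcophilus harrisii",       "Sarcophilus",   "Dasyuridae",       "Dasyuromorphia",   "Marsupialia",
  "Thylacinus cynocephalus",    "Thylacinus",    "Thylacinidae",     "Dasyuromorphia",   "Marsupialia",
  "Lagorchestes conspicillatus","Lagorchestes",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Lagostrophus fasciatus",     "Lagostrophus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Macropus fuliginosus",       "Macropus",      "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Macropus giganteus",         "Macropus",      "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Osphranter robustus",        "Osphranter",    "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Osphranter rufus",           "Osphranter",    "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Notamacropus agilis",        "Notamacropus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Notamacropus eugenii",       "Notamacropus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Notamacropus irma",          "Notamacropus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Notamacropus parma",         "Notamacropus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Notamacropus rufogriseus",   "Notamacropus",  "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Wallabia bicolor",           "Wallabia",      "Macropodidae",     "Diprotodontia",    "Marsupialia",
  "Petaurus breviceps",         "Petaurus",      "Petauridae",       "Diprotodontia",    "Marsupialia",
  "Trichosurus vulpecula",      "Trichosurus",   "Phalangeridae",    "Diprotodontia",    "Marsupialia",
  "Phascolarctos cinereus",     "Phascolarctos", "Phascolarctidae",  "Diprotodontia",    "Marsupialia",
  "Pseudocheirus peregrinus",   "Pseudocheirus", "Pseudocheiridae",  "Diprotodontia",    "Marsupialia",
  "Lasiorhinus sp.",            "Lasiorhinus",   "Vombatidae",       "Diprotodontia",    "Marsupialia",
  "Vombatus ursinus",           "Vombatus",      "Vombatidae",       "Diprotodontia",    "Marsupialia",
  "Isoodon macrourus",          "Isoodon",       "Peramelidae",      "Peramelemorphia",  "Marsupialia",
  "Perameles nasuta",           "Perameles",     "Peramelidae",      "Peramelemorphia",  "Marsupialia"
)

.panel_cells <- c(
  "Tachyglossus aculeatus"      = "b1120 b1182 b1198 1453 b1607 x b2121 b2848 b2873 b2889 bi2999 b3015 b3009 b1606",
  "Phascogale tapoatafa"        = "1162 x x 1453 1598 b1725 b2163 i2335 2897 2913 b2929 bi2945 2975 1652",
  "Sarcophilus harrisii"        = "1162 b1159 b1175 1453 1598 b1725 b2177 i2335 b2869 b2885 b2929 bi2945 2975 1652",
  "Thylacinus cynocephalus"     = "1162 b1159 b1175 1453 i1598 x b2121 i2335 b2869 b2885 b2929 bi2945 2975 i1652",
  "Lagorchestes conspicillatus" = "1162 1150 1166 1453 1598 x 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Lagostrophus fasciatus"      = "1162 1150 1166 1453 1598 i1680 2145 i2335 b2881 b2897 2943 i2959 2975 1652",
  "Macropus fuliginosus"        = "1162 1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 b2989 1652",
  "Macropus giganteus"          = "1162 1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 b2989 1652",
  "Osphranter robustus"         = "1162 1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Osphranter rufus"            = "1162 i1150 1166 1453 1598 i1680 2145 i2335 2897 i2913 2943 i2959 2975 1652",
  "Notamacropus agilis"         = "1162 1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Notamacropus eugenii"        = "1162 i1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 b1624",
  "Notamacropus irma"           = "1162 i1150 i1166 b1427 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Notamacropus parma"          = "1162 i1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Notamacropus rufogriseus"    = "1162 i1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 1652",
  "Wallabia bicolor"            = "1162 i1150 1166 1453 1598 i1680 2145 i2335 2897 2913 2943 i2959 2975 b1624",
  "Petaurus breviceps"          = "1162 bi1159 bi1175 b1411 1598 bi1650 2145 i2335 2897 2913 b2971 bi2987 i2975 b1624",
  "Trichosurus vulpecula"       = "1162 b1137 bi1153 1453 1598 x 2145 i2335 2897 2913 b2945 bi2961 2975 b1624",
  "Phascolarctos cinereus"      = "1162 b1159 b1175 b1397 1598 b1692 2145 i2335 b2869 bi2885 b2959 b2975 2975 b1624",
  "Pseudocheirus peregrinus"    = "1162 bi1137 bi1153 b1439 1598 bi1650 b2161 i2335 2897 2913 b2929 bi2945 2975 b1624",
  "Lasiorhinus sp."             = "1162 x x b1397 1598 b1692 2145 i2335 b2869 bi2885 b2959 bi2975 2975 b1624",
  "Vombatus ursinus"            = "1162 b1159 b1175 b1439 1598 bi1650 b2119 i2335 2897 2913 b2959 bi2975 b2991 b1624",
  "Isoodon macrourus"           = "1162 1150 1166 1453 1598 x b2177 i2335 2897 2913 b2957 bi2973 2975 b1624",
  "Perameles nasuta"            = "1162 bi1159 bi1175 1453 1598 x b2177 i2335 b2869 b2885 b2957 bi2973 2975 b1624"
)

# column index -> (marker, role); oxidation pairs are stored as two rows of
# one paired locus (role base / oxidized)
.panel_columns <- list(
  list("P1", "base"), list("A", "base"), list("A", "oxidized"),
  list("B", "base"), list("C", "base"), list("P2", "base"),
  list("D", "base"), list("E", "base"),
  list("F", "base"), list("F", "oxidized"),
  list("G", "base"), list("G", "oxidized"),
  list("COL1A2 10-42", "base"), list("COL1A2 889-906", "base")
)

# Marker peptide sequences keyed by (marker, nominal base mass). `taxon`
# disambiguates the two distinct D-locus sequences that share nominal 2121.
# `reconciles = FALSE` marks the one entry whose printed mass cannot be
# reproduced by any hydroxylation count within 1.0 Da; it is kept here for
# reference but never attached to a panel allele.
.table2_sequences <- tibble::tribble(
  ~marker, ~nominal, ~sequence, ~taxon, ~reconciles,
  "P1", 1120, "GVQGPAGPQGPR", NA, TRUE,
  "P1", 1162, "GVQGPPGPQGPR", NA, TRUE,
  "A", 1137, "PGNAGAVGPAGLR", NA, TRUE,
  "A", 1150, "PGQAGAVGPAGLR", NA, TRUE,
  "A", 1159, "PGHAGAVGPAGLR", NA, TRUE,
  "A", 1182, "SGQPGTVGPAGVR", NA, TRUE,
  "B", 1397, "GVAGEFGLPGPAGPR", NA, TRUE,
  "B", 1411, "GPAGEFGLPGPAGPR", NA, TRUE,
  "B", 1427, "GSPGEFGLPGPAGPR", NA, TRUE,
  "B", 1439, "GVPGEFGLPGPAGPR", NA, TRUE,
  "B", 1453, "GLPGEFGLPGPAGPR", NA, TRUE,
  "C", 1598, "GPPGESGAVGPTGSIGSR", NA, TRUE,
  "C", 1607, "GPPGESGAAGPTGPLGNR", NA, TRUE,
  "P2", 1650, "GPNGEPGSTGPSGPPGLR", NA, TRUE,
  "P2", 1680, "GPNGEPGSTGPTGPPGLR", NA, TRUE,
  "P2", 1692, "GPNGEPGSTGPPGPPGLR", NA, TRUE,
  "P2", 1725, "GPNGEPGSTGPMGPPGLR", NA, TRUE,
  "D", 2119, "GLPGVSGSLGEPGPLGIAGPAGAR", NA, TRUE,
  "D", 2121, "GLPGVSGGLGEPGPLGLSGPSGAR", "Tachyglossus aculeatus", TRUE,
  "D", 2121, "GLPGVSGSVGEPGPLGIAGPAGAR", "Thylacinus cynocephalus", TRUE,
  "D", 2145, "GLPGVSGALGEPGPLGIAGPPGAR", NA, TRUE,
  "D", 2161, "GLPGVSGSLGEPGPLGIAGPPGAR", NA, TRUE,
  "D", 2163, "GLPGVSGSVGEPGPLGISGPPGAR", NA, TRUE,
  "D", 2177, "GLPGVSGSLGEPGPLGISGPPGAR", NA, TRUE,
  "E", 2335, "GEQGPAGPPGFQGLPGPSGPAGEGGK", NA, TRUE,
  "E", 2848, "GEQGPAGPPGFQGLPGPSGPAGEVGKPGER", NA, TRUE,
  "F", 2869, "GLTGPIGPPGPAGPSGDKGESGPSGPAGPTGAR", NA, TRUE,
  "F", 2873, "GLTGPIGPPGPAGTSGDKGESGPSGPAGPTGAR", NA, TRUE,
  "F", 2881, "GLTGPIGPPGPAGPAGDKGESGPSGPVGPTGAR", NA, TRUE,
  "F", 2897, "GLTGPIGPPGPAGPSGDKGESGPSGPVGPTGAR", NA, TRUE,
  "G", 2929, "GPPGEAGASGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2943, "GPPGEAGATGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2945, "GPEGEAGASGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2957, "GPPGESGAVGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2959, "GPPGESGATGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2971, "GPPGESGALGPPGSSGPQGLLGAPGILGLPGSR", NA, TRUE,
  "G", 2999, "GPPGEAGATGPPGSSGPQGLWGAPGILGLPGSR", NA, FALSE,
  "COL1A2 10-42", 2975, "GPPGASGPPGAQGFQGPAGEPGEPGQTGPAGAR", NA, TRUE,
  "COL1A2 10-42", 2989, "GPPGATGPPGAQGFQGPAGEPGEPGQTGPAGAR", NA, TRUE,
  "COL1A2 10-42", 2991, "GPPGASGPPGAQGFQGPAGEPGEPGQTGPAGSR", NA, TRUE,
  "COL1A2 10-42", 3009, "GPPGASGPPGAQGFQGPAGEPGEDGQTGPAGAR", NA, TRUE,
  "COL1A2 889-906", 1606, "GEPGPVGSVGPVGPTGAR", NA, TRUE,
  "COL1A2 889-906", 1624, "GEPGPAGSVGPVGPFGAR", NA, TRUE,
  "COL1A2 889-906", 1652, "GEPGPVGSVGPVGPFGAR", NA, TRUE
)

# D-locus alleles reported with an ambiguous oxidation state: the same
# peptide is seen with both two and three hydroxylations, so the two masses
# 16 Da apart never mutually exclude. Keyed by (taxon-independent) nominal.
.d_state_partners <- c("2119" = 2135, "2161" = 2177, "2177" = 2161)

#' Marker peptide sequences
#'
#' The bundled table of marker peptide sequences keyed by marker locus and
#' nominal base mass, including the hydroxylation count inferred for each
#' printed mass. Entries that cannot be reconciled with their printed mass
#' within 1.0 Da are flagged `reconciles = FALSE` and are not attached to
#' panel alleles.
#'
#' @return A tibble: `marker`, `nominal`, `sequence`, `taxon` (only set where
#'   one nominal mass maps to different sequences in different taxa),
#'   `reconciles`, `hydroxylations`, `computed_mz`.
#' @export
marker_sequences <- function() {
  seqs <- .table2_sequences
  seqs$hydroxylations <- ifelse(
    seqs$reconciles,
    infer_hydroxylations(seqs$sequence, seqs$nominal),
    NA_integer_
  )
  seqs$computed_mz <- ifelse(
    is.na(seqs$hydroxylations), NA_real_,
    peptide_mhplus(seqs$sequence, dplyr::coalesce(seqs$hydroxylations, 0L))
  )
  seqs
}

# Build the full allele table from the compact cell encoding.
build_bundled_alleles <- function() {
  seqs <- marker_sequences()
  rows <- purrr::imap(.panel_cells, function(cells, taxon) {
    tokens <- strsplit(cells, " ", fixed = TRUE)[[1]]
    stopifnot(length(tokens) == length(.panel_columns))
    purrr::imap(tokens, function(tok, i) {
      marker <- .panel_columns[[i]][[1]]
      role <- .panel_columns[[i]][[2]]
      if (tok == "x") {
        return(tibble::tibble(
          taxon = taxon, marker = marker, role = role,
          visibility = "unreported", diagnostic = FALSE,
          nominal_mz = NA_real_
        ))
      }
      diag <- grepl("b", tok, fixed = TRUE)
      msms <- grepl("i", tok, fixed = TRUE)
      tibble::tibble(
        taxon = taxon, marker = marker, role = role,
        visibility = if (msms) "msms_only" else "maldi_visible",
        diagnostic = diag,
        nominal_mz = as.numeric(gsub("[bi]", "", tok))
      )
    })
  })
  alleles <- dplyr::bind_rows(purrr::flatten(rows))

  # attach sequences to base rows (oxidized partners reuse the base sequence
  # with one extra hydroxylation)
  attach_seq <- function(taxon, marker, nominal) {
    hit <- seqs[seqs$marker == marker & !is.na(seqs$nominal) &
                  seqs$nominal == nominal & seqs$reconciles &
                  (is.na(seqs$taxon) | seqs$taxon == taxon), , drop = FALSE]
    if (nrow(hit) == 0) return(list(sequence = NA_character_, k = NA_integer_))
    list(sequence = hit$sequence[[1]], k = hit$hydroxylations[[1]])
  }

  base_info <- purrr::pmap(
    list(alleles$taxon, alleles$marker, alleles$nominal_mz, alleles$role),
    function(taxon, marker, nominal, role) {
      if (is.na(nominal)) return(list(sequence = NA_character_, k = NA_integer_))
      if (role == "base") return(attach_seq(taxon, marker, nominal))
      # oxidized partner: look up the sequence of this taxon's base allele
      attach_seq(taxon, marker, nominal - 16)
    }
  )
  alleles$sequence <- purrr::map_chr(base_info, "sequence")
  alleles$hydroxylations <- purrr::map_int(base_info, function(x) {
    if (is.na(x$k)) NA_integer_ else x$k
  })
  alleles$hydroxylations <- alleles$hydroxylations +
    ifelse(alleles$role == "oxidized" & !is.na(alleles$hydroxylations), 1L, 0L)

  # pair linkage: oxidation-pair partners at paired loci, and the D-locus
  # two/three-oxidation states that never mutually exclude
  paired <- .panel_loci$marker[.panel_loci$paired]
  alleles$pair_partner_mz <- NA_real_
  alleles$partner_kind <- NA_character_
  for (r in seq_len(nrow(alleles))) {
    m <- alleles$marker[r]; nom <- alleles$nominal_mz[r]
    if (is.na(nom)) next
    if (m %in% paired) {
      alleles$pair_partner_mz[r] <-
        if (alleles$role[r] == "base") nom + 16 else nom - 16
      alleles$partner_kind[r] <- "oxpair"
    } else if (m == "D" && as.character(nom) %in% names(.d_state_partners)) {
      alleles$pair_partner_mz[r] <- .d_state_partners[[as.character(nom)]]
      alleles$partner_kind[r] <- "state"
    }
  }

  alleles$computed_mz <- ifelse(
    is.na(alleles$sequence) | is.na(alleles$hydroxylations), NA_real_,
    peptide_mhplus(
      ifelse(is.na(alleles$sequence), "G", alleles$sequence),
      dplyr::coalesce(alleles$hydroxylations, 0L)
    )
  )
  alleles
}
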