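#' ZooMS marker panel objects
#'
#' A `zooms_panel` bundles the taxon-by-locus allele table, the marker-locus
#' metadata (chain, span, whether the locus is conventionally reported as a
#' base/+16 oxidation pair), the taxonomic lineage of the reference taxa and
#' the registry of nominal masses that collide across loci or across
#' base/+16 states of different taxa.
#'
#' @param alleles A tibble of marker alleles (see [bundled_panel()] for the
#'   column set).
#' @param loci Locus metadata tibble; defaults to the bundled loci.
#' @param lineage Lineage tibble (`taxon`, `genus`, `family`, `order`,
#'   `clade`); defaults to the bundled lineage, subset to the allele taxa.
#' @return An object of class `zooms_panel`.
#' @export
zooms_panel <- function(alleles, loci = NULL, lineage = NULL) {
  alleles <- tibble::as_tibble(alleles)
  required <- c("taxon", "marker", "role", "visibility", "diagnostic",
                "nominal_mz")
  missing <- setdiff(required, names(alleles))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Allele table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  for (col in c("sequence", "hydroxylations", "pair_partner_mz",
                "partner_kind", "computed_mz")) {
    if (!col %in% names(alleles)) alleles[[col]] <- NA
  }
  if (is.null(loci)) {
    loci <- .panel_loci[.panel_loci$marker %in% alleles$marker, , drop = FALSE]
  }
  unknown <- setdiff(alleles$marker, loci$marker)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Alleles reference unknown loci: %s",
                         paste(unique(unknown), collapse = ", ")))
  }
  if (is.null(lineage)) {
    lineage <- .panel_lineage[.panel_lineage$taxon %in% alleles$taxon, ,
                              drop = FALSE]
  }
  bad <- alleles$visibility == "unreported" & !is.na(alleles$nominal_mz)
  if (any(bad)) {
    rlang::abort("Unreported alleles must not carry a nominal mass.")
  }
  structure(
    list(alleles = alleles, loci = tibble::as_tibble(loci),
         lineage = tibble::as_tibble(lineage),
         collisions = find_collisions(alleles, loci)),
    class = "zooms_panel"
  )
}

# Nominal masses attached to more than one locus, or appearing at a paired
# locus both as one taxon's base and another taxon's +16 partner (the
# base/oxidized state of such a peak is ambiguous without its pair).
find_collisions <- function(alleles, loci) {
  a <- alleles[!is.na(alleles$nominal_mz), , drop = FALSE]
  masses <- unique(a[, c("marker", "nominal_mz", "role")])
  cross <- masses |>
    dplyr::distinct(.data$marker, .data$nominal_mz) |>
    dplyr::count(.data$nominal_mz) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$nominal_mz)
  paired <- loci$marker[loci$paired]
  amb <- masses |>
    dplyr::filter(.data$marker %in% paired) |>
    dplyr::distinct(.data$marker, .data$nominal_mz, .data$role) |>
    dplyr::count(.data$marker, .data$nominal_mz) |>
    dplyr::filter(.data$n > 1)
  out <- dplyr::bind_rows(
    tibble::tibble(nominal_mz = cross, reason = "multiple_loci"),
    tibble::tibble(nominal_mz = amb$nominal_mz, reason = "base_vs_oxidized")
  )
  out |>
    dplyr::group_by(.data$nominal_mz) |>
    dplyr::summarise(reason = paste(sort(unique(.data$reason)), collapse = ";"),
                     .groups = "drop") |>
    dplyr::arrange(.data$nominal_mz)
}

#' @export
print.zooms_panel <- function(x, ...) {
  cat(sprintf("<zooms_panel> %d taxa, %d loci, %d alleles\n",
              length(unique(x$alleles$taxon)), nrow(x$loci),
              sum(!is.na(x$alleles$nominal_mz))))
  cat(sprintf("  colliding nominal masses: %s\n",
              paste(x$collisions$nominal_mz, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
tidy.zooms_panel <- function(x, ...) x$alleles

#' The bundled marsupial/monotreme reference panel
#'
#' MALDI-TOF collagen type I peptide marker masses for 24 Australian
#' marsupial and monotreme reference taxa across 11 marker loci (P1, A, B,
#' C, P2, D, E, F, G, COL1A2 10-42 and COL1A2 889-906; A, F and G are
#' base/+16 oxidation pairs). Each allele records its nominal integer m/z,
#' its visibility (`maldi_visible`, `msms_only` for markers seen only in
#' LC-MS/MS data, or `unreported`), a diagnostic flag, its peptide sequence
#' where one is known, the hydroxylation count that reproduces the nominal
#' mass, and the resulting computed monoisotopic \eqn{[M+H]^+}.
#'
#' @return A `zooms_panel`.
#' @examples
#' p <- bundled_panel()
#' p
#' @export
bundled_panel <- function() {
  zooms_panel(build_bundled_alleles(), loci = .panel_loci,
              lineage = .panel_lineage)
}

panel_tsv_required_cols <- c("taxon", "lineage", "chain", "span",
                             "marker_name", "nominal_mz", "sequence",
                             "visibility", "diagnostic", "pair_partner_mz")

#' Read and write marker panels as TSV
#'
#' The on-disk panel format is a UTF-8 tab-separated table with one row per
#' allele mass: `taxon`, `lineage` (semicolon-joined
#' clade;order;family;genus;species), `chain`, `span` (`start-end`),
#' `marker_name`, `nominal_mz` (empty for unreported alleles), `sequence`,
#' `visibility`, `diagnostic`, `pair_partner_mz`, plus any number of
#' additional columns, which are preserved on a load/save round trip.
#'
#' @param path Path to a panel TSV.
#' @return `read_panel()` returns a `zooms_panel`; `write_panel()` invisibly
#'   returns `path`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE),
    error = function(e) rlang::abort(sprintf("Cannot parse '%s': %s", path,
                                             conditionMessage(e)))
  )
  if (nrow(df) == 0) rlang::abort(sprintf("Panel file '%s' is empty.", path))
  missing <- setdiff(panel_tsv_required_cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Panel file is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  span_ok <- grepl("^[0-9]+-[0-9]+$", df$span)
  if (any(!span_ok)) {
    rlang::abort(sprintf("Malformed span '%s' at line %d of '%s'.",
                         df$span[which(!span_ok)[1]],
                         which(!span_ok)[1] + 1L, path))
  }
  lineage_parts <- strsplit(df$lineage, ";", fixed = TRUE)
  if (any(lengths(lineage_parts) != 5)) {
    i <- which(lengths(lineage_parts) != 5)[1]
    rlang::abort(sprintf(
      "Malformed lineage at line %d: expected clade;order;family;genus;species.",
      i + 1L))
  }
  extra_cols <- setdiff(names(df),
                        c(panel_tsv_required_cols, "role", "partner_kind",
                          "hydroxylations"))
  alleles <- tibble::tibble(
    taxon = df$taxon,
    marker = df$marker_name,
    role = if ("role" %in% names(df)) df$role else "base",
    visibility = df$visibility,
    diagnostic = toupper(df$diagnostic) %in% c("TRUE", "T", "1"),
    nominal_mz = suppressWarnings(as.numeric(df$nominal_mz)),
    sequence = dplyr::na_if(dplyr::coalesce(df$sequence, ""), ""),
    hydroxylations = if ("hydroxylations" %in% names(df)) {
      suppressWarnings(as.integer(df$hydroxylations))
    } else NA_integer_,
    pair_partner_mz = suppressWarnings(as.numeric(df$pair_partner_mz)),
    partner_kind = if ("partner_kind" %in% names(df)) {
      dplyr::na_if(dplyr::coalesce(df$partner_kind, ""), "")
    } else NA_character_
  )
  for (col in extra_cols) alleles[[col]] <- df[[col]]
  alleles$computed_mz <- ifelse(
    is.na(alleles$sequence) | is.na(alleles$hydroxylations), NA_real_,
    peptide_mhplus(ifelse(is.na(alleles$sequence), "G", alleles$sequence),
                   dplyr::coalesce(alleles$hydroxylations, 0L))
  )
  spans <- do.call(rbind, strsplit(df$span, "-", fixed = TRUE))
  loci <- tibble::tibble(
    marker = df$marker_name, chain = df$chain,
    span_start = as.integer(spans[, 1]), span_end = as.integer(spans[, 2])
  ) |> dplyr::distinct(.data$marker, .keep_all = TRUE)
  loci <- dplyr::left_join(
    loci, .panel_loci[, c("marker", "paired", "alias")], by = "marker")
  loci$paired[is.na(loci$paired)] <- FALSE
  lineage <- tibble::tibble(
    taxon = df$taxon,
    clade = vapply(lineage_parts, `[`, character(1), 1),
    order = vapply(lineage_parts, `[`, character(1), 2),
    family = vapply(lineage_parts, `[`, character(1), 3),
    genus = vapply(lineage_parts, `[`, character(1), 4)
  ) |> dplyr::distinct(.data$taxon, .keep_all = TRUE)
  lineage <- lineage[, c("taxon", "genus", "family", "order", "clade")]
  zooms_panel(alleles, loci = loci, lineage = lineage)
}

#' @rdname read_panel
#' @param panel A `zooms_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "zooms_panel"))
  a <- panel$alleles
  loci <- panel$loci
  lin <- panel$lineage
  lin_str <- stats::setNames(
    paste(lin$clade, lin$order, lin$family, lin$genus, lin$taxon, sep = ";"),
    lin$taxon
  )
  loc_chain <- stats::setNames(loci$chain, loci$marker)
  loc_span <- stats::setNames(
    paste0(loci$span_start, "-", loci$span_end), loci$marker)
  core <- tibble::tibble(
    taxon = a$taxon,
    lineage = unname(lin_str[a$taxon]),
    chain = unname(loc_chain[a$marker]),
    span = unname(loc_span[a$marker]),
    marker_name = a$marker,
    role = a$role,
    nominal_mz = a$nominal_mz,
    sequence = a$sequence,
    hydroxylations = a$hydroxylations,
    visibility = a$visibility,
    diagnostic = a$diagnostic,
    pair_partner_mz = a$pair_partner_mz,
    partner_kind = a$partner_kind
  )
  known <- c("taxon", "marker", "role", "visibility", "diagnostic",
             "nominal_mz", "sequence", "hydroxylations", "pair_partner_mz",
             "partner_kind", "computed_mz")
  for (col in setdiff(names(a), known)) core[[col]] <- a[[col]]
  readr::write_tsv(core, path, progress = FALSE)
  invisible(path)
}

#' Validate a marker panel
#'
#' Report-only consistency checks of a panel against its own sequences and
#' pairing structure: (i) for every allele with a sequence, the inferred
#' hydroxylation count must reproduce the nominal mass within 1.0 Da;
#' (ii) every oxidation-pair partner and every stored +16 state must sit
#' 15.99 (+/- 0.02) Da from its base when computed from sequence (within
#' 1 Da on nominal labels when no sequence is available); (iii) nominal
#' masses registered at more than one locus, or ambiguous between base and
#' +16 states of different taxa, are listed as collisions.
#'
#' @param panel A `zooms_panel`.
#' @return A `zooms_panel_validation` list with tibbles `sequence_checks`,
#'   `pair_checks`, `collisions` and `flags` (zero rows when the panel is
#'   fully consistent).
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "zooms_panel"))
  a <- panel$alleles
  with_seq <- a[!is.na(a$sequence) & !is.na(a$nominal_mz), , drop = FALSE]
  seq_checks <- tibble::tibble(
    taxon = with_seq$taxon, marker = with_seq$marker, role = with_seq$role,
    nominal_mz = with_seq$nominal_mz,
    inferred_k = infer_hydroxylations(with_seq$sequence, with_seq$nominal_mz),
    computed_mz = NA_real_, delta = NA_real_
  )
  ok <- !is.na(seq_checks$inferred_k)
  seq_checks$computed_mz[ok] <- peptide_mhplus(
    with_seq$sequence[ok], seq_checks$inferred_k[ok])
  seq_checks$delta <- seq_checks$computed_mz - seq_checks$nominal_mz
  seq_checks$consistent <- ok & abs(seq_checks$delta) <= 1.0

  # pair / +16-state offsets
  paired_rows <- a[!is.na(a$pair_partner_mz), , drop = FALSE]
  base_rows <- paired_rows[paired_rows$role == "base" |
                             is.na(paired_rows$partner_kind) |
                             paired_rows$partner_kind == "state", ,
                           drop = FALSE]
  base_rows <- base_rows[base_rows$role == "base", , drop = FALSE]
  pair_checks <- purrr::pmap_dfr(
    list(base_rows$taxon, base_rows$marker, base_rows$nominal_mz,
         base_rows$pair_partner_mz, base_rows$sequence,
         base_rows$hydroxylations, base_rows$partner_kind),
    function(taxon, marker, nom, partner, seq, k, kind) {
      if (!is.na(seq) && !is.na(k)) {
        base_m <- peptide_mhplus(seq, k)
        step <- if (partner > nom) 1L else -1L
        part_m <- peptide_mhplus(seq, k + step)
        offset <- abs(part_m - base_m)
        ok <- abs(offset - 15.99) <= 0.02
      } else {
        offset <- abs(partner - nom)
        ok <- abs(offset - 16) <= 1
      }
      tibble::tibble(taxon = taxon, marker = marker, kind = kind,
                     base_mz = nom, partner_mz = partner,
                     offset = offset, consistent = ok)
    }
  )

  flags <- dplyr::bind_rows(
    seq_checks[!seq_checks$consistent, c("taxon", "marker", "nominal_mz")] |>
      dplyr::mutate(issue = "sequence_mass_mismatch"),
    pair_checks[!pair_checks$consistent, c("taxon", "marker")] |>
      dplyr::mutate(nominal_mz = NA_real_, issue = "pair_offset_mismatch")
  )
  structure(
    list(sequence_checks = seq_checks, pair_checks = pair_checks,
         collisions = panel$collisions, flags = tibble::as_tibble(flags)),
    class = "zooms_panel_validation"
  )
}

#' @export
print.zooms_panel_validation <- function(x, ...) {
  cat(sprintf(
    "<zooms_panel_validation> %d sequence checks (%d inconsistent), %d pair checks (%d inconsistent)\n",
    nrow(x$sequence_checks), sum(!x$sequence_checks$consistent),
    nrow(x$pair_checks), sum(!x$pair_checks$consistent)))
  cat(sprintf("  collisions: %s\n",
              paste(x$collisions$nominal_mz, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
glance.zooms_panel_validation <- function(x, ...) {
  tibble::tibble(
    n_sequence_checks = nrow(x$sequence_checks),
    n_sequence_inconsistent = sum(!x$sequence_checks$consistent),
    n_pair_checks = nrow(x$pair_checks),
    n_pair_inconsistent = sum(!x$pair_checks$consistent),
    n_collisions = nrow(x$collisions),
    n_flags = nrow(x$flags)
  )
}

#' Group panel taxa into indistinguishable equivalence classes
#'
#' Two taxa are placed in one class when each is a candidate for a
#' noise-free, full-detection spectrum of the other under the classifier's
#' consistency rules (unreported loci are wildcards; absence never
#' discriminates). The partition is the set of connected components of this
#' mutual-consistency relation, so it is invariant to taxon input order.
#'
#' @param panel A `zooms_panel`.
#' @param visibility_mode `"maldi_visible_only"` uses only MALDI-visible
#'   masses as each taxon's emitted profile; `"all_reported"` also emits
#'   masses seen only in LC-MS/MS data.
#' @param tolerance Mass tolerance in Da used by the consistency rules.
#' @return A tibble `taxon`, `class` (integer id), `class_members`
#'   (semicolon-joined, alphabetical), ordered by class then taxon.
#' @export
equivalence_classes <- function(panel,
                                visibility_mode = c("maldi_visible_only",
                                                    "all_reported"),
                                tolerance = 0.3) {
  stopifnot(inherits(panel, "zooms_panel"))
  visibility_mode <- match.arg(visibility_mode)
  taxa <- sort(unique(panel$alleles$taxon))
  params <- match_params(tolerance = tolerance)
  profiles <- lapply(taxa, function(t) {
    emission_masses(panel, t, visibility_mode = visibility_mode)
  })
  cand <- lapply(profiles, function(mz) {
    if (length(mz) == 0) return(taxa)
    consistent_taxa(tibble::tibble(mz = mz, intensity = 1), panel, params)
  })
  n <- length(taxa)
  # union-find over the mutual-consistency graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && taxa[j] %in% cand[[i]] && taxa[i] %in% cand[[j]]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  class_id <- match(roots, sort(unique(roots)))
  members <- vapply(class_id, function(cid) {
    paste(sort(taxa[class_id == cid]), collapse = ";")
  }, character(1))
  tibble::tibble(taxon = taxa, class = class_id, class_members = members) |>
    dplyr::arrange(.data$class, .data$taxon)
}

# The exact m/z values a taxon's reference spectrum contains when every
# marker is detected and no mass error is applied: computed monoisotopic
# masses where sequences are known, nominal labels otherwise.
emission_masses <- function(panel, taxon,
                            visibility_mode = "maldi_visible_only") {
  a <- panel$alleles
  keep <- a$taxon == taxon & !is.na(a$nominal_mz) &
    (a$visibility == "maldi_visible" |
       (visibility_mode == "all_reported" & a$visibility == "msms_only"))
  rows <- a[keep, , drop = FALSE]
  sort(unique(dplyr::coalesce(rows$computed_mz, rows$nominal_mz)))
}
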