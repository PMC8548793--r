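#' Discover candidate peptide markers from homologous collagen chains
#'
#' Sequence-level marker discovery: each taxon's chain is digested in
#' silico (with the no-cleavage-before-proline rule applied per taxon, so a
#' substitution that creates or destroys a cut site produces a span shift),
#' tryptic peptides are aligned by their shared start column, and every
#' start position where at least two taxa differ in unmodified peptide mass
#' by at least `min_gap` is reported as a candidate marker, together with
#' its hydroxylation mass ladder and the taxon pairs it separates.
#'
#' Chains must be pre-aligned, gap-free and of equal length per chain
#' (collagen chains are near-equal length across taxa); building alignments
#' is out of scope.
#'
#' @param chains A tibble with columns `chain`, `taxon`, `sequence`
#'   (equal-length sequences within each chain), e.g. from
#'   [read_chain_fasta()] with ids of the form `taxon|chain`.
#' @param missed_cleavages Missed cleavages allowed per taxon (0 or 1).
#' @param min_gap Minimum base-mass difference (Da) between two taxa for a
#'   locus to count as discriminating; the default 2.0 stays clear of
#'   deamidation (+0.98) and oxidation (+15.99 between adjacent ladder
#'   rungs) confusions.
#' @param max_ladder Highest hydroxylation count reported in the mass
#'   ladder (capped at the number of P/K sites).
#' @return A tibble with one row per candidate locus: `chain`, `start`,
#'   `span_shifted` (do taxa disagree on the peptide end?), `max_gap`,
#'   `peptides` (list column: taxon, peptide, end, base m/z, ladder) and
#'   `pairs` (list column: discrimination table of separated taxon pairs
#'   and their mass gap).
#' @export
discover_markers <- function(chains, missed_cleavages = 1, min_gap = 2.0,
                             max_ladder = 6L) {
  if (!all(c("chain", "taxon", "sequence") %in% names(chains))) {
    rlang::abort("`chains` must have columns chain, taxon, sequence.")
  }
  if (nrow(chains) == 0) rlang::abort("`chains` must not be empty.")
  stopifnot(min_gap > 0, missed_cleavages %in% 0:1)
  out <- purrr::map_dfr(split(chains, chains$chain), function(cs) {
    if (length(unique(nchar(cs$sequence))) != 1) {
      rlang::abort(sprintf(
        "Chain '%s': sequences must be of equal (aligned) length.",
        cs$chain[1]))
    }
    if (nrow(cs) < 2) return(NULL)
    digests <- purrr::map2_dfr(cs$taxon, cs$sequence, function(t, s) {
      d <- digest(s, missed_cleavages = missed_cleavages)
      d$taxon <- t
      d
    })
    # fundamental (0-missed) peptides anchor the comparison; align by start
    base <- digests[digests$missed == 0, , drop = FALSE]
    purrr::map_dfr(split(base, base$start), function(grp) {
      if (length(unique(grp$taxon)) < 2) return(NULL)
      grp <- grp[!duplicated(grp$taxon), , drop = FALSE]
      grp$base_mhplus <- peptide_mhplus(grp$peptide)
      gaps <- outer(grp$base_mhplus, grp$base_mhplus,
                    function(a, b) abs(a - b))
      if (max(gaps) < min_gap) return(NULL)
      idx <- which(gaps >= min_gap & upper.tri(gaps), arr.ind = TRUE)
      pairs <- tibble::tibble(
        taxon_a = grp$taxon[idx[, 1]], taxon_b = grp$taxon[idx[, 2]],
        gap = gaps[idx]
      ) |> dplyr::arrange(.data$taxon_a, .data$taxon_b)
      peptides <- tibble::tibble(
        taxon = grp$taxon, peptide = grp$peptide,
        start = grp$start, end = grp$end,
        base_mhplus = grp$base_mhplus,
        ladder = purrr::map(grp$peptide, function(p) {
          kmax <- min(hydroxylation_sites(p), max_ladder)
          peptide_mhplus(rep(p, kmax + 1), 0:kmax)
        })
      ) |> dplyr::arrange(.data$taxon)
      tibble::tibble(
        chain = cs$chain[1], start = grp$start[1],
        span_shifted = length(unique(grp$end)) > 1,
        length_diff = max(nchar(grp$peptide)) - min(nchar(grp$peptide)),
        max_gap = max(gaps),
        peptides = list(peptides), pairs = list(pairs)
      )
    })
  })
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, .data$chain, .data$start)
}

#' Project discovered markers into the panel TSV schema
#'
#' Converts [discover_markers()] candidates into a panel-fragment allele
#' table (one row per taxon per locus, MALDI visibility assumed) that can
#' be written with [write_panel()] semantics and merged into curated
#' panels.
#'
#' @param candidates Output of [discover_markers()]; must be non-empty.
#' @param lineage Optional lineage tibble (`taxon`, `genus`, `family`,
#'   `order`, `clade`) for the projected taxa.
#' @return A `zooms_panel` containing the projected alleles.
#' @export
project_panel <- function(candidates, lineage = NULL) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    rlang::abort("`candidates` must be a non-empty discovery table.")
  }
  key <- paste(candidates$chain, candidates$start)
  if (anyDuplicated(key)) {
    rlang::abort("Conflicting duplicate loci in `candidates`.")
  }
  alleles <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    pep <- candidates$peptides[[i]]
    tibble::tibble(
      taxon = pep$taxon,
      marker = sprintf("%s %d-%d", candidates$chain[i],
                       candidates$start[i], max(pep$end)),
      role = "base",
      visibility = "maldi_visible",
      diagnostic = FALSE,
      nominal_mz = round(pep$base_mhplus),
      sequence = pep$peptide,
      hydroxylations = 0L,
      pair_partner_mz = NA_real_,
      partner_kind = NA_character_,
      computed_mz = pep$base_mhplus
    )
  })
  loci <- alleles |>
    dplyr::distinct(.data$marker) |>
    dplyr::mutate(
      chain = sub(" .*$", "", .data$marker),
      span = sub("^[^ ]+ ", "", .data$marker),
      span_start = as.integer(sub("-.*$", "", .data$span)),
      span_end = as.integer(sub("^.*-", "", .data$span)),
      paired = FALSE, alias = NA_character_
    ) |>
    dplyr::select("marker", "chain", "span_start", "span_end", "paired",
                  "alias")
  if (is.null(lineage)) {
    taxa <- sort(unique(alleles$taxon))
    known <- .panel_lineage[.panel_lineage$taxon %in% taxa, , drop = FALSE]
    unknown <- setdiff(taxa, known$taxon)
    lineage <- dplyr::bind_rows(
      known,
      tibble::tibble(taxon = unknown, genus = unknown, family = unknown,
                     order = unknown, clade = unknown)
    )
  }
  zooms_panel(alleles, loci = loci, lineage = lineage)
}
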