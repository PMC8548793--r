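#' Matching and classification parameters
#'
#' @param tolerance Mass tolerance in Da for peak-to-allele matching
#'   (default 0.3, an external-calibration MALDI-TOF scale). Alleles without
#'   a known sequence are matched against their nominal integer label with a
#'   window of at least 1.0 Da.
#' @param min_loci Minimum number of anchored marker loci other than P1
#'   required to call an identification (default 2).
#' @param require_pairs Should oxidation-pair loci (A, F, G) require the
#'   complete base/+16 pair before an observation can exclude taxa exactly?
#'   When `TRUE` (default) a lone pair member only excludes taxa whose
#'   base, +16 and +32 states are all out of tolerance.
#' @param require_collision_corroboration Should collision-flagged masses
#'   (e.g. 2975, shared between the G' oxidation state and the COL1A2 10-42
#'   marker) only anchor a locus when corroborated by another non-colliding
#'   anchored observation? Default `TRUE`.
#' @return A list of class `zooms_match_params`.
#' @export
match_params <- function(tolerance = 0.3, min_loci = 2,
                         require_pairs = TRUE,
                         require_collision_corroboration = TRUE) {
  stopifnot(tolerance > 0, min_loci >= 1)
  structure(
    list(tolerance = tolerance, min_loci = as.integer(min_loci),
         require_pairs = isTRUE(require_pairs),
         require_collision_corroboration =
           isTRUE(require_collision_corroboration)),
    class = "zooms_match_params"
  )
}

OXPAIR_DELTA <- 15.99491

# Flat per-allele matching table: one row per stored allele mass, with the
# m/z actually used for matching (computed monoisotopic where the sequence
# is known, nominal label otherwise), its matching window, and collision
# status of its nominal label.
allele_match_table <- function(panel, params) {
  a <- panel$alleles[!is.na(panel$alleles$nominal_mz), , drop = FALSE]
  tibble::tibble(
    taxon = a$taxon, marker = a$marker, role = a$role,
    visibility = a$visibility, nominal_mz = a$nominal_mz,
    match_mz = dplyr::coalesce(a$computed_mz, a$nominal_mz),
    window = ifelse(is.na(a$computed_mz), max(params$tolerance, 1.0),
                    params$tolerance),
    collision = a$nominal_mz %in% panel$collisions$nominal_mz,
    pair_partner_mz = a$pair_partner_mz,
    partner_kind = a$partner_kind,
    sequence = a$sequence,
    hydroxylations = a$hydroxylations
  )
}

# The masses a taxon can "explain" at any locus: every stored allele mass
# plus the +/-16 oxidation states stored as pair partners or D-locus states.
taxon_accept_table <- function(amt) {
  base <- amt[, c("taxon", "marker", "match_mz", "window")]
  states <- amt[!is.na(amt$partner_kind) & amt$partner_kind == "state", ,
                drop = FALSE]
  if (nrow(states) > 0) {
    states <- tibble::tibble(
      taxon = states$taxon, marker = states$marker,
      match_mz = states$match_mz +
        sign(states$pair_partner_mz - states$nominal_mz) * OXPAIR_DELTA,
      window = states$window
    )
  } else {
    states <- base[0, ]
  }
  dplyr::bind_rows(base, states)
}

#' Match observed peaks against a marker panel
#'
#' Every peak within tolerance of at least one stored allele mass is
#' recorded with all of its candidate alleles, across taxa and loci, and
#' flagged when the matched nominal mass is registered at more than one
#' locus (or is ambiguous between base and +16 oxidation states of
#' different taxa). Per-locus observations summarise the matched peaks and,
#' for oxidation-pair loci, whether a complete base/+16 pair is present.
#'
#' @param peaks A peak list (tibble with `mz`, `intensity`).
#' @param panel A `zooms_panel`.
#' @param params A [match_params()] object.
#' @return A `zooms_matches` list: `matches` (one row per peak x allele
#'   match), `loci` (one row per locus with matched peaks), plus the input
#'   peaks and parameters.
#' @export
match_peaks <- function(peaks, panel, params = match_params()) {
  stopifnot(inherits(panel, "zooms_panel"))
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    rlang::abort("`peaks` must have columns `mz` and `intensity`.")
  }
  amt <- allele_match_table(panel, params)
  empty_matches <- tibble::tibble(
    peak_mz = numeric(0), intensity = numeric(0),
    taxon = character(0), marker = character(0),
    role = character(0), visibility = character(0),
    nominal_mz = numeric(0), allele_mz = numeric(0),
    deviation = numeric(0), collision = logical(0))
  matches <- if (nrow(peaks) == 0) {
    empty_matches
  } else {
    hits <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
      dev <- peaks$mz[i] - amt$match_mz
      sel <- abs(dev) <= amt$window
      if (!any(sel)) return(NULL)
      tibble::tibble(
        peak_mz = peaks$mz[i], intensity = peaks$intensity[i],
        taxon = amt$taxon[sel], marker = amt$marker[sel],
        role = amt$role[sel], visibility = amt$visibility[sel],
        nominal_mz = amt$nominal_mz[sel], allele_mz = amt$match_mz[sel],
        deviation = dev[sel], collision = amt$collision[sel]
      )
    })
    if (nrow(hits) == 0) empty_matches else hits
  }
  loci <- summarise_locus_observations(matches, panel, params)
  structure(
    list(matches = matches, loci = loci, peaks = tibble::as_tibble(peaks),
         params = params),
    class = "zooms_matches"
  )
}

#' @export
print.zooms_matches <- function(x, ...) {
  cat(sprintf("<zooms_matches> %d peaks, %d matches over %d loci\n",
              nrow(x$peaks), nrow(x$matches), nrow(x$loci)))
  invisible(x)
}

#' @exportS3Method
tidy.zooms_matches <- function(x, ...) x$matches

# Per-locus observation summary; anchoring is resolved in two passes so
# collision-flagged masses can be corroborated by other loci.
summarise_locus_observations <- function(matches, panel, params) {
  vis <- matches[matches$visibility == "maldi_visible", , drop = FALSE]
  paired <- panel$loci$marker[panel$loci$paired]
  if (nrow(vis) == 0) {
    return(tibble::tibble(marker = character(0), peaks = list(),
                          pair_status = character(0),
                          strong_pairs = list(), weak_singles = list(),
                          anchor_peaks = list(), anchored = logical(0)))
  }
  by_marker <- split(vis, vis$marker)
  obs <- tibble::tibble(
    marker = names(by_marker),
    peaks = purrr::map(by_marker, function(d) sort(unique(d$peak_mz))),
    collision_only = purrr::map(by_marker, function(d) {
      pk <- sort(unique(d$peak_mz))
      vapply(pk, function(p) all(d$collision[d$peak_mz == p]), logical(1))
    })
  )
  tol <- params$tolerance
  obs$strong_pairs <- purrr::map(obs$peaks, function(pk) {
    if (length(pk) < 2) return(list())
    prs <- list()
    for (i in seq_along(pk)) {
      for (j in seq_along(pk)) {
        if (i < j && abs(pk[j] - pk[i] - OXPAIR_DELTA) <= 2 * tol) {
          prs[[length(prs) + 1L]] <- c(pk[i], pk[j])
        }
      }
    }
    prs
  })
  obs$weak_singles <- purrr::pmap(
    list(obs$marker, obs$peaks, obs$collision_only, obs$strong_pairs),
    function(m, pk, co, prs) {
      if (!m %in% paired) return(numeric(0))
      in_pair <- pk %in% unlist(prs)
      keep <- !in_pair &
        !(co & params$require_collision_corroboration)
      pk[keep]
    })
  # unpaired loci: non-collision peaks anchor directly; collision peaks need
  # corroboration from some other locus with a non-collision anchor
  obs$direct <- purrr::pmap(
    list(obs$marker, obs$peaks, obs$collision_only),
    function(m, pk, co) {
      if (m %in% paired) return(numeric(0))
      pk[!co | !params$require_collision_corroboration]
    })
  has_noncollision_anchor <-
    (lengths(obs$direct) > 0 & !obs$marker %in% paired) |
    (obs$marker %in% paired &
       (lengths(obs$strong_pairs) > 0 | lengths(obs$weak_singles) > 0))
  corroborated <- sum(has_noncollision_anchor) > 0
  obs$anchor_peaks <- purrr::pmap(
    list(obs$marker, obs$peaks, obs$collision_only, obs$direct),
    function(m, pk, co, direct) {
      if (m %in% paired) return(numeric(0))
      extra <- if (corroborated && params$require_collision_corroboration) {
        pk[co]
      } else numeric(0)
      sort(unique(c(direct, extra)))
    })
  obs$pair_status <- purrr::pmap_chr(
    list(obs$marker, obs$strong_pairs, obs$peaks),
    function(m, prs, pk) {
      if (!m %in% paired) return(NA_character_)
      if (length(prs) > 0) "complete_pair" else "single_member"
    })
  obs$anchored <- lengths(obs$strong_pairs) > 0 |
    lengths(obs$weak_singles) > 0 | lengths(obs$anchor_peaks) > 0
  obs[, c("marker", "peaks", "pair_status", "strong_pairs", "weak_singles",
          "anchor_peaks", "anchored")]
}

# Core consistency engine: which panel taxa are consistent with the
# observed peaks under the anchoring rules?
consistent_taxa <- function(peaks, panel, params = match_params()) {
  m <- match_peaks(peaks, panel, params)
  consistent_taxa_from_matches(m, panel, params)
}

consistent_taxa_from_matches <- function(m, panel, params) {
  obs <- m$loci[m$loci$anchored, , drop = FALSE]
  taxa <- sort(unique(panel$alleles$taxon))
  if (nrow(obs) == 0) return(taxa)
  amt <- allele_match_table(panel, params)
  accept <- taxon_accept_table(amt)
  unreported <- panel$alleles[panel$alleles$visibility == "unreported", ,
                              drop = FALSE]
  tol <- params$tolerance
  keep <- vapply(taxa, function(t) {
    acc_t <- accept[accept$taxon == t, , drop = FALSE]
    explained_anywhere <- function(p) {
      any(abs(p - acc_t$match_mz) <= acc_t$window)
    }
    for (r in seq_len(nrow(obs))) {
      mk <- obs$marker[r]
      if (any(unreported$taxon == t & unreported$marker == mk)) next
      rows <- amt[amt$taxon == t & amt$marker == mk, , drop = FALSE]
      if (nrow(rows) == 0) next # absence never discriminates
      base <- rows[rows$role == "base", , drop = FALSE]
      part <- rows[rows$role == "oxidized", , drop = FALSE]
      acc_mk <- acc_t[acc_t$marker == mk, , drop = FALSE]
      acc_other <- acc_t[acc_t$marker != mk, , drop = FALSE]
      ok <- TRUE
      for (pr in obs$strong_pairs[[r]]) {
        pair_ok <- FALSE
        for (b in seq_len(nrow(base))) {
          pm <- if (nrow(part) > 0) part$match_mz else
            base$match_mz[b] + OXPAIR_DELTA
          pw <- if (nrow(part) > 0) part$window else base$window[b]
          if (abs(pr[1] - base$match_mz[b]) <= base$window[b] &&
              any(abs(pr[2] - pm) <= pw)) {
            pair_ok <- TRUE; break
          }
        }
        if (!pair_ok) { ok <- FALSE; break }
      }
      if (ok) for (s in obs$weak_singles[[r]]) {
        ladder <- c(base$match_mz, base$match_mz + OXPAIR_DELTA,
                    base$match_mz + 2 * OXPAIR_DELTA,
                    part$match_mz, part$match_mz + OXPAIR_DELTA)
        w <- c(base$window, base$window, base$window, part$window,
               part$window)
        hit <- any(abs(s - ladder) <= w) ||
          any(abs(s - acc_other$match_mz) <= acc_other$window)
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) for (p in obs$anchor_peaks[[r]]) {
        hit <- any(abs(p - acc_mk$match_mz) <= acc_mk$window)
        if (!hit) {
          # a colliding mass explained by this taxon at another locus is
          # not held against it here
          coll <- any(m$matches$peak_mz == p & m$matches$collision)
          hit <- coll && any(abs(p - acc_other$match_mz) <= acc_other$window)
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
  taxa[keep]
}

#' Classify a sample from its panel matches
#'
#' Applies the consistency rules to the anchored locus observations of
#' [match_peaks()] and assigns one of four outcome statuses:
#' `identified` (the ubiquitous P1 marker plus at least `min_loci` other
#' anchored loci, with a non-empty candidate taxon set),
#' `collagen_unidentifiable` (P1 present but too few other markers),
#' `tentative_fish_or_bird` (a collagen-like marker series without the
#' P1 peak), or `failed` (too few matched peaks overall). A taxon is a
#' candidate if and only if every anchored observation is contained in its
#' allele set; unreported loci are wildcards and absence of a peak never
#' excludes. The resolved label is the lowest taxonomic rank shared by all
#' candidates.
#'
#' @param matches A `zooms_matches` from [match_peaks()].
#' @param panel The same `zooms_panel` used for matching.
#' @param params A [match_params()] object.
#' @return A `zooms_classification` list: `sample_id`, `status`,
#'   `candidates`, `label`, `rank`, `evidence` tibble, `warnings`, `params`.
#' @export
classify <- function(matches, panel, params = match_params()) {
  stopifnot(inherits(matches, "zooms_matches"), inherits(panel, "zooms_panel"))
  vis <- matches$matches[matches$matches$visibility == "maldi_visible", ,
                         drop = FALSE]
  p1_matched <- any(vis$marker == "P1")
  other_matched <- unique(vis$marker[vis$marker != "P1"])
  obs <- matches$loci[matches$loci$anchored, , drop = FALSE]
  anchored_other <- setdiff(obs$marker, "P1")
  n_matched_peaks <- length(unique(vis$peak_mz))
  candidates <- character(0)
  warnings <- character(0)
  if (!p1_matched) {
    status <- if (length(other_matched) >= params$min_loci) {
      "tentative_fish_or_bird"
    } else "failed"
  } else if (length(anchored_other) >= params$min_loci) {
    candidates <- consistent_taxa_from_matches(matches, panel, params)
    status <- if (length(candidates) > 0) "identified" else
      "collagen_unidentifiable"
    if (length(candidates) == 0) candidates <- character(0)
  } else {
    status <- "collagen_unidentifiable"
  }
  if (status == "identified" && length(anchored_other) <= params$min_loci) {
    warnings <- c(warnings, paste(
      "identification rests on few anchored loci; the P1 marker mass is",
      "shared with many bird and reptile collagens"))
  }
  if (status == "identified" && length(candidates) > 1) {
    if (msms_separable_only(candidates, panel)) {
      warnings <- c(warnings, paste(
        "some candidate taxa are separable only by markers not visible in",
        "MALDI spectra (LC-MS/MS evidence would be required)"))
    }
  }
  lab <- resolve_label(candidates, panel$lineage)
  evidence <- build_evidence(matches, panel, params)
  structure(
    list(sample_id = attr(matches$peaks, "sample_id") %||% NA_character_,
         status = status, candidates = sort(candidates),
         label = lab$label, rank = lab$rank,
         n_matched_peaks = n_matched_peaks,
         n_anchored_loci = length(anchored_other) + as.integer(p1_matched),
         evidence = evidence, warnings = warnings, params = params),
    class = "zooms_classification"
  )
}

#' @rdname classify
#' @param peaks A peak list.
#' @export
classify_spectrum <- function(peaks, panel, params = match_params()) {
  m <- match_peaks(peaks, panel, params)
  out <- classify(m, panel, params)
  out$sample_id <- attr(peaks, "sample_id") %||% out$sample_id
  out
}

# do candidate taxa share identical MALDI-visible profiles while differing
# in their full reported allele sets?
msms_separable_only <- function(candidates, panel) {
  vis_prof <- vapply(candidates, function(t) {
    paste(emission_masses(panel, t, "maldi_visible_only"), collapse = ",")
  }, character(1))
  all_prof <- vapply(candidates, function(t) {
    paste(emission_masses(panel, t, "all_reported"), collapse = ",")
  }, character(1))
  any(duplicated(vis_prof) & !duplicated(all_prof))
}

resolve_label <- function(candidates, lineage) {
  if (length(candidates) == 0) {
    return(list(label = NA_character_, rank = NA_character_))
  }
  lin <- lineage[lineage$taxon %in% candidates, , drop = FALSE]
  for (rank in c("taxon", "genus", "family", "order", "clade")) {
    vals <- unique(lin[[rank]])
    if (length(vals) == 1) {
      return(list(label = vals,
                  rank = c(taxon = "species", genus = "genus",
                           family = "family", order = "order",
                           clade = "clade")[[rank]]))
    }
  }
  list(label = "Mammalia", rank = "class")
}

build_evidence <- function(matches, panel, params) {
  obs <- matches$loci
  if (nrow(obs) == 0) {
    return(tibble::tibble(marker = character(0), observed = character(0),
                          anchored = logical(0), supporting = character(0),
                          conflicting = character(0)))
  }
  taxa <- sort(unique(panel$alleles$taxon))
  amt <- allele_match_table(panel, params)
  purrr::map_dfr(seq_len(nrow(obs)), function(r) {
    mk <- obs$marker[r]
    pk <- obs$peaks[[r]]
    support <- character(0); conflict <- character(0)
    for (t in taxa) {
      rows <- amt[amt$taxon == t & amt$marker == mk, , drop = FALSE]
      if (nrow(rows) == 0) next
      hit <- any(vapply(pk, function(p) {
        any(abs(p - rows$match_mz) <= rows$window)
      }, logical(1)))
      if (hit) support <- c(support, t) else conflict <- c(conflict, t)
    }
    tibble::tibble(
      marker = mk,
      observed = paste(sprintf("%.3f", pk), collapse = ";"),
      anchored = obs$anchored[r],
      supporting = paste(support, collapse = ";"),
      conflicting = paste(conflict, collapse = ";")
    )
  })
}

#' @export
print.zooms_classification <- function(x, ...) {
  cat(sprintf("<zooms_classification> %s: %s\n",
              x$sample_id %||% "(sample)", x$status))
  if (x$status == "identified") {
    cat(sprintf("  label: %s (%s); %d candidate taxa\n",
                x$label, x$rank, length(x$candidates)))
  }
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' @exportS3Method
tidy.zooms_classification <- function(x, ...) x$evidence

#' @exportS3Method
glance.zooms_classification <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, status = x$status,
    label = x$label, rank = x$rank,
    n_candidates = length(x$candidates),
    n_matched_peaks = x$n_matched_peaks,
    n_anchored_loci = x$n_anchored_loci,
    candidates = paste(x$candidates, collapse = ";")
  )
}

#' Classify every sample of an assemblage
#'
#' @param assemblage A `zooms_assemblage` (or tibble with `sample_id` and a
#'   `peaks` list column).
#' @param panel A `zooms_panel`.
#' @param params A [match_params()] object.
#' @return A tibble with one row per sample (the [glance()] of each
#'   classification, plus the truth column when present) and a
#'   `classification` list column.
#' @export
classify_assemblage <- function(assemblage, panel, params = match_params()) {
  stopifnot(all(c("sample_id", "peaks") %in% names(assemblage)))
  cls <- purrr::map2(assemblage$peaks, assemblage$sample_id,
                     function(pk, sid) {
    out <- classify_spectrum(pk, panel, params)
    out$sample_id <- sid
    out
  })
  res <- purrr::map_dfr(cls, glance)
  if ("truth" %in% names(assemblage)) {
    res <- dplyr::mutate(res, truth = assemblage$truth, .after = "sample_id")
  }
  res$classification <- cls
  res
}

#' Summarise assemblage classifications as an identification report
#'
#' Produces the NISP-style summary used in zooarchaeological reporting: one
#' row per resolved taxonomic label with its number of identified specimens,
#' plus a tally of the outcome statuses.
#'
#' @param classifications Output of [classify_assemblage()], or a list of
#'   `zooms_classification` objects.
#' @return A `zooms_report` list: `id_table` (label, rank, nisp) and
#'   `status_tally` (status, n).
#' @export
zooms_report <- function(classifications) {
  if (inherits(classifications, "zooms_classification")) {
    classifications <- list(classifications)
  }
  df <- if (is.data.frame(classifications)) {
    classifications
  } else {
    purrr::map_dfr(classifications, glance)
  }
  if (nrow(df) == 0) rlang::abort("At least one classification is required.")
  id_table <- df |>
    dplyr::filter(.data$status == "identified") |>
    dplyr::count(.data$label, .data$rank, name = "nisp") |>
    dplyr::arrange(dplyr::desc(.data$nisp), .data$label)
  status_tally <- df |>
    dplyr::count(.data$status, name = "n") |>
    dplyr::arrange(.data$status)
  structure(list(id_table = id_table, status_tally = status_tally,
                 n_samples = nrow(df)),
            class = "zooms_report")
}

#' @export
print.zooms_report <- function(x, ...) {
  cat(sprintf("<zooms_report> %d samples\n", x$n_samples))
  if (nrow(x$id_table) > 0) {
    cat("identifications (NISP):\n")
    for (r in seq_len(nrow(x$id_table))) {
      cat(sprintf("  %-28s %-8s %d\n", x$id_table$label[r],
                  x$id_table$rank[r], x$id_table$nisp[r]))
    }
  } else {
    cat("no identified samples\n")
  }
  cat("status tally:\n")
  for (r in seq_len(nrow(x$status_tally))) {
    cat(sprintf("  %-24s %d\n", x$status_tally$status[r],
                x$status_tally$n[r]))
  }
  invisible(x)
}

#' @rdname zooms_report
#' @param report A `zooms_report`.
#' @param path Output TSV path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "zooms_report"))
  out <- dplyr::bind_rows(
    dplyr::mutate(report$id_table, section = "identification"),
    tibble::tibble(label = report$status_tally$status, rank = NA_character_,
                   nisp = report$status_tally$n, section = "status")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
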