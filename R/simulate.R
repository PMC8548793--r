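#' Simulation parameters for synthetic MALDI spectra
#'
#' Collects the knobs of the synthetic-spectrum generator. Defaults emulate
#' a well-preserved bone sample on an externally calibrated MALDI-TOF:
#' Gaussian mass error with sd 0.05 Da, no calibration offset, 95% per-marker
#' detection, an even intensity split between the members of an oxidation
#' pair, five uniform noise peaks over the 800-3200 Da marker range, and
#' log-normal peak intensities.
#'
#' @param mass_sd Gaussian mass-error standard deviation, Da (>= 0).
#' @param calibration_offset Constant m/z offset added to every marker peak,
#'   Da.
#' @param detection Per-marker-locus detection probability in [0, 1].
#' @param oxidation_split Intensity share of the +16 partner when both
#'   members of an oxidation pair are visible, in [0, 1].
#' @param noise_peaks Number of uniform-random noise peaks over 800-3200 Da.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param preservation Optional preset overriding `detection`: `"good"`
#'   (0.95), `"degraded"` (0.6) or `"poor"` (0.25).
#' @return A list of class `zooms_sim_params`.
#' @export
sim_params <- function(mass_sd = 0.05, calibration_offset = 0,
                       detection = 0.95, oxidation_split = 0.5,
                       noise_peaks = 5, intensity_meanlog = log(1000),
                       intensity_sdlog = 0.7, preservation = NULL) {
  if (!is.null(preservation)) {
    detection <- switch(match.arg(preservation,
                                  c("good", "degraded", "poor")),
                        good = 0.95, degraded = 0.6, poor = 0.25)
  }
  stopifnot(mass_sd >= 0, detection >= 0, detection <= 1,
            oxidation_split >= 0, oxidation_split <= 1, noise_peaks >= 0)
  structure(
    list(mass_sd = mass_sd, calibration_offset = calibration_offset,
         detection = detection, oxidation_split = oxidation_split,
         noise_peaks = as.integer(noise_peaks),
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog),
    class = "zooms_sim_params"
  )
}

#' Read simulation parameters from a TOML-style config file
#'
#' Accepts a minimal `key = value` config (comments with `#`, optional
#' `[section]` headers, numeric values) whose keys match the arguments of
#' [sim_params()].
#'
#' @param path Path to the config file.
#' @return A `zooms_sim_params`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, character(1), 2))))
  args <- stats::setNames(as.list(vals), keys)
  known <- names(formals(sim_params))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown simulation parameter(s): %s",
                         paste(bad, collapse = ", ")))
  }
  do.call(sim_params, args)
}

#' Simulate a synthetic MALDI peak list
#'
#' Generates a centroided spectrum for one reference taxon, or for the
#' `"collagen_only"` state (collagen preserved but only the ubiquitous P1
#' marker detectable) or the `"non_collagen"` state (noise peaks only).
#' For each MALDI-visible marker of the taxon, the marker locus is detected
#' with probability `detection`; a detected locus emits its visible masses
#' (computed monoisotopic \eqn{[M+H]^+} where the sequence is known, the
#' nominal label otherwise), each perturbed by the calibration offset plus
#' Gaussian error. When both members of an oxidation pair are visible, one
#' log-normal intensity is split between them according to
#' `oxidation_split`. Markers reported only from LC-MS/MS data are never
#' emitted. Uniform noise peaks over 800-3200 Da are added last.
#'
#' Given identical `seed` and parameters, the output is identical; random
#' draws are organised per locus so that lowering `detection` only ever
#' removes peaks.
#'
#' @param panel A `zooms_panel`.
#' @param taxon A taxon present in the panel, or `"collagen_only"` /
#'   `"non_collagen"`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A `zooms_peaklist` with attributes `truth` (the taxon/state) and
#'   `seed`.
#' @export
simulate_spectrum <- function(panel, taxon, params = sim_params(),
                              seed = 1L) {
  stopifnot(inherits(panel, "zooms_panel"))
  states <- c("collagen_only", "non_collagen")
  if (!taxon %in% c(unique(panel$alleles$taxon), states)) {
    rlang::abort(sprintf("Unknown taxon or state: '%s'.", taxon))
  }
  withr::with_seed(as.integer(seed), {
    out <- simulate_spectrum_impl(panel, taxon, params)
  })
  attr(out, "truth") <- taxon
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sample_id") <- taxon
  out
}

simulate_spectrum_impl <- function(panel, taxon, params) {
  a <- panel$alleles
  mzs <- numeric(0); ints <- numeric(0)
  if (taxon == "collagen_only") {
    # the ubiquitous P1 marker only, at its marsupial mass
    p1 <- a[a$marker == "P1" & !is.na(a$nominal_mz) & a$nominal_mz > 1150, ,
            drop = FALSE]
    emit <- tibble::tibble(
      marker = "P1",
      mz = dplyr::coalesce(p1$computed_mz[1], p1$nominal_mz[1]),
      role = "base", both = FALSE
    )
  } else if (taxon == "non_collagen") {
    emit <- tibble::tibble(marker = character(0), mz = numeric(0),
                           role = character(0), both = logical(0))
  } else {
    vis <- a[a$taxon == taxon & a$visibility == "maldi_visible" &
               !is.na(a$nominal_mz), , drop = FALSE]
    vis$mz <- dplyr::coalesce(vis$computed_mz, vis$nominal_mz)
    both <- vis |>
      dplyr::group_by(.data$marker) |>
      dplyr::mutate(both = dplyr::n() > 1) |>
      dplyr::ungroup()
    emit <- both[order(both$marker, both$role), c("marker", "mz", "role", "both")]
  }
  # one draw block per locus, in fixed (sorted) order, independent of the
  # detection outcome, so detection only masks peaks
  for (m in unique(emit$marker)) {
    rows <- emit[emit$marker == m, , drop = FALSE]
    u <- stats::runif(1)
    base_int <- stats::rlnorm(1, params$intensity_meanlog,
                              params$intensity_sdlog)
    errs <- stats::rnorm(nrow(rows), 0, params$mass_sd)
    if (u <= params$detection || taxon == "collagen_only") {
      for (r in seq_len(nrow(rows))) {
        share <- if (!rows$both[r]) 1
                 else if (rows$role[r] == "base") 1 - params$oxidation_split
                 else params$oxidation_split
        mzs <- c(mzs, rows$mz[r] + params$calibration_offset + errs[r])
        ints <- c(ints, base_int * share)
      }
    }
  }
  if (params$noise_peaks > 0) {
    mzs <- c(mzs, stats::runif(params$noise_peaks, 800, 3200))
    ints <- c(ints, stats::rlnorm(params$noise_peaks,
                                  params$intensity_meanlog - 1,
                                  params$intensity_sdlog))
  }
  peaklist(mzs, ints, sample_id = taxon)
}

#' Simulate an assemblage with known truth
#'
#' Generates one synthetic spectrum per sample according to a named
#' composition (taxon or state -> count). Per-sample seeds are derived
#' deterministically from the master seed, so a fixed seed yields
#' byte-identical output.
#'
#' @param panel A `zooms_panel`.
#' @param composition Named integer vector: taxon/state -> sample count.
#' @param params A [sim_params()] template used for every sample.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, each spectrum is written
#'   as a two-column text peak list plus a `truth.tsv` table.
#' @return A tibble (`zooms_assemblage`): `sample_id`, `truth`, `seed`,
#'   `peaks` (list column of peak lists).
#' @export
simulate_assemblage <- function(panel, composition, params = sim_params(),
                                seed = 1L, out_dir = NULL) {
  stopifnot(inherits(panel, "zooms_panel"))
  if (length(composition) == 0 || is.null(names(composition)) ||
      sum(composition) == 0) {
    rlang::abort("`composition` must be a named vector with positive counts.")
  }
  if (any(composition < 0)) rlang::abort("Counts must be non-negative.")
  truths <- rep(names(composition), times = composition)
  n <- length(truths)
  seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    truth = truths,
    seed = seeds,
    peaks = purrr::map2(truths, seeds, function(t, s) {
      simulate_spectrum(panel, t, params, seed = s)
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::pwalk(samples[, c("sample_id", "peaks")], function(sample_id, peaks) {
      write_peaklist(peaks, file.path(out_dir, paste0(sample_id, ".txt")))
    })
    readr::write_tsv(samples[, c("sample_id", "truth", "seed")],
                     file.path(out_dir, "truth.tsv"), progress = FALSE)
  }
  class(samples) <- c("zooms_assemblage", class(samples))
  samples
}
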