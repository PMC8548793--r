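#' Construct a centroided peak list
#'
#' Normalises a set of (m/z, intensity) observations into the canonical
#' peak-list form used throughout the package: a tibble sorted by strictly
#' ascending m/z, with peaks closer than 0.01 Da merged (intensities summed,
#' m/z intensity-weighted).
#'
#' @param mz,intensity Numeric vectors; m/z must be positive and finite,
#'   intensities non-negative and finite.
#' @param sample_id Optional sample identifier stored as an attribute.
#' @return A tibble of class `zooms_peaklist` with columns `mz`, `intensity`.
#' @export
peaklist <- function(mz, intensity = rep(1, length(mz)), sample_id = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0) {
    if (any(!is.finite(mz)) || any(mz <= 0)) {
      rlang::abort("Peak m/z values must be finite and positive.")
    }
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      rlang::abort("Peak intensities must be finite and non-negative.")
    }
  }
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  # merge peaks closer than 0.01 Da
  if (length(mz) > 1) {
    grp <- cumsum(c(TRUE, diff(mz) >= 0.01))
    mz <- as.numeric(tapply(mz * pmax(intensity, .Machine$double.eps), grp, sum) /
                       tapply(pmax(intensity, .Machine$double.eps), grp, sum))
    intensity <- as.numeric(tapply(intensity, grp, sum))
  }
  out <- tibble::tibble(mz = mz, intensity = intensity)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("zooms_peaklist", class(out))
  out
}

#' @export
print.zooms_peaklist <- function(x, ...) {
  sid <- attr(x, "sample_id")
  cat(sprintf("<zooms_peaklist>%s %d peaks\n",
              if (!is.na(sid)) paste0(" ", sid) else "", nrow(x)))
  NextMethod()
}

#' Read a centroided MALDI peak list
#'
#' Supported formats: `text2col` (whitespace- or tab-separated m/z and
#' intensity columns; `#` starts a comment; a single column is read as m/z
#' with unit intensities), `csv` (columns `mz`/`intensity` or the first two
#' columns), and `mzml` (centroid arrays of the first MS1 spectrum of a
#' plain, uncompressed mzML document; requires the xml2 package). `"auto"`
#' picks the format from the file extension.
#'
#' @param path Path to the peak-list file.
#' @param format One of `"auto"`, `"text2col"`, `"csv"`, `"mzml"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A `zooms_peaklist`. An empty file yields an empty peak list.
#' @export
read_peaklist <- function(path, format = c("auto", "text2col", "csv", "mzml"),
                          sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  }
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, csv = "csv", mzml = "mzml", "text2col")
  }
  if (format == "mzml") return(read_peaklist_mzml(path, sample_id))
  lines <- readLines(path, warn = FALSE)
  sep <- if (format == "csv") "," else "[ \t]+"
  skip_first <- FALSE
  if (format == "csv" && length(lines) > 0 &&
      grepl("[A-Za-z]", strsplit(lines[1], ",")[[1]][1])) {
    skip_first <- TRUE # header row
  }
  mzs <- numeric(0); ints <- numeric(0)
  for (i in seq_along(lines)) {
    if (skip_first && i == 1) next
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, sep)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals))) {
      rlang::abort(sprintf("Unparsable token '%s' at line %d of '%s'.",
                           parts[which(is.na(vals))[1]], i, path))
    }
    mzs <- c(mzs, vals[1])
    ints <- c(ints, if (length(vals) >= 2) vals[2] else 1)
  }
  peaklist(mzs, ints, sample_id = sample_id)
}

# Plain-XML mzML reader: centroid m/z and intensity arrays of the first MS1
# spectrum; only uncompressed 32/64-bit float arrays are supported.
read_peaklist_mzml <- function(path, sample_id) {
  for (pkg in c("xml2", "jsonlite")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      rlang::abort(sprintf("Reading mzML requires the '%s' package.", pkg))
    }
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  spectra <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  if (length(spectra) == 0) return(peaklist(numeric(0), sample_id = sample_id))
  decode <- function(node, what) {
    arrays <- xml2::xml_find_all(node, ".//m:binaryDataArray", ns)
    for (arr in arrays) {
      cv <- xml2::xml_attr(
        xml2::xml_find_all(arr, ".//m:cvParam", ns), "name")
      if (!any(grepl(what, cv, fixed = TRUE))) next
      bits <- if (any(grepl("32-bit float", cv))) 4L else 8L
      raw <- jsonlite::base64_dec(
        xml2::xml_text(xml2::xml_find_first(arr, ".//m:binary", ns)))
      return(readBin(raw, "double", n = length(raw) %/% bits, size = bits))
    }
    numeric(0)
  }
  node <- spectra[[1]]
  peaklist(decode(node, "m/z array"), decode(node, "intensity array"),
           sample_id = sample_id)
}

#' @rdname read_peaklist
#' @param peaks A `zooms_peaklist` (or tibble with `mz`, `intensity`).
#' @export
write_peaklist <- function(peaks, path, format = c("text2col", "csv")) {
  format <- match.arg(format)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (format == "text2col") {
    writeLines(sprintf("%.6f\t%.6f", peaks$mz, peaks$intensity), path)
  } else {
    readr::write_csv(tibble::tibble(mz = peaks$mz,
                                    intensity = peaks$intensity),
                     path, progress = FALSE)
  }
  invisible(path)
}

#' Merge replicate spots into a consensus peak list
#'
#' Reference samples are typically spotted in triplicate; this pools the
#' replicate peak lists, clusters peaks whose m/z fall within `tolerance` of
#' the running intensity-weighted cluster mean, and keeps clusters observed
#' in at least `min_count` replicates. The consensus m/z is the
#' intensity-weighted mean and the consensus intensity the mean of the
#' per-replicate summed intensities, so merging identical replicates is an
#' identity.
#'
#' @param peaklists A list of two or more peak lists.
#' @param tolerance Clustering tolerance in Da (default 0.15).
#' @param min_count Minimum number of replicates a cluster must appear in
#'   (default 2, mirroring a 2-of-3 triplicate rule).
#' @return A `zooms_peaklist`.
#' @export
merge_replicates <- function(peaklists, tolerance = 0.15, min_count = 2) {
  if (!is.list(peaklists) || length(peaklists) < 2) {
    rlang::abort("`peaklists` must be a list of at least two peak lists.")
  }
  stopifnot(tolerance > 0)
  if (min_count > length(peaklists)) {
    rlang::abort(sprintf(
      "`min_count` (%d) exceeds the number of replicates (%d).",
      min_count, length(peaklists)))
  }
  pooled <- dplyr::bind_rows(purrr::imap(peaklists, function(pl, i) {
    tibble::tibble(mz = pl$mz, intensity = pl$intensity, replicate = i)
  }))
  if (nrow(pooled) == 0) return(peaklist(numeric(0)))
  pooled <- dplyr::arrange(pooled, .data$mz)
  cluster <- integer(nrow(pooled))
  cid <- 0L; wsum <- 0; isum <- 0
  for (r in seq_len(nrow(pooled))) {
    if (r == 1 || abs(pooled$mz[r] - wsum / isum) > tolerance) {
      cid <- cid + 1L
      wsum <- 0; isum <- 0
    }
    cluster[r] <- cid
    w <- max(pooled$intensity[r], .Machine$double.eps)
    wsum <- wsum + pooled$mz[r] * w
    isum <- isum + w
  }
  pooled$cluster <- cluster
  cons <- pooled |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_rep = dplyr::n_distinct(.data$replicate),
      mz = sum(.data$mz * pmax(.data$intensity, .Machine$double.eps)) /
        sum(pmax(.data$intensity, .Machine$double.eps)),
      intensity = sum(.data$intensity) / dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_rep >= min_count)
  peaklist(cons$mz, cons$intensity)
}
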