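#' In silico tryptic digestion
#'
#' Cuts a protein sequence after every lysine or arginine that is not
#' followed by proline (the classical trypsin rule; the no-cleavage-before-P
#' behaviour can be switched off) and enumerates all peptides with up to
#' `missed_cleavages` internal missed cut sites, i.e. every concatenation of
#' at most `missed_cleavages + 1` adjacent fundamental fragments.
#'
#' The proline rule matters for collagen fingerprinting: a substitution that
#' places a proline directly after a cut-site lysine fuses two tryptic
#' peptides into one, shifting a marker by four residues in the monotreme
#' COL1A2 454-483 case.
#'
#' @param sequence A single protein/chain string (uppercase one-letter code).
#' @param missed_cleavages Maximum number of missed cleavages (0-3).
#' @param cleave_before_proline If `TRUE`, K/R followed by P is cut anyway
#'   (i.e. the proline rule is disabled). Default `FALSE`.
#' @return A tibble with one row per peptide: `peptide`, 1-based `start` and
#'   `end`, and `missed` (number of internal missed cut sites). Rows are
#'   ordered by start position, then length. The zero-missed-cleavage rows
#'   concatenate to the input sequence.
#' @examples
#' digest("AAKGG")
#' digest("GGKPGR") # K before P is not cut
#' digest("AAKRGG", missed_cleavages = 1)
#' @export
digest <- function(sequence, missed_cleavages = 0L,
                   cleave_before_proline = FALSE) {
  stopifnot(length(sequence) == 1)
  check_sequence(sequence)
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0 || missed_cleavages > 3) {
    rlang::abort("`missed_cleavages` must be an integer between 0 and 3.")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(vapply(seq_len(n), function(i) {
    is_cut_site(chars, i, cleave_before_proline)
  }, logical(1)))
  # fragment boundaries: starts and ends of the fundamental fragments
  ends <- unique(c(cuts, n))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nfrag <- length(starts)
  out <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    for (j in i:min(i + missed_cleavages, nfrag)) {
      out[[length(out) + 1L]] <- list(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i], end = ends[j], missed = j - i
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$start, .data$end)
  tibble::as_tibble(res)
}

is_cut_site <- function(chars, i, cleave_before_proline) {
  n <- length(chars)
  if (!chars[i] %in% c("K", "R") || i == n) return(FALSE)
  cleave_before_proline || chars[i + 1L] != "P"
}

#' Extract a marker-locus peptide from a collagen chain
#'
#' Returns the substring of `chain` covering the 1-based inclusive span
#' `start`..`end`, together with a verdict on whether that span is a valid
#' tryptic product of the chain: it must be preceded by a cut site (or the
#' chain start) and end at one (or the chain end), under the same proline
#' rule as [digest()].
#'
#' @param chain A single chain sequence.
#' @param start,end 1-based inclusive span, `start <= end`.
#' @inheritParams digest
#' @return A one-row tibble: `peptide`, `start`, `end`, `tryptic` (logical).
#' @export
extract_locus_peptide <- function(chain, start, end,
                                  cleave_before_proline = FALSE) {
  stopifnot(length(chain) == 1)
  check_sequence(chain, "chain")
  start <- as.integer(start); end <- as.integer(end)
  n <- nchar(chain)
  if (is.na(start) || is.na(end) || start < 1 || end > n || start > end) {
    rlang::abort(sprintf(
      "Span %s-%s is not a valid 1-based span of a chain of length %d.",
      start, end, n
    ))
  }
  chars <- strsplit(chain, "", fixed = TRUE)[[1]]
  left_ok <- start == 1L || is_cut_site(chars, start - 1L, cleave_before_proline)
  right_ok <- end == n || is_cut_site(chars, end, cleave_before_proline)
  tibble::tibble(
    peptide = substr(chain, start, end),
    start = start, end = end,
    tryptic = left_ok && right_ok
  )
}

#' Read protein chains from a FASTA file
#'
#' Minimal FASTA ingestion for aligned collagen chains: the first
#' whitespace-delimited word of each header is used as the chain/taxon
#' identifier; sequences are uppercased and concatenated across wrapped
#' lines.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_chain_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    rlang::abort(sprintf("'%s' does not look like a FASTA file.", path))
  }
  idx <- cumsum(startsWith(lines, ">"))
  headers <- lines[startsWith(lines, ">")]
  ids <- vapply(strsplit(sub("^>", "", headers), "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!startsWith(lines, ">")],
                       idx[!startsWith(lines, ">")]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  tibble::tibble(id = ids, sequence = unname(seqs))
}
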