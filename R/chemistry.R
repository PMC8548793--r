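#' Monoisotopic residue masses
#'
#' Monoisotopic masses of the 20 canonical amino-acid residues, in daltons,
#' together with the constants used throughout the package: the mass of water
#' (added once per peptide), the proton mass (for singly protonated
#' \eqn{[M+H]^+} ions), the hydroxylation/oxidation delta (+15.99491 Da, the
#' modification that turns proline into hydroxyproline) and the deamidation
#' delta (+0.98402 Da, N/Q to D/E).
#'
#' @return A named numeric vector of residue masses (Da).
#' @examples
#' residue_masses()[["G"]]
#' @export
residue_masses <- function() .residue_masses

.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname residue_masses
#' @format NULL
#' @export
mass_constants <- function() {
  c(water = 18.010565, proton = 1.007276,
    hydroxylation = 15.99491, deamidation = 0.98402)
}

WATER_MASS <- 18.010565
PROTON_MASS <- 1.007276
HYDROXYLATION_MASS <- 15.99491
DEAMIDATION_MASS <- 0.98402

# Validate peptide strings against the canonical alphabet; errors name the
# offending symbol and its 1-based position.
check_sequence <- function(sequence, arg = "sequence") {
  if (length(sequence) == 0) {
    rlang::abort(sprintf("`%s` must contain at least one peptide string.", arg))
  }
  for (s in sequence) {
    if (is.na(s) || !nzchar(s)) {
      rlang::abort(sprintf("`%s` must be a non-empty peptide string.", arg))
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% names(.residue_masses))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "Non-canonical residue symbol '%s' at position %d of '%s'.",
        chars[bad[1]], bad[1], s
      ))
    }
  }
  invisible(sequence)
}

count_residues <- function(sequence, residues) {
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) sum(ch %in% residues), integer(1))
}

#' Count modifiable sites in a peptide
#'
#' Hydroxylation (oxidation) is siteable on proline and lysine (optionally
#' also methionine); deamidation on asparagine and glutamine. Modifications
#' are modelled as counts, not positions: positional isomers are
#' mass-identical and irrelevant for fingerprint matching.
#'
#' @param sequence Character vector of peptide strings (uppercase one-letter
#'   code).
#' @param include_met Should methionine count as a hydroxylation/oxidation
#'   site? Off by default: no bundled marker sequence requires it.
#' @return Integer vector of site counts.
#' @export
hydroxylation_sites <- function(sequence, include_met = FALSE) {
  check_sequence(sequence)
  count_residues(sequence, if (include_met) c("P", "K", "M") else c("P", "K"))
}

#' @rdname hydroxylation_sites
#' @export
deamidation_sites <- function(sequence) {
  check_sequence(sequence)
  count_residues(sequence, c("N", "Q"))
}

#' Monoisotopic peptide mass
#'
#' Computes the neutral monoisotopic mass, or the singly protonated
#' \eqn{[M+H]^+} m/z, of a peptide carrying a given number of hydroxylations
#' (+15.99491 Da each, on P/K sites) and deamidations (+0.98402 Da each, on
#' N/Q sites). Vectorised over `sequence` (modification counts are recycled).
#'
#' @inheritParams hydroxylation_sites
#' @param hydroxylations,deamidations Non-negative integer modification
#'   counts; each must not exceed the number of available sites.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mhplus("GVQGPPGPQGPR", hydroxylations = 1) # marsupial P1, ~1162.6
#' @export
peptide_mhplus <- function(sequence, hydroxylations = 0L, deamidations = 0L,
                           include_met = FALSE) {
  peptide_mass(sequence, hydroxylations, deamidations,
               include_met = include_met) + PROTON_MASS
}

#' @rdname peptide_mhplus
#' @export
peptide_mass <- function(sequence, hydroxylations = 0L, deamidations = 0L,
                         include_met = FALSE) {
  check_sequence(sequence)
  n <- length(sequence)
  k <- rep_len(as.integer(hydroxylations), n)
  d <- rep_len(as.integer(deamidations), n)
  if (any(is.na(k)) || any(k < 0) || any(is.na(d)) || any(d < 0)) {
    rlang::abort("Modification counts must be non-negative integers.")
  }
  kmax <- hydroxylation_sites(sequence, include_met)
  dmax <- deamidation_sites(sequence)
  if (any(k > kmax)) {
    i <- which(k > kmax)[1]
    rlang::abort(sprintf(
      "%d hydroxylations requested but '%s' has only %d siteable residues.",
      k[i], sequence[i], kmax[i]
    ))
  }
  if (any(d > dmax)) {
    i <- which(d > dmax)[1]
    rlang::abort(sprintf(
      "%d deamidations requested but '%s' has only %d siteable residues.",
      d[i], sequence[i], dmax[i]
    ))
  }
  res <- vapply(strsplit(sequence, "", fixed = TRUE),
                function(ch) sum(.residue_masses[ch]), numeric(1))
  res + WATER_MASS + k * HYDROXYLATION_MASS + d * DEAMIDATION_MASS
}

#' Infer the hydroxylation count behind a nominal marker mass
#'
#' ZooMS marker tables print integer m/z labels but not the hydroxyproline
#' counts that link a peptide sequence to its label. This searches k = 0 ..
#' (number of P/K sites) for the smallest count whose \eqn{[M+H]^+} falls
#' within `tolerance` of the nominal mass. The default tolerance of 1.0 Da
#' absorbs the mix of truncation and rounding seen in printed integer labels.
#'
#' @inheritParams peptide_mhplus
#' @param nominal Numeric vector of nominal (integer) marker masses, Da.
#' @param tolerance Maximum |computed - nominal| accepted, Da (> 0).
#' @return Integer vector: the inferred count, or `NA` when no count
#'   reproduces the nominal mass.
#' @examples
#' infer_hydroxylations("GVQGPAGPQGPR", 1120) # 0
#' infer_hydroxylations("GPNGEPGSTGPTGPPGLR", 1680) # 2
#' @export
infer_hydroxylations <- function(sequence, nominal, tolerance = 1.0,
                                 include_met = FALSE) {
  check_sequence(sequence)
  stopifnot(is.numeric(tolerance), length(tolerance) == 1, tolerance > 0)
  n <- max(length(sequence), length(nominal))
  sequence <- rep_len(sequence, n)
  nominal <- rep_len(nominal, n)
  purrr::map2_int(sequence, nominal, function(s, nom) {
    kmax <- hydroxylation_sites(s, include_met)
    for (k in 0:kmax) {
      if (abs(peptide_mhplus(s, k, include_met = include_met) - nom) <= tolerance) {
        return(as.integer(k))
      }
    }
    NA_integer_
  })
}
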