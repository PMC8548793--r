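# Independent oracles used by the property and acceptance tests. These are
# deliberately written as plain position scans and nested loops, separate
# from the package's vectorised implementations.

# Position-scan tryptic digest: walk the sequence, cut after K/R not
# followed by P, then enumerate adjacent-fragment unions up to the allowed
# number of missed cleavages.
oracle_digest <- function(sequence, missed_cleavages = 0) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  for (i in seq_len(n - 1)) {
    if (chars[i] %in% c("K", "R") && chars[i + 1] != "P") {
      boundaries <- c(boundaries, i)
    }
  }
  ends <- c(boundaries, n)
  starts <- c(1, boundaries + 1)
  peps <- character(0); st <- integer(0); en <- integer(0); mc <- integer(0)
  for (i in seq_along(starts)) {
    for (j in i:length(starts)) {
      if (j - i > missed_cleavages) break
      peps <- c(peps, paste(chars[starts[i]:ends[j]], collapse = ""))
      st <- c(st, starts[i]); en <- c(en, ends[j]); mc <- c(mc, j - i)
    }
  }
  ord <- order(st, en)
  data.frame(peptide = peps[ord], start = st[ord], end = en[ord],
             missed = mc[ord], stringsAsFactors = FALSE)
}

# Exhaustive hydroxylation-count search, written against its own residue
# mass table.
oracle_mhplus <- local({
  rm <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
          V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
          I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
          K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
          F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  function(sequence, k = 0, d = 0) {
    chars <- strsplit(sequence, "")[[1]]
    sum(rm[chars]) + 18.010565 + 1.007276 + 15.99491 * k + 0.98402 * d
  }
})

oracle_infer_k <- function(sequence, nominal, tolerance = 1.0) {
  chars <- strsplit(sequence, "")[[1]]
  cap <- sum(chars %in% c("P", "K"))
  for (k in 0:cap) {
    if (abs(oracle_mhplus(sequence, k) - nominal) <= tolerance) return(k)
  }
  NA_integer_
}

# Brute-force classification oracle: tests every taxon's full marker
# profile against the observed peak masses under the stated consistency
# rules (wildcards for unreported loci; exact matching of complete
# oxidation pairs; oxidation-ladder-tolerant matching of lone pair members;
# colliding masses only anchor when corroborated, and are excused for a
# taxon that explains them at the other locus; +/-16 state partners at the
# D locus never mutually exclude; absence never excludes).
oracle_candidates <- function(peak_mz, panel, tol = 0.3) {
  al <- panel$alleles[!is.na(panel$alleles$nominal_mz), ]
  al$mz <- ifelse(is.na(al$computed_mz), al$nominal_mz, al$computed_mz)
  al$w <- ifelse(is.na(al$computed_mz), max(tol, 1), tol)
  coll <- panel$collisions$nominal_mz
  paired <- panel$loci$marker[panel$loci$paired]
  vis <- al[al$visibility == "maldi_visible", ]

  # which loci does each peak hit (visible alleles only), and is the peak
  # explainable solely by colliding nominal masses?
  peak_loci <- lapply(peak_mz, function(p) {
    unique(vis$marker[abs(p - vis$mz) <= vis$w])
  })
  peak_coll <- vapply(seq_along(peak_mz), function(i) {
    hit <- abs(peak_mz[i] - vis$mz) <= vis$w
    any(hit) && all(vis$nominal_mz[hit] %in% coll)
  }, logical(1))

  loci_hit <- unique(unlist(peak_loci))
  # locus-level observations
  locus_obs <- lapply(loci_hit, function(L) {
    idx <- which(vapply(peak_loci, function(x) L %in% x, logical(1)))
    mzs <- sort(unique(peak_mz[idx]))
    co <- vapply(mzs, function(p) peak_coll[which(peak_mz == p)[1]],
                 logical(1))
    pairs <- list()
    if (L %in% paired && length(mzs) >= 2) {
      for (i in seq_along(mzs)) for (j in seq_along(mzs)) {
        if (i < j && abs(mzs[j] - mzs[i] - 15.99491) <= 2 * tol) {
          pairs[[length(pairs) + 1]] <- c(mzs[i], mzs[j])
        }
      }
    }
    list(marker = L, mzs = mzs, collision_only = co, pairs = pairs)
  })
  # corroboration: any locus with a non-collision observation?
  noncoll_anchor <- any(vapply(locus_obs, function(o) {
    if (o$marker %in% paired) {
      length(o$pairs) > 0 ||
        any(!o$collision_only[!o$mzs %in% unlist(o$pairs)])
    } else any(!o$collision_only)
  }, logical(1)))

  taxa <- sort(unique(panel$alleles$taxon))
  ok <- vapply(taxa, function(t) {
    rows_t <- al[al$taxon == t, ]
    # all masses this taxon can explain anywhere (incl. D-locus +/-16 states)
    explain <- rows_t$mz
    exw <- rows_t$w
    st <- rows_t[!is.na(rows_t$partner_kind) & rows_t$partner_kind == "state", ]
    if (nrow(st) > 0) {
      explain <- c(explain, st$mz + sign(st$pair_partner_mz - st$nominal_mz) *
                     15.99491)
      exw <- c(exw, st$w)
    }
    explains <- function(p) any(abs(p - explain) <= exw)
    for (o in locus_obs) {
      unrep <- any(panel$alleles$taxon == t &
                     panel$alleles$marker == o$marker &
                     panel$alleles$visibility == "unreported")
      if (unrep) next
      rows <- al[al$taxon == t & al$marker == o$marker, ]
      if (nrow(rows) == 0) next
      base <- rows[rows$role == "base", ]
      oxi <- rows[rows$role == "oxidized", ]
      if (o$marker %in% paired) {
        in_pair <- o$mzs %in% unlist(o$pairs)
        for (pr in o$pairs) {
          hit <- FALSE
          for (b in seq_len(nrow(base))) {
            pmz <- if (nrow(oxi) > 0) oxi$mz else base$mz[b] + 15.99491
            pw <- if (nrow(oxi) > 0) oxi$w else base$w[b]
            if (abs(pr[1] - base$mz[b]) <= base$w[b] &&
                any(abs(pr[2] - pmz) <= pw)) hit <- TRUE
          }
          if (!hit) return(FALSE)
        }
        singles <- o$mzs[!in_pair & !o$collision_only]
        for (s in singles) {
          ladder <- c(base$mz, base$mz + 15.99491, base$mz + 2 * 15.99491,
                      oxi$mz, oxi$mz + 15.99491)
          lw <- c(base$w, base$w, base$w, oxi$w, oxi$w)
          if (!any(abs(s - ladder) <= lw) && !explains(s)) return(FALSE)
        }
      } else {
        anchor <- o$mzs[!o$collision_only |
                          (noncoll_anchor & o$collision_only)]
        accept <- rows$mz
        aw <- rows$w
        stx <- rows[!is.na(rows$partner_kind) & rows$partner_kind == "state", ]
        if (nrow(stx) > 0) {
          accept <- c(accept, stx$mz +
                        sign(stx$pair_partner_mz - stx$nominal_mz) * 15.99491)
          aw <- c(aw, stx$w)
        }
        for (p in anchor) {
          if (any(abs(p - accept) <= aw)) next
          is_coll <- o$collision_only[o$mzs == p][1]
          if (is_coll && explains(p)) next
          return(FALSE)
        }
      }
    }
    TRUE
  }, logical(1))
  taxa[ok]
}

noise_free_params <- function() {
  sim_params(mass_sd = 0, calibration_offset = 0, detection = 1,
             noise_peaks = 0)
}
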