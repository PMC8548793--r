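---
title: "Marker-based collagen fingerprinting: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based collagen fingerprinting: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozzooms)
```

## The measurement model

ZooMS reads a bone sample as a set of singly protonated monoisotopic
peptide masses. For a tryptic collagen peptide with sequence $s$, $k$
hydroxylations and $d$ deamidations,

$$ m/z = \sum_i M(s_i) + 18.010565 + 1.007276 + 15.99491\,k + 0.98402\,d. $$

Hydroxyproline is pervasive in collagen, so every marker mass depends on a
hydroxylation count that reference tables do not print. `ozzooms` treats
modifications as *counts with site-capacity checks* (at most one per P/K
for hydroxylation, per N/Q for deamidation): positional isomers have
identical mass and are irrelevant to fingerprint matching, and site
localisation is deliberately not modelled. Methionine oxidation shares the
same +15.99491 Da delta; it can be enabled (`include_met = TRUE`) but is
off by default because no bundled marker sequence requires it.

`infer_hydroxylations()` recovers the count linking a sequence to its
printed integer label by exhaustive search over $k = 0..(\#P+\#K)$. The
agreement criterion is $\pm 1.0$ Da because published integer labels mix
truncation (1162.596 printed as 1162) with rounding (1679.798 printed as
1680); anything tighter would reject correct sequences, anything looser
could hop to the next oxidation rung (+15.99).

In-silico digestion cuts after K/R except before proline. The proline
rule matters biologically here: in the monotreme COL1A2 454–483 marker a
proline follows the lysine cut site, fusing four extra residues onto the
peptide relative to the marsupial form — the largest single
monotreme/marsupial mass difference in the panel. The rule can be
disabled (`cleave_before_proline = TRUE`) for generality.

## The bundled panel and its conventions

The panel covers 24 marsupial and monotreme reference taxa at 11 marker
loci. Three conventions from the source tables are encoded explicitly:

* **Visibility.** Some marker masses are only observed in LC-MS/MS data,
  never in MALDI fingerprints (`msms_only`). They are never emitted by the
  simulator and never anchor a locus during classification; a peak that
  happens to match one is recorded as support but can never exclude a
  taxon. `unreported` cells ("x" in the source) are wildcards: the locus
  never constrains that taxon.
* **Oxidation pairs.** Loci A, F and G are conventionally reported as a
  base mass plus a +16 partner (one extra hydroxylation of the same
  peptide). Both members are stored as rows of one paired locus, each
  with its own visibility.
* **Diagnostic flags.** Bold-face in the source marks masses usable to
  separate monotremes from marsupials (and other emphasised cells). The
  flag is stored as metadata only and never changes matching behaviour,
  because the separation already falls out of the mass arithmetic
  (P1 1120 vs 1162, C 1607 vs 1598, E 2848 vs 2335 all differ by > 2 Da).

Every allele that carries a sequence also stores the inferred
hydroxylation count and the resulting computed mass; `validate_panel()`
re-derives all of this and reports zero inconsistencies for the bundled
panel. One allele is stored *nominal-only*: the echidna G-locus entry at
2999/3015. Its published sequence cannot be reconciled with the printed
mass by any hydroxylation count (the nearest rung is 1.49 Da away, while
every other entry reconciles within 0.85 Da), so attaching it would
violate the panel's own consistency invariant. The sequence is kept,
flagged `reconciles = FALSE`, in `marker_sequences()`.

Two further panel-content choices were genuinely open. The two distinct
D-locus sequences printed at the same nominal 2121 are keyed by mass
only; we assign the more divergent GL..LS..PS variant to the echidna (the
evolutionary outlier) and the SV..IA..PA variant to the thylacine, whose
dasyurid relatives share that scaffold. The masses are near-identical, so
classification is unaffected either way. The common wombat's D marker is
stored at 2119 — its two-oxidation state, the one most visible in its
MALDI spectra — with the 2135 three-oxidation state allowed as a +16
partner.

## Matching and classification rules

Matching uses computed monoisotopic masses wherever a sequence is known
(window = `tolerance`, default 0.3 Da, an external-calibration MALDI-TOF
scale, configurable) and nominal integer labels otherwise (window =
max(tolerance, 1.0) Da, since an integer label carries at most ±0.5 Da of
information plus the truncation ambiguity).

A taxon is a candidate for a spectrum if and only if every *anchored*
locus observation is contained in its allele set. The anchoring rules
encode three ambiguities of real marker reading:

* **Complete oxidation pairs match exactly.** Two peaks 15.99 ± 2·tol
  apart at a paired locus form a strong anchor; a taxon must match both
  members. This is what lets the 2897/2913 pair exclude the banded hare
  wallaby (2881/2897) even though the two pairs overlap at 2897.
* **Lone pair members exclude only outside the oxidation ladder.** A
  single peak at a paired locus is compatible with a taxon's base, its
  +16 partner, *or the partner's own further-oxidised +32 state*. A lone
  2913 therefore never excludes the banded hare wallaby (it could be its
  2897 partner with one more oxidation), but a lone 1166 does exclude the
  brushtail possum (1137/1153): no oxidation state reaches it. This is
  deliberately weaker than requiring the complete pair before any
  exclusion — that stricter rule would leave the brushtail possum as a
  candidate for tammar-wallaby-type spectra, which the marker table
  plainly separates.
* **Colliding masses need corroboration.** Nominal masses registered at
  more than one locus (2975) or ambiguous between base and +16 states of
  different taxa (2897, 2945, 2959) only anchor when the spectrum also
  contains a non-colliding anchor; and a colliding peak is not held
  against a taxon that explains it at the other locus (an observed 2975
  is the wombat group's G′ state, so it cannot veto their 10–42 allele).
  The D-locus 2161/2177 masses are two oxidation states of one peptide
  and never mutually exclude; they are stored as ±16 state partners.

Within an anchored unpaired locus, *every* observed peak must be
explained (all-match). This is the monotone choice — removing peaks can
only grow the candidate set, and adding peaks can only shrink it — and it
makes the classifier fail safe: a noise peak that lands on a conflicting
allele mass empties the candidate set and the sample degrades to
`collagen_unidentifiable` rather than being misassigned. Absence is never
evidence: dropout dominates degraded bone, so a missing marker never
excludes anyone.

Outcome statuses mirror archaeological reporting: `identified` requires
the ubiquitous P1 marker, at least `min_loci` (default 2) other anchored
loci, and a non-empty candidate set; P1 with insufficient further
evidence is `collagen_unidentifiable`; a collagen-like series without P1
is `tentative_fish_or_bird` (P1 at 1162 is shared with many birds and
reptiles, which is also why thin identifications carry a warning note);
anything with fewer matches is `failed`. The reported label is the lowest
lineage rank shared by all candidates (species → genus → family → order →
clade), from a lineage table hard-coded for the panel taxa. Candidates
are reported alphabetically; all outputs are deterministic.

`equivalence_classes()` summarises the panel's intrinsic resolution.
Because visibility differs between taxa, "A's spectrum keeps B" is not
symmetric (the red kangaroo's F′ is MS/MS-only, so its noise-free
spectrum cannot exclude the banded hare wallaby, while the reverse
exclusion works). To obtain a genuine partition we group taxa by the
connected components of the *mutual*-consistency relation on noise-free,
full-detection profiles. The resulting classes reproduce the known
indistinguishable groups: the two grey kangaroos; the tammar wallaby with
the swamp wallaby; the six-macropod group; the koala with the
hairy-nosed wombat (identical everywhere the latter reports).

## What the simulator emulates — and what it does not

`simulate_spectrum()` generates centroided peak lists with known truth:
per-locus Bernoulli detection (presets: good 0.95, degraded 0.6, poor
0.25), Gaussian mass error (default sd 0.05 Da) plus a constant
calibration offset, an intensity split between visible pair members
(default 0.5), log-normal intensities, and uniform noise peaks over
800–3200 Da — the span of the marker masses — with log-normal
intensities (default 5 per spectrum, a simple adversarial stand-in; no
noise model is published for this kind of data). Two degenerate states
complete the outcome mix seen in archaeological assemblages:
`collagen_only` (only the P1 peak survives) and `non_collagen` (noise
only). Random draws are organised in fixed per-locus blocks so that, at a
fixed seed, lowering the detection probability only ever removes peaks.
Assemblage simulation derives per-sample seeds deterministically from a
master seed and writes plain-text spectra plus a truth table.

Real degraded spectra differ from this model in ways that matter:
dropout is correlated with mass and with overall preservation rather than
independent per marker; isotope envelopes, adducts, baseline and
calibration drift are absent; intensities carry no biological signal
here. Passing the simulation-based tests therefore demonstrates the
correctness of the marker-reading logic under the stated statistical
assumptions, not instrument-level performance on real material.

## Numerical choices and degenerate inputs

Peak lists are sorted, with peaks closer than 0.01 Da merged
(intensity-weighted m/z, summed intensity); an empty spectrum is a valid
empty peak list, not an error. Replicate merging clusters pooled peaks
against the running intensity-weighted cluster mean at 0.15 Da and keeps
clusters present in ≥ 2 replicates by default, mirroring triplicate
spotting; merging identical replicates is an identity. Marker discovery
requires pre-aligned, gap-free, equal-length chains, reports
hydroxylation ladders capped at k = 6 to avoid combinatorial noise, and
uses a 2.0 Da minimum gap so that deamidation (+0.98) and oxidation-rung
(+15.99 between k and k+1) confusions cannot masquerade as taxonomic
differences. Pair detection windows are 15.99 ± 2·tolerance (each member
carries its own error).

## Problem sizes used by the test suite

The suite exercises the digest against an independent position-scan
oracle on 1000 random sequences (length ≤ 60); classification against an
independently coded brute-force consistency oracle on all 24 taxa × 20
seeds at 0.05 Da error; and robustness at 0.1 Da error, 20% per-marker
dropout and 5 noise peaks with 100 seeded simulations per taxon, where
the true taxon must appear in ≥ 95% of identified samples and
collagen-only samples must never be assigned a taxon. These sizes keep
the full suite in the minutes range on a single core while leaving the
stochastic margins interpretable.

## Known limitations

* The panel resolves most taxa to genus but leaves a six-macropod group,
  the two grey kangaroos, tammar/swamp wallaby, and koala/hairy-nosed
  wombat unresolved by MALDI-visible markers alone; the spectacled hare
  wallaby is separable only by an LC-MS/MS-level sequence difference
  (COL1A2 671–700), which is outside the classifier's scope and surfaced
  as a note on affected identifications.
* Panels for non-marsupial comparison taxa (bovids, sea turtles, fish,
  birds) are not bundled; users can supply them as external TSVs.
* Likelihood or intensity-based scoring, mixture deconvolution, isotope
  envelope modelling and site-localised modification assignment are
  non-goals; the classifier is a transparent rule system, by design the
  same one a careful human marker-reader would apply.
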