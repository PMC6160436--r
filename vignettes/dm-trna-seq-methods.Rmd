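---
title: "Methods: modification calling and 3'-end analysis for DM-tRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modification calling and 3'-end analysis for DM-tRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtrnaseq)
```

## The measurement model

Demethylase tRNA sequencing (DM-tRNA-seq) reads tRNA with a thermostable
group II intron reverse transcriptase (TGIRT), which is processive enough
to traverse tRNA secondary structure. cDNA synthesis starts at the
molecule's 3' terminus — there is no fragmentation step, so every read is
anchored at the 3' CCA — and proceeds 5'-ward. When the RT encounters a
Watson–Crick-face modification such as N1-methyladenosine (m^1^A) it
either terminates or reads through with a misincorporated base. Each
sequenced library therefore carries two per-position signatures of
modification: truncated reads beginning just 3' of the modified base, and
read-through reads with a non-reference base call at it. Pairing each
library with a demethylase-treated counterpart separates methyl marks
(m^1^A/m^1^G/m^3^C class, erased by treatment) from signals that survive
it, such as the 2-thio perturbation of the wobble
5-taurinomethyl-2-thiouridine.

### Coordinates and conventions

All coordinates are 1-based, inclusive, on the mature sequence (gene body
plus the post-transcriptional CCA), 5'→3' in tRNA sense. A stop "at
position p" means p itself was **not** copied: the read covers
`p + 1 .. 3'-terminus`. The simulator and the pileup share this single
convention, which is what produces the characteristic two-peak pattern at
a genuinely modified site: the misincorporation peak sits at p while the
truncated reads begin at p + 1.

Mitochondrial tRNAs lack canonical D/T arms, so conventional tRNA
numbering does not coincide with the sequence index; position 58 of the
lysine tRNA, for instance, sits at mature index 54. The map from
conventional numbering to sequence index is therefore supplied as
reference metadata, never inferred from sequence.

### The Modification Index

At each position p we count, over uniquely aligned reads:

* `S(p)` — reads whose 5'-most covered position is p + 1 (RT stops at p);
* `R(p)` — reads covering p (read-throughs);
* `N(p) = S(p) + R(p)` — reads that reached the position;
* `X(p)` — read-throughs whose base call at p differs from the reference.

The stop fraction `S(p)/N(p)` and the mutation fraction `X(p)/N(p)` share
the denominator `N(p)`, and their sum is the Modification Index (MI).
The shared denominator is a deliberate design choice: it guarantees
`MI ∈ [0, 1]` algebraically (since `X ≤ R = N − S`) and yields a clean
recovery identity. For a site with modified fraction f, stop probability s
given modification, and misincorporation probability m given read-through,

    E[MI] = f · (s + (1 − s) · m)

when the site is far enough from the 3' end for its truncated cDNAs to be
retained (see below). A stop/mutation sum above 1 can only arise from
inconsistent denominators, so `modification_index()` treats it as an
internal error rather than clipping.

### The 3'-proximal lower bound

Because reads are 3'-anchored, a stop at position p produces a cDNA whose
length equals p's distance to the 3' terminus. cDNAs shorter than the
minimum insert length (default 15 nt) are lost during library
construction, so for 3'-proximal positions the stop signal vanishes and
only the mutation component remains: the MI under-reports the modified
fraction. We flag positions closer than 25 nt to the 3' end
(`lower_bound`), a conservative threshold since stop-length attrition is
gradual in real libraries.

One quantitative subtlety is worth recording. When every stop-derived
cDNA at a site is lost and the library is resampled to its target size,
the surviving reads are conditioned on *not* having stopped, so the
observed mutation-only MI concentrates at

    f · (1 − s) · m / (1 − f · s)

rather than the unconditioned `f·(1−s)·m`. Both are strictly below the
full-detection value — the lower-bound property holds either way — but
the validation suite asserts the conditional form, because that is what a
renormalised library actually measures.

### Estimating modified fractions near the 3' end

`estimate_modified_fraction()` rescales a mutation-only MI by the assumed
share of total signal that mutations contribute. The default share of 0.5
encodes the equal-contribution assumption justified when a context-matched
site (same local sequence, e.g. the m^1^ACA context shared by the
m^1^A16- and m^1^A58-type sites) shows comparable stop and mutation
components; with it, a mutation-only MI of 0.24 yields 0.48. The
empirical share of a specific calibration site (such as 0.074/0.16) can
be supplied instead, which would give 0.52 for the same input — the
choice of share, not the arithmetic, carries the uncertainty, so both are
exposed.

## Alignment policy

Reads are placed ungapped and end-to-end at every offset of every
reference, in both orientations, keeping placements with at most 3
mismatches, retaining only the minimum-mismatch stratum, and suppressing
reads whose best stratum exceeds 10 placements — the classic
`-v 3 -m 10 --best --strata` short-read policy. Within a stratum all ties
are reported with `unique = FALSE`; only `unique = TRUE` reads feed
pileups and abundance. Fragments shorter than 15 nt are removed before
alignment. At tRNA-reference scale (dozens of references of ~60–100 nt) a
direct scan is exact and fast, so no index structure is used; the inner
Hamming scan is compiled (Rcpp) and is verified against a plain-R
brute-force enumerator on randomized instances.

Reads that fail the primary pass are remapped against poly-A-appended
references (default tract 30 nt) so oligoadenylated molecules align
end-to-end; bases landing in the tract are reported as a 3' soft tail.
The remap panel also includes gene-body + poly-A references (no CCA):
without them, an adenylated molecule *lacking* the CCA could not align
end-to-end at all, because the templated CCA would sit mid-read. Records
carry which reference variant they matched.

Two details of the tie policy are package contracts rather than claims
about any particular aligner build: all equal-distance placements are
reported (no arbitrary winner), and `max_hits` counts placements in the
best stratum only.

## CCA status and oligo(A) tails

Uniquely aligned reads that reach the gene 3' end are sorted into
CCA-present and CCA-absent pools. CCA presence requires the read to cover
all three CCA positions with an exact, mismatch-free `CCA`: at realistic
depth a single mismatch there is indistinguishable from absence, so
strictness is the conservative contract, and a read ending `..CC` is
never counted as CCA-present. Reads that stop internally are excluded
from tail statistics rather than counted as CCA-absent — absence of
evidence is not absence of CCA.

The tail is everything 3' of the templated end: beyond the CCA for
CCA-present reads, beyond the gene body otherwise. This definition
matters for short tails. A CCA-less molecule with a 1–3 nt oligo(A) tail
aligns end-to-end against the *mature* reference with the A-for-C
mismatches absorbed by the mismatch allowance, so tail calling must not
trust the alignment's mismatch count; re-reading the read bases beyond
the gene end recovers those tails exactly. `oligoA_len` is the maximal
terminal adenosine run; mixed tails are kept verbatim in `tail_seq` but
only the terminal run counts toward adenylation.

## Quantification and comparison

Abundance is the fraction of uniquely aligned reads per reference, taken
from demethylase-treated libraries when both kinds are present (their
longer reads make assignment specific); untreated-only runs are allowed
with a warning. Heteroplasmy at a configured variant site uses
read-through base calls only — a stopped read carries no call at the site
— as alt/(ref + alt), with other bases reported as error mass. Condition
comparisons use the paired t statistic on replicate-paired values;
zero-variance differences leave t undefined rather than fabricated. Raw
p-values are primary; a Benjamini–Hochberg column is emitted alongside as
a clearly labelled extension. Replicate agreement is summarised as
pairwise Pearson correlation of abundance (or MI) vectors.

## The synthetic-data generator

Every stage is validated against libraries with fully known per-read
ground truth. `simulate_library()` emulates, in molecule-construction
order: heteroplasmic variants (e.g. an A>G at the site corresponding to
m.8344, applied per molecule at the configured fraction), CCA
presence/absence, oligo(A) tails (by default only on CCA-less molecules,
geometric lengths with mean 3), per-site modification with fraction f,
3'→5' cDNA synthesis with stop probability s and misincorporation
probability m at modified positions (demethylase treatment zeroes both
for sensitive profiles), uniform per-base sequencing error, and loss with
resampling of cDNAs below the minimum insert length (the discarded count
is recorded, keeping the lower-bound effect auditable). Reads are written
in cDNA orientation — the reverse complement of tRNA sense, as a TGIRT
library is sequenced — which exercises strand handling in the aligner.
Quality strings are constant because no stage is quality-dependent.

Per-modification s and m are calibration knobs, not measured constants:
the defaults used throughout the demo (m^1^A-like: s = 0.45, m = 0.45;
2-thio-like: s = 0, m = 0.25) give MI values in the range observed for
such sites, but real RT behaviour is sequence-context dependent. The
generator also does not model adapter read-through, PCR duplication,
quality-score structure, RT fall-off unrelated to modification, or a
nuclear-encoded tRNA background. Passing tests therefore demonstrate that
the pipeline's estimators recover the quantities the model defines — not
that the model captures every feature of real libraries.

When the pipeline simulates its own samples it draws per-reference read
counts multinomially from a fixed ~15-fold log-spread abundance profile,
so replicate libraries differ only by sampling noise, mirroring how real
replicates behave.

## Numerical choices

* Calling thresholds: `mi_min = 0.1` untreated signal, `treated_max =
  0.05` residual after treatment, `min_coverage = 50` reads. These are
  package defaults chosen to be stable at the coverages the validation
  suite uses; MI values are reported per position regardless, so callers
  can re-threshold.
* The validation suite sizes its simulations to make binomial error small
  relative to the quantity under test: 50,000 reads for point MI recovery
  (±0.01 covers >4 SD), 10,000–30,000 for tail-distribution, heteroplasmy
  and lower-bound checks, with stochastic assertions placed at 4 binomial
  SD. All randomness is seeded; FASTQ and TSV outputs are byte-identical
  under a fixed seed.
* Ties, degenerate inputs: equal-distance alignments are all reported;
  zero-coverage positions carry NA fractions rather than zeros;
  zero-variance statistics (correlation, paired t) are reported as
  undefined with a note.

## Known limitations

* Calls are signature classes (demethylase-sensitive methyl vs
  treatment-resistant signal), not chemical identities; distinguishing
  m^1^A from m^1^G, or resolving whether two modifications co-occur on
  the same molecule, is outside the per-position model (per-read
  co-occurrence can be explored from the alignment records directly).
* The distance convention (bases strictly 3' of a position, CCA included)
  is one of several in circulation; published distances for specific
  sites vary by ±1–2 nt depending on whether the CCA is counted. The
  lower-bound threshold is configurable for this reason.
* The aligner is exact but quadratic; it is intended for tRNA-sized
  reference sets, not genome-scale alignment.
* Abundance is reported as pool fractions and raw unique counts; no
  spike-in normalisation is attempted.
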