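---
title: "Designing and applying COI-barcode RFLP assays with coiRFLP"
author: "coiRFLP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and applying COI-barcode RFLP assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiRFLP)
```

## The method

PCR-RFLP species authentication rests on a simple chain of physics and
genetics: a COI barcode amplicon is double-stranded DNA of known length;
a restriction endonuclease cuts it wherever its recognition site occurs;
the fragment sizes are separated on an agarose gel; and because
restriction sites segregate between species much faster than within
them, the band pattern is a species fingerprint. `coiRFLP` models each
link of that chain explicitly, which is what lets it both *design* an
assay (choose the enzyme) and *apply* it (call species from bands).

The package works on linear, double-stranded sequences. Three modelling
conventions matter throughout:

* **Coordinates** are 0-based and half-open; "cut at position p" means
  the backbone bond between residues p-1 and p. Fragment lengths are then
  plain differences of cut coordinates, and they provably sum to the
  sequence length.
* **One cut per site, at the top-strand coordinate.** Enzymes whose two
  strand cuts are staggered (MboI leaves a 4 nt 5' overhang) produce one
  double-strand break per site; gels resolve double-stranded length, so
  we record the top-strand cut position. A window that matches on both
  strands (every palindromic site) is one site and contributes one cut; a
  bottom-strand-only match (possible only for non-palindromic patterns)
  maps through `L - cutOffset`. One consequence worth knowing: the
  fragment list of a reverse-complemented sequence is the reversed
  fragment list of the original only for enzymes whose cut is centred in
  the site (RsaI `GT^AC`); off-centre cutters shift each boundary by the
  overhang length. This is an exact property of the single-coordinate
  convention, not an implementation artefact.
* **Ambiguity is conservative.** A sequence base matches a pattern
  position only when its IUPAC set is a *subset* of the pattern code's
  set. An `N` in a sequencing consensus could complete a GATC site, but
  asserting a cut there would fabricate fragments; such windows are
  reported as *candidate* sites and never cut. The behaviour of the web
  tools historically used for in silico digestion on ambiguous bases is
  undocumented, so the package makes the cautious choice and surfaces
  the uncertainty instead of hiding it.

## The virtual gel

Digestion yields exact fragment lengths; a gel does not show them. Two
parameters translate between the two worlds, both carried in a
`GelParams` object and overridable everywhere:

* `minBand` (default **100 bp**): on a 3% agarose gel scored against a
  100 bp ladder, fragments below roughly 100 bp run off or are too faint
  to call. Published COIBar-RFLP patterns routinely omit such fragments
  (a digest summing to 650 bp may be reported as "510 + 95"), which is
  why the package reports *all* fragments from the digest and applies
  visibility filtering only in the gel model.
* `tolerance` (default **0.10**, relative to the larger band): gel size
  estimates are approximate; published band sizes are rounded to the
  nearest 5-10 bp and primer tails shift apparent sizes of terminal
  fragments. No canonical matching tolerance exists for gel work, so the
  package fixes one documented default (`defaultBandTolerance()`) and
  threads it through comigration merging, pattern matching and
  assignment. Users with tighter gels can lower it globally.

Pattern construction (`makePattern`) drops invisible fragments, sorts
the rest descending and merges comigrating neighbours — closest relative
pair first, replacing the pair by its round-half-up mean with summed
multiplicity, until no adjacent pair is within tolerance. Merging
closest-first makes the result order-independent and idempotent;
round-half-up avoids the banker's-rounding surprise of `round()` at
`.5`. Multiplicity is retained for reporting but ignored by matching:
band intensity is not reliably readable from a gel.

`patternsMatch` requires equal band counts and all size-ordered pairs
within tolerance. The relation is reflexive and symmetric but *not*
transitive (400 matches 380 matches 360, but 400 does not match 360).
That non-transitivity is why intraspecific variant clustering in
`profileSpecies` is defined greedily in record order — the first record
seeds variant 1, each later record joins the first variant it matches —
rather than by any global clustering whose result would depend on
implementation details. The order dependence is documented and
deterministic.

`patternDistance` pairs bands greedily in descending size order and
returns `1 - 2*matched/(nA + nB)`: 0 exactly on a full match, 1 when
nothing pairs. Assignment scores are `1 - distance`; the default
assignment threshold of **1** demands a full pattern match, which is how
identification on an actual gel is read. The threshold is exposed for
screening applications that can tolerate partial matches.

## Enzyme selection

A species pair is *distinguishable* under an enzyme when no gel-pattern
variant of one species matches any variant of the other. Intraspecific
variants — divergent clades segregating at a recognition site, as
swordfish does for MboI — do **not** disqualify an enzyme, as long as no
variant collides with another species; they are in fact an asset,
resolving below the species level. The report surfaces the variant count
per species so the analyst sees the extra complexity.

Candidate enzymes are ranked by: discriminates all pairs; then fewer
total intraspecific variants (simpler gels); then a larger smallest
cross-species band-size difference among equal-band-count pattern pairs
(patterns that differ by a near-tolerance step are hard to call on a
gel); then name, for determinism. When no single enzyme suffices, a
greedy set cover over undistinguished species pairs builds an enzyme
set; on small candidate lists the tests verify the greedy answer against
exhaustive search. A pair no enzyme separates yields an explicitly
infeasible solution rather than a silent best effort.

## Barcode quality control

COI is protein-coding on the mitochondrial genome, so a genuine barcode
translates without internal stop codons under the **vertebrate
mitochondrial code** (NCBI table 2: TGA = Trp, AGA/AGG = stop, ATA =
Met). Using the standard code here would be doubly wrong — flagging real
mitochondrial TGA-tryptophans and missing AGA/AGG pseudogene stops.
`checkCoding` translates the three forward frames (barcodes are
amplified from the coding strand with fixed primers; a six-frame switch
exists for arbitrary input), reports the frame with the fewest internal
stops, and passes a record if some frame is stop-free. A stop in the
final codon is a natural terminator, not a premature one. Sequences
below **600 bp** are flagged: nuclear mitochondrial pseudogene (NUMT)
co-amplicons are typically the shorter products.

Best-match identification replaces a database similarity search with a
reproducible local computation: a global alignment with free end gaps
(match +1, mismatch -1, gap -2) against every labelled reference, with
identity counted over the aligned columns (terminal overhangs excluded)
and rounded half-up to two decimals, matching the reporting precision
conventional for barcode surveys. Identities against a local curated
library will not numerically equal what a live database search returns
unless the same reference sequences are supplied; the package's claim is
the *best match*, not the database score. Mislabeling percentages are
always recomputed from counts (round-half-up, one decimal), never
stored.

## The synthetic panel generator

`makePanel` emulates the reference library of a COIBar-RFLP study: a
multi-species panel of barcode-length sequences in which exactly one
candidate enzyme carries a species-specific restriction signal. Defaults
are chosen as realistic study conditions: **5 species** (a typical
substitution panel), **10 records per species** (a typical per-species
reference depth), **680 bp** (a trimmed COI barcode plus primer
remnants) and an intraspecific substitution rate of **0.005 per site**,
at the scale of within-species COI divergence in fishes (< 1%).

Construction proceeds per species: draw a uniform-composition backbone;
*scrub* it of every recognition site of every candidate enzyme
(iteratively mutating one base inside each found site — whole-sequence
rejection sampling would essentially never terminate, since five 4-6 bp
motifs in ~700 bp leave an acceptance probability near 1e-5); then write
a species-specific set of planted-enzyme sites at positions sampled so
all fragments stay visible and the species' gel patterns are pairwise
non-matching under the gel parameters. Planting is verified by
re-scanning (a written site can create a second one at a junction) and
re-drawn on failure, with a bounded attempt budget that turns genuinely
infeasible requests (too many species for too short a sequence) into a
clear error. Within-species copies receive seeded random substitutions,
re-drawn if any mutation would create or destroy any enzyme's site, so
every record digests identically to its species backbone and the truth
object is exact. `makeCladeVariant` separately emulates clade structure
by gaining or losing exactly one site with the fewest possible
substitutions.

What the generator deliberately does not emulate: codon structure,
phylogenetic correlation, ambiguity codes, indels, or length variation
between conspecific records. Passing the planted-truth tests therefore
demonstrates the correctness of the scanning/digestion/selection/
assignment machinery, not the field performance of any particular
enzyme on real barcodes — that is what the shipped observed patterns
and published fragment tables are for.

## Numerical and interface choices

* Caret notation (`^GATC`) is parsed with exactly one cut marker;
  enzyme tables are TSV (`name`, `site`) and the package ships the five
  enzymes classically screened for fish COI RFLP (HpaII, HinfI, MboI,
  RsaI, HindIII — all palindromic).
* In silico PCR allows up to 2 IUPAC-aware mismatches per primer and no
  indels (degenerate fish-barcoding primers tolerate a couple of
  mismatches; indel-tolerant annealing is out of scope); the amplicon
  spans both primer footprints and carries sequencing tails verbatim,
  which is why an undigested tailed product runs ~100 bp above the
  trimmed barcode.
* FASTA labels ride in `species=` / `group=` header tokens so files stay
  readable by any other tool; duplicate record ids are an error because
  profiles and reports key on them; `U` is rejected (DNA consensus
  input). Input sequences are analysed as given — whether deposited
  barcodes retain primer remnants varies by record, and the package does
  not second-guess trimming.
* All randomness is seed-controlled (`makePanel`, `makeCladeVariant`,
  the CLI `simulate` subcommand); identical seeds give byte-identical
  outputs. The test suite exercises the scanner against a brute-force
  IUPAC-expansion oracle on a thousand random sequences, recovers
  planted truths on dozens of seeded panels (5 species x 2 records x
  700 bp), and verifies the greedy enzyme cover against exhaustive
  search on all small cases — problem sizes chosen to exercise every
  code path at desk scale.

## Known limitations

* No partial digestion, methylation sensitivity, star activity or
  circular topologies; bands below `minBand` are invisible rather than
  faint.
* Comigration merging models one gel; migration-curve physics and
  ladder calibration are not modelled, so `tolerance` absorbs all size
  uncertainty.
* Assignment is deterministic pattern matching, not probabilistic; mixed
  (two-species) samples are out of scope.
* The clade-resolution claim for swordfish rests on the two observed
  reference patterns; per-accession clade membership is not encoded.
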