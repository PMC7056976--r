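---
title: "Designing neutral spacers and dual-reporter vector maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing neutral spacers and dual-reporter vector maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlgl)
```

## The design problem

Divergent dual-reporter transgenes place a single enhancer between two
fluorescent reporter genes, each with its own core promoter, so that one
reporter reads out proximal activation and the other reads out activation
across a defined distance. Two sequence-design problems follow. First, the
distance is set by a *spacer*: DNA that must behave as inert filler, which
means it must not carry transcription-factor binding motifs of the system
under study (here Hox-family motifs, active in the fly abdomen where these
reporters are imaged) nor any recognition site of the restriction enzymes
reserved as single cutters for later cloning. Second, once a configuration
transmits regulatory activity to the distal promoter, the sequences
responsible can be mapped by *scanning mutagenesis*: a series of enhancer
mutants, each with one block of base pairs destroyed, compared for
proximal-only versus distal-and-proximal loss of expression. This package
implements both, together with an in silico cloning engine that makes every
assembly step checkable before synthesis.

## Mutation operators

All destructive mutations use the **non-complementary transversion**. A
base has two transversion partners (purine ↔ pyrimidine); one of them is
its Watson–Crick complement, and excluding it forces a unique map
`A→C, C→A, G→T, T→G`. The map is an involution, changes every base it
touches, never creates the complementary strand's base (so it cannot turn
a motif into its reverse-complement), and applied to every other position
it destroys all 2 bp and longer exact repeats between a sequence and its
mutated copy.

`apply_mutation_pattern()` applies it to all, odd, or even 1-based
positions, or to a block. Two phased applications build the tandem spacer:
`build_tandem_spacer()` concatenates an odd-mutated and an even-mutated
copy of the unit. At odd positions copy 1 is mutated and copy 2 is not; at
even positions the reverse; hence the two copies differ at **every**
aligned position and the doubled spacer contains no internal duplicate —
important because perfect repeats in a transgene invite recombination and
mis-annealing during synthesis and PCR.

The source material never states whether "every other bp" starts at
position 1 or 2. We default to odd-first (it matches the odd/even phasing
of the two tandem copies) and expose the phase as the `mode` argument
rather than guessing; both phases satisfy every invariant above.

`scramble_composition()` is a seeded uniform permutation (Fisher–Yates via
R's `sample()`), preserving the base multiset exactly. The seed is an
explicit argument and is recorded in the design provenance, because a
spacer that cannot be regenerated bit-for-bit is not auditable.

`scanning_series()` tiles left to right; a short terminal block is emitted
as its own mutant rather than merged into its neighbour, so every mutant's
interpretation ("exactly this interval was destroyed") stays uniform. The
manifest (mutant id, interval, parent) is the unit of record for wet-lab
follow-up.

## Motif scrubbing

A `forbidden_rule()` couples an IUPAC pattern to a strand policy and an
action. Defaults in `spacer_rules()`:

* `TTTAT` (Abd-B-type motif) — fixed replacement `TTGGG`, the published
  substitution for this motif; applied verbatim, reverse-complemented for
  minus-strand occurrences.
* `YTAATKV` (Hox-like motif, 12 expansions) — minimal substitution.
* Any reserved single-cutter recognition site — minimal substitution.

All rules default to both strands: protein–DNA binding is strand-agnostic,
and every bundled recognition site is palindromic, so a single-strand scan
would be both biologically and chemically wrong. This is a documented
default, not a claim about how the original spacers were scanned — the
source is silent on it — and `strand_policy = "given"` is available.

**The substitute_min policy** (the source says only that motifs were
"mutated" and sites "eliminated by bp substitutions", so the exact policy
is this package's design): fix the left-most match first; within the
matched window, edit the left-most position whose pattern code is
non-degenerate, replacing the base by its non-complementary transversion —
editing a fully-constrained position is what guarantees that *all*
expansions of the degenerate pattern are destroyed at once. If the edit
would create a new match to any active rule, the next candidate position is
tried, then alternative replacement bases in the fixed order transversion
partner, transition, complement. Fixed-replacement rules are applied before
substitute_min rules when matches overlap, honouring the verbatim `TTGGG`
substitution. Every candidate is vetted against the full rule set, so the
match count decreases strictly at each step; an iteration cap of 10× the
sequence length converts any rule conflict (e.g. two fixed replacements
that regenerate each other) into an explicit classed error carrying the
partial report.

Scanning uses a vectorized positional engine (one membership test per
pattern offset over all windows), and after each same-length edit only the
windows overlapping the edited bases are rescanned — an edit cannot create
or destroy a match elsewhere. This keeps the scan-and-fix loop linear in
practice on 10 kb substrates. `verify_clean()` deliberately reuses none of
the scrub bookkeeping, and the test suite re-certifies scrubbed output with
a third, regex-based scanner and with Biostrings' degenerate matcher.

**Coding mode.** `scrub_coding_synonymous()` may only exchange codons for
synonyms under the standard genetic code. Candidate edits are enumerated
over the codons overlapping the site; a candidate qualifies if it strictly
reduces the site count without creating a new occurrence. Tie-break:
minimal Hamming distance (single base preferred), then left-most codon,
then lexicographically smallest codon — deterministic without codon-usage
assumptions the source never states. A site spanning only Met/Trp codons
has no synonymous escape and fails explicitly.

## The cloning engine

Restriction enzymes are bundled as data (recognition, `cut_top`,
`cut_bottom` offsets from the recognition start on the top strand), with
overhang kind derived: top cut before bottom ⇒ 5′ overhang, after ⇒ 3′,
equal ⇒ blunt. The offsets were checked against the public REBASE catalog
and are regression-tested on the known overhangs (EcoRI `AATT`,
BamHI/BglII `GATC`, SbfI `TGCA`, SacII `GC`, StuI blunt).

A fragment's body is the top-strand span between consecutive top-strand
cuts, so bodies partition the substrate (nucleotide conservation with each
overhang counted once is an identity, not an approximation) and
concatenating bodies in original order reproduces the substrate exactly.
End chemistry records the protruding single strand read 5′→3′; two sticky
ends ligate iff they share polarity and their protrusions are reverse
complements, which makes the classic BamHI × BglII compatibility (both
`GATC`) and the EcoRI × BamHI incompatibility fall out of one rule.
`ligate()` rescans a window around every junction and reports which
configured enzymes could re-cut it; the BamHI × BglII scar `GGATCT`, cut by
neither parent, is a fixed regression test because the spacer-excision
construction depends on it.

PCR is modelled without thermodynamics: the 3′-terminal `min_anneal` bases
(default 15 bp, matching the homology-arm length implied by the published
In-Fusion primer names) must match the template exactly, IUPAC-aware, and
multiple binding sites abort rather than choose — a silent wrong amplicon
is worse than a failure. Degenerate primer positions resolve to the
template base inside the annealing footprint; in the unannealed tail there
is no template to copy, so they resolve to the lexicographically smallest
expansion base, a documented arbitrary choice. Homology-arm assembly
(`infusion_assemble()`) requires exact `arm_len` matches at both ends and
produces the seamless circle of length `vector + insert − 2·arm_len`.

Partial digestion, star activity, methylation sensitivity and melting
temperatures are out of scope; every site is always cut, as the cloning
narrative these tools model assumes.

## Vector assembly and verification

`design_config()` declares ordered parts (with orientation and feature
kind), per-junction restriction-site punctuation, declared unique cutters
and the forbidden-rule set. `assemble_reporter_vector()` concatenates parts
(minus-strand parts stored reverse-complemented so annotations read 5′→3′)
and punctuation into a circular `construct_map`, then runs four checks,
reported rather than raised: unique cutters cut exactly once (with all
positions listed on failure); spacer parts pass `verify_clean`; CDSs start
with ATG and translate without internal stops; and each CDS has a promoter
upstream in its orientation within the nearer half of the circle — the
divergent-architecture check. The canonical layout (distal cassette
reading away from the enhancer on the minus strand, proximal cassette
toward its polyA on the plus strand) is realized by the configuration, not
hard-coded, since the cloning narrative defines steps rather than a final
linear map. Inter-part filler beyond the punctuation sites defaults to
empty: we do not invent sequence that only the deposited vector files could
supply.

`example_dual_reporter_config()` builds a fully synthetic instance
(600 bp backbone, 300/720/250 bp distal cassette, 2 kb designed spacer,
690 bp enhancer, 250/720/300 bp proximal cassette, eleven unique cutters in
the punctuation pattern of the published series). Part sequences are
scrubbed individually, but a recognition site can still arise by chance
*across* a part/site boundary on the assembled map; the builder therefore
assembles, locates any cutter occurrence that is not an annotated
punctuation site, and repairs it by a transversion at an occurrence base
lying inside a non-CDS part — written back into the part so the
configuration and the map remain two routes to the same sequence. The
sequences are synthetic stand-ins throughout, not the deposited vectors.

`reconcile_cassettes()` checks assembled cassette lengths against the
printed values for the synthesized cassettes (1,296 bp EcoRI–AscI,
2,014 bp AscI–AgeI, 3,103 bp StuI–AgeI) when the deposited sequence file is
supplied; without it the checks report as not-run (`NA`), never as passes.
Whether the printed lengths include the flanking sites is resolvable only
by inspecting the deposited records, so no assumption is baked in.

**Spacer recipes by size class.** 1–2 kb: tandem duplication of a unit of
half the target length, then scrub. The published 1 kb spacer was obtained
by PCR from the 2 kb spacer — an interior slice — which we model as the
tandem recipe on a half-length unit; the slice boundaries are not printed,
so the 5′ end of the source is used. 4–8 kb: seeded composition scramble,
odd-position transversion, then scrub of motifs and all reserved
single-cutter sites, in that order.

## The fixture generator

`generate_fixture()` emulates what the design operators consume: random
background DNA of a chosen GC fraction, planted IUPAC motif instances and
restriction sites (concretized per position, either strand,
non-overlapping), and in-frame ORF segments. It is deterministic per spec
seed, returns a manifest of every plant, and audits chance background
occurrences of the planted patterns so plant-then-scrub tests account for
every match, not just the planted ones. It does **not** emulate real
genomic sequence: no repeat structure, no composition heterogeneity, no
chromatin or assay biology. Passing plant-then-scrub tests therefore
demonstrates that the operators meet their sequence-level contracts on
worst-case-free random DNA — they say nothing about whether a scrubbed
spacer is biologically inert, which only the reporter assay itself can
show.

## Problem sizes and numerical choices

The property suites run at fixed sizes chosen to exercise the contracts
densely while staying fast on one CPU: 10,000 random sequences (5–40 bp)
across the four mutagenesis invariants; 200 fixtures of 10 kb with 10 + 10
planted motifs and 4 planted sites each for plant-then-scrub certification,
plus 25 random ORFs for codon-conservation; 500 random circular plasmids
for digestion/ligation round-trips; three full example assemblies for the
fixed-point and two-route-swap properties. All random draws sit under fixed
seeds; the acceptance script derives every draw from its `--seed`
argument. Internally coordinates are 1-based inclusive throughout — R's
native convention — so the externally promised 1-based inclusive interface
involves no conversion at all; GenBank output uses `join(n..N,1..k)` for
origin-spanning features on circular maps.

## Known limitations

* Motif handling is exact-match IUPAC only: no position-weight matrices,
  no binding thermodynamics, no motif discovery.
* The scrubber edits greedily left-to-right; it certifies zero residual but
  does not minimize the global number of edits.
* PCR and assembly are sequence-logical models; primer design (Tm,
  secondary structure) is out of scope.
* The enzyme table covers the 13 enzymes used by this vector family;
  extending it is a data edit, but no general REBASE import is provided.
* Reconciliation against the deposited vector sequences runs only when
  those sequences are supplied by the user.
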