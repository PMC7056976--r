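# rlgl: design and in silico cloning of dual-reporter enhancer constructs

`rlgl` implements the sequence-design computations behind divergent
dual-reporter ("red light/green light") transgene assays, in which one
enhancer sits between two fluorescent reporter genes and a designed spacer
sets the enhancer–promoter distance. The package is aimed at people building
such vectors (or any construct that needs regulatory-neutral filler DNA):
it generates the spacers, certifies them free of unwanted regulatory and
cloning sequence, produces scanning-mutant enhancer series for mapping
remote-control elements, and simulates every cloning step so the final
annotated plasmid map can be verified before anything is synthesized.

## What it computes

**Neutral spacer generation.** The elementary operator is the
*non-complementary transversion*: each base has two purine↔pyrimidine
partners, one of which is its Watson–Crick complement, so excluding the
complement forces the involution

    A → C,  C → A,  G → T,  T → G.

Spacers are derived from natural source DNA either by tandem duplication
(copy 1 mutated at odd, copy 2 at even base pairs — the copies then differ
at 100% of aligned positions, leaving no perfect repeat) or, for the larger
size classes, by composition scrambling followed by odd-position
transversion.

**Motif scrubbing.** Spacers must contain no Hox-like binding motifs
(IUPAC `YTAATKV`, and `TTTAT`, which is replaced by the fixed text `TTGGG`)
and no recognition sites of enzymes reserved as single cutters in the
vector. `scrub_noncoding()` iterates scan-and-fix on both strands to a
certified zero-residual state and returns an auditable edit report;
`scrub_coding_synonymous()` removes sites from reporter CDSs using only
synonymous codon changes (preferring a single substitution), conserving the
protein exactly. `verify_clean()` re-certifies independently.

**Scanning mutagenesis.** `scanning_series()` tiles an enhancer with
non-overlapping blocks and emits one mutant per block, each differing from
the parent at exactly its block — the design used to localize remote-control
elements by comparing proximal and distal reporter readouts.

**In silico cloning.** `digest()` (13 bundled enzymes with catalog cut
offsets and 5′/3′/blunt overhang chemistry), `ligate()` (overhang
compatibility, junction scars re-scanned for regenerated sites — e.g. a
BamHI end joined to a BglII end leaves `GGATCT`, cut by neither),
`simulate_pcr()` (tailed and IUPAC-degenerate primers, exact-match 3′
annealing), and `infusion_assemble()` (15 bp homology-arm seamless
assembly). `assemble_reporter_vector()` composes parts and restriction-site
punctuation into an annotated circular map and `verify_design()` checks
unique cutters, spacer cleanliness, reporter ORFs, and the divergent
promoter architecture.

## Worked example

```r
library(rlgl)
set.seed(42)
src <- nuc_seq(paste(sample(c("A","C","G","T"), 1000, replace = TRUE),
                     collapse = ""), id = "intron_source")
rules <- spacer_rules(c("NheI", "SbfI", "SpeI", "SacII", "AgeI"))
sp <- design_spacer(src, 2, rules, seed = 42)
sp$report
```

```
<scrub_report> 10 edits, 10 iterations, converged (zero residual)
 position  from    to     rule
      562 TTTAT TTGGG     AbdB
      814 TTTAT TTGGG     AbdB
      944 TTTAT TTGGG     AbdB
     1276 TTTAT TTGGG     AbdB
     1921 TTTAT TTGGG     AbdB
      133     T     G Hox-like
      855     A     C Hox-like
     1145     A     C Hox-like
     1453     T     G Hox-like
     1836     A     C Hox-like
```

The 1 kb source was tandem-duplicated to 2,000 bp; five chance `TTTAT`
motifs were replaced by `TTGGG` and five chance Hox-like matches were
destroyed by single transversions; `verify_clean(sp$seq, rules)$clean`
returns `TRUE` — no forbidden motif or reserved site remains on either
strand.

```r
cfg <- example_dual_reporter_config(seed = 42)
rep <- assemble_reporter_vector(cfg)
rep$map
```

```
<construct_map> pDualDemo [circular, 5902 bp] 20 features
             label      kind start  end strand
          backbone      misc     1  600      +
             EcoRI      site   601  606      +
      polyA_distal UTR_polyA   607  906      -
              FseI      site   907  914      +
   reporter_distal       CDS   915 1634      -
              ...
```

`rep$checks` reports 16/16 design checks passing: each of the 11 declared
enzymes cuts the 5,902 bp map exactly once, the 2 kb spacer is clean, both
reporter ORFs translate without internal stops, and each CDS has its
promoter upstream in its annotated orientation. `write_genbank()` emits the
annotated map as a GenBank flat file.

A thin command-line wrapper (`inst/cli/rlgl.R`) exposes the same operations
(`mutate`, `spacer`, `scan`, `scrub`, `digest`, `pcr`, `fixture`) over
FASTA/JSON files; see `?rlgl_cli`.

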