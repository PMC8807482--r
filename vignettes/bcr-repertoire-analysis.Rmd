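---
title: "Methods: simulated BCR repertoires, germline annotation, and overlap statistics"
author: "bcrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated BCR repertoires, germline annotation, and overlap statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`bcrpipe` re-implements, as a tested and reusable pipeline, a heavy-chain
B-cell receptor (BCR) repertoire analysis of the kind used to compare
antigen-specific IgG subclass repertoires between an RNA-adjuvanted and an
adjuvant-free vaccination arm at two time points: clonotyping under two
definitions, read-normalized diversity, IGHV gene usage, somatic-mutation
profiling, cross-sample CDR3 sharing (percentages, Jaccard indexes, 3-set
Venn partitions), consensus of widely shared CDR3s, and a repertoire
similarity tree. The pipeline is driven either by AIRR Rearrangement TSV
files supplied by the user (including clonotype-level exports in a
MiXCR-style dialect) or by the bundled cohort simulator, which also emits a
per-read ground-truth table so that every downstream stage can be tested
against known answers.

This vignette explains the models and the numerical choices. It states no
empirical result beyond what the package's tests and `scripts/acceptance.R`
themselves compute.

# The germline mini-reference

All annotation is relative to a small murine-style IGH germline reference:
8 V segments (including IGHV1-7, so that a biased, IGHV1-7-dominant usage
profile can be expressed), 4 D and 4 J segments, with IMGT-style
`gene*allele` names. Each V segment records the 0-based position of the
first base of the conserved Cys-104 codon and each J segment the position of
the conserved Trp/Phe-118 codon; these two anchors delimit the CDR3
(anchors included) everywhere in the package. All coordinates are 0-based
and half-open.

The packaged reference under `inst/extdata/germline_synthetic/` is a
**synthetic stand-in**, not curated germline sequence: segment sequences are
simulated with the correct anchor structure, sense-codon junction-proximal
regions, and a shared FR4 stem. Two consequences of this design are worth
stating. First, the four J segments differ only in their 12-nt CDR3-proximal
prefix, so the prefixes are drawn such that every suffix of length at least
4 is at least half-mismatched between any two J segments — J identity
remains decidable from whatever prefix remnant junctional trimming leaves
behind. Second, all V segments share their last 15 nt (the FR3 tail and
anchor), which mirrors the high mutual similarity of real V-gene 3' ends.
Loading a reference validates every anchor (V anchors must translate to C,
J anchors to W or F) and rejects duplicate names.

# The cohort simulator

## What it emulates

The simulator emulates the study design the analysis is meant for: 2 groups
(`rna_loaded`, `rna_free`) x 2 time points (`d10`, `d17`) x `n_samples` mice,
each sample sequenced in 3 IgG subclasses (IgG1, IgG2b, IgG2c). One AIRR row
is one read (`duplicate_count` = 1), so "read counts" in the diversity
denominator are unambiguous.

A clone is one productive V(D)J rearrangement: V, D and J are drawn (V with
a configurable usage bias, defaulting to weight 0.6 on IGHV1-7*01 and the
rest split evenly), exonuclease trimming lengths follow bounded geometric
laws, and untemplated N1/N2 insertions are uniform random nucleotides.
Junctions are resampled until productive (CDR3 length divisible by 3,
starting with C, ending with W or F, stop-free); trimming bounds never
remove the anchor codons. Default junctional tuning gives a modal CDR3
length near 10 amino acids.

Somatic hypermutation is a uniform substitution-only process applied **once
per clonal lineage**: each position mutates independently with the time
point's per-base rate (defaults: 0.006 at d10, 0.015 at d17), and every read
of the clone inherits the lineage's mutations, reads being amplicon copies
of cells from that lineage. The alternative — independent mutations per
read — would make nearly every read a unique full-length sequence, at which
point the full-VDJ-nucleotide clonotype definition degenerates to one
clonotype per read and carries no information; lineage-level mutation is
both the more faithful reading of clonal expansion and the one under which
both clonotype definitions are meaningful. Lineage-*tree*-structured
mutation (subclones accumulating mutations along a phylogeny) is
deliberately out of scope.

## Read depth and isotypes

Each IgG subclass of a sample is amplified with subclass-specific primers
and sequenced as its own library, so read depth is a property of the
library, not of isotype abundance. The simulator therefore splits each
sample's exact read budget (`reads_per_sample`, default 2500) evenly over
the subclass libraries present in the sample, and expresses isotype
abundance where it biologically lives: in the number of clones assigned to
each isotype (isotype is drawn per clone from the group's isotype
proportions). Within a library, clone read counts are multinomial with
probabilities proportional to `rank^-zipf_exponent` — a heavy-tailed
clone-size law, the minimal structure that makes clonotype counts differ
from read counts. Emitted rows per sample always total `reads_per_sample`
exactly, and identical configuration and seed reproduce byte-identical
files.

Group defaults express the designed contrast, not measured quantities: the
`rna_loaded` arm has more clones per sample (800 vs 300), a flatter
clone-size law (Zipf exponent 1.1 vs 1.9) and IgG2b/IgG2c-dominant isotype
proportions (0.25/0.40/0.35 vs 0.60/0.30/0.10 for IgG1/IgG2b/IgG2c).

## Public clonotypes

Each group carries `n_public` fixed public CDR3 amino-acid strings (defaults
48 and 12; lengths drawn with mode 10 aa), embedded into a germline V/J
context: the V anchor codon and the last two J codons before the anchor are
germline-encoded (convergent junctions retain J-encoded ends, and this keeps
the J call decidable), the middle is reverse-translated with a fixed codon
table. Every sample of the group receives every public clone in its IgG2b
and IgG2c libraries, and in IgG1 with probability 0.3 — public clonotypes
are thereby correlated between IgG2b and IgG2c, which is what makes those
two subclasses measurably more related to each other than to IgG1 in the
comparison stage. Public clones keep their junction unmutated (hypermutation
is confined to the V framework for them): a mutated junction would by
definition be a different clonotype, which would defeat the purpose of a
spiked *public* clonotype. Each public entry receives a small fixed read
allowance (default 3 reads) taken out of the library budget, so spike-in
recovery is deterministic and the read budget stays exact.

## What the simulator does not capture

No sequencing error model, no paired-end structure or quality values, no
indels (neither junctional P-nucleotide modelling nor SHM indels), no
hotspot bias in mutation, no light chains, no lineage trees. Passing tests
on simulated data therefore demonstrate correctness of the statistics and
the recovery of designed structure under a clean substitution-only model —
they do not demonstrate robustness to sequencing artifacts or allelic
variation in real data.

# The annotator

Reads are aligned to every V and every J segment with a banded local
aligner (Gotoh affine-gap scoring: match +2, mismatch -2, gap open -6, gap
extend -1; a gap of length L costs 6 + L). The band (half-width 12
diagonals) is centred on the diagonal with the most shared 11-mers between
read and segment; if no k-mer is shared the full dynamic-programming matrix
is used, so short or dissimilar pairs are scored exactly. In the batch path,
a segment sharing no k-mer with the read is skipped entirely when an upper
bound on its achievable score — every k aligned columns must contain a
mismatch if no k-mer is shared — cannot beat the best seeded candidate;
this prunes most wrong-segment alignments without affecting the best call.
Ties between equal-scoring segments break to the longer aligned span, then
to the lexicographically smaller name, making annotation fully
deterministic and order-independent.

The CDR3 is extracted from the read base mapped to the V anchor through the
end of the codon mapped to the J anchor (anchors included); the junction is
then checked for productivity (length divisible by 3, C...W/F, stop-free).
V-region mutations are counted as substitution columns of the V alignment
**up to the end of the anchor codon**: junction columns beyond the anchor
belong to the CDR3, not the V count. Without this cut, optimal local
alignments that opportunistically extend a few columns into the junction
would contribute phantom "mutations". For the same reason, the
pass/fail indel rule is evaluated only within the segment windows that
matter (V: up to the anchor codon end; J: anchor onward): gap columns from
junction-side extension are alignment artifacts, not segment indels.

Failures are never errors: reads get `pass_filter = FALSE` with a reason
code (`no_v`, `no_j`, `anchor_unmapped`, `unproductive_cdr3`, `short_read`
for reads under 30 nt, `indel`).

Two statistical facts about local alignment matter for testing. A local
alignment under this scheme cannot end on a mismatch, nor on a
mismatch-then-single-match tail, so roughly the two terminal columns at
each alignment end are substitution-free by construction; the binomial
expectation for the mutation count in the counted V window is therefore
`rate x (window length - 2)` (only the left end of the window is an
alignment end; the right end is the anchor cut). Tests compare the measured
mean against this expectation within 3 standard errors, collapsing to one
read per clonal lineage first because lineage mutations are shared draws.

# Clonotyping and per-repertoire statistics

Two clonotype definitions are supported, matching the two axes the analysis
needs: `cdr3_aa` (key = CDR3 amino-acid sequence) and `vdj_nt` (key = full
VDJ nucleotide string over the aligned V-start..J-end span). Records
failing the filter are excluded and counted in a drop tally; conservation
(counts + drops = input rows) is asserted in the pipeline manifest.

*Diversity* is the repertoire's unique-clonotype count divided by its read
count — a richness-per-sequencing-depth ratio in (0, 1], taken literally as
the analysis' diversity statistic rather than an entropy-based index. It is
depth-sensitive by construction, which is exactly why the simulator
equalizes library depth rather than letting rare isotypes produce tiny,
ratio-inflated libraries.

*V usage* is computed over clonotypes, not reads, so clonal expansion does
not inflate the apparent usage of expanded clones' V genes (a read-weighted
variant is available via a flag). *Mutation summaries* (per V family and
overall) likewise collapse reads to clonotypes first and average the
per-clonotype means; a read-level variant is available. IgG2b+2c pooling is
plain concatenation of passing records before summarizing.

# Cross-repertoire comparison

The sharing universe is the union of unique CDR3 amino-acid sequences over
the compared repertoires, and all "shared by at least k" percentages are
fractions of this union; a per-repertoire variant (each repertoire's own
fraction of shared clonotypes) is reported alongside. The headline
threshold is occupancy >= 2 and the "top shared" threshold is occupancy
>= 7; both are parameters, because phrasings like "over 2 samples" and "at
least 2 repertoires" genuinely conflict and real data may disambiguate
them.

The Jaccard index |A∩B| / |A∪B| on CDR3 sets (0 when both sets are empty)
is the pairwise overlap measure; 1 - J is used as the repertoire distance
(Bray-Curtis on clonotype frequencies is available as an option that
preserves abundance information). Venn partitions of three isotype
repertoires report the 7 exclusive regions plus the three pairwise
intersections regardless of the third set.

Consensus of shared CDR3s is computed per position as the plurality residue
(ties break to the lexicographically smallest residue, making the output
deterministic), with conservation = plurality count / n. Because CDR3s of
different lengths are not aligned (gapped multiple alignment is out of
scope), consensus is restricted to a single length stratum; the modal
length stratum of the top-shared set is the one analyzed.

The repertoire tree is UPGMA (average-linkage agglomeration, delegated to
`stats::hclust(method = "average")` and verified in tests against an
independent naive agglomeration oracle) on the chosen distance matrix,
giving a deterministic ultrametric dendrogram serialized as Newick with
leaf depth equal to half the merge height. No algorithm is claimed beyond
that: the tree is a display of repertoire similarity, not a phylogeny.

# Pipeline, reproducibility, and the command line

`run_pipeline()` executes simulate (optional) → annotate → profile →
compare, writes every artifact under one output directory, and finishes
with a manifest containing the configuration echo, per-stage row counts
with drop tallies (asserted to reconcile), and MD5 checksums of all
tabular/JSON outputs. Identical configuration and seed reproduce identical
checksums. A failing stage leaves partial outputs and a `FAILED` marker
naming the stage. Figures (diversity bars, V-usage boxes, the tree) are
presentation-only, derived strictly from the computed objects, and excluded
from the checksum ledger.

A thin CLI at `inst/cli/bcrpipe` exposes `simulate`, `annotate`, `profile`,
`compare`, `run` and `import` as subcommands over the package functions;
cohort configurations can be given as YAML or JSON. `import` reads either
AIRR rows or MiXCR-style clone tables (`cloneCount`, `aaSeqCDR3`,
`allVHitsWithScore`; first V hit, score stripped) into the same clonotype
containers.

# Problem sizes used in tests

The test suite and the acceptance script exercise the default study design
at desk scale, as the package's own choice of problem size: 20 simulated
cohorts (one per seed) of 2 groups x 2 time points x 2 mice x 2500 reads
(2 x 10^4 reads per cohort), plus 10,000-clone draws for usage-bias
recovery and 10,000-replicate draws for the mutation-model oracle. Aligner
oracle equivalence uses 200 random pairs of length 20-60 against a
full-matrix reference implementation; Venn and UPGMA oracles use random
triples and random 6x6 matrices.

# Known limitations

The diversity ratio remains depth-sensitive across *datasets* even though
the simulator equalizes depth within a cohort; comparing repertoires
sequenced at very different depths requires rarefaction, which is out of
scope. The annotator does not attempt allele-level calling, paired-end
assembly, or quality-guided correction, and D-segment calls are
informational only (copied from input when present). Clonotype-level
concordance with MiXCR on real raw reads is not promised; the annotator is
a simplified, deterministic stand-in whose behaviour is fully specified
above.
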