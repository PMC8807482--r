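# bcrpipe

Heavy-chain B-cell receptor (BCR) repertoire analysis in R, built around the
AIRR Rearrangement TSV format. The package is aimed at immunologists and
bioinformaticians who want to compare antigen-specific IgG subclass
repertoires across cohorts and time points — for example an RNA-adjuvanted
versus an adjuvant-free vaccination arm — and at method developers who need
a fully ground-truthed synthetic repertoire to test such analyses against.

It provides, as one tested pipeline:

* a **cohort simulator**: productive V(D)J rearrangements over a packaged
  (synthetic) murine-style IGH mini-reference, bounded-geometric junctional
  trimming and N insertions, Zipf-distributed clone sizes, per-lineage
  somatic hypermutation, isotype-specific subclass libraries, biased IGHV
  usage, spiked public CDR3 clonotypes, and a per-read truth table;
* a **germline annotator**: banded Smith–Waterman (Gotoh affine gaps,
  match +2 / mismatch −2 / gap open −6 / gap extend −1) V and J assignment
  with deterministic tie-breaking, CDR3 extraction between the conserved
  Cys-104 and Trp/Phe-118 anchor codons, and V-region substitution counts;
* **clonotyping and per-repertoire statistics** under two clonotype
  definitions (CDR3 amino-acid sequence, or full VDJ nucleotide sequence):

  normalized diversity `D = n_clonotypes / n_reads`, V-gene usage over
  clonotypes, and mutation summaries per IGHV family;
* **cross-repertoire comparison**: sharing spectra over the CDR3 union
  (fraction with occupancy ≥ k), Jaccard indexes `J = |A∩B| / |A∪B|`,
  3-set Venn partitions, plurality consensus of widely shared CDR3s, and a
  UPGMA repertoire-similarity tree on 1 − J (Newick output);
* a **reproducible pipeline driver** (`run_pipeline()`) with manifest,
  row-count conservation checks and output checksums, plus a thin CLI
  (`inst/cli/bcrpipe`) and an importer for AIRR or MiXCR-style clonotype
  exports.

## Worked example

Simulate the default two-arm cohort (2 groups × 2 time points × 2 mice ×
2500 reads, three IgG subclass libraries per sample), annotate one
repertoire, and profile it:

```r
library(bcrpipe)

ref <- load_default_germline()
ref
#> <germline_reference> bcrpipe-synthetic-mini-1
#>   V: 8  D: 4  J: 4

sim   <- simulate_cohort(cohort_config(seed = 42), ref, "demo")
sheet <- sim$sample_sheet

reads <- read_airr(file.path("demo/airr", sheet$file[1]))
ann   <- annotate_sequences(reads$sequence, ref)
tab   <- build_clonotypes(ann, "cdr3_aa", sheet$repertoire_id[1])
tab
#> <clonotype_table> rna_loaded_d10_m1_IgG1 [cdr3_aa]: 133 clonotypes / 832 reads (2 dropped)

normalized_diversity(tab)        # unique clonotypes per read: 133/832
#> [1] 0.16
head(v_usage(tab), 3)            # fraction of clonotypes per V gene
#>  IGHV1-7 IGHV1-82  IGHV2-9
#>    0.579    0.083    0.083
mutation_summary(ann)$mean_mutations   # mean V substitutions per clonotype
#> [1] 1.59
```

The diversity of 0.16 means 16 unique CDR3 clonotypes were observed per 100
reads of this IgG1 library; IGHV1-7 carries ~58% of clonotypes, reflecting
the simulator's usage bias (0.6). Cross-repertoire sharing over the twelve
RNA-arm repertoires recovers the 48 spiked public clonotypes exactly, and
the consensus of their modal 10-residue stratum shows the anchor-position
conservation pattern (C…W fixed, junction middle variable):

```r
sets <- lapply(...)  # CDR3 key sets of the 12 rna_loaded repertoires
sp <- sharing_spectrum(sets, top_threshold = 8L)
sp
#> <sharing_report> 12 repertoires, universe 1584
#>   shared by >= 2: 5.0%; top shared (occupancy >= 8): 48

consensus_profile(modal_length_stratum(sp$top_shared))
#> <consensus_profile> n = 22 length 10
#>   CFLADKESIW
#>   conservation: 1.00 0.14 0.23 0.18 0.14 0.18 0.18 0.41 0.41 1.00
```

`run_pipeline(run_config(out_dir = "out", seed = 1))` runs all of the above
end to end and writes AIRR files, clonotype tables, JSON profiles, the
comparison report, the Newick tree and a checksummed manifest under `out/`.

The same steps are available from a shell via the CLI:

```sh
Rscript inst/cli/bcrpipe run --out out --seed 1
Rscript inst/cli/bcrpipe import --in mixcr_exports/ --dialect mixcr_export_tsv --out tables/
```

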