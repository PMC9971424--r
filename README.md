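# codonica

Codon usage bias of single-exon vs multiple-exon genes, decomposed by
internal correspondence analysis.

## What it does, and for whom

Intronless (single-exon) genes are a distinctive minority in plant
genomes, and in compositionally heterogeneous genomes their synonymous
codon usage can differ systematically from that of multiple-exon genes.
`codonica` is for molecular-evolution researchers who want to quantify
that difference and attribute it to mutational bias versus selection. It
covers the whole chain:

* **Gene catalog** — read genome FASTA + GFF3, pick the longest-CDS
  isoform per gene, apply six documented exclusion filters (internal
  stops, abnormal start/stop, ncRNA, short CDS, single-exon isoforms of
  multi-exon genes, unanchored scaffolds), classify survivors as SEG
  (1 exon) or MEG (≥ 2), extract spliced strand-corrected CDS, 200-bp
  noncoding flanks, and per-region chromosome summaries.
* **Codon usage indices** — Wright's effective number of codons (ENC),
  Sharp & Li's codon adaptation index (CAI), RSCU, Peden's A3s/T3s/C3s/G3s,
  GC1/GC2/GC3/GC3s/GC12 and flank GC, per gene.
* **Internal correspondence analysis** — the genes × codons table, with
  rows partitioned by gene class and columns by amino acid, has its total
  chi-square inertia split exactly into four parts:

  | | between amino acids | within amino acids (synonymous) |
  |---|---|---|
  | **between gene classes** | amino-acid usage difference | **the quantity of interest** |
  | **within gene classes** | amino-acid usage variation | synonymous variation |

  plus nine elementary analyses with eigenvalue spectra. The key output is
  the *between-class synonymous percentage* — how much of all codon usage
  variability is explained by synonymous differences between gene classes.
* **Significance** — size-matched subsampling of the larger class and
  label permutation, each re-running the decomposition per replicate,
  seeded and reproducible.
* **Diagnostics** — ENC plot against the mutation-only expectation
  `ENC_exp = 2 + GC3s + 29/(GC3s² + (1−GC3s)²)`, neutrality plot (GC12 on
  GC3) with slope comparison between classes, GC3/expression banding with
  matched group sizes.
* **Ka/Ks** — Nei–Gojobori (1986) with Jukes–Cantor correction on
  codon-aligned ortholog pairs.
* **Synthetic genomes** — a seeded generator producing FASTA/GFF3/truth
  tables with two gene classes whose synonymous preferences diverge by a
  controllable δ while amino-acid usage stays identical, heterogeneous
  GC3, exon/intron structure, expression values and ortholog alignments
  evolved at known ω — so the entire pipeline is testable end to end with
  no downloads.

## Worked example

```r
library(codonica)

cfg <- synthetic_config(seed = 42, n_seg = 150L, n_meg = 540L)
sim <- simulate_catalog(cfg, "example-genome")
catalog <- load_catalog(sim$fasta, sim$gff3)
catalog
#> gene_catalog: 690 genes on 2 chromosomes
#>   SEG: 150  MEG: 540  excluded: 0

profiles <- composition_profiles(catalog)
aggregate(cbind(enc, cai, gc3) ~ label, profiles, mean)
#>   label      enc       cai       gc3
#> 1   MEG 55.79499 0.6679457 0.5591048
#> 2   SEG 41.18902 0.7114590 0.5678789

tab <- build_table(attr(profiles, "counts"), profiles$label)
ica_decompose(tab)
#> Internal correspondence analysis (690 genes x 59 codons; classes: MEG, SEG)
#>   total inertia: 0.293835
#>   between-class x between-block:   0.03%
#>   between-class x within-block :   3.05%  (synonymous, between classes)
#>   within-class  x between-block:  28.29%
#>   within-class  x within-block :  68.62%
#>   margins: between-class 3.08% / within-class 96.92%; between-block 28.33% / within-block 71.67%

label_permutation(tab, n_iter = 199, seed = 42)
#> label_permutation: observed 3.0493%, null 0.1009% +/- 0.0837% (n_iter = 199, seed = 42)
#>   empirical p = 0.005
```

Reading the numbers: the generated SEG class is far more biased (mean ENC
41.2 vs 55.8 — smaller is more biased) and synonymous differences between
the two classes account for 3.05% of total codon usage variability, while
amino-acid usage differences between classes are negligible (0.03%) — the
generator diverges only synonymous preferences. The label permutation
shows the 3.05% is ~30× its chance level here (with the full-size default
configuration the separation exceeds 100×), with the smallest empirical
p-value attainable at 199 permutations.

`run_pipeline()` chains all stages (classification → profiles → three
decompositions: by gene type, GC3 band and expression band → diagnostics →
resampling) and writes a TSV/JSON report bundle; a thin command-line
wrapper lives at `inst/scripts/codonica.R`.

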