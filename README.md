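# famscan

Genome-wide characterization of a plant gene family, as one tested,
reusable R pipeline. famscan is aimed at anyone mining a genome for a
receptor-kinase family — the motivating case is the lectin receptor-like
kinases (LecRLKs), membrane proteins combining an extracellular lectin
domain, a transmembrane segment and an intracellular kinase domain — and
carrying the survey through to phylogeny, duplication history, promoter
content and expression behavior.

## What it computes

* **Identification & classification** — a protein is retained iff it has a
  lectin-class domain hit with e-value < 0.001 *and* kinase *and* TM
  evidence; the best lectin hit assigns the subfamily (Lectin_legB → L,
  B_lectin → G, Lectin_C → C), with EGF/PAN/S-locus/signal/TM architecture
  flags.
* **Protein & gene structure** — molecular weight (average masses + one
  water), isoelectric point (Bjellqvist pKa set, bisection on the
  Henderson–Hasselbalch net charge), exon/intron counts, CDS lengths.
* **Phylogeny** — Poisson-corrected distances with pairwise deletion,
  *d* = −ln(1 − *p*); Saitou–Nei neighbor joining; column-bootstrap
  supports; Newick output.
* **Duplications & dating** — duplicate pairs by global protein alignment
  (coverage > 70% of the longer gene, identity > 70%); tandem iff same
  chromosome, gap < 100 kb and ≤ 5 intervening genes; Nei–Gojobori
  Ka/Ks with Jukes–Cantor correction, *d* = −¾ ln(1 − 4*p*/3); divergence
  time *T* = *K*s/(2*r*), *r* = 1.5 × 10⁻⁸ synonymous substitutions per
  site per year.
* **Promoters** — the 1500 bp upstream of the translation start,
  strand-aware, scanned on both strands against a local catalog of IUPAC
  patterns with ubiquitous elements (CAAT-/TATA-/TATC-box) excluded.
* **Expression** — constitutive (FPKM ≥ 1 everywhere) and per-tissue
  high-expression (FPKM ≥ 2) sets, Venn region counts, seeded 3-group
  k-means on mean log₂(FPKM + 1), and qPCR 2^−ΔΔCT fold changes with
  Welch-t up/down/ns calls (p ≤ 0.05).
* **Synthetic truth** — a generator that plants family members, decoys,
  duplicate pairs at controlled Ka/Ks, promoter motifs, three-level
  expression and qPCR fold changes, so the whole pipeline is testable
  offline with known answers.

## Worked example

Generate a small synthetic study with known truth and run the full
pipeline over it:

```r
library(famscan)

cfg <- synth_config(seed = 42, n_members = c(G = 5, L = 4, C = 1),
                    n_decoys = 4, cds_len_range_bp = c(903L, 1203L),
                    tandem_pairs = 1L, dispersed_pairs = 1L,
                    pair_ks = c(0.30, 0.22), group_sizes = c(2L, 3L, 5L),
                    tissue_specific = c(root = 1L),
                    qpcr_plants = data.frame(slot = 1:2,
                                             condition = c("ABA", "IAA"),
                                             fold = c(88, 1/5)))
b <- write_synth_bundle(cfg, "demo_data")
res <- run_pipeline(run_config(
  proteins_fa = b$paths[["proteins"]], cds_fa = b$paths[["cds"]],
  gff3 = b$paths[["gff3"]], domains_tsv = b$paths[["domains"]],
  genome_fa = b$paths[["genome"]], motif_catalog_tsv = b$paths[["catalog"]],
  fpkm_tsv = b$paths[["fpkm"]], qpcr_csv = b$paths[["qpcr"]],
  boot_reps = 100, seed = 7, out_dir = "demo_out"))
cat(readLines("demo_out/summary.txt"), sep = "\n")
```

```
famscan pipeline summary
========================
members: 10 (L=4 G=5 C=1)
CDS length: 954 (SYN6G00020) - 1203 (SYN1G00020) bp; mean introns 1.60
MW: 35.7 (SYN6G00020.1) - 45.4 (SYN1G00030.1) kDa
duplication events: 2 (1 tandem); T = 10.02, 7.37 MYA
cis-elements: light=3 hormone=4 stress=3 development=2 other=1
expression: 5 constitutive; group means 23.34/6.22/1.16 FPKM
qPCR: 3 up events, 2 down events
```

All 10 planted members were recovered (none of the 4 decoys), the planted
tandem pair came back as tandem with *K*s = 0.3007 against a planted
target of 0.30 — hence *T* = 0.3007/(2 × 1.5 × 10⁻⁸) ≈ 10.02 million
years — and the dispersed cross-chromosome pair at *K*s = 0.2211 (target
0.22). The per-stage tables (`members.tsv`, `duplications.tsv`,
`tree.nwk`, `promoter_hits.tsv`, `expression_groups.tsv`,
`fold_changes.tsv`, …) land in `demo_out/`.

The same run is available from a shell:

```sh
famscan synth --seed 42 --out demo_data
famscan run --data demo_data --out demo_out --seed 7 --boot 1000
```

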