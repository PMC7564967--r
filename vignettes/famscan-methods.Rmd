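---
title: "Methods behind famscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind famscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

famscan characterizes a plant receptor-like-kinase gene family end to end:
it identifies members from domain evidence, classifies them into
subfamilies, computes protein and gene-structure statistics, builds a
bootstrapped neighbor-joining phylogeny, detects and dates duplication
events, scans promoters for cis-regulatory elements, and profiles
expression from FPKM matrices and qPCR Ct tables. This vignette explains
the underlying models, the tunable parameters, and the reasoning behind
the choices that were genuinely open.

## Identification and classification

A lectin receptor-like kinase (LecRLK) is defined by three simultaneous
pieces of domain evidence on one protein: an extracellular lectin domain,
at least one transmembrane (TM) segment and an intracellular kinase
domain. `filter_candidates()` retains a protein iff it has a lectin-class
hit (Lectin\_legB, B\_lectin or Lectin\_C) with e-value strictly below the
cutoff (default 0.001) *and* at least one kinase hit *and* at least one TM
hit. The strictness of the e-value bound is deliberate: the cutoff applies
to the lectin evidence only, because that hit decides family membership
and subfamily, while kinase and TM evidence from structure-confirmation
tools typically arrive with much weaker per-domain scores and need only be
present.

The subfamily (L, G or C) follows the lectin class of the best (lowest
e-value) significant lectin hit. When two different lectin classes tie
exactly, the classifier raises an error instead of guessing: in practice
such proteins were resolved by manual cross-checking of independent domain
databases, and silently picking one class would plant an undetectable
mistake in every downstream table. The kinase vocabulary accepts both the
serine/threonine (Pkinase, PF00069) and tyrosine (Pkinase\_Tyr, PF07714)
profiles, since family kinase domains are routinely annotated with either.

Signal-peptide and TM annotations are consumed as externally produced
tables; famscan never predicts them. The `domtblout` reader takes the
per-domain *independent* E-value column because the filter is a per-domain
test, not a whole-sequence one.

## Protein statistics

Molecular weight is the sum of average (isotope-weighted) residue masses
plus one water (18.0153 Da), reported in kDa; average rather than
monoisotopic masses are used because family-survey tables are quoted on
the average-mass scale. The isoelectric point solves
$\sum_i q_i(\mathrm{pH}) = 0$ for the Henderson–Hasselbalch charges of the
two termini and the D, E, C, Y, H, K, R side chains, by bisection on
$[0, 14]$ to $|q| < 10^{-4}$. The default pKa table is the Bjellqvist set
(the ExPASy convention, with a uniform N-terminal pKa of 7.50); it is
configurable because published pI values routinely differ by 0.1–0.3 pH
units between pKa sets, so pI equality against external predictions is
never asserted — only range plausibility.

## Phylogeny

Protein distances use the Poisson correction with pairwise deletion:
over the columns where neither of the two rows has a gap, with mismatch
proportion $p$, the distance is $d = -\ln(1 - p)$. Pairwise (not
complete) deletion was chosen because family alignments with long
subfamily-specific extracellular regions would otherwise discard most of
the signal.

The tree is built by the Saitou–Nei neighbor-joining algorithm with the
standard Q-criterion, implemented in the package itself (the test suite
cross-checks topologies against an independent NJ implementation and
verifies exact recovery of additive matrices). Negative branch-length
estimates — a well-known artifact of NJ on non-additive matrices — are
clamped to zero with the deficit transferred to the sister branch, the
convention used by the common desktop phylogenetics tools, so total path
lengths are preserved. The output is unrooted with a basal trifurcation;
rooting by outgroups is treated as presentation, not inference.

Bootstrap supports resample alignment columns with replacement (default
1000 replicates, seeded) and score each internal bipartition of the
full-data tree by the percentage of replicate trees containing it.

For convenience the package includes a center-star progressive aligner
(Needleman–Wunsch pairs under BLOSUM62, gap open 10, gap extend 0.5,
merged by "once a gap, always a gap"). It is a deliberately simple
stand-in adequate for the bootstrap and distance machinery; for
publication-grade alignments an externally computed alignment can be
supplied as FASTA anywhere an alignment is accepted.

## Duplication events and dating

A pair of members is a duplicate candidate iff, in a global protein
alignment, (a) the aligned-pair count covers more than 70% of the longer
sequence and (b) more than 70% of aligned residue pairs are identical —
both strict, matching the conventional ">70%" phrasing. "Similarity" is
interpreted as percent identity over aligned residue pairs, since no
operational definition beyond that is standard. A candidate pair is
*tandem* iff both genes share a chromosome, the gap between their nearest
gene boundaries is under 100 kb, and at most five annotated genes (any
strand, any family) lie strictly between them; otherwise it is reported
as *dispersed*, leaving segmental-versus-ectopic attribution to the user.
Gap distance is measured boundary-to-boundary rather than
midpoint-to-midpoint; with gene lengths in the kilobase range and a
100-kb bound, the difference never changes a call but
boundary-to-boundary is the less surprising convention.

Ka and Ks use the Nei–Gojobori (1986) counting method. Per codon, each
position contributes the fraction of its viable single-nucleotide changes
(changes creating stop codons are disregarded) that are synonymous, so
every codon carries exactly 3 sites split between synonymous (S) and
nonsynonymous (N). Differences between aligned codons are averaged over
all minimal mutational pathways, excluding pathways that pass through a
stop codon (all pathways are used if none survive, which for sense-codon
pairs is rare). The proportions $p_S = S_d/S$ and $p_N = N_d/N$ are then
corrected with the Jukes–Cantor formula
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which is undefined (reported
as a saturation error, never a number) at $p \ge 0.75$. The codon
alignment is projected from the protein alignment; terminal stop codons
are trimmed, internal stops are a hard error. Divergence time is
$T = K_s / (2r)$ with the dicot nuclear clock $r = 1.5\times10^{-8}$
synonymous substitutions per site per year by default, overridable.

## Promoters

The promoter is the 1500 bp immediately 5' of the *translation* start
(the first CDS base), not the transcription start — annotation sets for
non-model genomes rarely carry reliable UTRs, so the translation anchor
is the reproducible choice. Minus-strand promoters are
reverse-complemented so the returned string always reads 5'→3' toward the
gene. Scanning is exact IUPAC matching on both strands at every offset
against a local catalog of named degenerate patterns; this replaces
remote regulatory-element services with something offline, versionable
and testable, at the cost of ignoring their matrix-scored models.
Ubiquitous elements (CAAT-box, TATA-box, TATC-box by default) are
excluded. Because it is genuinely ambiguous whether summaries should
count element *types* or element *instances*, `categorize_elements()`
reports both.

## Expression and qPCR

A gene is *constitutive* iff FPKM ≥ 1 in every tissue, and belongs to a
tissue's high-expression set iff FPKM ≥ 2 there (both inclusive).
Expression-level groups are formed by seeded k-means (k = 3, 100
restarts) on the per-gene mean of $\log_2(\mathrm{FPKM}+1)$, relabeled
1..3 by descending mean FPKM; k-means on the log scale was chosen because
the high/mid/low structure of such families is multiplicative, and the
seeding plus restarts make the partition a deterministic function of
(matrix, seed). Venn membership over 2–5 tissue sets is computed by exact
set algebra, so region counts always sum to the union size.

qPCR fold changes follow the $2^{-\Delta\Delta C_T}$ method:
$\Delta C_T$ = target − reference per replicate, $\Delta\Delta C_T$ =
mean treatment − mean control, with a two-sided Welch t-test on the
replicate $\Delta C_T$ values. Welch rather than pooled-variance is used
because nothing guarantees equal variance across treatments. A gene is
called *up* iff fold change > 1 and p ≤ 0.05, *down* iff fold change < 1
and p ≤ 0.05. On noise-free data the t-test is degenerate (both groups
constant); p is then defined as 0 when the means differ and 1 otherwise,
so planted fold changes are recovered exactly at zero noise.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth
without downloads. Its defaults are the study conditions the package
emulates: 46 family members (23 G-type, 22 L-type, 1 C-type) across 7
chromosomes, CDS lengths 1803–2502 bp, an intron-poor exon-count
distribution (expected mean ≈ 1.5 introns per gene), 25 members without
signal peptides and 8 with more than two TM segments, G-type accessory
architectures of 9 EGF+PAN / 5 PAN-only / 8 EGF-only / 1 neither (the
four counts must sum to 23, so the EGF+PAN group absorbs the rounding),
one tandem duplicate pair (two intervening genes, ~7 kb gap) plus two
cross-chromosome pairs, expression groups of 7/12/27 genes with mean
FPKM 18.01/6.48/1.29 over ten named tissues, five tissue-specific genes,
and hormone/cold qPCR with three replicates, Ct noise sd 0.1, and planted
fold changes including an 88-fold induction and 17-fold and 5-fold
repressions.

Duplicate pairs are planted by site-category resampling rather than a
full Markov chain of codon evolution: the expected proportion
$p_S = \mathrm{invJC}(K_s)$ of synonymous sites receives one synonymous
single-nucleotide change (and likewise nonsynonymous sites), at most one
change per codon and never through a stop codon. This keeps the planted
difference counts analytic — the Nei–Gojobori counter must recover them
*exactly* — at the cost of not modeling multiple hits within a codon. The
planted $K_s$ targets (0.58, 0.46, 0.49 with $K_a/K_s = 0.15$) sit below
the generator's validity bound of $K_s < 0.75$, where single-change
planting still tracks the Jukes–Cantor expectation closely; deeper
divergences would need a true multiple-hit simulator. The default
$\omega = 0.15$ reflects the strong purifying selection typical of
receptor-kinase duplicates and keeps planted pairs above the 70% protein
identity detection threshold.

What the generator does *not* emulate: realistic base composition,
codon-usage bias, intron length distributions, alignment-difficult indel
patterns, UTRs, overlapping genes, or FPKM estimation noise from read
mapping. Tests passing on synthetic data therefore demonstrate the
correctness of the *computations* — filters, counters, estimators,
set algebra — not robustness to the messiness of real annotation and
expression pipelines.

## Numerical choices and degenerate inputs

* NJ cell ties on the Q-criterion are broken by first row-major position,
  making tree construction deterministic for any input order (order
  invariance of the resulting unrooted topology is tested).
* `poisson_distance` and `jukes_cantor` raise errors at saturation
  ($p \ge 1$, $p \ge 0.75$) instead of returning infinities.
* k-means degenerates to a warning and a single group when all genes
  share one expression value, and to a rank assignment when there are no
  more distinct values than groups.
* Bisection for pI runs at most 200 iterations and requires the charge to
  bracket zero at pH 0 and 14, which holds for any sequence because the
  termini always ionize.
* Promoters truncated at chromosome ends are returned shorter with a
  warning, never padded.

## Problem sizes used by the test and acceptance runs

The shipped tests run the full machinery at reduced sizes chosen to keep
the suite quick while preserving every planted structure: 10-member
families on 3 chromosomes for pipeline tests, 500-codon pairs with 20
replicates per divergence level for $K_s$ recovery, 100 bootstrap
replicates (10–25 in the end-to-end runs), and the full 46-member
configuration for the identification, tandem-classification and headline
acceptance checks. `scripts/acceptance.R` regenerates the full-size
synthetic study from scratch at the given seed and recomputes every
reported quantity by running the installed package.

## Known limitations

* The internal center-star aligner is adequate for distance/bootstrap
  machinery but inferior to profile-based MSA tools on divergent
  families; supply an external alignment for publication trees.
* Nei–Gojobori counting underestimates rates at high divergence compared
  with maximum-likelihood codon models; together with the Jukes–Cantor
  saturation bound this limits reliable dating to roughly
  $K_s \lesssim 0.7$.
* Maximum-likelihood phylogenies, collinearity-based segmental
  duplication calling, motif matrix scoring and de-novo motif discovery
  are out of scope.
* The qPCR caller assumes a single stable reference gene; multi-reference
  normalization is not implemented.
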