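---
title: "Gene-neighborhood discovery of Panacea-associated toxin-antitoxin loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-neighborhood discovery of Panacea-associated toxin-antitoxin loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantascan)
```

## The problem

Type II toxin-antitoxin (TA) systems are compact two-gene operons in which a
toxin that inhibits cell growth is neutralized by direct binding of its
cognate antitoxin. Some antitoxin domains are *hyperpromiscuous*: one domain
family, such as Panacea (DUF4065), appears paired in operons with many
unrelated toxin folds. Because the toxins are so diverse, they cannot be
found by sequence similarity to known toxins. What can be exploited instead
is genomic context: wherever the antitoxin domain occurs, a genuinely paired
toxin will sit immediately next to it, in the same orientation, across many
unrelated species.

`pantascan` turns that observation into a reusable pipeline:

1. **Seed scan** — find every protein carrying the seed (antitoxin) domain in
   a corpus of annotated genomes.
2. **Flank clustering** — group the proteins encoded within a window of
   `k` genes around every seed into homologous families across genomes.
3. **Locus calling** — call a putative TA (pTA) locus for every seed gene
   whose immediate neighbor is co-oriented, within 100 nt, and whose
   (partner family, gene order) architecture recurs in at least two species,
   provided the conserved neighborhood does not extend beyond three genes.
4. **Reciprocity filter** — discard partner families whose genome-wide
   homologs are not, in turn, predominantly seed-adjacent (transposases,
   integrases, ATPases and other families that drift next to TA loci).
5. **Annotation** — N-terminal extension extraction, two-pass
   helix-turn-helix (HTH) re-modelling, discovery of novel conserved
   extensions, and hydropathy-based transmembrane (TM) segments on the
   called toxins.
6. **Summary statistics** — copy numbers per taxon, chromosome/plasmid
   localization, gene-order tallies, locus and cluster counts.

A seeded synthetic-pangenome simulator with planted ground truth makes every
stage falsifiable end to end.

## The locus model

All geometry lives on 1-based inclusive coordinates (the GenBank convention;
GFF3 maps directly). The intergenic distance between two genes is
`max(0, later_start - earlier_end - 1)`: overlapping or book-ended genes are
clamped to 0 nt so that the "gap at most `max_gap_nt`" criterion is monotone
in the gap parameter. Neighborhoods are rank windows along a replicon; they
are truncated at replicon ends and never cross contigs, because neighborhood
conservation across a contig break is unknowable from the assembly.

A candidate pair is a seed gene plus an immediately adjacent (rank ± 1)
gene. Co-orientation is required by default: these loci are operonic, and an
operon is co-transcribed by definition; the flag `require_same_strand =
FALSE` relaxes this for exploratory use. Gene order is classified in
transcription direction (`antitoxin_first` when the seed gene is transcribed
before its partner), so the classification is invariant under coordinate
mirroring of a replicon.

Conservation is counted in **species**, not genomes: the species string of
the input metadata is the taxon unit, and two genomes of one species count
once. The unit of conservation is the *architecture* — the pair (partner
cluster, gene order) — rather than mere co-occurrence, so the same partner
family in opposite orientations forms two architectures that each need their
own support.

The three-gene allowance works by an outward chain walk from the pair:
neighbors are chained while they stay co-oriented and within the gap
criterion of the previous gene, and a chained gene counts as *conserved*
when its family co-occurs with the architecture in at least two species. A
contiguous conserved chain longer than three genes rejects the candidate
(`rejected_operon_length`); exactly three genes keeps the pair and records
the third gene as an accessory. This chain-walk operationalization is our
explicit interpretation of the "no longer operons than three genes"
criterion; alternatives (e.g. counting non-contiguous conserved genes) would
behave differently only for baroque neighborhoods that the reference
conditions do not generate.

## Scanning without a profile HMM

The seed scanner is an ungapped position-specific scoring matrix, not a full
profile HMM. Per column, the score of amino acid $a$ is

$$ s_j(a) = \log_2 \frac{(c_j(a) + \tau\, b_a) / (n_j + \tau)}{b_a} $$

with $c_j(a)$ the residue count in column $j$, $n_j$ the non-gap count,
$b_a$ the background frequency (uniform 1/20 by default) and $\tau$ the
pseudocount mass (default 1). Columns with more than 50% gaps are dropped. A
protein's score is the best ungapped placement of the full profile, one hit
per protein, accepted when it reaches the profile's gathering threshold —
by default 60% of the score of the profile's own consensus sequence, a
calibrated stand-in for curated per-family gathering cutoffs, exposed as
`gathering_frac`.

This is deliberate: the synthetic families are generated without indels, so
an ungapped scanner is exact for them, and for real corpora the package
accepts HMMER3 `--domtblout` tables through `parse_domain_table()`, so a
real profile-HMM scan can drive the identical downstream pipeline. The
dual path is the central anti-lock-in decision of the design.

## Flank clustering

Homology between flanking proteins is decided by global (end-to-end)
alignment with BLOSUM62, gap opening 11 and extension 1 (a gap run of length
$L$ costs $11 + L$), computed by a compiled Gotoh three-state aligner with a
fixed traceback preference so results are deterministic. Identity is
counted over aligned columns excluding terminal gaps; coverage is the
fraction of the shorter sequence aligned against a residue. An edge joins
two proteins at identity ≥ 0.3 and coverage ≥ 0.6, and clusters are
single-linkage connected components — mirroring the transitive character of
the iterative profile searches used by flanking-gene clustering tools, at
the cost of a documented chaining risk. Cluster ids are assigned by
descending size with ties broken by the smallest member protein id, which
makes the partition and the labels invariant to input order.

Two prefilters bound the all-vs-all cost: pairs with length ratio below 0.5
are skipped (they cannot reach the coverage threshold in any useful way),
and pairs sharing fewer than 5% of the smaller sequence's distinct 4-mers
are skipped before alignment. The 4-mer prescreen is the same seeding idea
fast homology searches are built on; at the identity levels where edges are
actually decided (≥ 30%) the shared-4-mer fraction is far above 5%, and
`min_kmer_frac = 0` disables it.

## The reciprocity filter

Some families sit next to seed genes in a few genomes purely because they
ride mobile elements or are ubiquitous (transposases, integrases, ATPases
with highly conserved motifs). The filter asks the reciprocal question: *of
this family's best homologs across all proteomes, what fraction is
seed-adjacent?* For each tested cluster the longest member (ties by protein
id) represents it; its `top_n = 20` best-scoring homologs above the
clustering thresholds are collected corpus-wide, and the cluster is flagged
spurious when fewer than `min_context_fraction = 0.5` of them lie within
the gap criterion of a seed gene. A cluster whose only homologs are its own
members is always retained — absence of external evidence cannot convict.
Accessory clusters pass through the same test; a flagged accessory is
detached from its locus while the pair itself survives. Product-keyword
tallies of spurious versus retained clusters are reported as diagnostics
only, because annotation strings are unreliable.

The exact reciprocity criterion used in the original analyses of this kind
is not fully specified in public methods; context-reciprocity with these
two knobs is this package's own operationalization, and both knobs are
exposed.

## Annotation stage

* **Extensions.** Everything before the seed-domain envelope is the
  N-terminal extension, kept at ≥ 40 aa — short enough to retain a typical
  50–60 aa HTH.
* **Two-pass HTH re-modelling.** Extensions are scanned with an initial HTH
  profile built from any HTH seed alignment; the hit regions are realigned
  into a new, sharper profile, and all extensions are rescanned. The rebuild
  recovers borderline family members that a generic initial model misses,
  and the suite asserts it never loses a pass-1 hit.
* **Novel conserved extensions.** Extensions without an HTH hit are
  clustered with the flank machinery; families with ≥ 5 members spanning
  ≥ 2 species are reported — the route by which a novel domain such as PAD1
  surfaces.
* **TM segments.** Kyte–Doolittle sliding-window hydropathy (window 19,
  threshold 1.6 — the standard settings for membrane-spanning helices)
  with merging of overlapping qualifying windows. This is a transparent
  stand-in for dedicated TM topology predictors; external predictions can
  be injected as a table.
* **Conservation profile.** Per alignment column, `1 - H / log2(20)` with
  `H` the Shannon entropy of non-gap residues; columns under 50% occupancy
  score 0. This replaces phylogeny-aware conservation scoring and is
  sufficient for its purpose here: invariant motif columns (a GPV-type
  signature) rank at the top.

## The simulator and what passing tests mean

`sim_config()` defaults define the reference conditions: 10 species × 3
genomes, 30 genes per genome on one chromosome, 5 cognate toxin families
each planted in 4 species (every architecture conservable), operon gaps
uniform on 0–80 nt, background intergenic gaps 150–400 nt (above the gap
criterion, so background adjacencies never chain), per-site substitution
probability 0.05 with **no indels**, toxin-first order for a quarter of
families, accessories in half of each family's species, one decoy family
placed seed-adjacent in 2 genomes of distinct species sharing a family and
at background positions in 18 more, and extension/TM fractions of
0.25/0.15/0.2. Gene order is fixed per family so the conserved-architecture
criterion is well-posed in truth; the accessory is planted on the outer
side of the toxin, never seed-adjacent, so a three-gene operon yields
exactly one true pair. Nucleotide sequences are never generated — gene
length in nt is 3× the aa length — because the pipeline consumes only
coordinates and protein sequences.

Two choices deliberately simplify relative to real data and bound what
green tests demonstrate. First, family evolution is i.i.d. substitution
from a single ancestor: no indels, no tree structure, no compositional
bias. The ungapped scanner and the identity computations are exact in this
regime; on real proteomes the HMMER injection path should be preferred and
clustering thresholds deserve care. Second, decoys are a single family with
a fixed adjacent/background split; real mobile elements are many families
with messier context distributions. Passing the planted-truth suite
therefore shows the machinery implements its stated criteria exactly — not
that those criteria are optimal for any particular real corpus.

For statistical checks of the gene-order fraction the suite scales the
corpus differently (250 families in 2 species each, one genome per
species, ≥ 500 planted loci, accessories/decoys/extensions off), because
order is drawn once per family: the binomial sample size for the recovery
check is the number of families, not the number of loci.

## Numerical and degenerate-input choices

* Intergenic distance clamps at 0; the gap criterion is inclusive at
  exactly 100 nt ("maximum distance of 100" read as ≤ 100).
* Profile consensus ties resolve to the alphabetically first residue;
  cluster and T-number ties resolve to the lexicographically smallest
  protein id; all orderings in outputs are explicit sorts — the pipeline
  contains no randomness.
* Scanning ties between equally scoring windows resolve to the leftmost
  placement.
* Proteins shorter than the profile, empty extension sets, zero pass-1 HTH
  hits, singleton clusters, and empty prediction sets all return empty (or
  identity) results rather than errors; evaluation reports precision as
  `NA` when nothing was predicted.
* Features without a resolvable translation are dropped at load and
  counted, not fatal: real annotations contain pseudogenes.
* Conservation-profile monotonicity holds for adding a copy of the
  per-column majority sequence; adding an arbitrary duplicate can
  legitimately raise column entropy.

## Problem sizes

The reference simulation (30 genomes, ~900 proteins) runs through the full
pipeline in a few seconds on one core; the 500-locus order-statistics
corpus (20 genomes, ~1100 proteins, 250 families) takes on the order of ten
seconds. These sizes were chosen so that every stage, including the
all-vs-all clustering and corpus-wide reciprocity searches, is exercised at
a scale where its complexity is visible but desk-friendly.

## Known limitations

* The ungapped scanner cannot model indel-rich domain families; that is
  what the HMMER injection path is for.
* The hydropathy TM stand-in has an appreciable false-positive rate on
  unstructured sequence: a random 110-aa protein contains a qualifying
  19-residue window a few percent of the time, so TM label accuracy on
  simulations sits slightly below 1 depending on the seed. Dedicated
  topology predictors injected through the TSV path do better on real data.
* Single-linkage clustering can chain distinct families through
  intermediates at permissive thresholds.
* Neighborhoods never cross contig boundaries, so draft assemblies with
  loci split across contigs lose those loci.
* The reciprocity filter sees only the corpus it is given; a partner family
  that is genuinely seed-linked but also rides mobile elements in the same
  corpus can be over-flagged.
* "Species" is taken from input metadata verbatim; strain-level corpora
  should either collapse metadata or use `per_strain = TRUE` in the
  copy-number report.
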