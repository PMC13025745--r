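---
title: "Methods: models, parameters and design choices in wsdfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in wsdfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsdfam)
```

wsdfam re-implements, as small auditable functions, the pipeline behind a
genome-wide gene-family study: identification, physicochemistry, gene
structure, synteny and duplication modes, clade extraction, motif scanning,
expression grouping, and regulator inference. This vignette documents the
models, the tunable parameters and their defaults, the synthetic-data
conditions, and the places where a genuine design choice had to be made.

## Family identification

A gene is a family member only if **both** lines of evidence hold:

1. *Homology*: the optimal Smith–Waterman local alignment (BLOSUM62, affine
   gaps open 11 / extend 1) against a seed-protein set reaches
   `E = K·m·n·e^{−λS} ≤ 10⁻⁵`, with the standard gapped-BLOSUM62 constants
   λ = 0.267, K = 0.041 and search space `m·n` = query length × total seed
   residues. The alignment engine is the Biostrings Gotoh implementation;
   unit tests hold it to a brute-force three-matrix DP oracle on all random
   instances up to 30 residues.
2. *Domain content*: both family domain profiles must hit at exact p < 10⁻⁹
   under an ungapped log-odds scan (below). Domain presence/absence is what
   the criterion needs, so a full profile HMM with insert/delete states is
   deliberately not used.

`X` is treated as an ambiguity residue and scored 0 against everything.
Coverage is measured against the shorter sequence — the published criterion
says only "coverage ≥ 50%", so the denominator is configurable in spirit;
we fix the shorter-sequence convention and state it.

Homoeolog naming (`{prefix}{NN}-{A/B/D}`, `L` suffix for extra tandem
copies, `-Un` for unplaced scaffolds) numbers groups by chromosome then
coordinate. Groups may be supplied or inferred as connected components of
the cross-subgenome reciprocal-best-hit graph. Within a group and subgenome
the lowest-coordinate copy is canonical and later copies get `L`, `L2`, …;
published families occasionally order these differently (manual curation),
which a positional rule cannot reproduce and does not attempt to.

## Physicochemistry

Molecular weight is the sum of average residue masses plus one water
(reported in kDa). The isoelectric point solves `charge(pH) = 0` by
bisection to |charge| < 10⁻⁶, where charge is the Henderson–Hasselbalch sum
over the termini and D/E/C/Y/H/K/R side chains. The default pKa set is
EMBOSS; Lehninger is selectable. Published pI values depend on the pKa set
of the original tool, which is rarely stated — therefore the package's
validation of the published family table goes through the shipped fixture,
not through recomputation from sequences we do not distribute. GRAVY is the
mean Kyte–Doolittle index; the hydrophobic class uses strict `GRAVY > 0`,
so a protein at exactly 0 counts as hydrophilic (this reproduces the
published count of 15 hydrophobic members, one member sitting exactly at 0).

## Gene structure

All coordinates are 1-based inclusive (the GFF3 dialect); gene length is
`end − start + 1`, and the "short gene" count uses strict `< 10000` bp.
These two conventions jointly reproduce the published 2.89–13.09 kb range
and the 39-of-43 below-10-kb count from the fixture's coordinates.
Multi-transcript genes keep the longest-CDS transcript as representative
(configurable to first-listed); the transcript-count column is stored but
not otherwise used.

## Synteny and duplication modes

Anchors are protein pairs passing E ≤ 10⁻¹⁰, identity ≥ 30%, coverage
≥ 50%, each keyed by gene-order rank on its chromosome. Blocks are
maximal-scoring monotone chains (both orientations) with score
`anchors − 0.2 × (rank gaps)`, rank jumps capped at 25, and at least 5
anchors per block; anchors join at most one block (best-first peeling;
equal scores prefer the smaller starting rank, making output
deterministic). The published analysis names its collinearity tool but not
its parameters, so these MCScanX-like defaults are declared here and are
configurable; the test surface is recovery of planted truth, plus a
brute-force monotone-chain oracle on all instances up to 12 anchors.

Classification precedence is segmental > tandem > proximal > dispersed >
singleton: block membership first, then an anchor partner at adjacent rank
on the same chromosome, then within 10 ranks ("proximal" is undefined in
the source analysis; 10 is our declared default), then any remaining
partner. Every family gene gets exactly one mode.

## Clade extraction

The retention rule — branch support ≥ 70 and ≥ 5 leaves — is applied to
*maximal* qualifying clades: a node is reported iff it qualifies and no
qualifying ancestor exists, so reported clades are pairwise disjoint.
Whether the original 12-clade result collapsed nested qualifying clades is
not stated; maximality is the only reading that yields a partition, and it
is what we implement (verified against exhaustive node enumeration on
random 50-leaf trees). Supports are read on the child edge of each internal
node; root support is ignored. Newick supports in [0, 1] are rescaled to
0–100. Neighbor joining (via ape) is provided purely as the tree stand-in
for synthetic tests — published trees are inputs to this pipeline, never
outputs.

## Motif scanning

PWMs are built from aligned instances with column probabilities
`(count + pc·background) / (n + pc)` and log-odds against a strictly
positive background; scores are integerized at 1/1000 bit, at which
granularity the p-value error is negligible even at the 10⁻⁹ threshold.
The exact null distribution over all achievable scores comes from
position-wise convolution under the i.i.d. background; unit tests hold it
to full enumeration for DNA widths ≤ 5 and protein widths ≤ 3, and a
calibration test checks the empirical false-hit rate on 10⁵ background
windows against the attained size of the threshold (the discrete null means
the attained size is at or below the nominal α; the empirical rate is
compared to the attained size, which is the exact quantity).

Promoter scanning reports, for a promoter whose 3′ end abuts the TSS,
`distance_to_tss = length − (start + width − 1) + 1` bp upstream; the
promoter generator plants sites under the same convention, so planted and
reported distances agree by construction. Default promoter length is
2000 bp (the usual plant cis-element window; the source analysis does not
state its choice). The catalytic-core check matches `HH...DG` and, failing
that, the `HH...DA` variant seen in a few family members.

## Expression atlas

Sample grouping runs in three declared phases:

1. average-linkage clustering on `1 − Pearson` distance between
   `log2(FPKM+1)` sample profiles, cut at the k (over 2–12 by default)
   maximizing the Dunn2 index — the minimum average between-cluster
   dissimilarity over the maximum average within-cluster dissimilarity
   (singletons contribute no within-average; all-singleton clusterings are
   rejected);
2. clusters mixing tissue labels are split by tissue;
3. groups under 3 samples are merged into the group with the smallest mean
   cophenetic distance on the sample dendrogram, repeatedly, so final
   groups have ≥ 3 members.

The distance metric behind the original study's clustering is unstated;
correlation distance on the log scale is the field's default for expression
profiles and is our declared choice. "Phylogenetically nearest" for merging
is read as the sample dendrogram itself. The atlas is group means on the
FPKM scale → `log2(x+1)` → per-gene min–max to [0, 1]; constant genes map
to all zeros (keeps the bound and marks no-signal genes lowest), and peak
groups break ties toward the first group in column order. The
"expressed at all" retention rule is configurable between `≥` and `>`
because a literal `FPKM ≥ 0` retains everything.

qPCR fold changes are `2^{−ΔΔCt}` with technical replicates averaged
within biological replicates; the calibrator group is an explicit argument
(the source analysis does not name its calibrator). Tukey HSD runs on the
per-replicate ΔCt values; the compact letter display uses the
insert-and-absorb algorithm, and a 1000-replicate null simulation in the
acceptance suite checks the family-wise error against 0.05.

## Regulator inference

The dual filter requires Pearson r ≥ 0.9 both globally and within the
*target's peak tissue* — the intra-tissue pass is what rejects correlations
manufactured purely by between-tissue mean shifts, and the package's tests
construct exactly that confound. "Intra-tissue" could also mean the best
tissue for the pair; both readings are implemented (`intra = "peak"`
default, `"max"` optional). TF-to-motif mapping takes the best local
alignment at E ≤ 10⁻⁵ with lexicographic tie-breaks; promoter scans use
p < 10⁻⁴ by default (the FIMO convention for short DNA motifs — the 10⁻⁹
threshold published alongside belongs to the protein-motif rescan, which is
much wider) and flag hits within 500 bp of the TSS.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions at desk scale:

* **Genome** (`genome_sim_config`): 3 chromosomes × 60 genes (the analysis
  scripts use 67 for ~200-gene genomes), a 13-member family realizing the
  plan segmental 6 / tandem 4 / proximal 1 / dispersed 2 — the published
  28/11/1/3 mode mix scaled to desk size — plus single-domain,
  homology-only and random decoys. Family proteins are ~500 residues with
  two planted high-information domain profiles (widths 45 and 55,
  consensus probability 0.85 per position) and the HHXXXDG core. Distinct
  planted units use distinct backbones, so at the anchor thresholds
  (coverage ≥ 50%) homology anchors form only within a unit and the
  duplication plan is recovered *exactly* at zero mutation: proximal genes
  are planted as satellites of a tandem array (their partners outrank them
  as tandem), and segmental units are single-gene subfamilies inside a
  duplicated segment padded with duplicated filler genes to reach block
  size.
* **Expression** (`expression_sim_config`): 6 tissues × 10 samples
  (60 samples standing in for an atlas of hundreds), lognormal noise
  (σ = 0.2) around tissue means of 50 (peak) and 2 (elsewhere), ±10%
  lognormal library-size factors. Planted TFs track their target's realized
  profile with noise calibrated per tissue so the stated correlation holds
  in both analytical dimensions; at planted r = 1 the correlation is
  exactly 1, which is the zero-noise condition under which recovery is
  asserted to be perfect.
* **Promoters**: i.i.d. background of stated composition with motif
  consensus instances planted at stated TSS distances and strands.

What passing these tests shows: the algorithms recover exactly what was
planted under the stated conditions, and their cores agree with independent
oracles. What it does not show: performance on real genomes — real gene
families have gap-rich alignments, pseudo-genes, fragmented annotations,
batch-confounded expression and diverged binding sites, none of which the
generators emulate (no indels, no assembly artifacts, no realistic wheat
karyotype, no read-level simulation).

## Numerical choices and problem sizes

Determinism: every generator takes a seed and restores the caller's RNG
state; equal seeds give byte-identical output. Bisection for pI runs to
|charge| < 10⁻⁶ with a hard cap of 200 iterations; the chain DP uses a
10⁻¹² tie tolerance; score integerization is 1/1000 bit. The test suite
runs the full synthetic pipeline at 3 × 60-gene chromosomes and 60
expression samples, and the analysis scripts and acceptance run at
3 genomes × 201 genes — sizes chosen so the whole suite completes in about
a minute while every planted feature remains unambiguous.

## Known limitations

* The ungapped domain scan would lose sensitivity on domains with real
  indel variation; the identification criterion only needs presence calls.
* p-distance phylogenies in the analysis scripts use a common-length crop
  of the simulated proteins rather than a true multiple alignment —
  adequate for identical-backbone copies, not for real data.
* The compact letter display is exact but can be conservative in its
  letter count for pathological nonsignificance graphs.
* Positional naming cannot reproduce manually curated exceptions in
  published family names (see Family identification).
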