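# wsdfam

Desk-scale, fully testable building blocks for genome-wide gene-family
characterization, developed around the wheat wax ester synthase /
diacylglycerol acyltransferase (WSD) family. WSD proteins are bifunctional
O-acyltransferases that synthesize the wax esters of the plant cuticle; the
wheat family comprises 43 members (TaWSDs) whose published coordinates and
protein properties ship with this package as a plain-text fixture.

The package is aimed at computational biologists who run — or need to audit —
the standard "gene family paper" pipeline: every stage is a small, documented
function, and synthetic genomes, transcriptomes and promoters with planted,
machine-readable truth make each stage testable without downloading a genome.

## What it implements

* **Family identification by dual evidence** — a gene joins the family only
  if its protein has a Smith–Waterman/BLOSUM62 local-alignment hit to a seed
  protein with Karlin–Altschul E-value `E = K·m·n·e^(−λS)` at most 1e−5 *and*
  carries both conserved domain profiles (ungapped log-odds scan, exact
  p-value < 1e−9). Positional names follow the `{prefix}{NN}-{A/B/D}`
  homoeolog convention with `L` suffixes for extra tandem copies.
* **Protein physicochemistry** — molecular weight from average residue
  masses, isoelectric point by bisection on the Henderson–Hasselbalch net
  charge (EMBOSS or Lehninger pKa sets), and GRAVY (mean Kyte–Doolittle
  index; GRAVY > 0 ⇒ hydrophobic).
* **Gene structure** — lengths (`end − start + 1`), exon-count histograms,
  UTR presence, short-gene counts, from GFF3 annotation.
* **Synteny and duplication modes** — homology anchors (E ≤ 1e−10,
  identity ≥ 30%, coverage ≥ 50%), dynamic-programming chaining into
  collinear blocks (score = anchors − 0.2·gaps, min 5 anchors, max rank gap
  25), and per-gene classification with precedence
  segmental > tandem > proximal > dispersed > singleton, plus
  reciprocal-best collinear ortholog calls.
* **Clade extraction** — maximal clades with branch support ≥ 70 and ≥ 5
  leaves from support-annotated trees, with taxonomic composition and
  lineage-specificity flags; a neighbor-joining builder serves as the tree
  stand-in for synthetic tests.
* **Motif scanning with exact p-values** — PWMs integerized at 1/1000 bit,
  the full null score distribution by position-wise convolution, FIMO-style
  scanning of proteins or promoters (both strands, TSS distances), IUPAC
  cis-element cataloging, and the HHXXXDG catalytic-core check (including
  the G→A variant).
* **Expression atlas** — FPKM filtering, average-linkage sample clustering
  on correlation distance with the cut chosen by the Dunn2 validity index,
  tissue subdivision of mixed clusters, cophenetic merging of undersized
  groups (final size ≥ 3), `log2(FPKM+1)` and per-gene min–max layers, and
  peak-group calls; qPCR `2^−ΔΔCt` fold changes with Tukey HSD compact
  letter displays.
* **Regulator inference** — candidate TFs must reach Pearson correlation
  ≥ 0.9 with a family gene both globally and within the gene's peak tissue;
  candidates are clustered (average linkage, Dunn2-chosen k), mapped to
  binding motifs by best protein hit, and cross-validated by promoter TFBS
  scanning with 500-bp TSS-window flags.
* **Synthetic data with planted truth** — annotated genomes realizing an
  exact duplication plan with single-domain/homology-only/random decoys,
  orthologous sister genomes, tissue-structured FPKM matrices with planted
  peak tissues and TF–target correlations, and promoters with planted
  binding sites.

## Worked example

```r
library(wsdfam)

s <- summarize_properties(load_table1())
s$pi_gt7_count    # 36   members with pI > 7 (83.72%)
s$hydrophobic_count   # 15   members with GRAVY > 0
s$gene_length_range_kb  # 2.89 13.09  (kb, end - start + 1)
s$genes_below_threshold # 39   of 43 shorter than 10 kb

# synthetic end-to-end: plant a family, recover it
dom <- make_domain_profiles()
gen <- generate_family_genome(genome_sim_config(seed = 1), dom)
fam <- identify_family(gen$proteome, gen$seeds, dom$profiles)
nrow(fam)                                  # 13 planted members, all found
anc <- find_anchors(gen$proteome, gen$proteome, gen$orders, gen$orders,
                    self = TRUE)
cls <- classify_duplicates(fam$gene_id, anc, chain_collinear(anc))
table(cls$mode)   # dispersed 2, proximal 1, segmental 6, tandem 4
```

The numbered scripts under `analysis/` run the whole workflow as a
narrative — simulation, identification, physicochemistry, synteny,
phylogeny, expression, regulators — each printing what it found and writing
its tables under `results/`.

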