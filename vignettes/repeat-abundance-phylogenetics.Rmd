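---
title: "Phylogenetic inference from genomic repeat abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic inference from genomic repeat abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatphylo)
```

## The idea

Repetitive elements — satellites, LTR retrotransposons (Ty1/Copia,
Ty3/Gypsy), DNA transposons, rDNA — make up a large share of many
eukaryote genomes, and their copy numbers change fast enough to differ
between closely related species. A shallow, random sample of genomic
reads ("genome skimming", typically 0.1–5% of the 1C genome) covers
high-copy repeats hundreds of times over even when single-copy genes
are missed entirely. If reads from several taxa are pooled and
clustered by sequence similarity, each cluster collects the reads of
one repeat family across all taxa, and the number of reads a taxon
contributes to a cluster estimates that family's genomic proportion in
that taxon.

`repeatphylo` treats those per-taxon abundances as *continuous
phylogenetic characters*: no recoding into discrete states, no
alignment of orthologous sites. Trees are inferred from the abundance
matrix in two ways:

* **Wagner (additive) maximum parsimony**, where the cost of change
  between two abundance values is their absolute difference, with exact
  tree search and symmetric-resampling supports; and
* **maximum likelihood under Brownian motion**, where each character
  drifts independently with variance proportional to branch length.

Both rest on the same biological premise: repeat abundances evolve
largely by drift-like expansion and contraction, so similarity in
abundance profiles reflects shared history.

## Pipeline and key parameters

### Read preparation (`loadReads`, `trimAndFilter`, `sampleToGenomeProportion`, `filterOrganelle`)

Reads are tagged with a short taxon code carried as a read-id prefix,
trimmed to a uniform length (default **100 bp**, keeping the 5' prefix
because base quality decays toward the 3' end on the common platforms),
and reads shorter than the target are discarded. Reads with more than
10% `N` are dropped at load time: the aligner scores `N` as a mismatch,
so such reads only inflate the singleton pool.

Each taxon is then sampled to an equal **genome proportion** (GP):
`n = round(gp/100 × genomeSize1C / readLength)` reads drawn uniformly
without replacement. Equal GP is what makes read counts comparable
across taxa — with equal read *numbers* instead, counts track genome
size rather than the repeat's share of the genome. When 1C values are
unavailable an explicit equal-read-count mode (`nReads`) is provided,
and it announces the caveat. Paired-end data are treated as independent
single-end reads.

Plastid/mitochondrial reads can be screened against user-supplied
organelle references with the same similarity rule as clustering.
Whether to filter before clustering or to drop organelle clusters
afterwards is left to the caller — both orders occur in practice and
the package exposes both (filter a `ReadSet`, or drop columns of the
matrix); neither is endorsed as canonical.

### Clustering (`pairwiseSimilarity`, `buildGraph`, `detectClusters`)

Every read pair whose best local alignment reaches **90% identity over
at least 55% of the read length** (both strands tried) becomes a
weighted edge in the read graph; the weight is the alignment score.
The aligner is a k-mer-seeded (default 13) Smith–Waterman-style local
alignment via `Biostrings::pairwiseAlignment` with megablast-like
constants (+5 match, −4 mismatch, −12 gap open, −2 gap extend),
recorded in `params`. The seed prescreen means a pair sharing no exact
13-mer in either orientation is never aligned; at the 90% acceptance
threshold genuinely similar pairs essentially always share seed words
unless mismatches are pathologically evenly spaced.

Communities are found by greedy weighted-modularity (Louvain) search,
seeded for determinism, so that reads are more similar within than
between clusters. Communities never span connected components (merging
disconnected groups always lowers modularity). Clusters are ranked
CL1, CL2, … by decreasing size, ties broken by the lexicographically
smallest member read id so numbering is total and stable. Size-1
communities are reported separately as singletons and excluded from
abundance matrices by default — they carry taxon-idiosyncratic noise —
with a flag to include them.

Two behaviours of modularity clustering are worth knowing. First, long
or internally diverged elements can be split over several clusters
(parts of an element are conserved to different degrees); because the
split is the same for every taxon in the run, per-taxon proportions —
and hence phylogenetic signal — are preserved. Second, cluster *graph
shape* reflects repeat structure: tandem monomers shorter than the read
length yield dense "spherical" graphs, monomers longer than the read
length yield rings (reads sample the monomer in circular permutation).
`classifyGraphShape` calls these from the subgraph diameter and the
spread of node eccentricities (ring: diameter ≥ 4 with eccentricity
CV ≤ 0.12; spherical: diameter ≤ 3·log n; linear: stretched with an
end-to-centre eccentricity gradient; anything smaller than 5 reads:
"other"). The thresholds are heuristics, recorded in `params`.

### Character matrices (`buildMatrix`, `tntScale`, `frequencyScale`, `rangeMatrix`, `writeTNT`)

`buildMatrix` keeps the top `topN` clusters (default **1000**) in rank
order; cells are raw read counts, zero-filled where a taxon is absent
from a cluster. Counts are deliberately *not* normalized per taxon —
equal-GP sampling upstream is the normalization.

Two scalings serve the two inference routes, both using the single
matrix-wide maximum (the wording "largest abundance" is singular, and a
global divisor preserves between-character ratios):

* `tntScale`: divide by `factor = max/65` so the maximum is exactly 65,
  the ceiling of the TNT continuous-character format. The map is
  linear, so parsimony tree lengths scale by `1/factor` and the set of
  most-parsimonious trees is unchanged (asserted by a cross-module
  test).
* `frequencyScale`: divide by the maximum cell so values lie in [0, 1]
  for the Brownian likelihood.

`rangeMatrix` turns replicate samplings into interval characters
`[mean − SE, mean + SE]` (sample, n−1, standard deviation over
`sqrt(r)`). Lower bounds are floored at 0 since abundances are
physically non-negative — whether the original workflow clamped is not
documented anywhere we know of, so the clamp is a local, documented
choice. On ranged characters taxa whose intervals overlap contribute no
steps, so taxa are only separated when they differ by more than
sampling noise.

TNT/Hennig86 continuous `xread` export writes 3 decimal places (far
below biological sampling noise; keeps files diff-stable) and refuses
matrices whose maximum exceeds 65; ranges serialize as `low-high`
tokens and round-trip bit-exactly at the printed precision.

### Parsimony (`characterSteps`, `treeLength`, `uppassBranchSteps`, `branchAndBoundSearch`, `symmetricResampling`)

The minimum cost of an additive character on a binary tree comes from
the classical interval down-pass: each leaf carries a degenerate
interval (or its supplied range); an internal node takes the
intersection of its children's intervals when they overlap (cost 0), or
the gap between them otherwise (cost = gap width). Unrooted trees are
traversed by rooting on the first leaf's pendant edge; every reported
statistic is rooting-invariant and tested as such. The implementation
is validated against an independent Sankoff dynamic program with linear
costs over the observed-state grid (exact by the median property of L1
costs on trees).

Branch-wise step counts come from an up-pass that fixes one
most-parsimonious reconstruction: the root leaf takes the point of its
interval closest to its neighbour's interval, and every other node the
point of its preliminary interval closest to its parent's final state.
Per-branch absolute differences then sum exactly to the tree length
(conservation is asserted to 1e−9 on random instances).

`branchAndBoundSearch` is implicit enumeration: taxa are added in input
order, partial-tree length is monotone under addition, and branches of
the search tree are pruned against the best complete tree (initialized
by greedy stepwise addition). All minimum-length topologies are
returned; equality uses a relative tolerance of 1e−9 so float noise
cannot split a genuine tie. The guard refuses more than 15 taxa, where
implicit enumeration stops being a desk-scale tool; no heuristic search
is implemented.

**Symmetric resampling** perturbs each character's weight
independently per replicate: with probability `pChange` (default
**1/3**, common practice) the weight is halved or doubled with equal
probability, otherwise 1. The up/down scheme is symmetric around 1 in
log space, avoiding the bias that plain reweighting bootstraps can
introduce. Because step counts are linear in the character values,
reweighting is implemented by scaling matrix columns; each replicate's
MPT set is found exactly (for ≤ 7 taxa all topologies are pre-scored,
which makes thousands of replicates cheap). A bipartition's support is
the percentage of replicates whose strict consensus of MPTs contains
it. The default of **10 000** replicates is a desk-scale compromise;
the count is a parameter. When the MPT is not unique, supports are
drawn on the strict consensus of MPTs (the alternative — picking one
MPT — presumes a uniqueness the data did not provide). Replicate trees
can be archived as multi-Newick for consensus-network tools.

Missing data are unsupported by design: absent taxa are zero-filled
upstream, so no missing cells can arise in this pipeline.

### Brownian-motion likelihood (`brownianLoglik`, `optimizeBranchLengths`, `mlSearch`, `bootstrapML`)

Each character is modelled as Brownian motion on the tree: independent
normal increments with variance rate × branch length. The likelihood is
computed by Felsenstein's contrasts/pruning construction, which yields
the *REML* likelihood — the root state never enters, removing a
nuisance parameter and making the value provably invariant to root
placement. The per-character rate is profiled out at its REML value
(`sharedRate = TRUE` fits one global rate instead). Characters constant
across taxa carry no information and are dropped with a logged count
rather than failing the run. The pruning likelihood is tested against a
dense multivariate-normal REML evaluation (full covariance matrix,
determinant, GLS quadratic form) to 1e−8.

The model is applied to the 0–1 frequency-scaled abundances *as is* —
deliberately **not** the arcsine/square-root gene-frequency transform
that classical gene-frequency ML programs apply internally. Repeat
abundances are not allele frequencies at a locus; the plain Brownian
model is the stated assumption, and the divergence from those programs'
internals is a documented caveat, not an oversight. With per-character
rates profiled, the likelihood depends on branch lengths only up to a
global scale factor, so optimized lengths are meaningful relatively.

Branch lengths are optimized coordinate-wise (golden-section on
[1e−8, 100] per branch, sweeps until the log-likelihood gain drops
below 1e−6 or 200 sweeps, all branches initialized at 0.1 —
deterministic). Topology search enumerates all unrooted topologies up
to 8 taxa; for 9–12 a stepwise-addition tree is refined by NNI to a
local optimum; beyond 12 the search refuses. Ties within 1e−6 are
flagged and broken first-found. `bootstrapML` resamples characters with
replacement (default **1000** replicates) and maps bipartition
frequencies onto the strict consensus of replicate trees, which may be
partly unresolved — an honest display of weak signal.

### Synthetic data (`simulateGenomes`, `simulateReads`, `simulateAbundanceEvolution`)

The generators provide ground truth at three pipeline stages:

* **Genomes**: i.i.d. uniform ACGT background with repeat families
  inserted at uniform random non-overlapping positions; each copy is
  independently mutated from the family consensus at the family's
  divergence rate; tandem families go in as one head-to-tail array. A
  truth table records every insertion, per-taxon copy numbers, and true
  genomic proportions.
* **Reads**: uniform positions on both strands,
  `round(gp/100 × G / readLength)` reads, substitution errors only
  (indels are not needed to probe an identity threshold); provenance by
  the family block containing the read midpoint.
* **Abundance matrices**: Brownian motion on *log*-abundance along a
  known tree (increments `Normal(0, sigma² × branch length)`), leaves
  exponentiated and floored at 0.001. Log-scale drift keeps abundances
  positive and matches multiplicative copy-number dynamics; this is a
  modelling choice of the generator, since no generative model is
  otherwise specified.

What the generators do **not** emulate: transposition bursts or
deletion mechanisms, GC/genic structure, paired-end reads, platform
homopolymer errors, or between-family sequence relatedness (family
consensuses are independent random sequences, hence far more distinct
than real superfamilies). Passing recovery tests on this synthetic
system therefore demonstrates the *inference machinery* — clustering
fidelity, counting, tree search, supports — not robustness to every
feature of real repeat biology.

### Performance experiments (`gpTitration`, `clusterNumberTitration`, `partitionAnalysis`, `repeatTypeInformativeness`)

These reproduce the method-performance protocol on synthetic (or user)
data: a GP ladder of 11 doubling levels from 0.005% to 5.12% with 3
replicate samplings per level; tree inference from the top-k clusters
over a grid spanning 5–1000 (the default grid
`{5, 15, 25, 35, 45, 75, 150, 300, 600, 1000}` is our choice — only the
range is prescribed by the protocol); per-150-cluster partitions
flagged when their tree conflicts with the reference; and per
repeat-type subsets scored by mean internal support. Every record
carries the derived seed it was produced under, so any row is
regenerable bit-exactly. Mean support averages internal branches only
(pendant branches have no support), and "resolved" means the strict
consensus of MPTs is fully binary.

## Numerical and design notes

* All randomized operations take an explicit integer seed and restore
  the caller's RNG state; identical inputs and seed give identical
  output, byte for byte.
* MPT-set and likelihood ties use relative tolerances (1e−9 and 1e−6)
  so floating-point noise neither splits nor invents ties.
* Degenerate inputs fail loudly and specifically: all-zero matrices
  cannot be scaled, fewer than 3 taxa admit no unrooted topology,
  all-constant matrices have no likelihood, taxon mismatches between
  tree and matrix report the symmetric difference.
* Duplicate similarity hits for a pair keep the maximum score; a read
  pair is stored once, unordered.
* Cluster rank ties, column order under truncation, and stepwise
  addition order are all made deterministic so that CL numbering and
  search results are stable across runs.
* Whether edge weights should be alignment scores or identities is not
  fixed by the clustering principle; scores are used and the choice is
  recorded in `params`.

The test suite exercises the exact search against full enumeration at
7 taxa (945 topologies), the interval engine against a Sankoff oracle
at ≤ 6 taxa and ≤ 10 characters, the likelihood against dense REML at
≤ 6 leaves, quartet recovery from 150-character Brownian matrices, and
an end-to-end run on four 600-kb synthetic genomes at 1% GP — sizes
chosen so the whole suite stays a coffee-break job on one core while
still covering every code path that matters.

## Known limitations

* No heuristic parsimony search: more than 15 taxa is out of scope, as
  is implied weighting and any discrete-character support.
* The Brownian ML route shares the parsimony route's premise but adds
  normality per character; heavy-tailed abundance changes (bursts) are
  mis-modelled by both, and the package makes no attempt at
  Ornstein–Uhlenbeck or rate-shift models.
* Polyploidy and hybridization violate a bifurcating tree; conflicting
  signal shows up as depressed supports, and replicate-tree archives
  are the intended input for external network tools.
* Cluster homology is similarity-based; families diverged beyond the
  90%/55% rule fragment, and abundances of fragments are correlated —
  characters are not strictly independent, which both inference models
  assume.
* Unequal genome-size information (or none) shifts what counts measure;
  the equal-read-count mode logs the caveat but cannot repair it.

## A worked miniature

```{r example, eval = FALSE}
# two planted satellite families separating {A,B} from {C,D}
specs <- list(
  repeatFamilySpec("SAT1", 70, c(A = 3000, B = 3000, C = 857, D = 857),
                   divergence = 2, typeLabel = "satellite", tandem = TRUE),
  repeatFamilySpec("SAT2", 80, c(A = 750, B = 750, C = 2625, D = 2625),
                   divergence = 2, typeLabel = "satellite", tandem = TRUE))
gen <- simulateGenomes(specs, genomeSize = 6e5, seed = 5)
rsets <- lapply(names(gen$genomes), function(tx)
  simulateReads(gen$genomes[[tx]], tx, gpPercent = 1, errorRate = 0.01,
                seed = 5 + match(tx, names(gen$genomes)))$readset)

hits <- pairwiseSimilarity(rsets)
res <- detectClusters(buildGraph(hits, rsets), seed = 1)
m <- buildMatrix(res, topN = nrow(clusterCounts(res)))
sr <- symmetricResampling(m, replicates = 1000, seed = 3)
ape::write.tree(sr$tree)
```

The README shows this example with the numbers it actually prints.
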