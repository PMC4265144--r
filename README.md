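# repeatphylo

Phylogenetic inference from the genomic abundance of repetitive DNA.

## The problem and who this is for

Most phylogenomic pipelines throw the repetitive fraction of the genome
away. Yet in many eukaryotes — flowering plants above all — satellites,
Ty1/Copia and Ty3/Gypsy retrotransposons, DNA transposons and rDNA make
up most of the nuclear genome, and their copy numbers diverge quickly
between species. A low-coverage, random read sample ("genome skimming",
0.1–5% of the 1C genome) covers every high-copy repeat family hundreds
of times, so pooling reads from several taxa and clustering them on a
sequence-similarity graph yields, per cluster, a per-taxon read count
that estimates the family's genomic proportion.

`repeatphylo` is for systematists and genome biologists who have such
skimming data (or want to explore the method on simulated data). It
implements the whole path from reads to trees:

1. **Read preparation** — taxon coding, trimming to 100 bp, sampling
   each taxon to an equal genome proportion (GP), optional organelle
   filtering (`loadReads`, `trimAndFilter`, `sampleToGenomeProportion`,
   `filterOrganelle`).
2. **Repeat clustering** — all-vs-all local alignment at the 90%
   identity / 55% coverage rule, graph construction, maximum-modularity
   communities, per-taxon counts, cluster graph shapes
   (`pairwiseSimilarity`, `buildGraph`, `detectClusters`,
   `countAbundances`, `classifyGraphShape`).
3. **Character matrices** — top-1000 cluster abundance matrices, TNT
   scaling (max = 65) and 0–1 frequency scaling, 150-cluster
   partitions, annotation subsets, mean ± SE range characters, and
   TNT/Hennig86 continuous export (`buildMatrix`, `tntScale`,
   `frequencyScale`, `partitionMatrix`, `subsetByAnnotation`,
   `rangeMatrix`, `writeTNT`).
4. **Trees** — continuous-character Wagner parsimony with exact
   branch-and-bound search and symmetric-resampling supports
   (`branchAndBoundSearch`, `symmetricResampling`), and Brownian-motion
   REML likelihood with bootstrap supports (`mlSearch`, `bootstrapML`).
5. **Synthetic data and method evaluation** — ground-truthed genome,
   read and Brownian abundance generators, plus the GP-titration,
   cluster-number, partition and repeat-type experiments
   (`simulateGenomes`, `simulateReads`, `simulateAbundanceEvolution`,
   `gpTitration`, `clusterNumberTitration`, `partitionAnalysis`,
   `repeatTypeInformativeness`).

## The models at the core

**Wagner parsimony on continuous characters.** An abundance character
is additive: changing from state `x` to `y` costs `|x − y|` — counts
are never recoded into discrete states. The minimum cost on a binary
tree comes from the interval down-pass (leaf intervals intersect → no
cost; disjoint → the gap width is added and the gap becomes the node
interval); an up-pass fixes a most-parsimonious reconstruction whose
per-branch absolute changes sum exactly to the tree length. Matrices
are scaled by `factor = max/65` for TNT-format compatibility, which
rescales lengths by `1/factor` and provably cannot change the set of
most-parsimonious trees. Supports come from symmetric resampling: per
replicate each character keeps weight 1 with probability 2/3, or is
halved/doubled with equal probability, and a clade's support is the
percentage of replicates whose strict consensus of exact MPTs contains
it.

**Brownian-motion likelihood.** On 0–1 scaled abundances each character
evolves by drift: contrasts are independent normals with variance
proportional to branch length, computed by pruning; the per-character
rate is profiled at its REML value, and the likelihood is invariant to
root placement. Topologies are enumerated exhaustively up to 8 taxa
(NNI refinement to 12), branch lengths optimized coordinate-wise.

## Worked example

Four synthetic 600-kb genomes carry two tandem satellite families with
abundances separating {A,B} from {C,D} (35% vs 10% of the genome, and
the reverse); reads are sampled at 1% GP with 1% sequencing error:

```r
library(repeatphylo)

specs <- list(
  repeatFamilySpec("SAT1", 70, c(A = 3000, B = 3000, C = 857, D = 857),
                   divergence = 2, typeLabel = "satellite", tandem = TRUE),
  repeatFamilySpec("SAT2", 80, c(A = 750, B = 750, C = 2625, D = 2625),
                   divergence = 2, typeLabel = "satellite", tandem = TRUE))
gen <- simulateGenomes(specs, genomeSize = 6e5, seed = 5)
rsets <- lapply(names(gen$genomes), function(tx)
  simulateReads(gen$genomes[[tx]], tx, gpPercent = 1, errorRate = 0.01,
                seed = 5 + match(tx, names(gen$genomes)))$readset)

hits <- pairwiseSimilarity(rsets)      # 3567 similarity hits
res  <- detectClusters(buildGraph(hits, rsets), seed = 1)
res
#> ClusteringResult: 3 clusters (>= 2 reads), 115 singletons, 4 taxa

m <- buildMatrix(res, topN = nrow(clusterCounts(res)))
abundances(m)
#>   CL1 CL2 CL3
#> A  28   7   2
#> B  26   4   0
#> C   3  24   0
#> D   9  22   0

sr <- symmetricResampling(m, replicates = 1000, seed = 3)
sr$supports
#> C|D
#> 100
ape::write.tree(sr$tree)
#> [1] "(A,(D,C)100,B);"
```

The counts mirror the planted design: CL1 (the SAT1 family) is ~4×
more abundant in A/B than in C/D, CL2 (SAT2) the reverse, and the 115
singletons are the single-copy background. The most parsimonious
unrooted tree groups C with D (equivalently A with B) and that clade
survives all 1000 symmetric-resampling replicates — support 100. For
TNT or the ML route, `writeTNT(tntScale(m), "m.tnt")` and
`writeFrequencyTable(frequencyScale(m), "m.freq")` serialize the scaled
matrices.

A thin command-line front end over the same functions ships at
`inst/scripts/repeatphylo.R` (subcommands `sample`, `cluster`,
`matrix`, `mptree`, `mltree`).

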