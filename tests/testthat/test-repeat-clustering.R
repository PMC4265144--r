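test_that("pairwise similarity: identity, coverage, strand and threshold decisions", {
  base <- rdna(100, seed = 21)
  # identical reads: identity 100, full coverage
  rs <- mkReadSet(c(a = base, b = base))
  h <- pairwiseSimilarity(rs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$coverage, 1)
  # reverse complement is found (strand symmetry)
  rs2 <- mkReadSet(c(a = base, b = revcomp(base)))
  h2 <- pairwiseSimilarity(rs2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$identity, 100)
  # 8 interior mismatches -> identity 92 >= 90: hit;
  # 12 mismatches -> identity 88 < 90: no hit
  # mismatches clustered mid-read so shared 13-mer seeds survive in the
  # flanks, and trimming them can never raise the local-alignment score
  pos8 <- 40 + 3 * (0:7)
  pos12 <- 30 + 3 * (0:11)
  h8 <- pairwiseSimilarity(mkReadSet(c(a = base, b = mutateAt(base, pos8))))
  expect_equal(nrow(h8), 1L)
  expect_equal(h8$identity, 92)
  h12 <- pairwiseSimilarity(mkReadSet(c(a = base, b = mutateAt(base, pos12))))
  expect_equal(nrow(h12), 0L)
})

test_that("similarity is symmetric under input order and monotone in thresholds", {
  set.seed(22)
  fam <- rdna(100)
  seqs <- c(vapply(1:6, function(i)
    mutateAt(fam, sample(100, sample(0:8, 1))), character(1)),
    replicate(4, rdna(100)))
  names(seqs) <- sprintf("r%02d", seq_along(seqs))
  rsF <- mkReadSet(seqs)
  rsR <- mkReadSet(rev(seqs))
  key <- function(h) {
    k <- paste(pmin(h$read_a, h$read_b), pmax(h$read_a, h$read_b))
    o <- order(k)
    list(k = k[o], id = round(h$identity[o], 9), sc = h$score[o])
  }
  expect_identical(key(pairwiseSimilarity(rsF)), key(pairwiseSimilarity(rsR)))
  # raising thresholds never adds edges
  loose <- pairwiseSimilarity(rsF, minIdentity = 85, minCov = 0.4)
  tight <- pairwiseSimilarity(rsF, minIdentity = 95, minCov = 0.7)
  expect_true(all(key(tight)$k %in% key(loose)$k))
})

test_that("graph construction: node bijection, edge count, de-duplication, dangling ids", {
  rs <- mkReadSet(setNames(replicate(5, rdna(100)), sprintf("r%d", 1:5)))
  empty <- data.frame(read_a = character(), read_b = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric())
  g0 <- buildGraph(empty, rs)
  expect_equal(igraph::vcount(g0), 5L)
  expect_equal(igraph::ecount(g0), 0L)
  hits <- data.frame(read_a = c("T1_r1", "T1_r2"), read_b = c("T1_r2", "T1_r3"),
                     identity = c(95, 96), coverage = c(1, 1),
                     score = c(400, 410))
  g1 <- buildGraph(hits, rs)
  expect_equal(igraph::ecount(g1), 2L)
  # duplicate pair keeps the max score
  dup <- rbind(hits, data.frame(read_a = "T1_r2", read_b = "T1_r1",
                                identity = 99, coverage = 1, score = 480))
  g2 <- buildGraph(dup, rs)
  expect_equal(igraph::ecount(g2), 2L)
  eid <- igraph::get_edge_ids(g2, c("T1_r1", "T1_r2"))
  expect_equal(igraph::E(g2)$weight[eid], 480)
  bad <- data.frame(read_a = "T1_r1", read_b = "T1_r9",
                    identity = 95, coverage = 1, score = 1)
  expect_error(buildGraph(bad, rs), "absent")
})

test_that("modularity clustering separates two cliques and respects components", {
  set.seed(23)
  # two 10-read cliques joined by one weak edge
  f1 <- rdna(100); f2 <- rdna(100)
  reads <- c(setNames(vapply(1:10, function(i) mutateAt(f1, sample(100, 2)),
                             character(1)), sprintf("a%02d", 1:10)),
             setNames(vapply(1:10, function(i) mutateAt(f2, sample(100, 2)),
                             character(1)), sprintf("b%02d", 1:10)))
  rs <- mkReadSet(reads)
  ids <- names(repeatphylo::reads(rs))
  cmb <- combn(ids, 2)
  within <- function(x, y) substr(x, 4, 4) == substr(y, 4, 4)
  hits <- data.frame(read_a = cmb[1, ], read_b = cmb[2, ],
                     identity = 98, coverage = 1, score = 450)
  hits <- hits[within(hits$read_a, hits$read_b), ]
  hits <- rbind(hits, data.frame(read_a = "T1_a01", read_b = "T1_b01",
                                 identity = 91, coverage = 0.6, score = 50))
  g <- buildGraph(hits, rs)
  res <- detectClusters(g, seed = 1)
  expect_equal(nrow(clusterCounts(res)), 2L)
  expect_setequal(lengths(res@members), c(10L, 10L))
  # the chosen 2-way split beats the 1-community partition and random
  # 3-way refinements in modularity (oracle check on this instance)
  memb <- rep(NA_integer_, igraph::vcount(g))
  names(memb) <- igraph::V(g)$name
  for (k in seq_along(res@members)) memb[res@members[[k]]] <- k
  modOf <- function(mb) igraph::modularity(g, mb, weights = igraph::E(g)$weight)
  expect_gt(modOf(memb), modOf(rep(1, length(memb))))
  for (i in 1:20) {
    mb3 <- memb
    mb3[sample(length(mb3), 5)] <- 3L
    expect_gte(modOf(memb), modOf(mb3))
  }
  # one clique -> one cluster
  res1 <- detectClusters(buildGraph(hits[within(hits$read_a, hits$read_b) &
                                           startsWith(hits$read_a, "T1_a"), ],
                                    rs), seed = 1)
  expect_true(all(startsWith(res1@members[["CL1"]], "T1_a")))
  # two components -> clusters never span components
  hitsNoBridge <- hits[!(hits$read_a == "T1_a01" & hits$read_b == "T1_b01"), ]
  gc <- buildGraph(hitsNoBridge, rs)
  resC <- detectClusters(gc, seed = 1)
  comp <- igraph::components(gc)$membership
  for (m in resC@members)
    expect_equal(length(unique(comp[m])), 1L)
})

test_that("clustering output is a seeded-deterministic partition with ranked ids", {
  set.seed(24)
  fams <- replicate(3, rdna(100))
  reads <- unlist(lapply(1:3, function(f)
    setNames(vapply(seq_len(c(8, 6, 6)[f]), function(i)
      mutateAt(fams[f], sample(100, 2)), character(1)),
      sprintf("f%d_%02d", f, seq_len(c(8, 6, 6)[f])))))
  reads <- c(reads, iso = rdna(100))
  rs <- mkReadSet(reads)
  hits <- pairwiseSimilarity(rs)
  g <- buildGraph(hits, rs)
  res <- detectClusters(g, seed = 5)
  # partition property
  expect_setequal(c(unlist(res@members), singletons(res)),
                  names(repeatphylo::reads(rs)))
  # CL1 is the largest; equal-size clusters ranked by smallest member id
  sizes <- res@clusterTable$size
  expect_true(all(diff(sizes) <= 0))
  tied <- which(sizes[-1] == sizes[-length(sizes)])
  for (i in tied)
    expect_true(min(res@members[[i]]) < min(res@members[[i + 1]]))
  # seeded determinism
  res2 <- detectClusters(g, seed = 5)
  expect_identical(res@members, res2@members)
})

test_that("per-taxon counts zero-fill absent taxa and respect marginals", {
  f1 <- rdna(100, seed = 25)
  rsA <- mkReadSet(setNames(vapply(1:3, function(i) mutateAt(f1, i),
                                   character(1)), paste0("r", 1:3)), "A")
  rsB <- mkReadSet(c(r9 = mutateAt(f1, 50)), "B")
  rsC <- mkReadSet(c(x1 = rdna(100, seed = 26)), "C")
  hits <- pairwiseSimilarity(list(rsA, rsB, rsC))
  res <- detectClusters(buildGraph(hits, list(rsA, rsB, rsC)), seed = 1)
  counts <- countAbundances(res)
  expect_identical(colnames(counts), c("A", "B", "C"))
  expect_equal(unname(counts["CL1", ]), c(3L, 1L, 0L))
  withS <- countAbundances(res, includeSingletons = TRUE)
  expect_equal(sum(withS), 5L)  # every read accounted for
})

test_that("planted families are each recovered as one cluster with copy-ratio counts", {
  cn1 <- c(A = 400, B = 200)
  cn2 <- c(A = 150, B = 300)
  specs <- list(
    repeatFamilySpec("FAM1", 60, cn1, divergence = 2, tandem = TRUE),
    repeatFamilySpec("FAM2", 70, cn2, divergence = 2, tandem = TRUE))
  gen <- simulateGenomes(specs, genomeSize = 1.2e5, seed = 31)
  sim <- lapply(c("A", "B"), function(tx)
    simulateReads(gen$genomes[[tx]], tx, gpPercent = 10, seed = 31,
                  truth = gen$truth))
  rsets <- lapply(sim, `[[`, "readset")
  prov <- do.call(rbind, lapply(sim, `[[`, "provenance"))
  hits <- pairwiseSimilarity(rsets)
  res <- detectClusters(buildGraph(hits, rsets), seed = 2)
  # each planted family maps to exactly one cluster
  famOf <- setNames(prov$family, prov$read_id)
  top <- res@members[1:2]
  majority <- vapply(top, function(m)
    names(which.max(table(famOf[m]))), character(1))
  expect_setequal(majority, c("FAM1", "FAM2"))
  purity <- vapply(top, function(m)
    max(table(famOf[m])) / length(m), numeric(1))
  expect_true(all(purity > 0.95))
  # singleton leakage <= 2% of family reads
  famReads <- sum(prov$family != "background")
  leaked <- sum(famOf[singletons(res)] != "background")
  expect_lte(leaked, 0.02 * famReads)
  # count ratio within 3 binomial SD of the planted 2:1 ratio
  c1 <- clusterCounts(res)[names(majority)[majority == "FAM1"], ]
  nA <- sum(prov$family == "FAM1" & startsWith(prov$read_id, "A"))
  nB <- sum(prov$family == "FAM1" & startsWith(prov$read_id, "B"))
  expect_gt(min(c1["A"] / c1["B"], nA / nB) / max(c1["A"] / c1["B"], nA / nB),
            0.6)
})

test_that("graph shapes: short tandem monomers spherical, long monomers ring, small other", {
  # classify the whole family subgraph (one cluster per family)
  wholeCluster <- function(rs) {
    ids <- names(reads(rs))
    counts <- matrix(length(ids), 1, 1,
                     dimnames = list("CL1", taxonCode(rs)))
    new("ClusteringResult",
        clusterTable = data.frame(rank_id = "CL1", size = length(ids),
                                  shape = NA_character_,
                                  annotation = NA_character_,
                                  annotation_label = NA_character_),
        members = list(CL1 = ids), singletons = character(0),
        counts = counts, params = list())
  }
  # monomer (60 bp) shorter than the read (100 bp): dense ball
  sph <- tiledReads(rdna(60, seed = 41), n = 30, taxon = "S")
  gS <- buildGraph(pairwiseSimilarity(sph), sph)
  resS <- classifyGraphShape(wholeCluster(sph), gS)
  expect_equal(resS@clusterTable$shape, "spherical")
  # monomer (500 bp) longer than the read: circular permutation -> ring
  rng <- tiledReads(rdna(500, seed = 42), n = 60, taxon = "R")
  gR <- buildGraph(pairwiseSimilarity(rng), rng)
  resR <- classifyGraphShape(wholeCluster(rng), gR)
  expect_equal(resR@clusterTable$shape, "ring")
  # reads tiled along a non-repetitive stretch: linear
  src <- rdna(1500, seed = 46)
  starts <- round(seq(1, 1400, length.out = 50))
  lin <- mkReadSet(setNames(substring(src, starts, starts + 99),
                            sprintf("l%02d", 1:50)), taxon = "L")
  gL <- buildGraph(pairwiseSimilarity(lin), lin)
  resL <- classifyGraphShape(wholeCluster(lin), gL)
  expect_equal(resL@clusterTable$shape, "linear")
  # size floor
  tiny <- mkReadSet(setNames(rep(rdna(100, seed = 43), 4), paste0("r", 1:4)))
  gT <- buildGraph(pairwiseSimilarity(tiny), tiny)
  resT <- classifyGraphShape(detectClusters(gT, seed = 1), gT)
  expect_equal(resT@clusterTable$shape, "other")
})

test_that("annotations attach by rank id with catch-all and referential integrity", {
  f1 <- rdna(100, seed = 44)
  rs <- mkReadSet(setNames(c(f1, mutateAt(f1, 1), rdna(100, seed = 45),
                             rdna(100, seed = 45)),
                           paste0("r", 1:4)))
  res <- detectClusters(buildGraph(pairwiseSimilarity(rs), rs), seed = 1)
  res2 <- attachAnnotations(res, c(CL1 = "Ty3/Gypsy"))
  expect_equal(annotations(res2)[["CL1"]], "Ty3/Gypsy")
  res3 <- attachAnnotations(res, c(CL1 = "LINE"))
  expect_equal(annotations(res3)[["CL1"]], "other/unclassified")
  expect_equal(res3@clusterTable$annotation_label[1], "LINE")
  expect_error(attachAnnotations(res, c(CL999 = "rDNA")), "CL999")
})
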