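# A small hand-built ClusteringResult used across matrix tests: three
# taxa so buildMatrix's unrooted-topology guard passes.
mkResult <- function() {
  members <- list(CL1 = c("A_r1", "A_r2", "A_r3", "B_r1"),
                  CL2 = c("B_r2", "B_r3"))
  counts <- matrix(c(3L, 1L, 0L, 0L, 2L, 0L), 2, 3, byrow = TRUE,
                   dimnames = list(c("CL1", "CL2"), c("A", "B", "C")))
  tab <- data.frame(rank_id = c("CL1", "CL2"), size = c(4L, 2L),
                    shape = NA_character_,
                    annotation = c("Ty3/Gypsy", "satellite"),
                    annotation_label = c("Ty3/Gypsy", "satellite"),
                    stringsAsFactors = FALSE)
  new("ClusteringResult", clusterTable = tab, members = members,
      singletons = character(0), counts = counts,
      params = list(seed = 1L))
}

test_that("buildMatrix transcribes counts with zero-fill, truncation and guards", {
  res <- mkResult()
  m <- buildMatrix(res, topN = 2)
  expect_equal(abundances(m),
               matrix(c(3, 0, 1, 2, 0, 0), 3, 2, byrow = TRUE,
                      dimnames = list(c("A", "B", "C"), c("CL1", "CL2"))))
  expect_identical(annotations(m)[["CL1"]], "Ty3/Gypsy")
  m1 <- buildMatrix(res, topN = 1)
  expect_identical(clusterIds(m1), "CL1")
  expect_warning(buildMatrix(res, topN = 10), "only 2 clusters")
  # fewer than 3 taxa is an error
  res2 <- mkResult()
  res2@counts <- res2@counts[, 1:2]
  expect_error(buildMatrix(res2, topN = 2), "3 taxa")
})

test_that("equal-size clusters order columns by the rank tie-break", {
  members <- list(CL1 = c("A_r1", "B_r1"), CL2 = c("A_r2", "B_r2"))
  counts <- matrix(1L, 2, 2, dimnames = list(c("CL1", "CL2"), c("A", "B")))
  counts <- cbind(counts, C = c(0L, 0L))
  tab <- data.frame(rank_id = c("CL1", "CL2"), size = c(2L, 2L),
                    shape = NA_character_, annotation = NA_character_,
                    annotation_label = NA_character_)
  res <- new("ClusteringResult", clusterTable = tab, members = members,
             singletons = character(0), counts = counts, params = list())
  # tie-break: CL1 must hold the smallest member read id
  expect_true(min(members$CL1) < min(members$CL2))
  m <- buildMatrix(res, topN = 2)
  expect_identical(clusterIds(m), c("CL1", "CL2"))
})

test_that("TNT scaling attains exactly 65 and preserves ratios", {
  v <- matrix(c(1300, 650, 0, 130, 13, 65), 3, 2,
              dimnames = list(c("A", "B", "C"), c("CL1", "CL2")))
  m <- mkAM(v)
  s <- tntScale(m)
  expect_equal(scalingInfo(s)$factor, 20)        # 1300 / 65
  expect_equal(abundances(s)["A", "CL1"], 65)
  expect_equal(abundances(s)["B", "CL1"], 32.5)
  expect_equal(abundances(s) * 20, v)            # ratios preserved exactly
  # fixed point
  m65 <- mkAM(matrix(c(65, 1, 2, 3, 4, 5), 3, 2,
                     dimnames = dimnames(v)))
  expect_equal(max(abundances(tntScale(m65))), 65)
  expect_equal(scalingInfo(tntScale(m65))$factor, 1)
  # any random positive matrix: post-scaling max is exactly 65
  set.seed(51)
  for (i in 1:10) {
    r <- mkAM(matrix(runif(12, 0, 10^sample(1:6, 1)), 3, 4,
                     dimnames = list(c("A", "B", "C"), paste0("CL", 1:4))))
    expect_equal(max(abundances(tntScale(r))), 65)
  }
  expect_error(tntScale(mkAM(matrix(0, 3, 1,
    dimnames = list(c("A", "B", "C"), "CL1")))), "all-zero")
  expect_error(tntScale(s), "already scaled")
})

test_that("frequency scaling maps onto [0, 1] with max exactly 1, order preserved", {
  v <- matrix(c(500, 50, 5, 0, 17, 400), 3, 2,
              dimnames = list(c("A", "B", "C"), c("CL1", "CL2")))
  f <- frequencyScale(mkAM(v))
  a <- abundances(f)
  expect_equal(a["B", "CL1"], 0.1)
  expect_equal(max(a), 1)
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(order(v), order(a))  # monotone map
  expect_error(frequencyScale(mkAM(matrix(0, 3, 1,
    dimnames = list(c("A", "B", "C"), "CL1")))), "all-zero")
})

test_that("partitioning is lossless with the documented block structure", {
  set.seed(52)
  v <- matrix(runif(3 * 1000), 3, 1000,
              dimnames = list(c("A", "B", "C"), paste0("CL", 1:1000)))
  m <- mkAM(v)
  blocks <- partitionMatrix(m, 150)
  expect_length(blocks, 7L)
  expect_equal(vapply(blocks, function(b) ncol(abundances(b)), numeric(1)),
               c(rep(150, 6), 100))
  expect_equal(do.call(cbind, lapply(blocks, abundances)), v)
  expect_length(partitionMatrix(m, 2000), 1L)
  expect_length(partitionMatrix(m, 1), 1000L)
})

test_that("annotation subsets keep order and re-unite to the original", {
  ann <- c("Ty3/Gypsy", "Ty1/Copia", "Ty3/Gypsy", "satellite", "Ty3/Gypsy")
  v <- matrix(seq_len(15), 3, 5,
              dimnames = list(c("A", "B", "C"), paste0("CL", 1:5)))
  m <- mkAM(v, annotations = ann)
  g <- subsetByAnnotation(m, "Ty3/Gypsy")
  expect_identical(clusterIds(g), c("CL1", "CL3", "CL5"))
  expect_error(subsetByAnnotation(m, "rDNA"), "available")
  united <- unlist(lapply(unique(ann), function(a)
    clusterIds(subsetByAnnotation(m, a))))
  expect_setequal(united, colnames(v))
})

test_that("range matrices implement mean +/- SE with the zero floor", {
  dm <- list(c("A", "B", "C"), "CL1")
  reps <- lapply(c(10, 12, 14), function(x)
    mkAM(matrix(c(x, 5, 1), 3, 1, dimnames = dm)))
  rm_ <- rangeMatrix(reps)
  # cell A: replicates {10,12,14}: mean 12, SD 2, SE 2/sqrt(3)
  se <- 2 / sqrt(3)
  expect_equal(abundances(rm_)$lo["A", "CL1"], 12 - se, tolerance = 1e-12)
  expect_equal(abundances(rm_)$hi["A", "CL1"], 12 + se, tolerance = 1e-12)
  # identical replicates: lo == hi == mean
  expect_equal(abundances(rm_)$lo["B", "CL1"], 5)
  expect_equal(abundances(rm_)$hi["B", "CL1"], 5)
  # clamping: mean 1 with large SE floors at 0
  reps2 <- lapply(c(0, 0, 3), function(x)
    mkAM(matrix(c(x, 5, 1), 3, 1, dimnames = dm)))
  expect_equal(abundances(rangeMatrix(reps2))$lo["A", "CL1"], 0)
  # lo <= mean <= hi everywhere on random replicates
  set.seed(53)
  reps3 <- lapply(1:4, function(i)
    mkAM(matrix(runif(9, 0, 50), 3, 3,
                dimnames = list(c("A", "B", "C"), paste0("CL", 1:3)))))
  rm3 <- rangeMatrix(reps3)
  mean3 <- Reduce(`+`, lapply(reps3, abundances)) / 4
  expect_true(all(abundances(rm3)$lo <= mean3 + 1e-12))
  expect_true(all(abundances(rm3)$hi >= mean3 - 1e-12))
  # mismatched cluster sets are refused with the difference named
  bad <- mkAM(matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), "CL9")))
  expect_error(rangeMatrix(list(reps[[1]], bad)), "CL9")
})

test_that("TNT files round-trip values and ranges at 3-decimal precision", {
  v <- matrix(c(65, 32.512, 0.004, 12.3456), 2, 2,
              dimnames = list(c("TaxA", "TaxB"), c("CL1", "CL2")))
  m <- AbundanceMatrix(v, scaling = list(type = "tnt", factor = 1))
  path <- withr::local_tempfile(fileext = ".tnt")
  writeTNT(m, path)
  back <- readTNT(path)
  expect_s4_class(back, "AbundanceMatrix")
  expect_equal(unname(abundances(back)), unname(round(v, 3)))
  expect_identical(taxa(back), c("TaxA", "TaxB"))
  # ranges
  lo <- matrix(c(10.845, 3, 0, 1), 2, 2,
               dimnames = dimnames(v))
  hi <- matrix(c(13.155, 3, 0.5, 1), 2, 2, dimnames = dimnames(v))
  rm_ <- new("RangeMatrix", lo = lo, hi = hi,
             annotations = c(NA_character_, NA_character_),
             provenance = list(nReplicates = 3L, seMultiplier = 1))
  writeTNT(rm_, path)
  back2 <- readTNT(path)
  expect_s4_class(back2, "RangeMatrix")
  expect_equal(unname(abundances(back2)$lo), unname(lo))
  expect_equal(unname(abundances(back2)$hi), unname(hi))
  # refusal of unscaled values beyond the TNT bound
  big <- mkAM(matrix(c(1300, 1, 2, 3), 2, 2, dimnames = dimnames(v)))
  expect_error(writeTNT(big, path), "tntScale")
})

test_that("the ML frequency table round-trips", {
  v <- matrix(c(1, 0.25, 0.003141, 0, 0.5, 1), 3, 2,
              dimnames = list(c("A", "B", "C"), c("CL1", "CL2")))
  m <- AbundanceMatrix(v, scaling = list(type = "frequency", factor = 500))
  path <- withr::local_tempfile(fileext = ".tab")
  writeFrequencyTable(m, path)
  back <- readFrequencyTable(path)
  expect_equal(unname(abundances(back)), unname(round(v, 6)))
  expect_identical(taxa(back), taxa(m))
})
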