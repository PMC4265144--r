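# Method-performance experiments: genome-proportion titration,
# cluster-number titration, matrix partitions, and repeat-type
# informativeness. Each record carries the condition it was measured
# under, so every run is regenerable from its seed.

# One MP analysis with supports; returns summary fields shared by all
# experiment records.
.mpAnalysis <- function(m, resampleReplicates, seed, referenceTree = NULL) {
  sr <- symmetricResampling(m, replicates = resampleReplicates,
                            seed = seed, archive = FALSE)
  sup <- sr$supports
  tree <- sr$tree
  internal <- .splitKeys(tree)
  meanSupport <- if (length(internal))
    mean(ifelse(is.na(sup[internal]), 0, sup[internal])) else NA_real_
  nTip <- length(tree$tip.label)
  resolved <- tree$Nnode == nTip - 2L   # fully binary unrooted tree
  match_ <- if (is.null(referenceTree)) NA else
    length(sr$mpts) == 1L && sameTopology(sr$mpts[[1]], referenceTree)
  list(tree = tree, mean_support = meanSupport, resolved = resolved,
       topology_match = match_)
}

# cluster one set of sampled ReadSets and return the abundance matrix
.clusterToMatrix <- function(readsets, seed, minIdentity = 90,
                             minCov = 0.55, topN = Inf) {
  hits <- pairwiseSimilarity(readsets, minIdentity = minIdentity,
                             minCov = minCov)
  g <- buildGraph(hits, readsets)
  res <- detectClusters(g, seed = seed)
  if (nrow(res@clusterTable) == 0) return(NULL)
  suppressWarnings(buildMatrix(res, topN = min(topN, nrow(res@counts))))
}

#' Genome-proportion titration
#'
#' Repeats the full pipeline (sample reads at a GP level, cluster,
#' build the matrix, parsimony tree with symmetric-resampling supports)
#' across a ladder of genome proportions with replicate samplings, to
#' find the minimal GP at which inference is reproducible. The default
#' ladder doubles from 0.005% to 5.12% (11 levels).
#'
#' @param readsets List of trimmed [ReadSet-class] objects (one per
#'   taxon, with genome sizes).
#' @param gpLevels Genome-proportion levels in percent.
#' @param replicates Replicate samplings per level (default 3).
#' @param referenceTree Expected topology (`phylo`) for
#'   `topology_match`.
#' @param seed Integer base seed.
#' @param resampleReplicates Symmetric-resampling replicates per tree.
#' @param minIdentity,minCov Clustering thresholds.
#' @return A `data.frame` of performance records (one row per level x
#'   replicate): `gp_percent`, `replicate`, `n_clusters`,
#'   `mean_support`, `resolved`, `topology_match`, `seed`.
#' @export
gpTitration <- function(readsets, gpLevels = 0.005 * 2^(0:10),
                        replicates = 3, referenceTree = NULL, seed = 1L,
                        resampleReplicates = 200, minIdentity = 90,
                        minCov = 0.55) {
  rec <- list()
  for (li in seq_along(gpLevels)) {
    gp <- gpLevels[li]
    for (rep_ in seq_len(replicates)) {
      s <- seed + 1000L * li + rep_
      sampled <- tryCatch(
        lapply(readsets, sampleToGenomeProportion, gpPercent = gp,
               seed = s),
        error = function(e) e)
      if (inherits(sampled, "error")) {
        warning("GP ", gp, "% skipped: ", conditionMessage(sampled))
        next
      }
      m <- .clusterToMatrix(sampled, seed = s, minIdentity = minIdentity,
                            minCov = minCov)
      if (is.null(m)) {
        warning("GP ", gp, "% replicate ", rep_,
                ": no clusters formed; skipped")
        next
      }
      an <- .mpAnalysis(m, resampleReplicates, seed = s,
                        referenceTree = referenceTree)
      rec[[length(rec) + 1L]] <- data.frame(
        gp_percent = gp, replicate = rep_, n_clusters = ncol(m@values),
        mean_support = an$mean_support, resolved = an$resolved,
        topology_match = an$topology_match, seed = s)
    }
  }
  do.call(rbind, rec)
}

#' Cluster-number titration
#'
#' Infers trees from the top-k clusters for a grid of k, to find how
#' many characters are needed to resolve the tree with high support.
#'
#' @param matrices An [AbundanceMatrix-class] or list of them (one per
#'   dataset/replicate).
#' @param counts Cluster-count grid (default
#'   `c(5, 15, 25, 35, 45, 75, 150, 300, 600, 1000)`).
#' @param referenceTree,seed,resampleReplicates As in [gpTitration()].
#' @return A `data.frame` of records: `n_clusters`, `dataset`,
#'   `mean_support`, `resolved`, `topology_match`, `seed`.
#' @export
clusterNumberTitration <- function(matrices,
                                   counts = c(5, 15, 25, 35, 45, 75,
                                              150, 300, 600, 1000),
                                   referenceTree = NULL, seed = 1L,
                                   resampleReplicates = 200) {
  if (is(matrices, "AbundanceMatrix")) matrices <- list(matrices)
  rec <- list()
  for (di in seq_along(matrices)) {
    m <- matrices[[di]]
    for (k in counts) {
      if (k > ncol(m@values)) {
        warning("count ", k, " exceeds available clusters (",
                ncol(m@values), "); skipped")
        next
      }
      s <- seed + 1000L * di + k
      mk <- new("AbundanceMatrix",
                values = m@values[, seq_len(k), drop = FALSE],
                annotations = m@annotations[seq_len(k)],
                scaling = m@scaling, gpPercent = m@gpPercent)
      an <- .mpAnalysis(mk, resampleReplicates, seed = s,
                        referenceTree = referenceTree)
      rec[[length(rec) + 1L]] <- data.frame(
        n_clusters = k, dataset = di, mean_support = an$mean_support,
        resolved = an$resolved, topology_match = an$topology_match,
        seed = s)
    }
  }
  do.call(rbind, rec)
}

#' Partition analysis of phylogenetic signal across the matrix
#'
#' Splits each matrix into consecutive rank-order blocks (default 150
#' clusters) and infers a tree per block, flagging blocks whose tree
#' conflicts with the reference — a map of where in the abundance
#' spectrum the signal lives. Supply one matrix per GP level to
#' reproduce the GP comparison.
#'
#' @param matrices Named list of [AbundanceMatrix-class] objects (names
#'   identify the condition, e.g. the GP level), or a single matrix.
#' @param blockSize Clusters per partition (default 150).
#' @param referenceTree,seed,resampleReplicates As in [gpTitration()].
#' @return A `data.frame`: `condition`, `partition_index`,
#'   `n_clusters`, `mean_support`, `resolved`, `topology_match`
#'   (`FALSE` marks inconsistent groupings), `seed`.
#' @export
partitionAnalysis <- function(matrices, blockSize = 150,
                              referenceTree = NULL, seed = 1L,
                              resampleReplicates = 200) {
  if (is(matrices, "AbundanceMatrix")) matrices <- list(full = matrices)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("set", seq_along(matrices))
  rec <- list()
  for (ci in seq_along(matrices)) {
    blocks <- partitionMatrix(matrices[[ci]], blockSize = blockSize)
    for (bi in seq_along(blocks)) {
      s <- seed + 1000L * ci + bi
      an <- .mpAnalysis(blocks[[bi]], resampleReplicates, seed = s,
                        referenceTree = referenceTree)
      rec[[length(rec) + 1L]] <- data.frame(
        condition = names(matrices)[ci], partition_index = bi,
        n_clusters = ncol(blocks[[bi]]@values),
        mean_support = an$mean_support, resolved = an$resolved,
        topology_match = an$topology_match, seed = s)
    }
  }
  do.call(rbind, rec)
}

#' Relative informativeness of repeat types
#'
#' Subsets the matrix to each annotation category in turn, infers an MP
#' tree with symmetric-resampling supports, and reports the mean
#' bootstrap over internal branches as a proxy for tree resolution.
#' Empty categories are skipped with a warning.
#'
#' @param m An annotated [AbundanceMatrix-class].
#' @param types Annotation categories to assess (default: all six).
#' @param seed,resampleReplicates As in [gpTitration()].
#' @param referenceTree Optional expected topology.
#' @return A `data.frame`: `repeat_type`, `n_clusters`, `mean_support`,
#'   `resolved`, `topology_match`, `seed` — one row per non-empty
#'   category.
#' @export
repeatTypeInformativeness <- function(m, types = .annotationCategories,
                                      seed = 1L, resampleReplicates = 200,
                                      referenceTree = NULL) {
  stopifnot(is(m, "AbundanceMatrix"))
  rec <- list()
  for (ti in seq_along(types)) {
    sub <- tryCatch(subsetByAnnotation(m, types[ti]),
                    error = function(e) NULL)
    if (is.null(sub)) {
      warning("no clusters annotated '", types[ti], "'; skipped")
      next
    }
    s <- seed + 1000L * ti
    an <- .mpAnalysis(sub, resampleReplicates, seed = s,
                      referenceTree = referenceTree)
    rec[[length(rec) + 1L]] <- data.frame(
      repeat_type = types[ti], n_clusters = ncol(sub@values),
      mean_support = an$mean_support, resolved = an$resolved,
      topology_match = an$topology_match, seed = s)
  }
  do.call(rbind, rec)
}

#' Summarize performance records
#'
#' Mean and standard error of the mean support per condition.
#'
#' @param records A record `data.frame` from one of the experiment
#'   functions.
#' @param by Name of the condition column (guessed from the columns
#'   present when omitted).
#' @return A `data.frame` with `mean_support`, `se_support`, `n`, and
#'   the fraction of records matching the reference topology.
#' @export
summarizePerformance <- function(records, by = NULL) {
  if (is.null(by))
    by <- intersect(c("gp_percent", "n_clusters", "condition",
                      "repeat_type"), names(records))[1]
  sp <- split(records, records[[by]])
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    condition = d[[by]][1],
    mean_support = mean(d$mean_support, na.rm = TRUE),
    se_support = sd(d$mean_support, na.rm = TRUE) /
      sqrt(sum(!is.na(d$mean_support))),
    n = nrow(d),
    prop_topology_match = mean(d$topology_match, na.rm = TRUE))))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
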