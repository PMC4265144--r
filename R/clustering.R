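#' Partition the read graph into repeat-family clusters
#'
#' Communities are found by greedy weighted-modularity maximization
#' (Louvain), so that reads are more densely connected within clusters
#' than between them — each community is one repeat family (or a
#' conserved part of one). Communities in different connected components
#' are never merged (joining unconnected groups always lowers
#' modularity). Clusters of two or more reads are ranked CL1..CLm by
#' decreasing size, ties broken by the lexicographically smallest member
#' read id; size-1 communities are reported as singletons.
#'
#' @param g Read graph from [buildGraph()].
#' @param seed Integer seed fixing the node-visitation randomness of the
#'   community search; identical inputs and seed give identical results.
#' @return A [ClusteringResult-class].
#' @export
detectClusters <- function(g, seed = 1L) {
  nv <- igraph::vcount(g)
  emptyTab <- data.frame(rank_id = character(), size = integer(),
                         shape = character(), annotation = character(),
                         annotation_label = character(),
                         stringsAsFactors = FALSE)
  params <- list(seed = seed, algorithm = "louvain (greedy modularity)",
                 edge_weight = "alignment score")
  if (nv == 0)
    return(new("ClusteringResult", clusterTable = emptyTab, members = list(),
               singletons = character(), params = params,
               counts = matrix(0L, 0, 0)))
  comm <- .withSeed(seed, igraph::cluster_louvain(
    g, weights = if (igraph::ecount(g)) igraph::E(g)$weight else NULL))
  memb <- igraph::membership(comm)
  ids <- igraph::V(g)$name
  groups <- split(ids, memb)
  sizes <- lengths(groups)
  singles <- unlist(groups[sizes == 1L], use.names = FALSE)
  if (is.null(singles)) singles <- character(0)
  groups <- groups[sizes >= 2L]
  # rank: decreasing size, ties by smallest member read id
  minId <- vapply(groups, function(m) min(m), character(1))
  ord <- order(-lengths(groups), minId)
  groups <- unname(groups[ord])
  m <- length(groups)
  rank_id <- paste0("CL", seq_len(m))
  names(groups) <- rank_id
  taxAll <- sort(unique(.readTaxa(ids)))
  counts <- matrix(0L, m, length(taxAll),
                   dimnames = list(rank_id, taxAll))
  for (i in seq_len(m)) {
    tb <- table(.readTaxa(groups[[i]]))
    counts[i, names(tb)] <- as.integer(tb)
  }
  tab <- data.frame(rank_id = rank_id, size = lengths(groups),
                    shape = NA_character_, annotation = NA_character_,
                    annotation_label = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("ClusteringResult", clusterTable = tab, members = groups,
      singletons = sort(singles), counts = counts, params = params)
}

#' Per-taxon read counts per cluster
#'
#' The comparative counts of reads per cluster and taxon: at equal
#' genome proportion these are proportional to the genomic abundance of
#' each repeat family in each taxon. Taxa absent from a cluster are
#' recorded as 0, never missing. Singletons carry taxon-idiosyncratic
#' noise and are excluded by default.
#'
#' @param result A [ClusteringResult-class].
#' @param includeSingletons If `TRUE`, append each singleton read as an
#'   additional size-1 cluster (ranked after all true clusters).
#' @return Integer matrix, clusters (rows, `rank_id`) x taxa (columns).
#' @export
countAbundances <- function(result, includeSingletons = FALSE) {
  stopifnot(is(result, "ClusteringResult"))
  counts <- result@counts
  if (includeSingletons && length(result@singletons)) {
    s <- sort(result@singletons)
    extra <- matrix(0L, length(s), ncol(counts),
                    dimnames = list(
                      paste0("CL", nrow(counts) + seq_along(s)),
                      colnames(counts)))
    tx <- .readTaxa(s)
    for (i in seq_along(s)) extra[i, tx[i]] <- 1L
    counts <- rbind(counts, extra)
  }
  counts
}

#' Classify the graph shape of each cluster
#'
#' Tandem repeats with monomers shorter than the read length produce
#' densely interconnected ("spherical") cluster graphs, while monomers
#' longer than the read length produce ring-shaped graphs (reads sample
#' the monomer in circular permutation, so only phase-neighbours
#' overlap). The classifier uses graph diameter and the spread of node
#' eccentricities: a stretched graph (diameter at least
#' `minRingDiameter`) with near-uniform eccentricities is a ring (every
#' node lies on the cycle, there are no ends); a compact graph with
#' diameter at most `sphericalFactor * log(n)` is spherical; a
#' stretched graph with an end-to-centre eccentricity gradient is
#' linear; everything else (including clusters of fewer than `minSize`
#' reads or disconnected subgraphs) is "other". Thresholds are recorded
#' in `params`.
#'
#' @param result A [ClusteringResult-class].
#' @param g The read graph the clusters were detected on.
#' @param minSize Clusters smaller than this are labelled "other".
#' @param sphericalFactor Diameter threshold multiplier on `log(n)`.
#' @param ringEccCV Maximum coefficient of variation of eccentricities
#'   for a ring call.
#' @param minRingDiameter Minimum diameter for a ring call (cliques and
#'   dense cores also have uniform eccentricities, but tiny diameters).
#' @return The [ClusteringResult-class] with the `shape` column filled.
#' @export
classifyGraphShape <- function(result, g, minSize = 5,
                               sphericalFactor = 3, ringEccCV = 0.12,
                               minRingDiameter = 4) {
  stopifnot(is(result, "ClusteringResult"))
  shapes <- vapply(result@members, function(m) {
    n <- length(m)
    if (n < minSize) return("other")
    sub <- igraph::induced_subgraph(g, m)
    if (!igraph::is_connected(sub)) return("other")
    d <- igraph::diameter(sub, weights = NA)
    ecc <- igraph::eccentricity(sub, weights = NA)
    cv <- sd(ecc) / mean(ecc)
    if (d >= minRingDiameter && cv <= ringEccCV) return("ring")
    if (d <= sphericalFactor * log(n)) return("spherical")
    "linear"
  }, character(1))
  result@clusterTable$shape <- unname(shapes)
  result@params$shape <- list(minSize = minSize,
                              sphericalFactor = sphericalFactor,
                              ringEccCV = ringEccCV,
                              minRingDiameter = minRingDiameter)
  validObject(result)
  result
}

#' Attach repeat-type annotations to clusters
#'
#' Annotation labels (e.g. from BLAST of cluster contigs against a
#' repeat database, performed outside this package) are consumed as a
#' user-supplied table. Labels outside the six standard categories are
#' stored under "other/unclassified" with the original text retained.
#'
#' @param result A [ClusteringResult-class].
#' @param table Named character vector (`rank_id` -> label) or a
#'   `data.frame` with columns `rank_id` and `label`.
#' @return The annotated [ClusteringResult-class].
#' @export
attachAnnotations <- function(result, table) {
  stopifnot(is(result, "ClusteringResult"))
  if (is.data.frame(table))
    table <- setNames(as.character(table$label), table$rank_id)
  unknown <- setdiff(names(table), result@clusterTable$rank_id)
  if (length(unknown))
    stop("annotation table names unknown cluster(s): ",
         paste(unknown, collapse = ", "))
  idx <- match(names(table), result@clusterTable$rank_id)
  canon <- ifelse(table %in% .annotationCategories,
                  table, "other/unclassified")
  result@clusterTable$annotation[idx] <- canon
  result@clusterTable$annotation_label[idx] <- unname(table)
  validObject(result)
  result
}

#' Export a clustering result as a TSV table
#'
#' One row per cluster: rank id, size, shape, annotation and one read
#' count column per taxon.
#'
#' @param result A [ClusteringResult-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(result, path) {
  stopifnot(is(result, "ClusteringResult"))
  tab <- cbind(result@clusterTable, as.data.frame(result@counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
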