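#' Build the taxa x clusters abundance matrix
#'
#' Transcribes per-taxon cluster read counts into a continuous character
#' matrix: rows are taxa, columns are the `topN` most abundant clusters
#' in rank order (CL1 first), cells are raw read counts with taxa absent
#' from a cluster zero-filled. Counts are used raw — the equal
#' genome-proportion sampling upstream is what makes them comparable
#' across taxa.
#'
#' @param result A [ClusteringResult-class].
#' @param topN Number of most abundant clusters to keep (default 1000);
#'   if fewer exist, all are used with a warning.
#' @param includeSingletons Passed to [countAbundances()].
#' @return An unscaled [AbundanceMatrix-class].
#' @export
buildMatrix <- function(result, topN = 1000, includeSingletons = FALSE) {
  counts <- countAbundances(result, includeSingletons = includeSingletons)
  if (ncol(counts) < 3)
    stop("at least 3 taxa are required (no unrooted topology exists for ",
         ncol(counts), ")")
  if (nrow(counts) < topN) {
    warning("only ", nrow(counts), " clusters available; using all ",
            "(topN = ", topN, " requested)")
    topN <- nrow(counts)
  }
  keep <- seq_len(topN)
  values <- t(counts[keep, , drop = FALSE]) * 1.0
  ann <- result@clusterTable$annotation[
    match(rownames(counts)[keep], result@clusterTable$rank_id)]
  AbundanceMatrix(values, annotations = ann)
}

#' Scale a matrix into the TNT continuous-character range
#'
#' Divides every cell by `factor = max(values) / maxValue` so the global
#' maximum becomes exactly `maxValue` (65, the largest value the TNT
#' continuous-character implementation accepts). Relative ratios are
#' preserved exactly; the transformation only reranges the characters.
#'
#' @param m An unscaled [AbundanceMatrix-class].
#' @param maxValue Target global maximum (default 65).
#' @return The scaled [AbundanceMatrix-class] with scaling recorded.
#' @export
tntScale <- function(m, maxValue = 65) {
  stopifnot(is(m, "AbundanceMatrix"))
  if (m@scaling$type != "none")
    stop("matrix is already scaled (", m@scaling$type, ")")
  mx <- max(m@values)
  if (mx <= 0) stop("all-zero matrix cannot be scaled")
  fac <- mx / maxValue
  m@values <- m@values / fac
  m@scaling <- list(type = "tnt", factor = fac, maxValue = maxValue)
  validObject(m)
  m
}

#' Scale abundances to 0-1 frequencies
#'
#' Divides every cell by the single largest cell so values lie in
#' `[0, 1]` with maximum exactly 1, the representation expected by the
#' Brownian-motion likelihood module (abundances treated like allele
#' frequencies).
#'
#' @param m An unscaled [AbundanceMatrix-class].
#' @return The scaled [AbundanceMatrix-class] with scaling recorded.
#' @export
frequencyScale <- function(m) {
  stopifnot(is(m, "AbundanceMatrix"))
  if (m@scaling$type != "none")
    stop("matrix is already scaled (", m@scaling$type, ")")
  mx <- max(m@values)
  if (mx <= 0) stop("all-zero matrix cannot be scaled")
  m@values <- m@values / mx
  m@scaling <- list(type = "frequency", factor = mx)
  validObject(m)
  m
}

#' Partition a matrix into consecutive rank-order blocks
#'
#' Splits the columns into consecutive blocks of `blockSize` clusters
#' (the last block may be smaller); concatenating the blocks reproduces
#' the input. Used to probe how phylogenetic signal varies from the most
#' to the least abundant repeat families.
#'
#' @param m An [AbundanceMatrix-class].
#' @param blockSize Number of clusters per block (default 150).
#' @return Ordered list of [AbundanceMatrix-class] blocks.
#' @export
partitionMatrix <- function(m, blockSize = 150) {
  stopifnot(is(m, "AbundanceMatrix"), blockSize >= 1)
  nc <- ncol(m@values)
  starts <- seq(1L, nc, by = as.integer(blockSize))
  lapply(starts, function(s) {
    idx <- s:min(s + blockSize - 1L, nc)
    new("AbundanceMatrix", values = m@values[, idx, drop = FALSE],
        annotations = m@annotations[idx], scaling = m@scaling,
        gpPercent = m@gpPercent)
  })
}

#' Subset a matrix to one repeat-type annotation category
#'
#' @param m An [AbundanceMatrix-class] whose clusters carry annotations.
#' @param category One of the annotation categories (e.g. `"Ty3/Gypsy"`).
#' @return The [AbundanceMatrix-class] restricted to matching columns,
#'   order preserved.
#' @export
subsetByAnnotation <- function(m, category) {
  stopifnot(is(m, "AbundanceMatrix"))
  keep <- which(!is.na(m@annotations) & m@annotations == category)
  if (!length(keep)) {
    avail <- sort(unique(m@annotations[!is.na(m@annotations)]))
    stop("no clusters annotated '", category, "'; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  new("AbundanceMatrix", values = m@values[, keep, drop = FALSE],
      annotations = m@annotations[keep], scaling = m@scaling,
      gpPercent = m@gpPercent)
}

#' Ranged characters from replicate samplings
#'
#' Builds per-cell closed intervals `[mean - SE, mean + SE]` from two or
#' more abundance matrices obtained by independent read samplings, where
#' SE is the sample (n-1) standard deviation divided by `sqrt(r)`.
#' Lower bounds are floored at 0 (abundances are physically
#' non-negative). On ranged characters, taxa whose intervals overlap
#' contribute no parsimony steps, so taxa are only separated where they
#' differ by more than sampling noise.
#'
#' @param replicates List of >= 2 [AbundanceMatrix-class] objects with
#'   identical taxa and cluster columns (matched by rank id).
#' @param seMultiplier Half-width of the interval in SE units (default 1).
#' @return A [RangeMatrix-class].
#' @export
rangeMatrix <- function(replicates, seMultiplier = 1) {
  stopifnot(is.list(replicates), length(replicates) >= 2)
  vals <- lapply(replicates, function(m) {
    stopifnot(is(m, "AbundanceMatrix"))
    m@values
  })
  ref <- vals[[1]]
  for (v in vals[-1]) {
    if (!identical(rownames(v), rownames(ref)))
      stop("replicate matrices must share taxa (in the same order)")
    if (!identical(colnames(v), colnames(ref))) {
      d <- union(setdiff(colnames(v), colnames(ref)),
                 setdiff(colnames(ref), colnames(v)))
      stop("replicate matrices differ in clusters: ",
           paste(head(d, 10), collapse = ", "))
    }
  }
  r <- length(vals)
  arr <- array(unlist(vals), dim = c(dim(ref), r))
  mean_ <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), sd) / sqrt(r)
  lo <- mean_ - seMultiplier * se
  lo[lo < 0] <- 0
  hi <- mean_ + seMultiplier * se
  dimnames(lo) <- dimnames(hi) <- dimnames(ref)
  new("RangeMatrix", lo = lo, hi = hi,
      annotations = replicates[[1]]@annotations,
      provenance = list(nReplicates = r, seMultiplier = seMultiplier))
}
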