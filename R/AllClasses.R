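#' ReadSet: taxon-coded short reads plus genome size
#'
#' A set of single-end DNA reads from one taxon, carried as a
#' [Biostrings::DNAStringSet] whose names are read identifiers prefixed
#' with the taxon code (`<code>_<id>`). The 1C genome size (bp) is the
#' denominator used when sampling reads to a target genome proportion.
#'
#' @slot reads A [Biostrings::DNAStringSet]; names are unique read ids.
#' @slot taxonCode Single string matching `[A-Za-z0-9]{1,8}`.
#' @slot genomeSize1C 1C genome size in bp, or `NA` when unknown.
#' @slot readLength Common read length in bp after trimming, or `NA`
#'   when reads are not (yet) uniform.
#' @slot log Named list of processing counts (reads dropped, sampled, ...).
#'
#' @seealso [loadReads()], [trimAndFilter()], [sampleToGenomeProportion()]
#' @exportClass ReadSet
setClass("ReadSet",
  representation(
    reads = "DNAStringSet",
    taxonCode = "character",
    genomeSize1C = "numeric",
    readLength = "numeric",
    log = "list"
  ),
  prototype(genomeSize1C = NA_real_, readLength = NA_real_, log = list())
)

setValidity("ReadSet", function(object) {
  msg <- character()
  if (length(object@taxonCode) != 1L ||
      !grepl("^[A-Za-z0-9]{1,8}$", object@taxonCode))
    msg <- c(msg, "taxonCode must match [A-Za-z0-9]{1,8}")
  nm <- names(object@reads)
  if (length(object@reads) > 0) {
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      msg <- c(msg, "all reads must be named")
    else {
      if (anyDuplicated(nm))
        msg <- c(msg, "read ids must be unique")
      if (!all(startsWith(nm, paste0(object@taxonCode, "_"))))
        msg <- c(msg, "read ids must carry the '<taxonCode>_' prefix")
    }
  }
  if (!is.na(object@readLength) && length(object@reads) > 0 &&
      !all(Biostrings::width(object@reads) == object@readLength))
    msg <- c(msg, "readLength does not match the widths of the reads")
  if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#'
#' @param reads A [Biostrings::DNAStringSet] (or object coercible to one).
#'   Names that do not already start with `<taxonCode>_` are prefixed.
#' @param taxonCode Short taxon code (`[A-Za-z0-9]{1,8}`).
#' @param genomeSize1C 1C genome size in bp (`NA` if unknown).
#' @param log Optional named list of processing counts.
#' @return A [ReadSet-class] object.
#' @export
ReadSet <- function(reads, taxonCode, genomeSize1C = NA_real_, log = list()) {
  reads <- methods::as(reads, "DNAStringSet")
  nm <- names(reads)
  if (is.null(nm))
    nm <- if (length(reads)) sprintf("r%06d", seq_along(reads))
          else character(0)
  pre <- paste0(taxonCode, "_")
  fix <- !startsWith(nm, pre)
  nm[fix] <- paste0(pre, nm[fix])
  names(reads) <- nm
  w <- Biostrings::width(reads)
  rl <- if (length(w) > 0 && length(unique(w)) == 1L) w[1] else NA_real_
  new("ReadSet", reads = reads, taxonCode = taxonCode,
      genomeSize1C = as.numeric(genomeSize1C), readLength = as.numeric(rl),
      log = log)
}

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet for taxon '", object@taxonCode, "': ",
      length(object@reads), " reads", sep = "")
  if (!is.na(object@readLength))
    cat(", uniform length ", object@readLength, " bp", sep = "")
  if (!is.na(object@genomeSize1C))
    cat("; 1C = ", format(object@genomeSize1C, big.mark = ","), " bp",
        sep = "")
  cat("\n")
})

#' ClusteringResult: repeat-family partition of a read-similarity graph
#'
#' Communities of the read graph found by maximum modularity, ranked by
#' size as CL1, CL2, ... (ties broken by the lexicographically smallest
#' member read id). Size-1 communities are kept apart as singletons.
#'
#' @slot clusterTable `data.frame` with columns `rank_id`, `size`,
#'   `shape`, `annotation`, `annotation_label`.
#' @slot members Named list, `rank_id` -> character vector of read ids.
#' @slot singletons Character vector of read ids in size-1 communities.
#' @slot counts Integer matrix, clusters x taxa, of member read counts.
#' @slot params Named list recording thresholds, seed and options used.
#'
#' @seealso [detectClusters()], [countAbundances()], [buildMatrix()]
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(
    clusterTable = "data.frame",
    members = "list",
    singletons = "character",
    counts = "matrix",
    params = "list"
  )
)

setValidity("ClusteringResult", function(object) {
  msg <- character()
  tab <- object@clusterTable
  if (nrow(tab) != length(object@members))
    msg <- c(msg, "clusterTable rows and members must correspond")
  all_members <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(c(all_members, object@singletons)))
    msg <- c(msg, "clusters and singletons must be disjoint")
  if (nrow(tab) > 0) {
    sizes <- lengths(object@members)
    if (!all(tab$size == sizes))
      msg <- c(msg, "cluster sizes must equal member counts")
    if (is.unsorted(-tab$size))
      msg <- c(msg, "clusters must be ranked by decreasing size")
    if (!identical(tab$rank_id, paste0("CL", seq_len(nrow(tab)))))
      msg <- c(msg, "rank ids must be CL1..CLm in order")
    if (nrow(object@counts) == nrow(tab) &&
        !all(rowSums(object@counts) == sizes))
      msg <- c(msg, "per-taxon counts must sum to cluster sizes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult: ", nrow(object@clusterTable), " clusters (>= 2 reads), ",
      length(object@singletons), " singletons, ",
      ncol(object@counts), " taxa\n", sep = "")
  if (nrow(object@clusterTable) > 0) {
    cat("Largest clusters:\n")
    print(head(object@clusterTable, 5))
  }
})

#' AbundanceMatrix: taxa x clusters continuous characters
#'
#' Real-valued matrix of per-taxon repeat-cluster abundances (raw read
#' counts, TNT-scaled values with maximum 65, or 0-1 frequencies), with
#' provenance of the scaling applied.
#'
#' @slot values Numeric matrix, taxa (rows) x clusters (columns), >= 0.
#' @slot annotations Character vector of per-cluster annotation
#'   categories (`NA` when unannotated).
#' @slot scaling List `list(type, factor)`; `type` is one of `"none"`,
#'   `"tnt"`, `"frequency"`.
#' @slot gpPercent Named numeric of per-taxon genome proportions (%), or
#'   `NA` when unknown.
#'
#' @seealso [buildMatrix()], [tntScale()], [frequencyScale()], [writeTNT()]
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix",
  representation(
    values = "matrix",
    annotations = "character",
    scaling = "list",
    gpPercent = "numeric"
  ),
  prototype(scaling = list(type = "none", factor = NA_real_),
            gpPercent = NA_real_)
)

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(v < 0)) msg <- c(msg, "abundances must be non-negative")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry taxon rownames and cluster colnames")
  if (length(object@annotations) != ncol(v))
    msg <- c(msg, "one annotation per cluster column required")
  type <- object@scaling$type
  if (is.null(type) || !type %in% c("none", "tnt", "frequency"))
    msg <- c(msg, "scaling$type must be 'none', 'tnt' or 'frequency'")
  else if (length(v) > 0) {
    if (type == "tnt" && max(v) > 65 + 1e-9)
      msg <- c(msg, "tnt-scaled values must not exceed 65")
    if (type == "frequency" && max(v) > 1 + 1e-12)
      msg <- c(msg, "frequency-scaled values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values Numeric taxa x clusters matrix with dimnames.
#' @param annotations Optional per-column annotation categories.
#' @param scaling Scaling record, `list(type, factor)`.
#' @param gpPercent Optional named per-taxon genome proportions (%).
#' @return An [AbundanceMatrix-class].
#' @export
AbundanceMatrix <- function(values,
                            annotations = rep(NA_character_, ncol(values)),
                            scaling = list(type = "none", factor = NA_real_),
                            gpPercent = NA_real_) {
  new("AbundanceMatrix", values = values, annotations = annotations,
      scaling = scaling, gpPercent = gpPercent)
}

setMethod("show", "AbundanceMatrix", function(object) {
  v <- object@values
  cat("AbundanceMatrix: ", nrow(v), " taxa x ", ncol(v), " clusters; scaling: ",
      object@scaling$type, "\n", sep = "")
  if (length(v) > 0)
    cat("value range [", format(min(v)), ", ", format(max(v)), "]\n", sep = "")
  print(v[, seq_len(min(5L, ncol(v))), drop = FALSE])
  if (ncol(v) > 5) cat("... (", ncol(v) - 5L, " more clusters)\n", sep = "")
})

#' RangeMatrix: per-cell abundance intervals (mean +/- 1 SE)
#'
#' Ranged continuous characters built from replicate read samplings:
#' each cell is the closed interval mean +/- one standard error of the
#' mean, floored at 0. Interval parsimony charges no steps where ranges
#' overlap across taxa, so sampling noise does not masquerade as change.
#'
#' @slot lo,hi Numeric matrices (taxa x clusters) with `lo <= hi`.
#' @slot annotations Per-cluster annotation categories.
#' @slot provenance List with `nReplicates` and `seMultiplier`.
#'
#' @seealso [rangeMatrix()], [treeLength()]
#' @exportClass RangeMatrix
setClass("RangeMatrix",
  representation(
    lo = "matrix",
    hi = "matrix",
    annotations = "character",
    provenance = "list"
  )
)

setValidity("RangeMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@lo), dim(object@hi)))
    msg <- c(msg, "lo and hi must have identical dimensions")
  else if (any(object@lo > object@hi + 1e-12))
    msg <- c(msg, "lo must be <= hi elementwise")
  if (any(object@lo < 0)) msg <- c(msg, "lower bounds must be >= 0")
  nr <- object@provenance$nReplicates
  if (is.null(nr) || nr < 2)
    msg <- c(msg, "a RangeMatrix requires >= 2 replicate matrices")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RangeMatrix", function(object) {
  cat("RangeMatrix: ", nrow(object@lo), " taxa x ", ncol(object@lo),
      " clusters; mean +/- ", object@provenance$seMultiplier,
      " SE from ", object@provenance$nReplicates, " replicates\n", sep = "")
})

# ---- accessors -------------------------------------------------------------

#' @describeIn ReadSet Number of reads.
#' @param x,object A ReadSet.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' Accessors for repeatphylo classes
#'
#' `reads()` returns the underlying `DNAStringSet`; `taxonCode()`,
#' `genomeSize1C()` and `readLength()` return the corresponding ReadSet
#' fields. `taxa()` returns taxon codes, `clusterIds()` cluster rank ids,
#' `abundances()` the numeric matrix of an [AbundanceMatrix-class] (or the
#' `lo`/`hi` bounds of a [RangeMatrix-class] as a list), `annotations()`
#' per-cluster annotation categories, `clusterCounts()` the clusters x
#' taxa count matrix of a [ClusteringResult-class], and `singletons()` its
#' size-1 communities.
#'
#' @param x An object of the documented classes.
#' @return See the per-function description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))
#' @rdname accessors
#' @export
setMethod("reads", "ReadSet", function(x) x@reads)

#' @rdname accessors
#' @export
setGeneric("taxonCode", function(x) standardGeneric("taxonCode"))
#' @rdname accessors
#' @export
setMethod("taxonCode", "ReadSet", function(x) x@taxonCode)

#' @rdname accessors
#' @export
setGeneric("genomeSize1C", function(x) standardGeneric("genomeSize1C"))
#' @rdname accessors
#' @export
setMethod("genomeSize1C", "ReadSet", function(x) x@genomeSize1C)

#' @rdname accessors
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))
#' @rdname accessors
#' @export
setMethod("readLength", "ReadSet", function(x) x@readLength)

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setMethod("taxa", "AbundanceMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("taxa", "RangeMatrix", function(x) rownames(x@lo))
#' @rdname accessors
#' @export
setMethod("taxa", "ClusteringResult", function(x) colnames(x@counts))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setMethod("clusterIds", "AbundanceMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("clusterIds", "RangeMatrix", function(x) colnames(x@lo))
#' @rdname accessors
#' @export
setMethod("clusterIds", "ClusteringResult", function(x) x@clusterTable$rank_id)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "AbundanceMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("abundances", "RangeMatrix", function(x) list(lo = x@lo, hi = x@hi))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "AbundanceMatrix",
          function(x) setNames(x@annotations, colnames(x@values)))
#' @rdname accessors
#' @export
setMethod("annotations", "ClusteringResult",
          function(x) setNames(x@clusterTable$annotation, x@clusterTable$rank_id))

#' @rdname accessors
#' @export
setGeneric("clusterCounts", function(x) standardGeneric("clusterCounts"))
#' @rdname accessors
#' @export
setMethod("clusterCounts", "ClusteringResult", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setMethod("singletons", "ClusteringResult", function(x) x@singletons)

#' @rdname accessors
#' @export
setGeneric("scalingInfo", function(x) standardGeneric("scalingInfo"))
#' @rdname accessors
#' @export
setMethod("scalingInfo", "AbundanceMatrix", function(x) x@scaling)
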