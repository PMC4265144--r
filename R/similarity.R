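# Shared local-alignment similarity engine.
#
# Scoring follows megablast-like constants: match +5, mismatch -4, gap
# open -12, gap extend -2. Identity is matches / alignment columns * 100
# and coverage is the aligned span of the read divided by the (uniform)
# read length; both strands are tested and the better-scoring
# orientation kept.

.SIM_SCORING <- list(match = 5, mismatch = -4, gapOpening = 12, gapExtension = 2)

.simSubstMatrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(
    match = .SIM_SCORING$match, mismatch = .SIM_SCORING$mismatch,
    baseOnly = FALSE)
}

# Align each pattern against `subject` on both strands; return per-pattern
# best score, identity (%), and coverage (fraction of the pattern length).
.bestLocalAlignment <- function(patterns, subject,
                                substMatrix = .simSubstMatrix()) {
  stats <- function(pats, subj) {
    pwa <- Biostrings::pairwiseAlignment(
      pats, subj, type = "local", substitutionMatrix = substMatrix,
      gapOpening = .SIM_SCORING$gapOpening,
      gapExtension = .SIM_SCORING$gapExtension)
    list(score = Biostrings::score(pwa),
         identity = Biostrings::pid(pwa, type = "PID1"),
         coverage = Biostrings::width(Biostrings::pattern(pwa)) /
           Biostrings::width(patterns))
  }
  fw <- stats(patterns, subject)
  rv <- stats(patterns, Biostrings::reverseComplement(
    methods::as(subject, "DNAString")))
  useRv <- rv$score > fw$score
  data.frame(
    score = ifelse(useRv, rv$score, fw$score),
    identity = ifelse(useRv, rv$identity, fw$identity),
    coverage = ifelse(useRv, rv$coverage, fw$coverage)
  )
}

#' All-against-all read similarity above a threshold
#'
#' Finds every unordered read pair whose best local alignment (both
#' strands tested) reaches at least `minIdentity` percent identity over
#' at least `minCov` of the read length — the clustering acceptance rule
#' of 90% similarity over 55% of the read length. Candidate pairs are
#' pre-screened by a shared exact `seedKmer`-mer, so pairs without any
#' shared seed word are never aligned.
#'
#' @param readsets A [ReadSet-class] or list of ReadSets (one per
#'   taxon); reads must all share one length.
#' @param minIdentity Minimum percent identity in `(0, 100]`.
#' @param minCov Minimum aligned fraction of the read length in `(0, 1]`.
#' @param seedKmer Exact-match seed length (default 13).
#' @return A `data.frame` of similarity hits with columns `read_a`,
#'   `read_b` (each unordered pair once, `read_a` first in input order),
#'   `identity`, `coverage`, `score`.
#' @export
pairwiseSimilarity <- function(readsets, minIdentity = 90, minCov = 0.55,
                               seedKmer = 13) {
  stopifnot(minIdentity > 0, minIdentity <= 100, minCov > 0, minCov <= 1)
  all <- .combineReads(readsets)
  emptyHits <- data.frame(read_a = character(), read_b = character(),
                          identity = numeric(), coverage = numeric(),
                          score = numeric())
  n <- length(all)
  if (n < 2) return(emptyHits)
  w <- unique(Biostrings::width(all))
  if (length(w) != 1)
    stop("reads must share one uniform length (coverage denominator); ",
         "found lengths ", paste(sort(w), collapse = ", "))
  pairs <- .candidatePairs(all, seedKmer)
  if (nrow(pairs) == 0) return(emptyHits)

  subst <- .simSubstMatrix()
  res <- vector("list", length(unique(pairs$j)))
  k <- 0L
  for (j in sort(unique(pairs$j))) {
    i_idx <- pairs$i[pairs$j == j]
    sc <- .bestLocalAlignment(all[i_idx], all[[j]], subst)
    keep <- sc$identity >= minIdentity & sc$coverage >= minCov
    if (any(keep)) {
      k <- k + 1L
      res[[k]] <- data.frame(
        read_a = names(all)[i_idx[keep]], read_b = names(all)[j],
        identity = sc$identity[keep], coverage = sc$coverage[keep],
        score = sc$score[keep])
    }
  }
  if (k == 0L) return(emptyHits)
  do.call(rbind, res[seq_len(k)])
}

# Merge one or more ReadSets into a single named DNAStringSet.
.combineReads <- function(readsets) {
  if (is(readsets, "ReadSet")) readsets <- list(readsets)
  if (is(readsets, "DNAStringSet")) return(readsets)
  sets <- lapply(readsets, function(rs) {
    stopifnot(is(rs, "ReadSet"))
    rs@reads
  })
  all <- do.call(c, sets)
  if (anyDuplicated(names(all)))
    stop("read ids must be unique across taxa (are taxon codes distinct?)")
  all
}

# taxon code of each read, from the '<code>_' id prefix
.readTaxa <- function(ids) sub("_.*$", "", ids)

# Unordered candidate pairs (i < j) sharing at least one seed k-mer in
# either relative orientation.
.candidatePairs <- function(reads, k) {
  n <- length(reads)
  fw <- lapply(as.character(reads), .stringKmers, k = k)
  rv <- lapply(as.character(Biostrings::reverseComplement(reads)),
               .stringKmers, k = k)
  fTab <- data.frame(kmer = unlist(fw),
                     idx = rep(seq_len(n), lengths(fw)))
  rTab <- data.frame(kmer = unlist(rv),
                     idx = rep(seq_len(n), lengths(rv)))
  fTab <- unique(fTab); rTab <- unique(rTab)

  acc <- list(); nAcc <- 0L
  addPairs <- function(ii, jj) {
    sel <- ii != jj
    if (!any(sel)) return(invisible())
    a <- pmin(ii[sel], jj[sel]); b <- pmax(ii[sel], jj[sel])
    nAcc <<- nAcc + 1L
    acc[[nAcc]] <<- a * (n + 1) + b   # unordered pair key
  }
  # forward vs forward: pairs within each k-mer's posting list
  for (g in split(fTab$idx, fTab$kmer)) {
    if (length(g) >= 2) {
      cmb <- combn(g, 2)
      addPairs(cmb[1, ], cmb[2, ])
    }
  }
  # forward vs reverse complement
  common <- intersect(fTab$kmer, rTab$kmer)
  if (length(common)) {
    s1 <- split(fTab$idx, fTab$kmer)[common]
    s2 <- split(rTab$idx, rTab$kmer)[common]
    for (q in seq_along(common)) {
      eg <- expand.grid(i = s1[[q]], j = s2[[q]])
      addPairs(eg$i, eg$j)
    }
  }
  if (nAcc == 0L) return(data.frame(i = integer(), j = integer()))
  key <- unique(unlist(acc))
  data.frame(i = key %/% (n + 1), j = key %% (n + 1))
}

#' Build the read-similarity graph
#'
#' One node per read (isolated reads included), one weighted undirected
#' edge per similarity hit; nodes carry their taxon code. Duplicate hits
#' for the same unordered pair keep the maximum score.
#'
#' @param hits Similarity hits from [pairwiseSimilarity()].
#' @param readsets The same reads the hits were computed from.
#' @return An [igraph::igraph] with vertex attribute `taxon` and edge
#'   attributes `weight` (alignment score), `identity`, `coverage`.
#' @export
buildGraph <- function(hits, readsets) {
  all <- .combineReads(readsets)
  ids <- names(all)
  bad <- setdiff(unique(c(hits$read_a, hits$read_b)), ids)
  if (length(bad))
    stop("hits reference read ids absent from the read set: ",
         paste(head(bad, 5), collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$read_a == hits$read_b)) stop("self-hits are not allowed")
    a <- pmin(hits$read_a, hits$read_b)
    b <- pmax(hits$read_a, hits$read_b)
    key <- paste(a, b)
    ord <- order(key, -hits$score)
    hits <- hits[ord, ][!duplicated(key[ord]), ]
  }
  vertices <- data.frame(name = ids, taxon = .readTaxa(ids))
  igraph::graph_from_data_frame(
    data.frame(from = hits$read_a, to = hits$read_b, weight = hits$score,
               identity = hits$identity, coverage = hits$coverage),
    directed = FALSE, vertices = vertices)
}
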