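#' Load a FASTA/FASTQ read file as a taxon-coded ReadSet
#'
#' Records become reads carrying the taxon code as a read-id prefix
#' (`<code>_<id>`), the convention that lets downstream comparative
#' clustering attribute each read to its taxon. Bases are uppercased,
#' IUPAC ambiguity codes are replaced by `N`, and reads with more than
#' `maxNFraction` of `N` bases are discarded (similarity scoring treats
#' `N` as mismatch, so high-N reads would only create spurious
#' singletons). FASTQ qualities are checked for length but otherwise
#' ignored.
#'
#' @param path Path to the read file.
#' @param taxonCode Short taxon code (`[A-Za-z0-9]{1,8}`).
#' @param format `"auto"` (by extension), `"fasta"`, or `"fastq"`.
#' @param genomeSize1C 1C genome size in bp for this taxon (`NA` if
#'   unknown; then only equal-read-count sampling is possible).
#' @param maxNFraction Reads with a higher fraction of `N` are dropped.
#' @return A [ReadSet-class]; record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "ggccggcc"), fa)
#' loadReads(fa, taxonCode = "T1")
#' @export
loadReads <- function(path, taxonCode,
                      format = c("auto", "fasta", "fastq"),
                      genomeSize1C = NA_real_, maxNFraction = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0) {
    warning("empty read file: ", path)
    return(ReadSet(Biostrings::DNAStringSet(), taxonCode, genomeSize1C,
                   log = list(input = 0L)))
  }
  seqs <- tryCatch({
    if (format == "fastq") {
      # validate the 4-line record structure first: Biostrings pads
      # mismatched qualities silently, so check lengths from the text
      ln <- readLines(path, warn = FALSE)
      if (length(ln) %% 4 != 0)
        stop("FASTQ parse error: line count not a multiple of 4 in ", path)
      sq <- ln[seq(2, length(ln), by = 4)]
      ql <- ln[seq(4, length(ln), by = 4)]
      bad <- which(nchar(sq) != nchar(ql))
      if (length(bad))
        stop("FASTQ parse error: quality length differs from sequence ",
             "length in record(s) ", paste(head(bad, 5), collapse = ", "),
             " (line ", 4 * bad[1] - 2, ") of ", path)
      Biostrings::readDNAStringSet(path, format = "fastq")
    } else {
      Biostrings::readDNAStringSet(path, format = "fasta")
    }
  }, error = function(e) {
    stop("malformed ", format, " in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  nlog <- list(input = length(seqs))
  # first whitespace token of the header is the read id
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate read ids in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  names(seqs) <- ids
  seqs <- Biostrings::replaceAmbiguities(seqs, new = "N")
  nfrac <- Biostrings::letterFrequency(seqs, "N") / pmax(1L, Biostrings::width(seqs))
  keep <- as.vector(nfrac) <= maxNFraction
  nlog$dropped_high_N <- sum(!keep)
  if (any(!keep)) {
    message(sum(!keep), " read(s) with > ", maxNFraction * 100,
            "% N discarded for taxon ", taxonCode)
    seqs <- seqs[keep]
  }
  ReadSet(seqs, taxonCode, genomeSize1C, log = nlog)
}

#' Trim reads to a fixed length and drop shorter reads
#'
#' Keeps the 5' prefix of each read at exactly `targetLength` bp and
#' discards reads shorter than that, so that all reads entering the
#' similarity graph have a common length (the coverage denominator of
#' the similarity threshold). The operation is idempotent.
#'
#' @param rs A [ReadSet-class].
#' @param targetLength Target read length in bp (default 100).
#' @return A [ReadSet-class] with all reads exactly `targetLength` bp.
#' @export
trimAndFilter <- function(rs, targetLength = 100) {
  stopifnot(is(rs, "ReadSet"))
  if (length(targetLength) != 1 || is.na(targetLength) || targetLength < 1)
    stop("targetLength must be a positive integer")
  targetLength <- as.integer(targetLength)
  w <- Biostrings::width(rs@reads)
  keep <- w >= targetLength
  out <- Biostrings::subseq(rs@reads[keep], start = 1L, end = targetLength)
  nlog <- rs@log
  nlog$dropped_short <- sum(!keep)
  nlog$trimmed_to <- targetLength
  if (any(!keep))
    message(sum(!keep), " read(s) shorter than ", targetLength,
            " bp discarded for taxon ", rs@taxonCode)
  new("ReadSet", reads = out, taxonCode = rs@taxonCode,
      genomeSize1C = rs@genomeSize1C, readLength = as.numeric(targetLength),
      log = nlog)
}

#' Sample reads to a target genome proportion
#'
#' Draws `n = round(gpPercent/100 * genomeSize1C / readLength)` reads
#' uniformly without replacement, so that every taxon contributes the
#' same genome proportion (GP) to the comparative clustering. Without
#' this standardization cluster abundances reflect genome size rather
#' than the genomic proportion of each repeat. When genome sizes are
#' unknown, the explicit `nReads` mode takes a fixed number of reads per
#' taxon instead (and says so).
#'
#' @param rs A trimmed [ReadSet-class] (uniform read length).
#' @param gpPercent Target genome proportion as a percentage (e.g. `1`
#'   for 1% of the 1C genome).
#' @param seed Integer seed; sampling is bit-reproducible.
#' @param nReads Equal-read-count mode: take exactly this many reads and
#'   ignore `gpPercent`/genome size (use when 1C values are unavailable).
#' @return A [ReadSet-class] of the sampled reads, in original order.
#' @export
sampleToGenomeProportion <- function(rs, gpPercent = NULL, seed = 1L,
                                     nReads = NULL) {
  stopifnot(is(rs, "ReadSet"))
  if (is.na(rs@readLength))
    stop("reads must be trimmed to a uniform length first ",
         "(see trimAndFilter())")
  if (is.null(nReads)) {
    if (is.na(rs@genomeSize1C))
      stop("genome size (1C) unknown for taxon ", rs@taxonCode,
           ": supply genomeSize1C when loading reads, or use the ",
           "explicit equal-read-count mode via the nReads argument")
    if (is.null(gpPercent) || gpPercent <= 0)
      stop("gpPercent must be > 0")
    n <- round(gpPercent / 100 * rs@genomeSize1C / rs@readLength)
  } else {
    message("equal-read-count mode: taking ", nReads, " reads for taxon ",
            rs@taxonCode, " (genome proportion not standardized)")
    n <- as.integer(nReads)
  }
  if (n > length(rs@reads)) {
    maxGP <- length(rs@reads) * rs@readLength / rs@genomeSize1C * 100
    stop("taxon ", rs@taxonCode, ": ", n, " reads requested but only ",
         length(rs@reads), " available",
         if (!is.na(rs@genomeSize1C))
           paste0(" (maximum achievable GP = ",
                  format(maxGP, digits = 4), "%)") else "")
  }
  idx <- sort(.withSeed(seed, sample.int(length(rs@reads), n)))
  nlog <- rs@log
  nlog$sampled <- n
  gp <- if (!is.na(rs@genomeSize1C))
    n * rs@readLength / rs@genomeSize1C * 100 else NA_real_
  nlog$gp_percent <- gp
  new("ReadSet", reads = rs@reads[idx], taxonCode = rs@taxonCode,
      genomeSize1C = rs@genomeSize1C, readLength = rs@readLength, log = nlog)
}

#' Remove organelle-derived reads by similarity to reference sequences
#'
#' Plastid and mitochondrial reads are highly abundant and would form
#' large non-nuclear clusters, so they are screened out against supplied
#' organelle references using the same seeded local-alignment engine and
#' acceptance rule (identity over coverage of the read length) as the
#' read-versus-read similarity stage.
#'
#' @param rs A trimmed [ReadSet-class].
#' @param references Organelle reference sequences: a
#'   [Biostrings::DNAStringSet], character vector, or path to a FASTA
#'   file.
#' @param minIdentity Minimum percent identity (default 90).
#' @param minCov Minimum alignment coverage as a fraction of the read
#'   length (default 0.55).
#' @param seedKmer Exact-match seed length used to pre-screen candidate
#'   reads (default 13).
#' @return A [ReadSet-class] with matching reads removed.
#' @export
filterOrganelle <- function(rs, references, minIdentity = 90,
                            minCov = 0.55, seedKmer = 13) {
  stopifnot(is(rs, "ReadSet"))
  if (is.character(references) && length(references) == 1 &&
      file.exists(references))
    references <- Biostrings::readDNAStringSet(references)
  references <- methods::as(references, "DNAStringSet")
  if (length(references) == 0) stop("references must be non-empty")
  if (length(rs@reads) == 0) return(rs)
  rl <- rs@readLength
  if (is.na(rl)) stop("reads must be trimmed to a uniform length first")

  # k-mer prescreen: a read lacking any shared seed with the references
  # (either strand) cannot reach the identity threshold
  refBoth <- c(references, Biostrings::reverseComplement(references))
  refK <- unique(unlist(lapply(seq_along(refBoth), function(i)
    .stringKmers(as.character(refBoth[[i]]), seedKmer))))
  readK <- lapply(as.character(rs@reads), .stringKmers, k = seedKmer)
  cand <- which(vapply(readK, function(k) any(k %in% refK), logical(1)))

  hit <- logical(length(rs@reads))
  if (length(cand)) {
    for (j in seq_along(references)) {
      todo <- cand[!hit[cand]]
      if (!length(todo)) break
      sc <- .bestLocalAlignment(rs@reads[todo], references[[j]])
      hit[todo] <- sc$identity >= minIdentity & sc$coverage >= minCov
    }
  }
  message(sum(hit), " organelle-matching read(s) removed for taxon ",
          rs@taxonCode)
  nlog <- rs@log
  nlog$organelle_removed <- sum(hit)
  new("ReadSet", reads = rs@reads[!hit], taxonCode = rs@taxonCode,
      genomeSize1C = rs@genomeSize1C, readLength = rs@readLength, log = nlog)
}

# all k-mers of a character string
.stringKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}
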