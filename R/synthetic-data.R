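# Ground-truthed synthetic data at every pipeline stage: repeat-laden
# genomes, reads at a chosen genome proportion, and abundance matrices
# evolved by Brownian motion on a known tree.

#' Describe a synthetic repeat family
#'
#' @param familyId Family identifier string.
#' @param monomerLength Monomer length in bp.
#' @param copyNumber Named integer vector: copies per taxon (>= 0).
#' @param divergence Percent divergence of each copy from the family
#'   consensus, in `[0, 50)`.
#' @param typeLabel Annotation category for the family (one of the six
#'   standard categories).
#' @param tandem If `TRUE`, copies are inserted as one head-to-tail
#'   array (satellite-like); otherwise each copy is placed
#'   independently (dispersed, retroelement-like).
#' @return A `repeatFamilySpec` list.
#' @export
repeatFamilySpec <- function(familyId, monomerLength, copyNumber,
                             divergence = 2, typeLabel = "other/unclassified",
                             tandem = FALSE) {
  stopifnot(monomerLength >= 1, all(copyNumber >= 0),
            divergence >= 0, divergence < 50,
            !is.null(names(copyNumber)))
  structure(list(familyId = familyId, monomerLength = monomerLength,
                 copyNumber = copyNumber, divergence = divergence,
                 typeLabel = typeLabel, tandem = tandem),
            class = "repeatFamilySpec")
}

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at `rate` (per base), never to the same base
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    bases[hit] <- vapply(bases[hit], function(b)
      sample(setdiff(alt, b), 1), character(1))
  }
  paste(bases, collapse = "")
}

#' Simulate repeat-laden genomes with a truth table
#'
#' Each taxon's genome is an i.i.d. random background with family
#' copies inserted at uniform random non-overlapping positions; every
#' copy is independently mutated from the family consensus at the
#' family divergence rate, and tandem families are inserted as a single
#' head-to-tail array. The truth table records the position and family
#' of every inserted block, the per-taxon copy numbers, and the true
#' genomic proportion of each family.
#'
#' @param specs List of [repeatFamilySpec()] objects.
#' @param genomeSize Genome size in bp: single value or named per-taxon
#'   vector (taxa taken from the specs' `copyNumber` names).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List with `genomes` (named [Biostrings::DNAStringSet]),
#'   `truth` (list: `intervals` data.frame taxon/family/start/end,
#'   `copyNumber` and `gpTrue` family x taxon matrices), and
#'   `consensus` (the family consensus sequences).
#' @export
simulateGenomes <- function(specs, genomeSize, seed = 1L) {
  if (is(specs, "repeatFamilySpec")) specs <- list(specs)
  taxaList <- lapply(specs, function(s) names(s$copyNumber))
  taxa <- taxaList[[1]]
  stopifnot(all(vapply(taxaList, setequal, logical(1), taxa)))
  if (length(genomeSize) == 1 && is.null(names(genomeSize)))
    genomeSize <- setNames(rep(genomeSize, length(taxa)), taxa)
  famIds <- vapply(specs, `[[`, character(1), "familyId")
  .withSeed(seed, {
    consensus <- setNames(lapply(specs, function(s)
      .randomDNA(s$monomerLength)), famIds)
    genomes <- character(length(taxa))
    intervals <- list()
    copyNumber <- matrix(0L, length(specs), length(taxa),
                         dimnames = list(famIds, taxa))
    for (ti in seq_along(taxa)) {
      tx <- taxa[ti]
      G <- genomeSize[[tx]]
      blocks <- list(); blockFam <- character(0)
      for (si in seq_along(specs)) {
        s <- specs[[si]]
        cn <- s$copyNumber[[tx]]
        copyNumber[si, ti] <- cn
        if (cn == 0) next
        copies <- vapply(seq_len(cn), function(i)
          .mutate(consensus[[si]], s$divergence / 100), character(1))
        if (s$tandem) {
          blocks <- c(blocks, paste(copies, collapse = ""))
          blockFam <- c(blockFam, s$familyId)
        } else {
          blocks <- c(blocks, as.list(copies))
          blockFam <- c(blockFam, rep(s$familyId, cn))
        }
      }
      occupied <- sum(nchar(unlist(blocks)))
      if (occupied > G)
        stop("taxon ", tx, ": repeat families occupy ", occupied,
             " bp but the genome is only ", G, " bp")
      bg <- G - occupied
      nb <- length(blocks)
      ord <- sample.int(nb)
      blocks <- blocks[ord]; blockFam <- blockFam[ord]
      # distribute background bp uniformly into the nb + 1 gaps
      cuts <- sort(sample.int(bg + nb, nb))
      gapLens <- diff(c(0L, cuts, bg + nb + 1L)) - 1L
      pieces <- character(2 * nb + 1)
      pos <- 0L
      iv <- data.frame(taxon = character(0), family = character(0),
                       start = integer(0), end = integer(0))
      for (bi in seq_len(nb)) {
        gseq <- .randomDNA(gapLens[bi])
        pieces[2 * bi - 1] <- gseq
        pos <- pos + gapLens[bi]
        blen <- nchar(blocks[[bi]])
        pieces[2 * bi] <- blocks[[bi]]
        iv <- rbind(iv, data.frame(taxon = tx, family = blockFam[bi],
                                   start = pos + 1L, end = pos + blen))
        pos <- pos + blen
      }
      pieces[2 * nb + 1] <- .randomDNA(gapLens[nb + 1])
      genomes[ti] <- paste(pieces, collapse = "")
      intervals[[ti]] <- iv
    }
    genomes <- Biostrings::DNAStringSet(setNames(genomes, taxa))
    gpTrue <- copyNumber * vapply(specs, `[[`, numeric(1), "monomerLength")
    gpTrue <- sweep(gpTrue, 2, genomeSize[taxa], `/`) * 100
    list(genomes = genomes,
         truth = list(intervals = do.call(rbind, intervals),
                      copyNumber = copyNumber, gpTrue = gpTrue),
         consensus = consensus,
         specs = setNames(specs, famIds))
  })
}

#' Simulate uniform random short reads from a genome
#'
#' Draws `n = round(gpPercent/100 * genomeLength / readLength)` reads
#' uniformly from both strands, applies per-base substitution errors,
#' and (when a truth table is supplied) records the provenance of each
#' read: the family whose inserted block contains the read midpoint,
#' else "background".
#'
#' @param genome A single genome: `DNAString`, character, or one
#'   element of the `genomes` slot of [simulateGenomes()].
#' @param taxonCode Taxon code for the resulting [ReadSet-class].
#' @param gpPercent Genome proportion to sample, in percent.
#' @param readLength Read length in bp (default 100).
#' @param errorRate Per-base substitution error probability (default 0).
#' @param seed Integer seed.
#' @param truth Optional `truth` list from [simulateGenomes()] (used
#'   for provenance of this taxon's reads).
#' @return List with `readset` (a [ReadSet-class]) and `provenance`
#'   (data.frame read_id/family, when `truth` supplied).
#' @export
simulateReads <- function(genome, taxonCode, gpPercent, readLength = 100,
                          errorRate = 0, seed = 1L, truth = NULL) {
  stopifnot(gpPercent > 0)
  gseq <- as.character(methods::as(genome, "DNAString"))
  G <- nchar(gseq)
  n <- round(gpPercent / 100 * G / readLength)
  if (n < 1) stop("genome proportion too small: zero reads requested")
  .withSeed(seed, {
    starts <- sample.int(G - readLength + 1L, n, replace = TRUE)
    minus <- runif(n) < 0.5
    reads <- substring(gseq, starts, starts + readLength - 1L)
    if (any(minus)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[minus])))
      reads[minus] <- rc
    }
    if (errorRate > 0)
      reads <- vapply(reads, .mutate, character(1), rate = errorRate,
                      USE.NAMES = FALSE)
    ids <- sprintf("r%06d", seq_len(n))
    rs <- ReadSet(Biostrings::DNAStringSet(setNames(reads, ids)),
                  taxonCode = taxonCode, genomeSize1C = G)
    prov <- NULL
    if (!is.null(truth)) {
      iv <- truth$intervals[truth$intervals$taxon == taxonCode, ,
                            drop = FALSE]
      mid <- starts + readLength %/% 2L
      fam <- rep("background", n)
      if (nrow(iv)) {
        ivo <- iv[order(iv$start), ]
        slot_ <- findInterval(mid, ivo$start)
        ok <- slot_ >= 1
        ok[ok] <- mid[ok] <= ivo$end[slot_[ok]]
        fam[ok] <- ivo$family[slot_[ok]]
      }
      prov <- data.frame(read_id = names(reads(rs)), family = fam,
                         start = starts, strand = ifelse(minus, "-", "+"))
    }
    list(readset = rs, provenance = prov)
  })
}

#' Evolve an abundance matrix by Brownian motion on a known tree
#'
#' Each character evolves independently on log-abundance: increments
#' along a branch are normal with mean 0 and variance
#' `sigma^2 * branch length` (multiplicative copy-number dynamics keep
#' abundances positive). Leaf values are exponentiated back and floored
#' at 0.001.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param nCharacters Number of characters (clusters) to simulate.
#' @param sigma Brownian standard deviation per unit branch length on
#'   the log scale.
#' @param rootValues Root abundances: vector of length `nCharacters`
#'   (recycled if length 1).
#' @param seed Integer seed.
#' @return List with `matrix` (an unscaled [AbundanceMatrix-class],
#'   taxa x characters) and `tree` (the generating tree).
#' @export
simulateAbundanceEvolution <- function(tree, nCharacters, sigma = 1,
                                       rootValues = 100, seed = 1L) {
  stopifnot(sigma > 0, nCharacters >= 1)
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  rootValues <- rep_len(rootValues, nCharacters)
  nTip <- length(tree$tip.label)
  phy <- ape::reorder.phylo(tree, "postorder")
  nn <- max(phy$edge)
  root <- phy$edge[nrow(phy$edge), 1]
  .withSeed(seed, {
    x <- matrix(NA_real_, nn, nCharacters)
    x[root, ] <- log(rootValues)
    for (r in rev(seq_len(nrow(phy$edge)))) {   # preorder
      p <- phy$edge[r, 1]; ch <- phy$edge[r, 2]
      bl <- phy$edge.length[r]
      x[ch, ] <- x[p, ] + rnorm(nCharacters, 0, sigma * sqrt(bl))
    }
    vals <- pmax(exp(x[seq_len(nTip), , drop = FALSE]), 0.001)
    dimnames(vals) <- list(phy$tip.label,
                           paste0("CL", seq_len(nCharacters)))
    list(matrix = AbundanceMatrix(vals), tree = tree)
  })
}
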