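# Fixtures built in code.

# deterministic random DNA string
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a ReadSet from a character vector of sequences
mkReadSet <- function(seqs, taxon = "T1", genomeSize = NA_real_) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("r%03d", seq_along(seqs))
  ReadSet(Biostrings::DNAStringSet(seqs), taxonCode = taxon,
          genomeSize1C = genomeSize)
}

# mutate a sequence at exactly the given positions (transversion A<->C, G<->T)
mutateAt <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  b[pos] <- swap[b[pos]]
  paste(b, collapse = "")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

quartetTree <- function(bl = NULL) {
  if (is.null(bl)) ape::read.tree(text = "((A,B),(C,D));")
  else ape::read.tree(text = sprintf(
    "((A:%f,B:%f):%f,(C:%f,D:%f):%f);", bl[1], bl[1], bl[2],
    bl[1], bl[1], bl[2]))
}

allQuartets <- function() phangorn::allTrees(4, rooted = FALSE,
                                             tip.label = c("A", "B", "C", "D"))

# abundance matrix helper
mkAM <- function(values, annotations = rep(NA_character_, ncol(values))) {
  AbundanceMatrix(values, annotations = annotations)
}

# reads tiled at every offset from a tandem array of `monomer`, so the
# cluster subgraph shape is fully determined by the monomer length
tiledReads <- function(monomer, readLength = 100, n = 40, taxon = "T1",
                       seed = 1) {
  set.seed(seed)
  arr <- paste(rep(monomer, ceiling((readLength + n * 4) / nchar(monomer)) + 2),
               collapse = "")
  starts <- round(seq(1, nchar(monomer), length.out = n))
  seqs <- substring(arr, starts, starts + readLength - 1L)
  mkReadSet(setNames(seqs, sprintf("t%03d", seq_len(n))), taxon = taxon)
}
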