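# Continuous-character (Wagner) parsimony.
#
# Characters are additive: the cost of change between two states is
# their absolute difference, with no recoding or discretization. The
# minimum total cost on a binary tree is found by the classical
# interval down-pass: each leaf carries a degenerate interval (or a
# supplied range), and each internal node receives the intersection of
# its children's intervals when they overlap (no cost) or the gap
# between them otherwise (cost = gap width).

# lo/hi leaf matrices from any accepted matrix type
.asLoHi <- function(m) {
  if (is(m, "AbundanceMatrix")) list(lo = m@values, hi = m@values)
  else if (is(m, "RangeMatrix")) list(lo = m@lo, hi = m@hi)
  else if (is.matrix(m)) list(lo = m, hi = m)
  else stop("m must be an AbundanceMatrix, RangeMatrix, or plain matrix")
}

# Vectorized Farris down-pass over all characters.
# struct: from .treeStruct (rooted at tip `rootTip`); loTips/hiTips:
# tip-indexed (rows = tip ids) character matrices.
# Returns per-character minimum steps and the preliminary intervals.
.farrisDown <- function(struct, loTips, hiTips) {
  nn <- struct$nNodes
  nc <- ncol(loTips)
  lo <- matrix(NA_real_, nn, nc)
  hi <- matrix(NA_real_, nn, nc)
  cost <- numeric(nc)
  rootTip <- struct$rootTip
  for (v in struct$postorder) {
    ch <- struct$children[[v]]
    nch <- length(ch)
    if (nch == 0L) {                      # leaf
      lo[v, ] <- loTips[v, ]; hi[v, ] <- hiTips[v, ]
    } else if (v == rootTip) {            # final combine with the root leaf
      il <- pmax(loTips[v, ], lo[ch, ])
      ih <- pmin(hiTips[v, ], hi[ch, ])
      cost <- cost + pmax(il - ih, 0)
      lo[v, ] <- pmin(il, ih); hi[v, ] <- pmax(il, ih)
    } else if (nch == 1L) {               # degree-2 node (old root): pass through
      lo[v, ] <- lo[ch, ]; hi[v, ] <- hi[ch, ]
    } else if (nch == 2L) {
      a <- ch[1]; b <- ch[2]
      il <- pmax(lo[a, ], lo[b, ])
      ih <- pmin(hi[a, ], hi[b, ])
      cost <- cost + pmax(il - ih, 0)
      lo[v, ] <- pmin(il, ih); hi[v, ] <- pmax(il, ih)
    } else {
      stop("binary trees required (a node has ", nch, " children)")
    }
  }
  list(perCharacter = cost, lo = lo, hi = hi)
}

# Tip matrices aligned to tip ids of a phylo tree.
.tipMatrices <- function(phy, m) {
  lh <- .asLoHi(m)
  mt <- rownames(lh$lo)
  d <- union(setdiff(phy$tip.label, mt), setdiff(mt, phy$tip.label))
  if (length(d))
    stop("tree leaves and matrix taxa differ: ", paste(d, collapse = ", "))
  list(lo = lh$lo[phy$tip.label, , drop = FALSE],
       hi = lh$hi[phy$tip.label, , drop = FALSE])
}

#' Minimum steps of one continuous character on a tree
#'
#' Runs the interval down-pass for a single additive character and
#' returns its minimum step count together with the preliminary state
#' interval of every node. Leaves may carry point values or closed
#' ranges; the unrooted tree is handled by rooting on the pendant edge
#' of the first leaf (all reported quantities are rooting-invariant).
#'
#' @param tree A binary `phylo`.
#' @param values Named numeric vector of leaf values, or a two-column
#'   matrix (`lo`, `hi`) with leaf rownames.
#' @return List with `steps` (minimum step count) and `intervals`
#'   (nodes x 2 matrix of preliminary `lo`/`hi`, rows indexed by the
#'   tree's node numbering).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' characterSteps(tr, c(A = 1, B = 1, C = 5, D = 5))$steps  # 4
#' @export
characterSteps <- function(tree, values) {
  if (is.null(dim(values))) {
    miss <- setdiff(tree$tip.label, names(values))
    if (length(miss))
      stop("missing value for leaf/leaves: ", paste(miss, collapse = ", "))
    vm <- matrix(values[tree$tip.label], ncol = 1,
                 dimnames = list(tree$tip.label, NULL))
    m <- list(lo = vm, hi = vm)
  } else {
    miss <- setdiff(tree$tip.label, rownames(values))
    if (length(miss))
      stop("missing value for leaf/leaves: ", paste(miss, collapse = ", "))
    m <- list(lo = values[tree$tip.label, 1, drop = FALSE],
              hi = values[tree$tip.label, 2, drop = FALSE])
  }
  st <- .treeStruct(tree$edge, rootTip = 1L)
  res <- .farrisDown(st, m$lo, m$hi)
  nTip <- length(tree$tip.label)
  iv <- cbind(lo = res$lo[, 1], hi = res$hi[, 1])
  rownames(iv) <- c(tree$tip.label,
                    paste0("node", seq_len(st$nNodes - nTip) + nTip))[
                      seq_len(st$nNodes)]
  list(steps = unname(res$perCharacter[1]), intervals = iv)
}

#' Parsimony tree length over a character matrix
#'
#' Total Wagner-parsimony length: the sum over characters of the
#' per-character minimum steps from the interval down-pass. Invariant
#' under re-rooting.
#'
#' @param tree A binary `phylo` whose leaves match the matrix taxa.
#' @param m An [AbundanceMatrix-class], [RangeMatrix-class], or plain
#'   taxa x characters matrix.
#' @return List with `total` and `perCharacter` step counts.
#' @export
treeLength <- function(tree, m) {
  tm <- .tipMatrices(tree, m)
  st <- .treeStruct(tree$edge, rootTip = 1L)
  res <- .farrisDown(st, tm$lo, tm$hi)
  list(total = sum(res$perCharacter), perCharacter = res$perCharacter)
}

#' Per-branch step counts (up-pass assignment)
#'
#' After the down-pass, a most-parsimonious reconstruction is fixed by
#' an up-pass in the spirit of Goloboff's final-state computation: the
#' root leaf takes the point of its interval closest to its neighbour's
#' preliminary interval, and every other node takes the point of its
#' preliminary interval closest to its parent's final state. Branch
#' steps are the per-branch absolute state differences summed over
#' characters; they sum exactly to the total tree length.
#'
#' @param tree A binary `phylo`.
#' @param m Character matrix as in [treeLength()].
#' @return The tree with `edge.length` set to per-branch step counts
#'   and attributes `total` (tree length) and `finalStates` (node x
#'   character matrix of the reconstruction).
#' @export
uppassBranchSteps <- function(tree, m) {
  tm <- .tipMatrices(tree, m)
  st <- .treeStruct(tree$edge, rootTip = 1L)
  res <- .farrisDown(st, tm$lo, tm$hi)
  nn <- st$nNodes
  nc <- ncol(tm$lo)
  f <- matrix(NA_real_, nn, nc)
  rootTip <- st$rootTip
  child <- st$children[[rootTip]]
  # closest point of the root leaf's own interval to the neighbour interval
  f[rootTip, ] <- pmin(pmax(res$lo[child, ], tm$lo[rootTip, ]),
                       tm$hi[rootTip, ])
  pre <- rev(st$postorder)
  for (v in pre[-1]) {
    p <- st$parent[v]
    lov <- if (length(st$children[[v]])) res$lo[v, ] else tm$lo[v, ]
    hiv <- if (length(st$children[[v]])) res$hi[v, ] else tm$hi[v, ]
    f[v, ] <- pmin(pmax(f[p, ], lov), hiv)
  }
  steps <- vapply(seq_len(nrow(tree$edge)), function(r) {
    u <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    sum(abs(f[u, ] - f[v, ]))
  }, numeric(1))
  tree$edge.length <- steps
  attr(tree, "total") <- sum(res$perCharacter)
  attr(tree, "finalStates") <- f
  tree
}

#' Exact most-parsimonious tree search (implicit enumeration)
#'
#' Branch-and-bound over unrooted binary topologies: taxa are added in
#' input order, every placement of the next taxon is scored, and a
#' partial tree is abandoned as soon as its length exceeds the current
#' best complete tree (partial length is monotone under taxon
#' addition). The initial upper bound comes from a greedy
#' stepwise-addition tree. All topologies attaining the global minimum
#' are returned.
#'
#' @param m An [AbundanceMatrix-class], [RangeMatrix-class], or plain
#'   taxa x characters matrix, with 3 to 15 taxa.
#' @return A `multiPhylo` of all minimum-length trees, with attributes
#'   `minLength` and `nVisited`.
#' @export
branchAndBoundSearch <- function(m) {
  lh <- .asLoHi(m)
  taxa <- rownames(lh$lo)
  n <- length(taxa)
  if (n < 3) stop("at least 3 taxa required")
  if (n > 15)
    stop("more than 15 taxa: implicit enumeration would be intractable; ",
         "a heuristic search is not implemented")
  loT <- lh$lo; hiT <- lh$hi
  scoreEdges <- function(edges) {
    st <- .treeStruct(edges, rootTip = 1L)
    sum(.farrisDown(st, loT, hiT)$perCharacter)
  }
  # initial 3-taxon star (exactly one unrooted topology)
  e0 <- cbind(rep(n + 1L, 3L), 1:3)
  if (n == 3) {
    out <- list(.edgesToPhylo(e0, n, taxa))
    class(out) <- "multiPhylo"
    attr(out, "minLength") <- scoreEdges(e0)
    attr(out, "nVisited") <- 1L
    return(out)
  }
  addTaxon <- function(edges, edgeRow, tip, newInt) {
    u <- edges[edgeRow, 1]; v <- edges[edgeRow, 2]
    rbind(edges[-edgeRow, , drop = FALSE],
          c(u, newInt), c(newInt, v), c(newInt, tip))
  }
  # greedy stepwise addition for the upper bound
  edges <- e0
  for (k in 4:n) {
    cand <- lapply(seq_len(nrow(edges)), function(r)
      addTaxon(edges, r, k, n + k - 2L))
    sc <- vapply(cand, scoreEdges, numeric(1))
    edges <- cand[[which.min(sc)]]
  }
  best <- scoreEdges(edges)
  tolOf <- function(L) 1e-9 * (1 + abs(L))
  results <- list(edges)
  nVisited <- 0L
  recurse <- function(edges, k) {
    for (r in seq_len(nrow(edges))) {
      e2 <- addTaxon(edges, r, k, n + k - 2L)
      L <- scoreEdges(e2)
      nVisited <<- nVisited + 1L
      if (L > best + tolOf(best)) next
      if (k == n) {
        if (L < best - tolOf(best)) {
          best <<- L
          results <<- list(e2)
        } else {
          results[[length(results) + 1L]] <<- e2
        }
      } else {
        recurse(e2, k + 1L)
      }
    }
  }
  recurse(e0, 4L)
  # deduplicate topologies (the stepwise tree is rediscovered by the search)
  trees <- lapply(results, .edgesToPhylo, nTip = n, tipLabels = taxa)
  sig <- vapply(trees, .topologySignature, character(1))
  keepBest <- vapply(results, scoreEdges, numeric(1)) <= best + tolOf(best)
  trees <- trees[keepBest & !duplicated(sig)]
  class(trees) <- "multiPhylo"
  attr(trees, "minLength") <- best
  attr(trees, "nVisited") <- nVisited
  trees
}

# Enumerate all unrooted topologies with pre-built traversal structures;
# used to score many reweighted replicates cheaply for small taxon sets.
.enumerateTopologies <- function(taxa) {
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  list(trees = trees,
       structs = lapply(trees, function(t) .treeStruct(t$edge, 1L)),
       keys = lapply(trees, .splitKeys))
}

#' Symmetric resampling supports for the parsimony tree
#'
#' A modification of the bootstrap that avoids weight-related bias:
#' per replicate each character independently keeps weight 1 with
#' probability `1 - pChange`, or is perturbed symmetrically (weight
#' halved or doubled with equal probability). Because step counts are
#' linear in the character values, reweighting is applied by scaling
#' columns. Each replicate's most-parsimonious tree set is found
#' exactly; the support of a bipartition is the percentage of
#' replicates whose strict consensus of MPTs contains it.
#'
#' @param m Character matrix ([AbundanceMatrix-class],
#'   [RangeMatrix-class], or plain matrix).
#' @param replicates Number of resampling replicates (default 10000).
#' @param pChange Per-character perturbation probability (default 1/3).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param archive Keep the per-replicate trees (for consensus networks).
#' @return List with `tree` (the MPT, or strict consensus of MPTs when
#'   not unique, node labels = supports), `supports` (named percent per
#'   bipartition), `mpts` (the unperturbed MPT set), and
#'   `replicateTrees` (a `multiPhylo`, when `archive = TRUE`).
#' @export
symmetricResampling <- function(m, replicates = 10000, pChange = 1/3,
                                seed = 1L, archive = TRUE) {
  stopifnot(replicates >= 1)
  lh <- .asLoHi(m)
  taxa <- rownames(lh$lo)
  n <- length(taxa)
  nc <- ncol(lh$lo)
  mpts <- branchAndBoundSearch(m)
  mainTree <- if (length(mpts) == 1L) mpts[[1]] else strictConsensus(mpts)

  useEnum <- n <= 7
  if (useEnum) enum <- .enumerateTopologies(taxa)
  splitCount <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(keys) for (k in keys)
    splitCount[[k]] <- (if (is.null(splitCount[[k]])) 0L else splitCount[[k]]) + 1L
  repTrees <- if (archive) vector("list", replicates) else NULL

  .withSeed(seed, {
    for (b in seq_len(replicates)) {
      w <- rep(1, nc)
      hitC <- runif(nc) < pChange
      w[hitC] <- ifelse(runif(sum(hitC)) < 0.5, 0.5, 2)
      loW <- sweep(lh$lo, 2, w, `*`)
      hiW <- sweep(lh$hi, 2, w, `*`)
      if (useEnum) {
        sc <- vapply(enum$structs, function(st)
          sum(.farrisDown(st, loW, hiW)$perCharacter), numeric(1))
        mn <- min(sc)
        isMin <- sc <= mn + 1e-9 * (1 + abs(mn))
        keys <- Reduce(intersect, enum$keys[isMin])
        bump(keys)
        if (archive) {
          sel <- which(isMin)
          repTrees[[b]] <- if (length(sel) == 1L) enum$trees[[sel]]
            else strictConsensus(enum$trees[sel])
        }
      } else {
        wm <- if (identical(lh$lo, lh$hi)) loW else .makeRange(loW, hiW)
        set <- branchAndBoundSearch(wm)
        keys <- Reduce(intersect, lapply(set, .splitKeys))
        bump(keys)
        if (archive)
          repTrees[[b]] <- if (length(set) == 1L) set[[1]]
            else strictConsensus(set)
      }
    }
  })
  keys <- ls(splitCount)
  supports <- setNames(
    vapply(keys, function(k) 100 * splitCount[[k]] / replicates, numeric(1)),
    keys)
  tree <- .mapSupports(mainTree, supports)
  out <- list(tree = tree, supports = supports, mpts = mpts,
              params = list(replicates = replicates, pChange = pChange,
                            seed = seed))
  if (archive) {
    class(repTrees) <- "multiPhylo"
    out$replicateTrees <- repTrees
  }
  out
}

# internal: wrap lo/hi matrices as a RangeMatrix without provenance checks
.makeRange <- function(lo, hi) {
  new("RangeMatrix", lo = pmax(lo, 0), hi = hi,
      annotations = rep(NA_character_, ncol(lo)),
      provenance = list(nReplicates = 2L, seMultiplier = NA_real_))
}
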