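# Internal tree machinery shared by the parsimony and likelihood modules.
#
# Unrooted binary trees are traversed by rooting at tip 1 (a virtual
# rooting on the pendant edge of the first leaf); every statistic
# reported by the package is invariant to this choice.

# Rooted-at-tip traversal structure from a phylo edge matrix.
# Returns postorder node ids, children lists and the parent vector;
# node ids follow the input numbering (tips 1..nTip).
.treeStruct <- function(edge, rootTip = 1L) {
  nn <- max(edge)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(nn)
  seen <- logical(nn)
  stack <- rootTip
  seen[rootTip] <- TRUE
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  children <- vector("list", nn)
  for (v in visit[-1]) children[[parent[v]]] <- c(children[[parent[v]]], v)
  list(postorder = rev(visit), children = children, parent = parent,
       rootTip = rootTip, nNodes = nn)
}

# Convert an edge matrix (tips 1..nTip, arbitrary internal ids) into an
# ape phylo object. Rooted at the internal node adjacent to tip 1, which
# yields the standard ape representation of an unrooted binary tree
# (basal trichotomy).
.edgesToPhylo <- function(edges, nTip, tipLabels) {
  st <- .treeStruct(edges, rootTip = 1L)
  rootInt <- st$children[[1L]]          # internal neighbour of tip 1
  # renumber: tips keep 1..nTip, internals get nTip+1.. in preorder from rootInt
  newId <- integer(st$nNodes)
  newId[seq_len(nTip)] <- seq_len(nTip)
  cnt <- nTip
  edgeOut <- matrix(0L, 0, 2)
  stack <- rootInt
  cnt <- cnt + 1L
  newId[rootInt] <- cnt
  order <- rootInt
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- st$children[[v]]
    if (v == rootInt) kids <- c(1L, kids)   # tip 1 hangs off the root
    for (w in kids) {
      if (w > nTip) {
        cnt <- cnt + 1L
        newId[w] <- cnt
        stack <- c(stack, w)
      }
      edgeOut <- rbind(edgeOut, c(newId[v], newId[w]))
    }
  }
  phy <- list(edge = edgeOut, Nnode = cnt - nTip,
              tip.label = tipLabels)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# Non-trivial bipartition keys of an unrooted tree: for every split, the
# tip-label set on the side NOT containing the first label
# (alphabetically), sorted and joined with '|'. Returns a character
# vector (possibly empty for a star tree).
.splitKeys <- function(phy) {
  labs <- phy$tip.label
  nTip <- length(labs)
  anchor <- labs[order(labs)][1]
  st <- .treeStruct(phy$edge, rootTip = 1L)
  below <- vector("list", st$nNodes)
  for (v in st$postorder) {
    if (v <= nTip) below[[v]] <- labs[v]
    else below[[v]] <- unlist(lapply(st$children[[v]], function(w) below[[w]]))
  }
  keys <- character(0)
  for (v in seq_len(st$nNodes)) {
    if (v <= nTip || v == st$children[[1L]]) next  # tips and the root node
    side <- below[[v]]
    if (length(side) < 2 || length(side) > nTip - 2) next
    if (anchor %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# Split key for an arbitrary clade (character vector of labels) given
# the full label set.
.keyForClade <- function(cladeLabels, allLabels) {
  anchor <- sort(allLabels)[1]
  side <- cladeLabels
  if (anchor %in% side) side <- setdiff(allLabels, side)
  paste(sort(side), collapse = "|")
}

# Canonical topology signature (ignores branch lengths and rooting).
.topologySignature <- function(phy) {
  paste(sort(.splitKeys(phy)), collapse = ";")
}

#' Do two trees share the same unrooted topology?
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return `TRUE` when the unrooted bipartition sets are identical.
#' @export
sameTopology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  identical(.topologySignature(t1), .topologySignature(t2))
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) on one leaf set.
#' @return A `phylo`; may be unresolved (polytomies) where trees differ.
#' @export
strictConsensus <- function(trees) {
  if (is(trees, "phylo")) return(trees)
  trees <- unclass(trees)
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(labs[-1], identical, logical(1), labs[[1]])))
    stop("all trees must share the same leaf set")
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}

# Annotate internal nodes of `phy` with supports (percent) looked up by
# split key in `supports` (named numeric). Nodes whose split is absent
# get NA. Returns phy with node.label set.
.mapSupports <- function(phy, supports) {
  labs <- phy$tip.label
  nTip <- length(labs)
  st <- .treeStruct(phy$edge, rootTip = 1L)
  below <- vector("list", st$nNodes)
  for (v in st$postorder) {
    if (v <= nTip) below[[v]] <- labs[v]
    else below[[v]] <- unlist(lapply(st$children[[v]], function(w) below[[w]]))
  }
  nodeLab <- rep("", phy$Nnode)
  for (v in seq_len(st$nNodes)) {
    if (v <= nTip) next
    side <- below[[v]]
    if (length(side) < 2 || length(side) > nTip - 2) next
    key <- .keyForClade(side, labs)
    if (!is.na(supports[key]))
      nodeLab[v - nTip] <- format(round(unname(supports[key]), 1))
  }
  phy$node.label <- nodeLab
  phy
}
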