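# Maximum likelihood for continuous characters under Brownian motion.
#
# Each character is assumed to evolve independently by random drift:
# changes along a branch are normal with variance (rate x branch
# length). The likelihood is computed by the contrasts (pruning)
# construction, which gives the REML likelihood — the root state is
# never estimated, and the value is invariant to root placement. The
# per-character rate is profiled out at its REML value unless a shared
# rate is requested.

# Postorder evaluation plan for a phylo topology: for each internal
# node (in postorder), the rows of the postorder edge matrix leading to
# its children.
.bmPlan <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  edge <- phy$edge
  parents <- unique(edge[, 1])
  groups <- lapply(parents, function(p) which(edge[, 1] == p))
  list(phy = phy, edge = edge, parents = parents, groups = groups,
       nTip = length(phy$tip.label), tip.label = phy$tip.label)
}

# Independent contrasts for all characters at once.
# X: tip-id-ordered (rows 1..nTip) numeric matrix; bl: per postorder
# edge. Returns U ((nTip-1) x nchar) and contrast variances V.
.bmContrasts <- function(plan, bl, X) {
  nn <- max(plan$edge)
  nc <- ncol(X)
  xv <- matrix(0, nn, nc)
  xv[seq_len(plan$nTip), ] <- X
  vv <- numeric(nn)
  U <- matrix(0, plan$nTip - 1L, nc)
  V <- numeric(plan$nTip - 1L)
  k <- 0L
  for (gi in seq_along(plan$parents)) {
    rows <- plan$groups[[gi]]
    ch <- plan$edge[rows, 2]
    x1 <- xv[ch[1], ]
    v1 <- vv[ch[1]] + bl[rows[1]]
    for (q in seq_along(ch)[-1]) {
      x2 <- xv[ch[q], ]
      v2 <- vv[ch[q]] + bl[rows[q]]
      k <- k + 1L
      U[k, ] <- x1 - x2
      V[k] <- v1 + v2
      x1 <- (v2 * x1 + v1 * x2) / (v1 + v2)
      v1 <- v1 * v2 / (v1 + v2)
    }
    p <- plan$parents[gi]
    xv[p, ] <- x1
    vv[p] <- v1
  }
  list(U = U, V = V)
}

# REML log-likelihood from contrasts, rates profiled out.
.bmLoglikFromContrasts <- function(U, V, sharedRate = FALSE) {
  df <- length(V)
  ss <- colSums(U^2 / V)
  sumLogV <- sum(log(V))
  if (sharedRate) {
    s2 <- sum(ss) / (df * length(ss))
    per <- NULL
    total <- -0.5 * (df * length(ss) * (log(2 * pi * s2) + 1) +
                       length(ss) * sumLogV)
  } else {
    s2 <- ss / df
    per <- -0.5 * (df * (log(2 * pi * s2) + 1) + sumLogV)
    total <- sum(per)
  }
  structure(total, perCharacter = per)
}

# Align matrix taxa to tip ids and drop constant characters.
.bmData <- function(phy, m, warnDrop = TRUE) {
  vals <- if (is(m, "AbundanceMatrix")) m@values else m
  if (!is.matrix(vals)) stop("m must be an AbundanceMatrix or matrix")
  d <- union(setdiff(phy$tip.label, rownames(vals)),
             setdiff(rownames(vals), phy$tip.label))
  if (length(d))
    stop("tree leaves and matrix taxa differ: ", paste(d, collapse = ", "))
  X <- vals[phy$tip.label, , drop = FALSE]
  const <- apply(X, 2, function(x) max(x) - min(x) == 0)
  if (all(const))
    stop("all characters are constant across taxa; no likelihood exists")
  if (any(const)) {
    if (warnDrop)
      warning(sum(const), " character(s) constant across taxa excluded ",
              "from the likelihood (zero variance)")
    X <- X[, !const, drop = FALSE]
  }
  X
}

#' Brownian-motion REML log-likelihood of a tree
#'
#' Sums the REML log-likelihood over characters on a tree with branch
#' lengths, computed by independent contrasts (Felsenstein's pruning):
#' each character's contrasts are independent normals with variance
#' proportional to the contrast branch-length sums, and the
#' per-character rate is profiled out at its REML value. The value is
#' invariant to root placement. Characters constant across all taxa
#' carry no information and are excluded with a warning.
#'
#' @param tree A `phylo` with branch lengths (accumulated drift
#'   variance units).
#' @param m A frequency-scaled [AbundanceMatrix-class] (values in
#'   `[0, 1]`) or plain taxa x characters matrix.
#' @param sharedRate Fit one global rate across characters instead of
#'   profiling each character's rate separately.
#' @return The total log-likelihood, with attribute `perCharacter`.
#' @export
brownianLoglik <- function(tree, m, sharedRate = FALSE) {
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  X <- .bmData(tree, m)
  plan <- .bmPlan(tree)
  bl <- plan$phy$edge.length
  if (any(bl < 0)) stop("negative branch lengths")
  ct <- .bmContrasts(plan, pmax(bl, 1e-12), X)
  .bmLoglikFromContrasts(ct$U, ct$V, sharedRate)
}

#' Optimize branch lengths for a fixed topology
#'
#' Coordinate-wise maximization of the REML log-likelihood: each branch
#' in turn is optimized on `[1e-8, upper]` (golden-section), cycling
#' until the improvement per sweep falls below `tol` or `maxSweeps` is
#' reached. Deterministic given the initialization (all branches 0.1).
#' With per-character rates profiled out the likelihood depends on
#' branch lengths only up to a global scale factor, so lengths are
#' meaningful relatively.
#'
#' @param topology A `phylo`; any branch lengths present are ignored.
#' @param m Matrix as in [brownianLoglik()].
#' @param sharedRate Passed to [brownianLoglik()].
#' @param tol Convergence threshold on the log-likelihood gain per
#'   sweep (default 1e-6).
#' @param maxSweeps Sweep cap (default 200).
#' @param upper Upper bound for any single branch length.
#' @return List with `tree` (branch lengths set), `loglik`,
#'   `converged`, and `sweeps`.
#' @export
optimizeBranchLengths <- function(topology, m, sharedRate = FALSE,
                                  tol = 1e-6, maxSweeps = 200, upper = 100) {
  X <- .bmData(topology, m, warnDrop = FALSE)
  plan <- .bmPlan(topology)
  nb <- nrow(plan$edge)
  bl <- rep(0.1, nb)
  obj <- function(bl) {
    ct <- .bmContrasts(plan, bl, X)
    as.numeric(.bmLoglikFromContrasts(ct$U, ct$V, sharedRate))
  }
  cur <- obj(bl)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < maxSweeps) {
    sweeps <- sweeps + 1L
    prev <- cur
    for (i in seq_len(nb)) {
      op <- optimize(function(b) { bl2 <- bl; bl2[i] <- b; obj(bl2) },
                     interval = c(1e-8, upper), maximum = TRUE,
                     tol = 1e-7)
      if (op$objective > cur) {
        bl[i] <- op$maximum
        cur <- op$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("branch-length optimization did not converge in ", maxSweeps,
            " sweeps; returning the best fit found")
  phy <- plan$phy
  phy$edge.length <- bl
  list(tree = phy, loglik = cur, converged = converged, sweeps = sweeps)
}

#' Maximum-likelihood tree search under Brownian motion
#'
#' For up to 8 taxa every unrooted topology is enumerated and scored by
#' [optimizeBranchLengths()]; for 9-12 taxa a greedy stepwise-addition
#' tree is refined by nearest-neighbour interchanges to a local
#' optimum. Likelihood ties are broken by the first topology found and
#' flagged.
#'
#' @param m A frequency-scaled [AbundanceMatrix-class] or plain matrix
#'   with 3 to 12 taxa.
#' @param sharedRate Passed to [brownianLoglik()].
#' @param quiet Suppress the constant-character warning (used by the
#'   bootstrap).
#' @return List with `tree` (branch lengths set), `loglik`, `tie`
#'   (`TRUE` when another topology came within 1e-6), and `nScored`.
#' @export
mlSearch <- function(m, sharedRate = FALSE, quiet = FALSE) {
  vals <- if (is(m, "AbundanceMatrix")) m@values else m
  taxa <- rownames(vals)
  n <- length(taxa)
  if (n < 3) stop("at least 3 taxa required")
  if (n > 12)
    stop("more than 12 taxa: exhaustive/NNI ML search not supported")
  const <- apply(vals, 2, function(x) max(x) - min(x) == 0)
  if (all(const))
    stop("all characters are constant across taxa; no likelihood exists")
  if (any(const)) {
    if (!quiet)
      warning(sum(const), " constant character(s) excluded from the ",
              "likelihood (zero variance)")
    vals <- vals[, !const, drop = FALSE]
  }
  fit1 <- function(phy) suppressWarnings(
    optimizeBranchLengths(phy, vals, sharedRate = sharedRate))
  if (n <= 8) {
    cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    fits <- lapply(cand, fit1)
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    bestI <- which.max(ll)
    tie <- sum(ll >= ll[bestI] - 1e-6) > 1L
    out <- fits[[bestI]]
    return(list(tree = out$tree, loglik = out$loglik, tie = tie,
                nScored = length(cand)))
  }
  # stepwise addition on edge matrices, then NNI refinement
  addTaxon <- function(edges, edgeRow, tip, newInt) {
    u <- edges[edgeRow, 1]; v <- edges[edgeRow, 2]
    rbind(edges[-edgeRow, , drop = FALSE],
          c(u, newInt), c(newInt, v), c(newInt, tip))
  }
  edges <- cbind(rep(n + 1L, 3L), 1:3)
  nScored <- 0L
  for (k in 4:n) {
    cand <- lapply(seq_len(nrow(edges)), function(r)
      addTaxon(edges, r, k, n + k - 2L))
    ll <- vapply(cand, function(e) {
      phy <- .edgesToPhylo(e, k, taxa[seq_len(k)])
      fit1(phy)$loglik
    }, numeric(1))
    nScored <- nScored + length(cand)
    edges <- cand[[which.max(ll)]]
  }
  phy <- .edgesToPhylo(edges, n, taxa)
  repeat {
    curFit <- fit1(phy)
    nbr <- phangorn::nni(phy)
    fits <- lapply(nbr, fit1)
    nScored <- nScored + length(nbr)
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    if (max(ll) > curFit$loglik + 1e-8) {
      phy <- fits[[which.max(ll)]]$tree
    } else {
      return(list(tree = curFit$tree, loglik = curFit$loglik,
                  tie = any(abs(ll - curFit$loglik) <= 1e-6),
                  nScored = nScored))
    }
  }
}

#' Bootstrap supports for the Brownian-motion ML tree
#'
#' Characters are resampled with replacement per replicate, the ML tree
#' found for each resampled matrix, and bipartition frequencies mapped
#' onto the strict consensus of the replicate trees (which may be
#' partially unresolved).
#'
#' @param m A frequency-scaled [AbundanceMatrix-class] or plain matrix.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; same seed gives identical supports.
#' @param sharedRate Passed to [mlSearch()].
#' @return List with `tree` (strict consensus with supports as node
#'   labels), `supports` (named percent per bipartition), `mlTree` (the
#'   full-data ML fit), and `replicateTrees`.
#' @export
bootstrapML <- function(m, replicates = 1000, seed = 1L, sharedRate = FALSE) {
  stopifnot(replicates >= 1)
  vals <- if (is(m, "AbundanceMatrix")) m@values else m
  nc <- ncol(vals)
  full <- suppressWarnings(mlSearch(vals, sharedRate = sharedRate,
                                    quiet = TRUE))
  repTrees <- .withSeed(seed, lapply(seq_len(replicates), function(b) {
    idx <- sample.int(nc, nc, replace = TRUE)
    vb <- vals[, idx, drop = FALSE]
    suppressWarnings(mlSearch(vb, sharedRate = sharedRate,
                              quiet = TRUE)$tree)
  }))
  class(repTrees) <- "multiPhylo"
  keyList <- lapply(repTrees, .splitKeys)
  tab <- table(unlist(keyList))
  supports <- setNames(100 * as.numeric(tab) / replicates, names(tab))
  cons <- strictConsensus(repTrees)
  cons <- .mapSupports(cons, supports)
  list(tree = cons, supports = supports, mlTree = full,
       replicateTrees = repTrees)
}
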