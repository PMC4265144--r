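# Independent oracles used to pin down expected values.

# Sankoff dynamic programming with linear (L1) state-change cost over
# the grid of observed leaf values. Exact for additive characters on
# trees because an optimal labelling exists on the observed-value grid
# (median property of L1 costs). Recursive, unvectorized — deliberately
# a different construction from the package's interval down-pass.
sankoffLength <- function(phy, X) {
  X <- X[phy$tip.label, , drop = FALSE]
  nTip <- length(phy$tip.label)
  edge <- phy$edge
  nn <- max(edge)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  total <- 0
  for (ci in seq_len(ncol(X))) {
    x <- X[, ci]
    states <- sort(unique(x))
    subtreeCost <- function(v, parent) {
      kids <- setdiff(adj[[v]], parent)
      if (!length(kids)) {
        out <- rep(Inf, length(states))
        out[states == x[v]] <- 0
        return(out)
      }
      out <- rep(0, length(states))
      for (w in kids) {
        cw <- subtreeCost(w, v)
        out <- out + vapply(states, function(s)
          min(cw + abs(states - s)), numeric(1))
      }
      out
    }
    nb <- adj[[1L]]
    c1 <- subtreeCost(nb, 1L)
    total <- total + min(c1 + abs(states - x[1L]))
  }
  total
}

# Dense multivariate-normal REML log-likelihood for one character on a
# tree with branch lengths: uses the full tip covariance matrix, its
# determinant and a GLS quadratic form, with the rate profiled out.
denseREML <- function(phy, x) {
  V <- ape::vcv(phy)
  x <- x[rownames(V)]
  n <- length(x)
  Vi <- solve(V)
  mu <- sum(Vi %*% x) / sum(Vi)
  rss <- as.numeric(t(x - mu) %*% Vi %*% (x - mu))
  s2 <- rss / (n - 1)
  as.numeric(-0.5 * ((n - 1) * log(2 * pi * s2) + (n - 1) +
                       determinant(V)$modulus + log(sum(Vi))))
}

# Minimal character-by-character FASTA reader (reference parser).
refReadFasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); cur <- ""
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ids <- c(ids, sub("\\s.*$", "", substring(ln, 2)))
      seqs <- c(seqs, cur <- "")
    } else {
      seqs[length(seqs)] <- cur <- paste0(cur, toupper(trimws(ln)))
    }
  }
  setNames(seqs, ids)
}
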