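# Independent brute-force oracles used to cross-check the package's
# traversal code. These deliberately share no code with the implementation:
# component sizes come from igraph on an explicit pixel-adjacency graph,
# morphology from direct set arithmetic over offsets.

# component-size map via igraph connected components
oracleComponentSizes <- function(mask, radius = 3) {
  m <- if (methods::is(mask, "BinaryMask")) mask@.Data else mask
  off <- neighborhoodOffsets(NeighborhoodSpec(radius = radius))
  idx <- which(m)
  out <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0L) return(out)
  nr <- nrow(m)
  rc <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
  id <- matrix(0L, nrow(m), ncol(m))
  id[idx] <- seq_along(idx)
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    r2 <- rc[, 1] + off[k, 1]; c2 <- rc[, 2] + off[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(m) & c2 >= 1 & c2 <= ncol(m)
    ok[ok] <- m[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- rbind(edges, cbind(id[idx[ok]], id[cbind(r2[ok], c2[ok])]))
  }
  if (is.null(edges)) { out[idx] <- 1L; return(out) }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  out[idx] <- as.integer(comp$csize[comp$membership[seq_along(idx)]])
  out
}

# set-arithmetic binary morphology (background outside the image)
.kernOffsets <- function(kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  w <- which(kern > 0, arr.ind = TRUE)
  cbind(w[, 1] - r - 1L, w[, 2] - r - 1L)
}

oracleDilate <- function(m, kern) {
  off <- .kernOffsets(kern)
  out <- matrix(FALSE, nrow(m), ncol(m))
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0L) return(out)
  for (k in seq_len(nrow(off))) {
    r2 <- fg[, 1] + off[k, 1]; c2 <- fg[, 2] + off[k, 2]
    ok <- r2 >= 1 & r2 <= nrow(m) & c2 >= 1 & c2 <= ncol(m)
    out[cbind(r2[ok], c2[ok])] <- TRUE
  }
  out
}

oracleErode <- function(m, kern) {
  off <- .kernOffsets(kern)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off))) {
    sh <- matrix(FALSE, nrow(m), ncol(m)) # outside = background
    rs <- max(1, 1 + off[k, 1]):min(nrow(m), nrow(m) + off[k, 1])
    cs <- max(1, 1 + off[k, 2]):min(ncol(m), ncol(m) + off[k, 2])
    sh[rs - off[k, 1], cs - off[k, 2]] <- m[rs, cs]
    out <- out & sh
  }
  out
}

# plane semantics: close inside a zero-padded embedding, then crop
oracleClosing <- function(m, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  p <- matrix(FALSE, nrow(m) + 2L * r, ncol(m) + 2L * r)
  p[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m))] <- m
  cl <- oracleErode(oracleDilate(p, kern), kern)
  cl[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

randomMask <- function(nr = 64, nc = 64, density = 0.2, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc) < density, nr, nc)
}
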