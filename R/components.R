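# Connected-component labeling for binary 2D/3D grids.
# Full box connectivity (8-connected in 2D, 26-connected in 3D): voxels
# sharing a face, edge or corner belong to the same component. Breadth-first
# search with vectorized frontier expansion; only foreground voxels are
# visited, so cost scales with lesion size, not grid size.

label_components <- function(a) {
  dims <- dim(a)
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L))
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), nd)))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  k <- nrow(offs)
  labels <- array(0L, dims)
  fg <- which(a > 0)
  n_comp <- 0L
  if (!length(fg)) return(list(labels = labels, n = 0L))
  unvisited <- array(FALSE, dims)
  unvisited[fg] <- TRUE
  for (seed_lin in fg) {
    if (!unvisited[seed_lin]) next
    n_comp <- n_comp + 1L
    unvisited[seed_lin] <- FALSE
    labels[seed_lin] <- n_comp
    frontier <- seed_lin
    while (length(frontier)) {
      co <- arrayInd(frontier, dims)
      m <- nrow(co)
      nb <- co[rep(seq_len(m), each = k), , drop = FALSE] +
        offs[rep(seq_len(k), times = m), , drop = FALSE]
      ok <- rep(TRUE, nrow(nb))
      for (d in seq_len(nd)) ok <- ok & nb[, d] >= 1L & nb[, d] <= dims[d]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(coords_to_linear(nb, dims))
      lin <- lin[unvisited[lin]]
      if (length(lin)) {
        unvisited[lin] <- FALSE
        labels[lin] <- n_comp
        frontier <- lin
      } else {
        frontier <- integer(0)
      }
    }
  }
  list(labels = labels, n = n_comp)
}

# physical-mm centroids (voxel center of index i at (i-1)*spacing) per label
component_centroids <- function(labels, n, spacing) {
  if (n == 0L) return(matrix(numeric(0), ncol = length(dim(labels))))
  fg <- which(labels > 0)
  co <- arrayInd(fg, dim(labels))
  lab <- labels[fg]
  cen <- rowsum(co, lab) / as.vector(table(lab))
  sweep(cen - 1, 2, spacing, `*`)
}
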