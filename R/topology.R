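#' Lattice specification
#'
#' @param rows,cols lattice dimensions (default 60 x 60; 80 x 80 is
#'   supported by all builders).
#' @return A list with `rows`, `cols`, `n`.
#' @export
lattice_spec <- function(rows = 60, cols = 60) {
  stopifnot(rows >= 2, cols >= 2)
  list(rows = as.integer(rows), cols = as.integer(cols),
       n = as.integer(rows * cols))
}

## column-major cell index of (i, j)
cell_index <- function(i, j, rows) (j - 1L) * rows + i

#' 4-neighbour lattice adjacency
#'
#' Builds the undirected 4-neighbour grid graph of a layer as a sparse
#' binary symmetric matrix with zero diagonal. Edge count is
#' `rows*(cols-1) + cols*(rows-1)`.
#'
#' @param spec a [lattice_spec()].
#' @return A `dgCMatrix` (n x n).
#' @export
build_lattice4 <- function(spec) {
  nr <- spec$rows; nc <- spec$cols
  i <- rep(seq_len(nr), nc); j <- rep(seq_len(nc), each = nr)
  k <- cell_index(i, j, nr)
  ## vertical edges (i, j) -- (i+1, j); horizontal (i, j) -- (i, j+1)
  vsel <- i < nr; hsel <- j < nc
  from <- c(k[vsel], k[hsel])
  to <- c(k[vsel] + 1L, k[hsel] + nr)
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(spec$n, spec$n))
}

#' TC-RE cross map (4 nearest neighbours across layers)
#'
#' Connects every cell of one layer to the four nearest-neighbour positions
#' of the other layer (rows truncated at the boundary). The same map also
#' serves as the lateral excitation map of the collapsed thalamic layer in
#' the reduced model. Structurally identical to [build_lattice4()].
#'
#' @param spec a [lattice_spec()] shared by both layers.
#' @return A `dgCMatrix` whose interior rows sum to 4, corner rows to 2.
#' @export
build_c_th <- function(spec) build_lattice4(spec)

## symmetric upper-triangle edge list of a binary symmetric matrix
.edge_list <- function(adj) {
  ut <- Matrix::triu(adj, 1)
  sm <- methods::as(methods::as(ut, "generalMatrix"), "TsparseMatrix")
  cbind(i = sm@i + 1L, j = sm@j + 1L)
}

.from_edge_list <- function(edges, n) {
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                       j = c(edges[, 2], edges[, 1]),
                       x = 1, dims = c(n, n))
}

#' Thin a lattice adjacency to a target connectivity fraction
#'
#' Removes edges uniformly at random (symmetrically) until exactly
#' `round(fraction * full)` edges remain, where `full` is the edge count of
#' the reference full 4-neighbour lattice (the 100% level). By-count
#' construction: the realised fraction matches the target to within one
#' edge. Deterministic under the R random seed.
#'
#' @param adj symmetric binary adjacency (subset of the 4-neighbour
#'   lattice).
#' @param fraction target fraction of the full lattice's edges.
#' @param full_edges edge count of the reference full lattice; defaults to
#'   the current edge count of `adj` (so thinning an intact lattice gives
#'   the usual meaning).
#' @return Thinned adjacency.
#' @export
thin_uniform <- function(adj, fraction, full_edges = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  edges <- .edge_list(adj)
  m <- nrow(edges)
  if (is.null(full_edges)) full_edges <- m
  target <- round(fraction * full_edges)
  if (target >= m) {
    if (target > m) warning("target above current edge count; no-op")
    return(adj)
  }
  keep <- sample.int(m, target)
  .from_edge_list(edges[keep, , drop = FALSE], nrow(adj))
}

#' Cluster specification for clustered intracortical connectivity
#'
#' @param regions a list of rectangular blocks, each
#'   `list(rows = i1:i2, cols = j1:j2)`.
#' @param intra_fraction target connectivity inside the regions (of the
#'   full-lattice edges contained in them).
#' @param overall_fraction global target fraction.
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(regions, intra_fraction = 0.90,
                         overall_fraction = 0.25) {
  stopifnot(is.list(regions), length(regions) >= 1,
            intra_fraction > 0, intra_fraction <= 1,
            overall_fraction > 0, overall_fraction <= 1)
  structure(list(regions = regions, intra_fraction = intra_fraction,
                 overall_fraction = overall_fraction),
            class = "cluster_spec")
}

#' Thin a lattice, keeping clusters densely connected
#'
#' Edges with both endpoints inside a cluster region are kept at
#' `intra_fraction`; edges outside are thinned so that the overall fraction
#' equals `overall_fraction`. Both counts are realised exactly (to one
#' edge). Errors with the feasibility bound if the outside edge budget
#' would be negative.
#'
#' @param adj the intact 4-neighbour adjacency of the layer.
#' @param spec a [lattice_spec()] describing the layer.
#' @param cluster a [cluster_spec()].
#' @return Thinned adjacency.
#' @export
thin_clustered <- function(adj, spec, cluster) {
  stopifnot(inherits(cluster, "cluster_spec"))
  edges <- .edge_list(adj)
  m <- nrow(edges)
  inside_cell <- rep(FALSE, spec$n)
  for (rg in cluster$regions) {
    ij <- expand.grid(i = rg$rows, j = rg$cols)
    inside_cell[cell_index(ij$i, ij$j, spec$rows)] <- TRUE
  }
  e_in <- inside_cell[edges[, 1]] & inside_cell[edges[, 2]]
  n_in <- sum(e_in); n_out <- m - n_in
  keep_in <- round(cluster$intra_fraction * n_in)
  total <- round(cluster$overall_fraction * m)
  keep_out <- total - keep_in
  if (keep_out < 0)
    stop("infeasible cluster spec: overall fraction must be at least ",
         format(keep_in / m, digits = 4),
         " given the intra-cluster fraction")
  if (keep_out > n_out)
    stop("infeasible cluster spec: only ", n_out,
         " edges outside the clusters, need ", keep_out)
  sel_in <- which(e_in)[sample.int(n_in, keep_in)]
  sel_out <- which(!e_in)[sample.int(n_out, keep_out)]
  .from_edge_list(edges[c(sel_in, sel_out), , drop = FALSE], spec$n)
}

#' Random bipartite connectivity matrix
#'
#' Places exactly `round(fraction * n_pre * n_post)` ones uniformly at
#' random without replacement. Deterministic under the R random seed.
#'
#' @param n_pre,n_post matrix dimensions (post x pre: row gathers
#'   presynaptic values).
#' @param fraction fraction of all pairs connected.
#' @return A binary `dgCMatrix` (n_post x n_pre).
#' @export
random_bipartite <- function(n_pre, n_post, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  total <- as.double(n_pre) * n_post
  k <- round(fraction * total)
  if (k == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_post, n_pre)))
  pos <- sample(total, k)
  Matrix::sparseMatrix(i = as.integer((pos - 1) %% n_post) + 1L,
                       j = as.integer((pos - 1) %/% n_post) + 1L,
                       x = 1, dims = c(n_post, n_pre))
}

#' Topographic projection mask
#'
#' Selects exactly `round(fraction * n)` source cells, uniformly at random,
#' that project to their matching lattice position in the target layer
#' (e.g. "10% of relay cells affect the cortex directly"). Returned as a
#' 0/1 vector over cells; multiplying a synapse field by it implements the
#' projection.
#'
#' @param n number of cells.
#' @param fraction fraction of cells that project.
#' @return Numeric 0/1 vector of length `n`.
#' @export
topographic_mask <- function(n, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  m <- numeric(n)
  k <- round(fraction * n)
  if (k > 0) m[sample.int(n, k)] <- 1
  m
}

#' Assign excitatory/inhibitory labels
#'
#' Exactly `round(n * excitatory_fraction)` cells are labelled excitatory,
#' uniformly at random.
#'
#' @param n number of cells.
#' @param excitatory_fraction fraction labelled `"E"`.
#' @return Character vector of `"E"`/`"I"`.
#' @export
assign_ei <- function(n, excitatory_fraction = 0.8) {
  stopifnot(excitatory_fraction >= 0, excitatory_fraction <= 1)
  lab <- rep("I", n)
  k <- round(n * excitatory_fraction)
  if (k > 0) lab[sample.int(n, k)] <- "E"
  lab
}

#' Realised connectivity fraction
#'
#' Kept connections over possible connections. For intra-cortical
#' adjacencies the reference is the edge count of the full 4-neighbour
#' lattice; for bipartite matrices it is `n_pre * n_post`; for masks the
#' number of cells.
#'
#' @param x adjacency matrix or mask vector.
#' @param reference possible-connection count.
#' @return Fraction in `[0, 1]`.
#' @export
connectivity_fraction <- function(x, reference) {
  kept <- if (is.numeric(x) && is.null(dim(x))) sum(x != 0)
          else Matrix::nnzero(x) / 2  # symmetric adjacency: count edges
  if (methods::is(x, "Matrix") && nrow(x) != ncol(x))
    kept <- Matrix::nnzero(x)  # bipartite: count entries
  kept / reference
}

#' Count undirected edges of a symmetric adjacency
#'
#' @param adj symmetric binary matrix.
#' @return Edge count (nnz / 2).
#' @export
edge_count <- function(adj) Matrix::nnzero(adj) / 2

#' Export / import connectivity as coordinate-list text
#'
#' Writes the (row, col) coordinates of nonzero entries as a tab-separated
#' file plus a JSON sidecar recording dimensions and any metadata, enabling
#' exact replay.
#'
#' @param x sparse matrix.
#' @param path output path (`.tsv`); the sidecar goes to `paste0(path,
#'   ".json")`.
#' @param meta named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(x, path, meta = list()) {
  sm <- methods::as(methods::as(x, "generalMatrix"), "TsparseMatrix")
  utils::write.table(data.frame(row = sm@i + 1L, col = sm@j + 1L),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(nrow = nrow(x), ncol = ncol(x)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  Matrix::sparseMatrix(i = df$row, j = df$col, x = 1,
                       dims = c(side$nrow, side$ncol))
}
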