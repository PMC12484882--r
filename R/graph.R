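#' Unit direction vectors for a set of directed edges
#'
#' For each directed edge `(i, j)` returns the unit vector pointing from
#' atom `j` towards atom `i`: `d_ij = (p_i - p_j) / ||p_i - p_j||`.
#' Directions are antisymmetric, `d_ji = -d_ij`.
#'
#' @param conf a [conformation()] (or any object with a `positions` matrix).
#' @param edges integer matrix `e x 2` of directed edges `(i, j)` (1-based).
#' @return numeric matrix `e x 3` of unit vectors.
#' @export
unit_directions <- function(conf, edges) {
  pos <- if (is.matrix(conf)) conf else conf$positions
  edges <- matrix(as.integer(edges), ncol = 2L)
  diff <- pos[edges[, 1L], , drop = FALSE] - pos[edges[, 2L], , drop = FALSE]
  len <- row_norms(diff)
  if (any(len < 1e-12))
    stop("zero-length edge between coincident atoms: ",
         paste(edges[which(len < 1e-12)[1L], ], collapse = ","))
  diff / len
}

#' Build a molecular radius graph with nearest-neighbor augmentation
#'
#' Connects every atom pair within `cutoff`; any atom left with fewer than
#' `min_neighbors` neighbors is additionally connected to its nearest atoms
#' until the minimum is reached. If an atom's neighbor directions are still
#' (near-)coplanar and unconnected atoms remain, the next-nearest atoms are
#' added until the directions span 3D. The edge set is symmetric and stored
#' in both directions, ordered lexicographically by `(i, j)`.
#'
#' On generic (non-planar) molecules with at least 4 atoms this guarantees
#' every node at least 3 neighbors whose directions span 3D — the condition
#' the sphere-fit coordinate reconstruction relies on.
#'
#' @param conf a [conformation()].
#' @param cutoff radius cutoff in Angstrom (default 5).
#' @param min_neighbors minimum neighbor count per node (default 3).
#' @return an object of class `molecular_graph` with fields `edges`
#'   (`e x 2`, directed, 1-based), `directions` (`e x 3` unit vectors
#'   `d_ij` from `j` to `i`), `lengths` (`e`), `neighbors` (list of
#'   integer vectors), `rev_index` (index of the opposite directed edge)
#'   and `incoming` (list: directed edges `(i, .)` per node `i`).
#' @export
build_graph <- function(conf, cutoff = 5.0, min_neighbors = 3L) {
  pos <- conf$positions
  n <- nrow(pos)
  if (n < 2L) stop("graph undefined for a single-atom molecule")
  d2 <- as.matrix(stats::dist(pos))
  diag(d2) <- Inf
  if (min(d2) < 1e-12) {
    bad <- which(d2 < 1e-12, arr.ind = TRUE)[1L, ]
    stop("degenerate pair: atoms ", bad[1L], " and ", bad[2L],
         " are coincident")
  }
  adj <- d2 <= cutoff
  mn <- min(min_neighbors, n - 1L)
  for (i in seq_len(n)) {
    ord <- setdiff(order(d2[i, ]), i)
    k <- sum(adj[i, ])
    if (k < mn) {
      add <- ord[seq_len(mn)]
      adj[i, add] <- TRUE
      adj[add, i] <- TRUE
    }
    # fallback: extend until neighbor directions span 3D (when possible)
    if (n >= 4L) {
      repeat {
        nb <- which(adj[i, ])
        dirs <- pos[nb, , drop = FALSE] -
          matrix(pos[i, ], length(nb), 3L, byrow = TRUE)
        dirs <- dirs / row_norms(dirs)
        if (length(nb) >= 3L &&
            min(eigen(crossprod(dirs), symmetric = TRUE,
                      only.values = TRUE)$values) > 1e-8) break
        rest <- setdiff(ord, nb)
        if (length(rest) == 0L) break
        j <- rest[1L]
        adj[i, j] <- TRUE
        adj[j, i] <- TRUE
      }
    }
  }
  idx <- which(adj, arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  new_molecular_graph(pos, edges)
}

# Assemble graph bookkeeping (directions, neighbor sets, reverse-edge and
# incoming-edge indices) for a fixed directed edge set.
new_molecular_graph <- function(pos, edges) {
  n <- nrow(pos)
  directions <- unit_directions(pos, edges)
  lengths <- row_norms(pos[edges[, 1L], , drop = FALSE] -
                         pos[edges[, 2L], , drop = FALSE])
  neighbors <- lapply(seq_len(n), function(i) edges[edges[, 1L] == i, 2L])
  key <- edges[, 1L] + (edges[, 2L] - 1) * n
  rkey <- edges[, 2L] + (edges[, 1L] - 1) * n
  rev_index <- match(rkey, key)
  incoming <- split(seq_len(nrow(edges)), edges[, 1L])
  incoming <- lapply(as.character(seq_len(n)), function(k)
    incoming[[k]] %||% integer(0))
  structure(list(edges = edges, directions = directions, lengths = lengths,
                 neighbors = neighbors, rev_index = rev_index,
                 incoming = incoming, n_nodes = n),
            class = "molecular_graph")
}

#' Recompute graph geometry for new coordinates
#'
#' Keeps the edge topology of `graph` but refreshes directions and lengths
#' from `positions` — used after each learned coordinate update.
#'
#' @param graph a `molecular_graph`.
#' @param positions `n x 3` matrix of new coordinates.
#' @return a `molecular_graph` with updated geometry.
#' @export
update_graph_geometry <- function(graph, positions) {
  positions <- as.matrix(positions)
  g <- graph
  g$directions <- unit_directions(positions, g$edges)
  g$lengths <- row_norms(positions[g$edges[, 1L], , drop = FALSE] -
                           positions[g$edges[, 2L], , drop = FALSE])
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}
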