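# Edge-projection label decomposition and the closed-form sphere-fit
# reconstruction of per-node coordinate updates.

#' Decompose node-level displacement labels into edge scalars
#'
#' Projects each node's target displacement onto the unit direction of
#' every incoming edge: `u_ij = <d_ij, dp*_i>`. Each scalar depends only
#' on the edge direction and the node's own displacement, so it is
#' independent of the neighborhood size and invariant to how the graph was
#' constructed.
#'
#' @param delta_star `n x 3` matrix of target displacements per node.
#' @param graph a `molecular_graph` whose directions correspond to the
#'   geometry at which the supervision is defined.
#' @return numeric vector of per-directed-edge label scalars `u`.
#' @export
decompose_labels <- function(delta_star, graph) {
  delta_star <- as.matrix(delta_star)
  rowSums(graph$directions * delta_star[graph$edges[, 1L], , drop = FALSE])
}

#' Reconstruct per-node coordinate updates from edge projections
#'
#' Given a predicted scalar `m_ij` per directed edge, forms the projection
#' vectors `v_ij = m_ij * d_ij` and, for every node, fits the sphere
#' through the origin that best matches them by minimizing
#' `sum_j (||v_ij - c_i||^2 - ||c_i||^2)^2`. The minimizer is available in
#' closed form: with `b_i = mean_j (v_ij' v_ij) v_ij` and
#' `A_i = mean_j v_ij v_ij'`, the center is
#' `c_i = (2 A_i + eps I)^{-1} b_i` and the update is `dp_i = 2 c_i`.
#' When the projections are consistent (`m_ij = <d_ij, dp>` for a common
#' `dp`) and the directions span 3D, `dp` is recovered exactly at
#' `eps = 0`.
#'
#' @param m numeric vector of per-directed-edge scalars (or a list with a
#'   field `m`).
#' @param graph a `molecular_graph`; every node needs >= 3 neighbors.
#' @param eps ridge regularization added to `2 A_i` (default `1e-6`);
#'   guards near-coplanar neighborhoods without biasing well-conditioned
#'   ones.
#' @return object of class `position_update`: `delta_p` (`n x 3`),
#'   `centers`, `b` (`n x 3`), `A` (`3 x 3 x n`), `v` (`e x 3`), `m`,
#'   `reg_eps`.
#' @export
reconstruct_update <- function(m, graph, eps = 1e-6) {
  if (is.list(m)) m <- m$m
  if (eps < 0) stop("eps must be >= 0")
  e <- nrow(graph$edges)
  stopifnot(length(m) == e)
  d <- graph$directions
  v <- m * d
  n <- graph$n_nodes
  delta_p <- matrix(0, n, 3L)
  centers <- matrix(0, n, 3L)
  b_all <- matrix(0, n, 3L)
  A_all <- array(0, c(3L, 3L, n))
  for (i in seq_len(n)) {
    ids <- graph$incoming[[i]]
    k <- length(ids)
    di <- d[ids, , drop = FALSE]
    mi <- m[ids]
    b <- colSums(mi^3 * di) / k
    A <- crossprod(di * mi^2, di) / k
    A <- (A + t(A)) / 2
    M <- 2 * A + diag(eps, 3L)
    if (eps == 0 && rcond(M) < 1e-12)
      stop("singular projection matrix at node ", i,
           "; use eps > 0 to regularize")
    ci <- solve(M, b)
    ci <- ci + solve(M, b - M %*% ci)  # one step of iterative refinement
    b_all[i, ] <- b
    A_all[, , i] <- A
    centers[i, ] <- ci
    delta_p[i, ] <- 2 * ci
  }
  structure(list(delta_p = delta_p, centers = centers, b = b_all,
                 A = A_all, v = v, m = m, reg_eps = eps),
            class = "position_update")
}

# Gradient of a loss wrt the edge scalars m, given the gradient wrt the
# reconstructed updates delta_p. Uses the closed-form derivative of
# c = (2A + eps I)^{-1} b with db/dm = 3 m^2 d / k and
# d(Ac)/dm = 2 m <d, c> d / k.
reconstruct_update_backward <- function(recon, graph, g_delta_p) {
  d <- graph$directions
  m <- recon$m
  g_m <- numeric(length(m))
  for (i in seq_len(graph$n_nodes)) {
    ids <- graph$incoming[[i]]
    k <- length(ids)
    M <- 2 * recon$A[, , i] + diag(recon$reg_eps, 3L)
    y <- solve(M, 2 * g_delta_p[i, ])        # d(loss)/d(b-side), symmetric M
    ci <- recon$centers[i, ]
    di <- d[ids, , drop = FALSE]
    mi <- m[ids]
    g_m[ids] <- g_m[ids] +
      (di %*% y) * (3 * mi^2 - 4 * mi * drop(di %*% ci)) / k
  }
  g_m
}

#' Initialize a positional update head
#'
#' A two-layer feed-forward map (GeLU nonlinearity) from the concatenated
#' head-node, tail-node and edge features of each directed edge to the
#' scalar projection magnitude `m_ij`.
#'
#' @param hidden_dim width of node/edge features.
#' @param d_hidden hidden width of the head (default `hidden_dim`).
#' @return parameter list (`ffn` field).
#' @export
init_position_head <- function(hidden_dim, d_hidden = hidden_dim) {
  list(ffn = init_ffn(3L * hidden_dim, d_hidden, 1L))
}

#' Predict and apply a coordinate update
#'
#' The positional update block of the architecture: per-edge scalars are
#' predicted by the head from `[x_i || x_j || e_ij]`, reconstructed into
#' per-node updates via [reconstruct_update()], and added to the current
#' coordinates. Because the predicted scalars are invariant features and
#' the directions rotate with the molecule, the update is
#' SE(3)-equivariant.
#'
#' @param node_feats `n x h` node features.
#' @param edge_feats `e x h` edge features.
#' @param graph `molecular_graph` matching the current positions.
#' @param positions `n x 3` current coordinates.
#' @param head parameters from [init_position_head()].
#' @param eps regularization for the reconstruction.
#' @param block_index integer used in error messages.
#' @return list with `positions` (updated), `delta` (`n x 3`), `m`,
#'   `recon` and `cache` (for backpropagation).
#' @export
positional_update_block <- function(node_feats, edge_feats, graph, positions,
                                    head, eps = 1e-6, block_index = 1L) {
  ii <- graph$edges[, 1L]
  jj <- graph$edges[, 2L]
  z <- cbind(node_feats[ii, , drop = FALSE],
             node_feats[jj, , drop = FALSE],
             edge_feats)
  ff <- ffn_fwd(z, head$ffn)
  m <- drop(ff$out)
  if (!all(is.finite(m)))
    stop("non-finite edge predictions in positional update block ",
         block_index)
  recon <- reconstruct_update(m, graph, eps = eps)
  list(positions = positions + recon$delta_p, delta = recon$delta_p,
       m = m, recon = recon, cache = ff)
}

# Backward for positional_update_block. g_positions is the gradient wrt
# the updated coordinates; g_m_extra adds any direct edge-level loss
# gradient on m. Returns head gradients plus gradients wrt the incoming
# node and edge features (coordinates are treated as constants).
positional_update_backward <- function(block_out, graph, head, hidden_dim,
                                       g_positions = NULL, g_m_extra = NULL) {
  e <- length(block_out$m)
  g_m <- if (is.null(g_positions)) numeric(e) else
    reconstruct_update_backward(block_out$recon, graph, g_positions)
  if (!is.null(g_m_extra)) g_m <- g_m + g_m_extra
  bw <- ffn_bwd(block_out$cache, head$ffn, matrix(g_m, ncol = 1L))
  gz <- bw$gx
  h <- hidden_dim
  ii <- graph$edges[, 1L]
  jj <- graph$edges[, 2L]
  g_node <- matrix(0, graph$n_nodes, h)
  acc_i <- rowsum(gz[, 1:h, drop = FALSE], ii, reorder = TRUE)
  g_node[as.integer(rownames(acc_i)), ] <- acc_i
  acc_j <- rowsum(gz[, (h + 1L):(2L * h), drop = FALSE], jj, reorder = TRUE)
  g_node[as.integer(rownames(acc_j)), ] <-
    g_node[as.integer(rownames(acc_j)), , drop = FALSE] + acc_j
  list(grad = list(ffn = bw$grad),
       g_node = g_node,
       g_edge = gz[, (2L * h + 1L):(3L * h), drop = FALSE])
}
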