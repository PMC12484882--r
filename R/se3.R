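# Chirality-aware SE(3) edge featurization: permutation-invariant cross
# product vectors, torsion angles, circular harmonics and radial basis.

#' Permutation-invariant chirality vectors per directed edge
#'
#' For each directed edge `(i, j)` computes
#' `c_ij = sum_{k in N(i) \\ j} d_ij x d_ik`, the sum of cross products of
#' the edge direction with all other neighbor directions at `i`. The sum is
#' independent of neighbor enumeration order and rotates with the molecule.
#' Since `sum_k d_ij x d_ik = d_ij x (S_i - d_ij) = d_ij x S_i` with
#' `S_i = sum_{k in N(i)} d_ik`, the sum collapses to a single cross
#' product, which is how it is evaluated here.
#'
#' Edges whose own or whose reverse vector has near-zero norm (collinear or
#' too-sparse neighborhoods) are flagged degenerate rather than erroring.
#'
#' @param graph a `molecular_graph` from [build_graph()].
#' @param tol norm threshold below which a vector counts as degenerate.
#' @return list with `c` (`e x 3`, the vector for each stored directed
#'   edge), `c_rev` (`e x 3`, the vector of the opposite edge) and
#'   `degenerate_mask` (logical, per edge).
#' @export
chirality_vectors <- function(graph, tol = 1e-8) {
  d <- graph$directions
  n <- graph$n_nodes
  head_node <- graph$edges[, 1L]
  s <- rowsum(d, head_node, reorder = TRUE)
  s_full <- matrix(0, n, 3L)
  s_full[as.integer(rownames(s)), ] <- s
  cvec <- cross3(d, s_full[head_node, , drop = FALSE])
  c_rev <- cvec[graph$rev_index, , drop = FALSE]
  deg <- row_norms(cvec) < tol | row_norms(c_rev) < tol
  list(c = cvec, c_rev = c_rev, degenerate_mask = deg)
}

#' Chirality-aware torsion angle per edge
#'
#' Computes `psi_ij = asin(< (c_ij x c_ji) / (|c_ij| |c_ji|), d_ij >)` for
#' every directed edge. The angle lies in `[-pi/2, pi/2]`, takes the same
#' value in both edge directions, is invariant under rotations and
#' translations, and flips sign when the molecule is reflected — the
#' property that makes the featurization chirality-aware. Degenerate edges
#' get `psi = 0` with `valid = FALSE`. The `asin` argument is clamped to
#' `[-1, 1]` against roundoff.
#'
#' @param cv chirality vectors from [chirality_vectors()] on the same graph.
#' @param graph the `molecular_graph` the vectors were computed on.
#' @return list with `psi` (numeric, radians) and `valid` (logical).
#' @export
torsion_angles <- function(cv, graph) {
  num <- cross3(cv$c, cv$c_rev)
  denom <- row_norms(cv$c) * row_norms(cv$c_rev)
  denom[cv$degenerate_mask] <- 1
  arg <- rowSums(num * graph$directions) / denom
  psi <- asin(clamp(arg, -1, 1))
  psi[cv$degenerate_mask] <- 0
  list(psi = psi, valid = !cv$degenerate_mask)
}

#' Circular-harmonic embedding of torsion angles
#'
#' Expands each angle into `sin(w * psi)` (degree `l = 1`) and
#' `cos(w * psi)` (degree `l = -1`) for every order
#' `w in {-Omega, ..., Omega}`. Column layout: the `2*Omega + 1` sine
#' channels for `w = -Omega..Omega` first, then the `2*Omega + 1` cosine
#' channels in the same order. The sine block is negated under reflection
#' of the molecule; the cosine block is unchanged.
#'
#' @param psi torsion angles (radians), or the list from [torsion_angles()].
#' @param Omega maximal harmonic order (>= 1).
#' @return matrix `length(psi) x 2*(2*Omega+1)` with entries in `[-1, 1]`.
#' @export
circular_harmonics <- function(psi, Omega = 4L) {
  if (is.list(psi)) psi <- psi$psi
  if (Omega < 1L) stop("Omega must be >= 1")
  omega <- seq.int(-Omega, Omega)
  ang <- outer(psi, omega)
  cbind(sin(ang), cos(ang))
}

#' Gaussian radial basis embedding of edge lengths
#'
#' Evaluates `n_basis` Gaussian bumps with centers evenly spaced on
#' `[0, r_max]` and width equal to the center spacing:
#' `exp(-0.5 * ((r - c_k) / w)^2)`. A length sitting exactly on a center
#' scores 1 there; values decay monotonically away from each center.
#'
#' @param lengths positive edge lengths (Angstrom).
#' @param n_basis number of basis functions (default 32).
#' @param r_max upper end of the center grid (Angstrom, > 0).
#' @return matrix `length(lengths) x n_basis` with entries in `(0, 1]`.
#' @export
radial_embedding <- function(lengths, n_basis = 32L, r_max = 5.0) {
  if (r_max <= 0) stop("r_max must be positive")
  if (n_basis < 2L) stop("n_basis must be >= 2")
  if (any(lengths <= 0)) stop("edge lengths must be positive")
  centers <- seq(0, r_max, length.out = n_basis)
  width <- centers[2L] - centers[1L]
  exp(-0.5 * ((outer(lengths, centers, `-`)) / width)^2)
}

#' Initialize the SE(3) encoder parameters
#'
#' The encoder embeds atomic numbers into `hidden_dim`-vectors and maps the
#' concatenated circular-harmonic + radial edge descriptor through a
#' learned affine layer. Setting `use_torsion = FALSE` zeroes the harmonic
#' block, which makes the encoder purely distance-based and therefore
#' blind to reflections (useful as an ablation baseline).
#'
#' @param hidden_dim feature width.
#' @param Omega maximal circular-harmonic order.
#' @param n_basis number of radial basis functions.
#' @param r_max radial basis range (Angstrom); sensibly the graph cutoff.
#' @param supported_elements atomic numbers the encoder accepts.
#' @param use_torsion include the chirality-aware harmonic block?
#' @param seed integer seed for weight initialization.
#' @return parameter list of class `se3_encoder`.
#' @export
init_se3_encoder <- function(hidden_dim = 64L, Omega = 4L, n_basis = 32L,
                             r_max = 5.0,
                             supported_elements = c(1L, 5L, 6L, 7L, 8L, 9L,
                                                    14L, 15L, 16L, 17L,
                                                    35L, 53L),
                             use_torsion = TRUE, seed = 1L) {
  n_harm <- 2L * (2L * Omega + 1L)
  f_in <- n_harm + n_basis
  with_seed(seed, {
    structure(list(
      element_embedding = matrix(stats::rnorm(length(supported_elements) *
                                                hidden_dim, sd = 0.5),
                                 length(supported_elements), hidden_dim),
      W_edge = matrix(stats::rnorm(f_in * hidden_dim, sd = 1 / sqrt(f_in)),
                      f_in, hidden_dim),
      b_edge = numeric(hidden_dim),
      supported_elements = supported_elements,
      hidden_dim = as.integer(hidden_dim), Omega = as.integer(Omega),
      n_basis = as.integer(n_basis), r_max = r_max,
      use_torsion = isTRUE(use_torsion)),
      class = "se3_encoder")
  })
}

#' Encode a conformation into node and edge features
#'
#' Edge features are a learned affine map of the concatenated
#' circular-harmonic (torsion) and Gaussian radial descriptors; node
#' features are the element embedding plus the sum of incoming edge
#' features. All outputs are invariant under rigid motions of the input;
#' with `use_torsion = TRUE` the harmonic channels additionally flip sign
#' under reflection, making mirror images distinguishable.
#'
#' @param conf a [conformation()].
#' @param graph the `molecular_graph` built on `conf`.
#' @param encoder parameters from [init_se3_encoder()].
#' @return list with `node` (`n x hidden`), `edge` (`e x hidden`),
#'   `edge_raw` (pre-affine descriptors), `psi`, `valid` and the element
#'   row index `elem_idx` (kept for backpropagation).
#' @export
se3_encode <- function(conf, graph, encoder) {
  elem_idx <- match(conf$elements, encoder$supported_elements)
  if (anyNA(elem_idx))
    stop("unknown element(s) ",
         paste(unique(conf$elements[is.na(elem_idx)]), collapse = ", "),
         "; supported atomic numbers: ",
         paste(encoder$supported_elements, collapse = ", "))
  tors <- torsion_angles(chirality_vectors(graph), graph)
  harm <- circular_harmonics(tors$psi, encoder$Omega)
  if (!encoder$use_torsion) harm[] <- 0
  radial <- radial_embedding(graph$lengths, encoder$n_basis, encoder$r_max)
  edge_raw <- cbind(harm, radial)
  edge <- edge_raw %*% encoder$W_edge +
    rep(encoder$b_edge, each = nrow(edge_raw))
  pooled <- rowsum(edge, graph$edges[, 1L], reorder = TRUE)
  node <- encoder$element_embedding[elem_idx, , drop = FALSE]
  got <- as.integer(rownames(pooled))
  node[got, ] <- node[got, , drop = FALSE] + pooled
  list(node = node, edge = edge, edge_raw = edge_raw,
       psi = tors$psi, valid = tors$valid, elem_idx = elem_idx)
}

# Backward pass of se3_encode: given upstream gradients for node and edge
# features, returns parameter gradients. Geometry (edge_raw) receives none:
# coordinates are treated as constants for differentiation.
se3_encode_backward <- function(enc_out, graph, encoder, g_node, g_edge) {
  g_edge_total <- g_edge
  heads <- graph$edges[, 1L]
  g_edge_total <- g_edge_total + g_node[heads, , drop = FALSE]
  g_emb <- matrix(0, nrow(encoder$element_embedding), encoder$hidden_dim)
  acc <- rowsum(g_node, enc_out$elem_idx, reorder = TRUE)
  g_emb[as.integer(rownames(acc)), ] <- acc
  list(element_embedding = g_emb,
       W_edge = crossprod(enc_out$edge_raw, g_edge_total),
       b_edge = colSums(g_edge_total))
}
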