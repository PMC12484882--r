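# Model assembly: configuration, parameter initialization, the
# attention + mixture-of-experts layer, recycled blocks with positional
# updates, the node-softmax readout, and full analytic backpropagation.

#' Model configuration
#'
#' @param hidden_dim node/edge feature width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_layers_per_block transformer layers per block (may be 0 for a
#'   pure encoder + readout model).
#' @param n_recycles number of recycled blocks `S` (>= 1).
#' @param n_experts experts in each mixture-of-experts layer.
#' @param d_emb task-embedding dimension.
#' @param Omega maximal circular-harmonic order.
#' @param n_basis radial basis size.
#' @param cutoff,min_neighbors graph construction parameters (Angstrom).
#' @param use_torsion include chirality-aware torsion features?
#' @param position_update run the coordinate update block each recycle?
#' @param share_recycle_weights reuse one block's weights across recycles?
#' @param supported_elements atomic numbers accepted by the encoder.
#' @param max_tasks, d_id task-id embedding capacity and width.
#' @param eps ridge regularization for the sphere-fit reconstruction.
#' @return a validated config list of class `model_config`.
#' @export
model_config <- function(hidden_dim = 128L, n_heads = 8L,
                         n_layers_per_block = 3L, n_recycles = 4L,
                         n_experts = 8L, d_emb = 64L, Omega = 4L,
                         n_basis = 32L, cutoff = 5.0, min_neighbors = 3L,
                         use_torsion = TRUE, position_update = TRUE,
                         share_recycle_weights = TRUE,
                         supported_elements = c(1L, 5L, 6L, 7L, 8L, 9L,
                                                14L, 15L, 16L, 17L,
                                                35L, 53L),
                         max_tasks = 64L, d_id = 8L, eps = 1e-6) {
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              n_heads = as.integer(n_heads),
              n_layers_per_block = as.integer(n_layers_per_block),
              n_recycles = as.integer(n_recycles),
              n_experts = as.integer(n_experts),
              d_emb = as.integer(d_emb), Omega = as.integer(Omega),
              n_basis = as.integer(n_basis), cutoff = cutoff,
              min_neighbors = as.integer(min_neighbors),
              use_torsion = isTRUE(use_torsion),
              position_update = isTRUE(position_update),
              share_recycle_weights = isTRUE(share_recycle_weights),
              supported_elements = as.integer(supported_elements),
              max_tasks = as.integer(max_tasks), d_id = as.integer(d_id),
              eps = eps)
  if (cfg$n_recycles < 1L) stop("n_recycles must be >= 1")
  if (cfg$hidden_dim < 1L || cfg$d_emb < 1L) stop("dimensions must be positive")
  if (cfg$n_layers_per_block > 0L && cfg$hidden_dim %% cfg$n_heads != 0L)
    stop("hidden_dim must be divisible by n_heads")
  if (cfg$n_experts < 1L) stop("n_experts must be >= 1")
  structure(cfg, class = "model_config")
}

# Encoder view combining config metadata with trainable encoder weights.
encoder_view <- function(config, enc_params) {
  structure(list(element_embedding = enc_params$element_embedding,
                 W_edge = enc_params$W_edge, b_edge = enc_params$b_edge,
                 supported_elements = config$supported_elements,
                 hidden_dim = config$hidden_dim, Omega = config$Omega,
                 n_basis = config$n_basis, r_max = config$cutoff,
                 use_torsion = config$use_torsion),
            class = "se3_encoder")
}

init_attention <- function(h, n_heads) {
  list(Wq = matrix(stats::rnorm(h * h, sd = 1 / sqrt(h)), h, h),
       Wk = matrix(stats::rnorm(h * h, sd = 1 / sqrt(h)), h, h),
       Wv = matrix(stats::rnorm(h * h, sd = 1 / sqrt(h)), h, h),
       Wo = matrix(stats::rnorm(h * h, sd = 1 / sqrt(h)), h, h),
       W_bias = matrix(stats::rnorm(h * n_heads, sd = 1 / sqrt(h)),
                       h, n_heads),
       no_edge_bias = numeric(n_heads))
}

init_layer <- function(config) {
  h <- config$hidden_dim
  list(attn = init_attention(h, config$n_heads),
       ln1 = init_layernorm(h),
       experts = lapply(seq_len(config$n_experts), function(i)
         init_ffn(h, 2L * h, h)),
       ln2 = init_layernorm(h))
}

init_block <- function(config) {
  out <- list(layers = lapply(seq_len(config$n_layers_per_block),
                              function(i) init_layer(config)))
  if (config$position_update)
    out$pos_head <- init_position_head(config$hidden_dim)
  out
}

#' Initialize a full model
#'
#' @param config a [model_config()].
#' @param seed integer seed for all weight initialization.
#' @return object of class `moltask_model` with `$config` and the
#'   trainable parameter tree `$params`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  with_seed(seed, {
    enc <- init_se3_encoder(config$hidden_dim, config$Omega, config$n_basis,
                            config$cutoff, config$supported_elements,
                            config$use_torsion,
                            seed = derive_seed(seed, 1L))
    n_blocks <- if (config$share_recycle_weights) 1L else config$n_recycles
    params <- list(
      encoder = list(element_embedding = enc$element_embedding,
                     W_edge = enc$W_edge, b_edge = enc$b_edge),
      task_enc = init_task_encoder(config$d_emb, config$d_id,
                                   config$max_tasks, config$d_emb,
                                   seed = derive_seed(seed, 2L)),
      router = init_router(config$d_emb, config$n_experts,
                           seed = derive_seed(seed, 3L)),
      blocks = lapply(seq_len(n_blocks), function(i) init_block(config)),
      readout = list(
        score = init_ffn(config$hidden_dim + config$d_emb,
                         config$hidden_dim, 1L),
        head_reg = init_linear(config$hidden_dim, 1L),
        head_cls = init_linear(config$hidden_dim, 1L)))
    structure(list(config = config, params = params, seed = seed),
              class = "moltask_model")
  })
}

#' @export
print.moltask_model <- function(x, ...) {
  cat("<moltask_model> hidden", x$config$hidden_dim, "| layers/block",
      x$config$n_layers_per_block, "| recycles", x$config$n_recycles,
      "| experts", x$config$n_experts, "\n")
  invisible(x)
}

# ---- attention ----------------------------------------------------------

attention_fwd <- function(X, edge_feat, graph, p, n_heads) {
  n <- nrow(X)
  h <- ncol(X)
  dh <- h %/% n_heads
  scale <- 1 / sqrt(dh)
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  bias_e <- edge_feat %*% p$W_bias      # e x n_heads
  eidx <- cbind(graph$edges[, 1L], graph$edges[, 2L])
  heads <- vector("list", n_heads)
  O <- matrix(0, n, h)
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    B <- matrix(p$no_edge_bias[hd], n, n)
    B[eidx] <- bias_e[, hd]
    L <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) *
      scale + B
    P <- softmax_rows(L)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    heads[[hd]] <- list(P = P, cols = cols)
  }
  out <- O %*% p$Wo
  list(out = out, Q = Q, K = K, V = V, O = O, heads = heads,
       bias_e = bias_e, eidx = eidx, scale = scale)
}

attention_bwd <- function(cache, X, edge_feat, p, g_out) {
  n <- nrow(X)
  gWo <- crossprod(cache$O, g_out)
  gO <- g_out %*% t(p$Wo)
  gQ <- matrix(0, n, ncol(X)); gK <- gQ; gV <- gQ
  g_bias_e <- matrix(0, nrow(edge_feat), length(cache$heads))
  g_noedge <- numeric(length(cache$heads))
  for (hd in seq_along(cache$heads)) {
    hh <- cache$heads[[hd]]
    cols <- hh$cols
    P <- hh$P
    gOh <- gO[, cols, drop = FALSE]
    gP <- tcrossprod(gOh, cache$V[, cols, drop = FALSE])
    gV[, cols] <- crossprod(P, gOh)
    gL <- P * (gP - rowSums(gP * P))
    gQ[, cols] <- gL %*% cache$K[, cols, drop = FALSE] * cache$scale
    gK[, cols] <- crossprod(gL, cache$Q[, cols, drop = FALSE]) * cache$scale
    g_bias_e[, hd] <- gL[cache$eidx]
    gB_other <- sum(gL) - sum(gL[cache$eidx])
    g_noedge[hd] <- gB_other
  }
  gX <- gQ %*% t(p$Wq) + gK %*% t(p$Wk) + gV %*% t(p$Wv)
  list(grad = list(Wq = crossprod(X, gQ), Wk = crossprod(X, gK),
                   Wv = crossprod(X, gV), Wo = gWo,
                   W_bias = crossprod(edge_feat, g_bias_e),
                   no_edge_bias = g_noedge),
       gX = gX,
       g_edge = g_bias_e %*% t(p$W_bias))
}

# ---- transformer layer --------------------------------------------------

#' One model layer: biased self-attention plus task-routed MoE
#'
#' Multi-head self-attention over the nodes of one molecule with an
#' additive per-edge attention bias derived from the edge features
#' (non-adjacent pairs share a learned "no edge" bias), residual
#' connection and layer norm, then the dense task-routed
#' mixture-of-experts feed-forward with another residual + layer norm.
#'
#' @param X `n x h` node features.
#' @param edge_feat `e x h` edge features.
#' @param graph `molecular_graph`.
#' @param alpha expert gating weights for the current task.
#' @param layer layer parameters.
#' @param n_heads attention head count.
#' @return list with `out` and `cache`.
#' @export
transformer_layer <- function(X, edge_feat, graph, alpha, layer, n_heads) {
  at <- attention_fwd(X, edge_feat, graph, layer$attn, n_heads)
  l1 <- layernorm_fwd(X + at$out, layer$ln1)
  mo <- moe_forward(l1$out, alpha, layer$experts)
  l2 <- layernorm_fwd(l1$out + mo$out, layer$ln2)
  list(out = l2$out,
       cache = list(at = at, l1 = l1, mo = mo, l2 = l2, X = X))
}

transformer_layer_bwd <- function(cache, edge_feat, alpha, layer, n_heads,
                                  g_out) {
  b2 <- layernorm_bwd(cache$l2, layer$ln2, g_out)
  mb <- moe_backward(cache$mo, alpha, layer$experts, b2$gx)
  g_l1out <- b2$gx + mb$gX
  b1 <- layernorm_bwd(cache$l1, layer$ln1, g_l1out)
  ab <- attention_bwd(cache$at, cache$X, edge_feat, layer$attn, b1$gx)
  list(grad = list(attn = ab$grad, ln1 = b1$grad, experts = mb$experts,
                   ln2 = b2$grad),
       gX = b1$gx + ab$gX,
       g_edge = ab$g_edge,
       g_alpha = mb$g_alpha)
}

# Recompute edge descriptors + features for updated geometry.
encode_edges <- function(graph, enc) {
  tors <- torsion_angles(chirality_vectors(graph), graph)
  harm <- circular_harmonics(tors$psi, enc$Omega)
  if (!enc$use_torsion) harm[] <- 0
  radial <- radial_embedding(graph$lengths, enc$n_basis, enc$r_max)
  edge_raw <- cbind(harm, radial)
  list(edge_raw = edge_raw,
       edge = edge_raw %*% enc$W_edge + rep(enc$b_edge,
                                            each = nrow(edge_raw)),
       psi = tors$psi, valid = tors$valid)
}

# ---- forward ------------------------------------------------------------

#' Precompute the geometry-derived descriptors of a conformation
#'
#' Builds the graph and the raw (pre-affine) edge descriptors for the
#' input geometry. These depend only on the coordinates and the encoder
#' hyper-parameters, not on any trainable weight, so they can be computed
#' once per molecule and reused across every training step — pass the
#' result to [model_forward()] as `precomp`.
#'
#' @param conf a [conformation()].
#' @param config a [model_config()].
#' @return list with `graph`, `edge_raw`, `psi`, `valid`, `elem_idx`.
#' @export
featurize_conformation <- function(conf, config) {
  elem_idx <- match(conf$elements, config$supported_elements)
  if (anyNA(elem_idx))
    stop("unknown element(s) ",
         paste(unique(conf$elements[is.na(elem_idx)]), collapse = ", "),
         "; supported atomic numbers: ",
         paste(config$supported_elements, collapse = ", "))
  if (n_atoms(conf) == 1L)
    return(list(graph = NULL, edge_raw = NULL, psi = NULL, valid = NULL,
                elem_idx = elem_idx))
  graph <- build_graph(conf, config$cutoff, config$min_neighbors)
  tors <- torsion_angles(chirality_vectors(graph), graph)
  harm <- circular_harmonics(tors$psi, config$Omega)
  if (!config$use_torsion) harm[] <- 0
  radial <- radial_embedding(graph$lengths, config$n_basis, config$cutoff)
  list(graph = graph, edge_raw = cbind(harm, radial),
       psi = tors$psi, valid = tors$valid, elem_idx = elem_idx)
}

# Apply the trainable part of the encoder to precomputed descriptors.
se3_encode_from_raw <- function(precomp, enc) {
  edge <- precomp$edge_raw %*% enc$W_edge +
    rep(enc$b_edge, each = nrow(precomp$edge_raw))
  pooled <- rowsum(edge, precomp$graph$edges[, 1L], reorder = TRUE)
  node <- enc$element_embedding[precomp$elem_idx, , drop = FALSE]
  got <- as.integer(rownames(pooled))
  node[got, ] <- node[got, , drop = FALSE] + pooled
  list(node = node, edge = edge, edge_raw = precomp$edge_raw,
       psi = precomp$psi, valid = precomp$valid,
       elem_idx = precomp$elem_idx)
}

#' Full model forward pass
#'
#' Encodes a conformation, routes the task, runs `S` recycled blocks of
#' transformer layers (each optionally followed by a positional update
#' whose geometry is re-encoded), and applies the node-softmax attention
#' readout with a task-type-appropriate head. Graph-level outputs are
#' invariant under rigid motions of the input; with torsion features
#' enabled they are sensitive to reflection (mirror images can differ).
#'
#' @param model a `moltask_model`.
#' @param conf a [conformation()].
#' @param meta a [task_meta()].
#' @param keep_cache retain all intermediate caches (needed for
#'   backpropagation; increases memory).
#' @param precomp optional precomputed descriptors from
#'   [featurize_conformation()] for the same conformation and config.
#' @return list (`model_output`): `prediction` (probability for
#'   classification, z-scored scale for regression), `graph_embedding`,
#'   `node_attention`, `trajectory` (list of `S + 1` position matrices),
#'   `psi`, `alpha`, `t_emb`, and `cache` when requested.
#' @export
model_forward <- function(model, conf, meta, keep_cache = FALSE,
                          precomp = NULL) {
  cfg <- model$config
  pr <- model$params
  if (n_atoms(conf) < 1L) stop("empty molecule")
  enc <- encoder_view(cfg, pr$encoder)
  single <- n_atoms(conf) == 1L
  if (!single) {
    if (is.null(precomp)) precomp <- featurize_conformation(conf, cfg)
    graph0 <- precomp$graph
    enc_out <- se3_encode_from_raw(precomp, enc)
    X <- enc_out$node
  } else {
    graph0 <- NULL
    elem_idx <- match(conf$elements, enc$supported_elements)
    if (anyNA(elem_idx)) stop("unknown element ", conf$elements)
    enc_out <- list(elem_idx = elem_idx)
    X <- enc$element_embedding[elem_idx, , drop = FALSE]
  }
  te <- encode_task_meta(meta, pr$task_enc)
  rt <- route(te$t_emb, pr$router)
  alpha <- rt$alpha

  pos <- conf$positions
  trajectory <- list(pos)
  graph_cur <- graph0
  edge_feat <- if (!single) enc_out$edge
  edge_states <- if (!single) list(list(edge_raw = enc_out$edge_raw,
                                        edge = enc_out$edge))
  blocks_cache <- vector("list", cfg$n_recycles)
  for (s in seq_len(cfg$n_recycles)) {
    bi <- if (cfg$share_recycle_weights) 1L else s
    bp <- pr$blocks[[bi]]
    layer_caches <- vector("list", cfg$n_layers_per_block)
    for (l in seq_len(cfg$n_layers_per_block)) {
      if (single) {
        # attention over one node is the identity; layer reduces to
        # residual MoE + norms
        lp <- bp$layers[[l]]
        at_out <- X %*% lp$attn$Wv %*% lp$attn$Wo
        l1 <- layernorm_fwd(X + at_out, lp$ln1)
        mo <- moe_forward(l1$out, alpha, lp$experts)
        l2 <- layernorm_fwd(l1$out + mo$out, lp$ln2)
        layer_caches[[l]] <- list(single = TRUE, l1 = l1, mo = mo,
                                  l2 = l2, X = X)
        X <- l2$out
      } else {
        lo <- transformer_layer(X, edge_feat, graph_cur, alpha,
                                bp$layers[[l]], cfg$n_heads)
        layer_caches[[l]] <- lo$cache
        X <- lo$out
      }
    }
    pos_cache <- NULL
    if (cfg$position_update && !single) {
      pu <- positional_update_block(X, edge_feat, graph_cur, pos,
                                    bp$pos_head, eps = cfg$eps,
                                    block_index = s)
      pos <- pu$positions
      pos_cache <- pu
      graph_cur <- update_graph_geometry(graph_cur, pos)
      if (s < cfg$n_recycles) {
        es <- encode_edges(graph_cur, enc)
        edge_feat <- es$edge
        edge_states[[s + 1L]] <- es
      }
    } else if (!single && s < cfg$n_recycles) {
      edge_states[[s + 1L]] <- edge_states[[s]]
    }
    trajectory[[s + 1L]] <- pos
    blocks_cache[[s]] <- list(layers = layer_caches, pos = pos_cache,
                              graph = graph_cur, edge_state = s)
  }

  score_in <- cbind(X, matrix(te$t_emb, nrow(X), cfg$d_emb, byrow = TRUE))
  sc <- ffn_fwd(score_in, pr$readout$score)
  att <- softmax_vec(drop(sc$out))
  gemb <- drop(crossprod(X, att))
  if (meta$task_type == "regression") {
    raw <- sum(pr$readout$head_reg$W * gemb) + pr$readout$head_reg$b
    prediction <- raw
  } else {
    raw <- sum(pr$readout$head_cls$W * gemb) + pr$readout$head_cls$b
    prediction <- 1 / (1 + exp(-raw))
  }
  out <- list(prediction = prediction, raw = raw,
              graph_embedding = gemb, node_attention = att,
              trajectory = trajectory, alpha = alpha, t_emb = te$t_emb,
              psi = if (!single) enc_out$psi,
              task_type = meta$task_type)
  if (keep_cache)
    out$cache <- list(enc_out = enc_out, te = te, rt = rt,
                      graph0 = graph0, blocks = blocks_cache,
                      edge_states = edge_states, X_final = X,
                      score = sc, score_in = score_in, att = att,
                      single = single)
  structure(out, class = "model_output")
}

# ---- backward -----------------------------------------------------------

# Full reverse pass. g_raw: gradient wrt the pre-sigmoid / regression
# output scalar. g_pos_final: gradient wrt the final coordinates (from a
# geometry loss); because each block's update enters the final positions
# additively and geometry re-encoding is treated as constant, the same
# gradient reaches every block's reconstruction. g_m_blocks: optional list
# of per-block gradients wrt the predicted edge scalars.
model_backward <- function(model, fwd, meta, g_raw = 0,
                           g_pos_final = NULL, g_m_blocks = NULL) {
  cfg <- model$config
  pr <- model$params
  ca <- fwd$cache
  if (is.null(ca)) stop("forward pass was run without keep_cache = TRUE")
  grads <- tree_zeros_like(pr)
  h <- cfg$hidden_dim
  X <- ca$X_final
  n <- nrow(X)

  # readout
  head_name <- if (meta$task_type == "regression") "head_reg" else "head_cls"
  head <- pr$readout[[head_name]]
  gemb <- fwd$graph_embedding
  g_gemb <- g_raw * drop(head$W)
  grads$readout[[head_name]]$W <- matrix(g_raw * gemb, ncol = 1L)
  grads$readout[[head_name]]$b <- g_raw
  att <- ca$att
  gX <- att %o% g_gemb
  g_att <- drop(X %*% g_gemb)
  g_s <- att * (g_att - sum(g_att * att))
  sb <- ffn_bwd(ca$score, pr$readout$score, matrix(g_s, ncol = 1L))
  grads$readout$score <- sb$grad
  gX <- gX + sb$gx[, 1:h, drop = FALSE]
  g_t_emb <- colSums(sb$gx[, (h + 1L):(h + cfg$d_emb), drop = FALSE])

  g_alpha <- numeric(cfg$n_experts)
  g_edge_acc <- NULL  # per edge-state accumulated edge-feature gradients
  if (!ca$single)
    g_edge_acc <- lapply(ca$edge_states, function(es)
      matrix(0, nrow(es$edge_raw), h))

  for (s in rev(seq_len(cfg$n_recycles))) {
    bi <- if (cfg$share_recycle_weights) 1L else s
    bp <- pr$blocks[[bi]]
    bc <- ca$blocks[[s]]
    es_idx <- bc$edge_state
    # positional update head
    if (!is.null(bc$pos)) {
      g_m_extra <- if (!is.null(g_m_blocks)) g_m_blocks[[s]]
      if (!is.null(g_pos_final) || !is.null(g_m_extra)) {
        graph_in <- if (s == 1L) ca$graph0 else ca$blocks[[s - 1L]]$graph
        pb <- positional_update_backward(bc$pos, graph_in, bp$pos_head, h,
                                         g_positions = g_pos_final,
                                         g_m_extra = g_m_extra)
        grads$blocks[[bi]]$pos_head <-
          tree_map2(`+`, grads$blocks[[bi]]$pos_head, pb$grad)
        gX <- gX + pb$g_node
        g_edge_acc[[es_idx]] <- g_edge_acc[[es_idx]] + pb$g_edge
      }
    }
    # layers in reverse
    for (l in rev(seq_len(cfg$n_layers_per_block))) {
      lc <- bc$layers[[l]]
      lp <- bp$layers[[l]]
      if (ca$single) {
        b2 <- layernorm_bwd(lc$l2, lp$ln2, gX)
        mb <- moe_backward(lc$mo, fwd$alpha, lp$experts, b2$gx)
        g_alpha <- g_alpha + mb$g_alpha
        g_l1 <- b2$gx + mb$gX
        b1 <- layernorm_bwd(lc$l1, lp$ln1, g_l1)
        grads$blocks[[bi]]$layers[[l]]$ln2 <-
          tree_map2(`+`, grads$blocks[[bi]]$layers[[l]]$ln2, b2$grad)
        grads$blocks[[bi]]$layers[[l]]$ln1 <-
          tree_map2(`+`, grads$blocks[[bi]]$layers[[l]]$ln1, b1$grad)
        grads$blocks[[bi]]$layers[[l]]$experts <-
          tree_map2(`+`, grads$blocks[[bi]]$layers[[l]]$experts, mb$experts)
        # single-node attention path: out = X Wv Wo
        gAout <- b1$gx
        grads$blocks[[bi]]$layers[[l]]$attn$Wo <-
          grads$blocks[[bi]]$layers[[l]]$attn$Wo +
          crossprod(lc$X %*% lp$attn$Wv, gAout)
        grads$blocks[[bi]]$layers[[l]]$attn$Wv <-
          grads$blocks[[bi]]$layers[[l]]$attn$Wv +
          crossprod(lc$X, gAout %*% t(lp$attn$Wo))
        gX <- b1$gx + gAout %*% t(lp$attn$Wo) %*% t(lp$attn$Wv)
      } else {
        edge_feat <- ca$edge_states[[es_idx]]$edge
        lb <- transformer_layer_bwd(lc, edge_feat, fwd$alpha, lp,
                                    cfg$n_heads, gX)
        grads$blocks[[bi]]$layers[[l]] <-
          tree_map2(`+`, grads$blocks[[bi]]$layers[[l]], lb$grad)
        gX <- lb$gX
        g_edge_acc[[es_idx]] <- g_edge_acc[[es_idx]] + lb$g_edge
        g_alpha <- g_alpha + lb$g_alpha
      }
    }
  }

  # encoder: initial node/edge features plus re-encoded edge states
  if (!ca$single) {
    enc <- encoder_view(cfg, pr$encoder)
    eb <- se3_encode_backward(ca$enc_out, ca$graph0, enc,
                              gX, g_edge_acc[[1L]])
    grads$encoder$element_embedding <- eb$element_embedding
    grads$encoder$W_edge <- eb$W_edge
    grads$encoder$b_edge <- eb$b_edge
    if (length(g_edge_acc) > 1L) {
      for (k in 2L:length(g_edge_acc)) {
        ge <- g_edge_acc[[k]]
        if (any(ge != 0)) {
          grads$encoder$W_edge <- grads$encoder$W_edge +
            crossprod(ca$edge_states[[k]]$edge_raw, ge)
          grads$encoder$b_edge <- grads$encoder$b_edge + colSums(ge)
        }
      }
    }
  } else {
    acc <- rowsum(gX, ca$enc_out$elem_idx, reorder = TRUE)
    grads$encoder$element_embedding[as.integer(rownames(acc)), ] <- acc
  }

  # router and task encoder
  rb <- route_backward(ca$rt, fwd$t_emb, pr$router, g_alpha)
  grads$router <- rb$router
  g_t_emb <- g_t_emb + rb$g_t_emb
  grads$task_enc <- encode_task_meta_backward(ca$te, meta, pr$task_enc,
                                              g_t_emb)
  grads
}

# ---- checkpoints --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Stores weights, configuration and the initialization seed in a single
#' archive.
#'
#' @param model a `moltask_model`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               seed = model$seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = structure(x$config, class = "model_config"),
                 params = x$params, seed = x$seed),
            class = "moltask_model")
}
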