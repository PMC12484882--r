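# Task meta-information encoding, routing, and the task-routed
# mixture-of-experts layer.

#' Recognized task supergroups
#' @export
task_groups <- c("absorption", "distribution", "metabolism", "excretion",
                 "toxicity", "physicochemical", "other")

#' Task meta-information
#'
#' Describes one prediction task: an integer id, its supergroup, whether it
#' is classification or regression, and the label statistics the model
#' conditions on — the positive-class ratio `eta` for classification, or
#' the target mean/std for regression. Exactly one of the two statistic
#' sets must be given, matching the task type.
#'
#' @param task_id integer index (>= 1).
#' @param task_type `"classification"` or `"regression"`.
#' @param group one of [task_groups].
#' @param positive_ratio proportion of positive training labels, in (0, 1)
#'   (classification only; also used as the loss reweighting ratio).
#' @param target_mean,target_std training-label mean and standard deviation
#'   (regression only; `target_std > 0`).
#' @param name optional human-readable task name.
#' @return object of class `task_meta`.
#' @export
task_meta <- function(task_id, task_type, group = "other",
                      positive_ratio = NULL, target_mean = NULL,
                      target_std = NULL, name = NULL) {
  task_type <- match.arg(task_type, c("classification", "regression"))
  group <- match.arg(group, task_groups)
  task_id <- as.integer(task_id)
  if (is.na(task_id) || task_id < 1L) stop("task_id must be a positive integer")
  if (task_type == "classification") {
    if (is.null(positive_ratio) || !is.null(target_mean) ||
        !is.null(target_std))
      stop("classification tasks need positive_ratio and no mean/std")
    if (positive_ratio <= 0 || positive_ratio >= 1)
      stop("positive_ratio must lie in (0, 1)")
  } else {
    if (!is.null(positive_ratio) || is.null(target_mean) ||
        is.null(target_std))
      stop("regression tasks need target_mean and target_std and no ",
           "positive_ratio")
    if (target_std <= 0) stop("target_std must be positive")
  }
  structure(list(task_id = task_id, task_type = task_type, group = group,
                 positive_ratio = positive_ratio,
                 target_mean = target_mean, target_std = target_std,
                 name = name %||% paste0("task", task_id)),
            class = "task_meta")
}

#' Read / write task meta tables
#'
#' CSV schema: columns `task_id, name, type, group, positive_ratio, mean,
#' std` (absent statistics empty).
#'
#' @param path CSV file path.
#' @return `read_task_meta`: list of [task_meta()] objects.
#' @export
read_task_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(r) {
    cls <- identical(df$type[r], "classification")
    task_meta(df$task_id[r], df$type[r], df$group[r],
              positive_ratio = if (cls) df$positive_ratio[r],
              target_mean = if (!cls) df$mean[r],
              target_std = if (!cls) df$std[r],
              name = df$name[r])
  })
}

#' @rdname read_task_meta
#' @param metas list of [task_meta()] objects.
#' @export
write_task_meta <- function(metas, path) {
  df <- do.call(rbind, lapply(metas, function(m)
    data.frame(task_id = m$task_id, name = m$name, type = m$task_type,
               group = m$group,
               positive_ratio = m$positive_ratio %||% NA_real_,
               mean = m$target_mean %||% NA_real_,
               std = m$target_std %||% NA_real_)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Fixed numeric part of the meta encoding: [one-hot group || one-hot type
# || eta, mu, sigma] with absent statistics zero-filled. The learned id
# embedding is appended by encode_task_meta.
task_meta_raw <- function(meta) {
  g <- as.numeric(task_groups == meta$group)
  ty <- as.numeric(c("classification", "regression") == meta$task_type)
  stats_ <- c(meta$positive_ratio %||% 0,
              meta$target_mean %||% 0,
              meta$target_std %||% 0)
  c(g, ty, stats_)
}

#' Initialize the task meta-information encoder
#'
#' @param d_emb task-embedding dimension.
#' @param d_id width of the learned per-task id embedding.
#' @param max_tasks largest task_id supported.
#' @param d_hidden hidden width of the encoder MLP.
#' @param seed integer seed.
#' @return parameter list: `id_embedding` (`max_tasks x d_id`) and a
#'   two-layer `ffn`.
#' @export
init_task_encoder <- function(d_emb = 64L, d_id = 8L, max_tasks = 64L,
                              d_hidden = 64L, seed = 1L) {
  d_raw <- length(task_groups) + 2L + 3L
  with_seed(seed, list(
    id_embedding = matrix(stats::rnorm(max_tasks * d_id, sd = 0.5),
                          max_tasks, d_id),
    ffn = init_ffn(d_raw + d_id, d_hidden, d_emb)))
}

#' Encode task meta-information into a task embedding
#'
#' Concatenates the fixed numeric encoding (one-hot group, one-hot type,
#' statistics with absent fields zero-filled) with the learned id
#' embedding and passes it through a two-layer GeLU MLP. Deterministic
#' given fixed parameters.
#'
#' @param meta a [task_meta()].
#' @param enc parameters from [init_task_encoder()].
#' @return list with `t_emb` (numeric vector) and `cache`.
#' @export
encode_task_meta <- function(meta, enc) {
  stopifnot(inherits(meta, "task_meta"))
  if (meta$task_id > nrow(enc$id_embedding))
    stop("task_id ", meta$task_id, " exceeds encoder capacity ",
         nrow(enc$id_embedding))
  x <- matrix(c(task_meta_raw(meta), enc$id_embedding[meta$task_id, ]),
              nrow = 1L)
  ff <- ffn_fwd(x, enc$ffn)
  list(t_emb = drop(ff$out), cache = ff)
}

# Backward: gradient of loss wrt t_emb -> encoder parameter gradients.
encode_task_meta_backward <- function(enc_out, meta, enc, g_t_emb) {
  bw <- ffn_bwd(enc_out$cache, enc$ffn, matrix(g_t_emb, nrow = 1L))
  d_raw <- length(task_meta_raw(meta))
  g_id <- matrix(0, nrow(enc$id_embedding), ncol(enc$id_embedding))
  g_id[meta$task_id, ] <- bw$gx[1L, -seq_len(d_raw)]
  list(id_embedding = g_id, ffn = bw$grad)
}

#' Initialize the task router
#'
#' @param d_emb task-embedding dimension.
#' @param n_experts number of experts `N_M` (>= 1).
#' @param seed integer seed.
#' @export
init_router <- function(d_emb, n_experts, seed = 1L) {
  if (n_experts < 1L) stop("number of experts must be >= 1")
  with_seed(seed, init_linear(d_emb, n_experts))
}

#' Compute expert gating weights from a task embedding
#'
#' `alpha = softmax(router(t_emb))`: non-negative weights over the experts
#' summing to one.
#'
#' @param t_emb task embedding vector.
#' @param router parameters from [init_router()].
#' @return list with `alpha` (simplex vector) and `logits`.
#' @export
route <- function(t_emb, router) {
  logits <- drop(linear_fwd(matrix(t_emb, nrow = 1L), router))
  list(alpha = softmax_vec(logits), logits = logits)
}

# Backward: gradient wrt alpha -> router grads and gradient wrt t_emb.
route_backward <- function(route_out, t_emb, router, g_alpha) {
  a <- route_out$alpha
  g_logits <- a * (g_alpha - sum(g_alpha * a))
  bw <- linear_bwd(matrix(t_emb, nrow = 1L), router,
                   matrix(g_logits, nrow = 1L))
  list(router = list(W = bw$W, b = bw$b), g_t_emb = drop(bw$x))
}

#' Initialize the expert bank of a mixture-of-experts layer
#'
#' @param d width of node features (experts map `d -> d`).
#' @param n_experts number of experts.
#' @param d_hidden hidden width of each expert FFN.
#' @param seed integer seed.
#' @export
init_experts <- function(d, n_experts, d_hidden = 2L * d, seed = 1L) {
  with_seed(seed, lapply(seq_len(n_experts), function(i)
    init_ffn(d, d_hidden, d)))
}

#' Dense mixture-of-experts forward pass
#'
#' `Y = sum_i alpha_i * FFN_i(X)`: every expert sees every row and the
#' gating weights mix their outputs (no top-k sparsification). Applied
#' row-wise, so the layer is permutation-equivariant over nodes.
#'
#' @param X `n x d` feature matrix.
#' @param alpha gating weights (length = number of experts, simplex).
#' @param experts list from [init_experts()].
#' @return list with `out` and per-expert `caches`.
#' @export
moe_forward <- function(X, alpha, experts) {
  if (length(alpha) != length(experts))
    stop("gating weight length (", length(alpha),
         ") does not match expert count (", length(experts), ")")
  caches <- lapply(experts, function(p) ffn_fwd(X, p))
  out <- matrix(0, nrow(X), ncol(X))
  for (i in seq_along(experts)) out <- out + alpha[i] * caches[[i]]$out
  list(out = out, caches = caches)
}

# Backward: returns per-expert grads, gX, and g_alpha.
moe_backward <- function(moe_out, alpha, experts, gY) {
  gX <- 0
  grads <- vector("list", length(experts))
  g_alpha <- numeric(length(experts))
  for (i in seq_along(experts)) {
    g_alpha[i] <- sum(gY * moe_out$caches[[i]]$out)
    bw <- ffn_bwd(moe_out$caches[[i]], experts[[i]], alpha[i] * gY)
    grads[[i]] <- bw$grad
    gX <- gX + bw$gx
  }
  list(experts = grads, gX = gX, g_alpha = g_alpha)
}
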