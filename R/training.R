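# Desk-scale training loop: task-balanced sampling, analytic gradients,
# Adam updates and per-task metric logging.

#' Multi-task molecular dataset
#'
#' Bundles conformations with a hypergraph of partially annotated tasks:
#' each task labels a subset of the molecules (imperfect annotation is the
#' expected case).
#'
#' @param conformations named list of [conformation()] objects (names are
#'   molecule ids).
#' @param tasks list of [task_meta()] objects (may be empty for pure
#'   geometry training).
#' @param labels data frame with columns `mol_id`, `task_id`, `value`.
#' @return object of class `mol_dataset`.
#' @export
mol_dataset <- function(conformations, tasks = list(),
                        labels = data.frame(mol_id = character(),
                                            task_id = integer(),
                                            value = numeric())) {
  if (is.null(names(conformations)))
    names(conformations) <- vapply(conformations, `[[`, "", "mol_id")
  stopifnot(all(c("mol_id", "task_id", "value") %in% names(labels)))
  if (nrow(labels) && !all(labels$mol_id %in% names(conformations)))
    stop("labels reference unknown molecule ids")
  task_ids <- vapply(tasks, `[[`, 0L, "task_id")
  if (nrow(labels) && !all(labels$task_id %in% task_ids))
    stop("labels reference unknown task ids")
  structure(list(conformations = conformations, tasks = tasks,
                 labels = labels, task_ids = task_ids),
            class = "mol_dataset")
}

# Per-task membership (the hyperedges of the annotation hypergraph).
task_membership <- function(data) {
  lapply(data$task_ids, function(tid)
    data$labels$mol_id[data$labels$task_id == tid])
}

# Sampling probabilities over tasks following the balanced sizes.
task_sampling_probs <- function(sizes, theta) {
  adj <- balanced_batch_sizes(sizes, theta)
  adj / sum(adj)
}

rank_auc <- function(y, p) {
  # Wilcoxon form of the ROC AUC; used when pROC is unavailable.
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auc_metric <- function(y, p) {
  if (requireNamespace("pROC", quietly = TRUE)) {
    if (length(unique(y)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  } else rank_auc(y, p)
}

# Gradient of the weighted BCE wrt the pre-sigmoid logit.
cls_grad_raw <- function(y, p, t_plus) {
  -y / (2 * t_plus) * (1 - p) + (1 - y) / (2 * (1 - t_plus)) * p
}

# Loss + gradients for one molecule of one task (property + geometry).
mol_loss_grads <- function(model, conf, meta, value, gamma, lambda_geo,
                           supervise_blocks, precomp = NULL) {
  fwd <- model_forward(model, conf, meta, keep_cache = TRUE,
                       precomp = precomp)
  l_reg <- 0; l_cls <- 0; g_raw <- 0
  if (!is.null(value) && !is.na(value)) {
    if (meta$task_type == "regression") {
      y_norm <- zscore(value, meta$target_mean, meta$target_std)
      l_reg <- regression_loss(y_norm, fwd$prediction)
      g_raw <- sign(fwd$prediction - y_norm)
    } else {
      l_cls <- classification_loss(value, fwd$prediction,
                                   meta$positive_ratio)
      g_raw <- gamma * cls_grad_raw(value, fwd$prediction,
                                    meta$positive_ratio)
    }
  }
  l_geo <- 0; g_pos <- NULL; g_m_blocks <- NULL
  S <- model$config$n_recycles
  if (lambda_geo > 0 && model$config$position_update &&
      !is.null(conf$equilibrium_positions) && n_atoms(conf) > 1L) {
    P_S <- fwd$trajectory[[S + 1L]]
    P_star <- conf$equilibrium_positions
    l_geo <- forcefield_loss(P_S, fwd$trajectory[[S]], P_star)
    g_pos <- lambda_geo * sign(P_S - P_star) / length(P_S)
    if (supervise_blocks) {
      g_m_blocks <- vector("list", S)
      for (s in seq_len(S)) {
        graph_in <- if (s == 1L) fwd$cache$graph0 else
          fwd$cache$blocks[[s - 1L]]$graph
        u <- decompose_labels(P_star - fwd$trajectory[[s]], graph_in)
        m <- fwd$cache$blocks[[s]]$pos$m
        l_geo <- l_geo + lambda_geo * mean(abs(m - u)) / S
        g_m_blocks[[s]] <- lambda_geo * sign(m - u) / (length(m) * S)
      }
    }
  }
  grads <- model_backward(model, fwd, meta, g_raw = g_raw,
                          g_pos_final = g_pos, g_m_blocks = g_m_blocks)
  list(loss = total_loss(l_reg, l_cls, gamma) + lambda_geo * l_geo,
       l_reg = l_reg, l_cls = l_cls, l_geo = l_geo,
       prediction = fwd$prediction, grads = grads)
}

#' Train a model on a multi-task dataset
#'
#' Each optimizer step draws one task with probability proportional to its
#' balanced size, then a batch of its labeled molecules, and performs one
#' Adam update on the combined objective
#' `L_reg + gamma * L_cls + lambda_geo * L_geometry`. Geometry supervision
#' is active for molecules carrying an equilibrium geometry when the model
#' runs positional updates. Tasks without labeled molecules are skipped
#' with a warning. Fixed seeds make runs reproducible.
#'
#' @param model a `moltask_model`.
#' @param data a [mol_dataset()].
#' @param steps number of optimizer steps.
#' @param batch_size molecules per step.
#' @param lr Adam learning rate.
#' @param gamma classification loss weight.
#' @param theta task-balancing factor in `[0, 1]`.
#' @param lambda_geo geometry loss weight.
#' @param supervise_blocks also supervise intermediate blocks through the
#'   edge-level label decomposition (default: only the final state).
#' @param seed integer seed controlling sampling.
#' @param eval_every evaluate per-task metrics every this many steps
#'   (NULL: only at the end).
#' @param eval_max maximum molecules per task used in metric evaluation.
#' @param verbose print progress lines.
#' @return list with the trained `model`, a `log` data frame of per-step
#'   losses and a `metrics` data frame of per-task evaluations.
#' @export
train_model <- function(model, data, steps = 100L, batch_size = 16L,
                        lr = 1e-3, gamma = 1.0, theta = 0.5,
                        lambda_geo = 1.0, supervise_blocks = FALSE,
                        seed = 1L, eval_every = NULL, eval_max = 200L,
                        verbose = FALSE) {
  stopifnot(inherits(data, "mol_dataset"))
  members <- task_membership(data)
  has_labels <- lengths(members) > 0L
  for (k in which(!has_labels))
    warning("task ", data$task_ids[k], " has no labeled molecules; skipped")
  geometry_only <- !any(has_labels)
  if (!geometry_only) {
    tasks <- data$tasks[has_labels]
    members <- members[has_labels]
    probs <- task_sampling_probs(lengths(members), theta)
  }
  opt <- adam_init(model$params)
  log_rows <- vector("list", steps)
  feat_cache <- new.env(parent = emptyenv())
  get_precomp <- function(id) {
    pc <- feat_cache[[id]]
    if (is.null(pc)) {
      pc <- featurize_conformation(data$conformations[[id]], model$config)
      feat_cache[[id]] <- pc
    }
    pc
  }
  with_seed(derive_seed(seed, 17L), {
    for (st in seq_len(steps)) {
      if (geometry_only) {
        meta <- task_meta(1L, "regression", target_mean = 0, target_std = 1)
        ids <- sample(names(data$conformations),
                      min(batch_size, length(data$conformations)))
        vals <- rep(NA_real_, length(ids))
      } else {
        ti <- sample.int(length(tasks), 1L, prob = probs)
        meta <- tasks[[ti]]
        ids <- sample(members[[ti]], min(batch_size, length(members[[ti]])))
        vals <- data$labels$value[match(paste(ids, meta$task_id),
                                        paste(data$labels$mol_id,
                                              data$labels$task_id))]
      }
      acc <- NULL
      tot <- c(loss = 0, l_reg = 0, l_cls = 0, l_geo = 0)
      for (b in seq_along(ids)) {
        r <- mol_loss_grads(model, data$conformations[[ids[b]]], meta,
                            vals[b], gamma, lambda_geo, supervise_blocks,
                            precomp = get_precomp(ids[b]))
        acc <- if (is.null(acc)) r$grads else tree_map2(`+`, acc, r$grads)
        tot <- tot + c(r$loss, r$l_reg, r$l_cls, r$l_geo)
      }
      nb <- length(ids)
      acc <- tree_map(function(g) g / nb, acc)
      stp <- adam_step(model$params, acc, opt, lr = lr)
      model$params <- stp$params
      opt <- stp$state
      log_rows[[st]] <- data.frame(step = st,
                                   task_id = if (geometry_only) NA_integer_
                                             else meta$task_id,
                                   loss = tot[1L] / nb, l_reg = tot[2L] / nb,
                                   l_cls = tot[3L] / nb, l_geo = tot[4L] / nb)
      if (verbose && (st %% 10L == 0L || st == 1L))
        message(sprintf("step %d  loss %.4f", st, tot[1L] / nb))
    }
  })
  metrics <- if (!geometry_only)
    evaluate_tasks(model, data, eval_max = eval_max,
                   feat_cache = feat_cache) else NULL
  list(model = model, log = do.call(rbind, log_rows), metrics = metrics)
}

#' Per-task evaluation metrics
#'
#' Computes AUC + accuracy for classification tasks and MAE + R^2 (on the
#' original label scale) for regression tasks over the labeled molecules.
#'
#' @param model a `moltask_model`.
#' @param data a [mol_dataset()].
#' @param eval_max cap on molecules per task (for speed).
#' @param mol_ids optional subset of molecule ids to evaluate on.
#' @param feat_cache optional environment of precomputed descriptors
#'   keyed by molecule id (see [featurize_conformation()]).
#' @return data frame, one row per task.
#' @export
evaluate_tasks <- function(model, data, eval_max = Inf, mol_ids = NULL,
                           feat_cache = NULL) {
  rows <- lapply(seq_along(data$tasks), function(k) {
    meta <- data$tasks[[k]]
    lab <- data$labels[data$labels$task_id == meta$task_id, ]
    if (!is.null(mol_ids)) lab <- lab[lab$mol_id %in% mol_ids, ]
    if (nrow(lab) == 0L) return(NULL)
    if (nrow(lab) > eval_max) lab <- lab[seq_len(eval_max), ]
    preds <- vapply(lab$mol_id, function(id)
      model_forward(model, data$conformations[[id]], meta,
                    precomp = if (!is.null(feat_cache))
                      feat_cache[[id]])$prediction, 0)
    if (meta$task_type == "classification") {
      data.frame(task_id = meta$task_id, name = meta$name,
                 type = meta$task_type, n = nrow(lab),
                 auc = auc_metric(lab$value, preds),
                 accuracy = mean((preds > 0.5) == (lab$value == 1)),
                 mae = NA_real_, r2 = NA_real_)
    } else {
      yhat <- zscore_inverse(preds, meta$target_mean, meta$target_std)
      ss <- sum((lab$value - mean(lab$value))^2)
      data.frame(task_id = meta$task_id, name = meta$name,
                 type = meta$task_type, n = nrow(lab),
                 auc = NA_real_, accuracy = NA_real_,
                 mae = mean(abs(yhat - lab$value)),
                 r2 = if (ss > 0) 1 - sum((yhat - lab$value)^2) / ss
                      else NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Relax a conformation with a trained model
#'
#' Runs the forward pass and returns the coordinate trajectory
#' `P^0 ... P^S` together with per-step displacement norms.
#'
#' @param model a `moltask_model` with positional updates enabled.
#' @param conf a [conformation()].
#' @param meta optional [task_meta()] used for task conditioning; defaults
#'   to a neutral regression task.
#' @return list with `trajectory` (list of `S + 1` matrices) and
#'   `step_norms` (mean per-atom displacement of each step).
#' @export
relax_conformation <- function(model, conf, meta = NULL) {
  meta <- meta %||% task_meta(1L, "regression", target_mean = 0,
                              target_std = 1)
  fwd <- model_forward(model, conf, meta)
  traj <- fwd$trajectory
  norms <- vapply(seq_len(length(traj) - 1L), function(s)
    mean(row_norms(traj[[s + 1L]] - traj[[s]])), 0)
  list(trajectory = traj, step_norms = norms)
}
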