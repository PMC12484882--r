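test_that("model configuration is validated", {
  expect_error(model_config(n_recycles = 0L), "n_recycles")
  expect_error(model_config(hidden_dim = 15L, n_heads = 4L), "divisible")
  expect_error(model_config(n_experts = 0L), "n_experts")
})

test_that("trajectory length equals the recycle count plus one", {
  conf <- fixture_random_conf(6L, seed = 2)
  meta <- fixture_cls_meta()
  for (S in c(1L, 4L)) {
    model <- init_model(fixture_config(n_recycles = S), seed = 1L)
    fwd <- model_forward(model, conf, meta)
    expect_length(fwd$trajectory, S + 1L)
  }
})

test_that("node attention is a simplex; single atoms get weight one", {
  model <- init_model(fixture_config(), seed = 3L)
  conf <- fixture_random_conf(7L, seed = 5)
  fwd <- model_forward(model, conf, fixture_reg_meta())
  expect_true(all(fwd$node_attention >= 0))
  expect_lt(abs(sum(fwd$node_attention) - 1), 1e-6)
  single <- conformation(6L, matrix(0, 1, 3))
  fs <- model_forward(model, single, fixture_cls_meta())
  expect_equal(fs$node_attention, 1.0)
  expect_true(is.finite(fs$prediction))
})

test_that("graph-level outputs are invariant under node permutation", {
  conf <- fixture_random_conf(8L, seed = 7)
  model <- init_model(fixture_config(), seed = 2L)
  meta <- fixture_reg_meta()
  f1 <- model_forward(model, conf, meta)
  withr::with_seed(1, perm <- sample(8L))
  conf2 <- conformation(conf$elements[perm],
                        conf$positions[perm, ], mol_id = conf$mol_id)
  f2 <- model_forward(model, conf2, meta)
  expect_lt(max(abs(f1$graph_embedding - f2$graph_embedding)), 1e-9)
  expect_lt(max(abs(f1$node_attention[perm] - f2$node_attention)), 1e-9)
  expect_lt(abs(f1$prediction - f2$prediction), 1e-9)
})

test_that("predictions are invariant under rigid motions", {
  conf <- fixture_random_conf(9L, seed = 9)
  model <- init_model(fixture_config(), seed = 4L)
  for (meta in list(fixture_cls_meta(), fixture_reg_meta())) {
    base <- model_forward(model, conf, meta)$prediction
    withr::with_seed(42, {
      for (k in 1:20) {
        conf2 <- transform_conformation(conf, random_rotation(), rnorm(3, sd = 4))
        p <- model_forward(model, conf2, meta)$prediction
        expect_lt(abs(p - base) / max(abs(base), 1e-9), 1e-5)
      }
    })
  }
})

test_that("torsion ablation yields exact reflection invariance", {
  mol <- make_chiral_dataset(1, seed = 8)[[1]]
  conf <- mol$conformation
  mirror <- reflect_conformation(conf)
  meta <- fixture_cls_meta()
  off <- init_model(fixture_config(use_torsion = FALSE,
                                   position_update = FALSE), seed = 6L)
  p1 <- model_forward(off, conf, meta)
  p2 <- model_forward(off, mirror, meta)
  expect_lt(abs(p1$prediction - p2$prediction), 1e-9)
  expect_lt(max(abs(p1$graph_embedding - p2$graph_embedding)), 1e-9)
})

test_that("with torsion features enantiomer predictions usually differ", {
  mol <- make_chiral_dataset(1, seed = 9)[[1]]
  conf <- mol$conformation
  mirror <- reflect_conformation(conf)
  meta <- fixture_cls_meta()
  gaps <- vapply(1:25, function(s) {
    m <- init_model(fixture_config(position_update = FALSE), seed = s)
    abs(model_forward(m, conf, meta)$prediction -
          model_forward(m, mirror, meta)$prediction)
  }, 0)
  expect_gte(mean(gaps > 1e-12), 0.95)
})

test_that("separate recycle weights change the forward pass", {
  conf <- fixture_random_conf(6L, seed = 11)
  meta <- fixture_reg_meta()
  shared <- init_model(fixture_config(share_recycle_weights = TRUE),
                       seed = 5L)
  distinct <- init_model(fixture_config(share_recycle_weights = FALSE),
                         seed = 5L)
  expect_length(distinct$params$blocks, 2L)
  expect_length(shared$params$blocks, 1L)
  expect_true(is.finite(model_forward(distinct, conf, meta)$prediction))
})

test_that("checkpoints round-trip exactly", {
  model <- init_model(fixture_config(), seed = 10L)
  conf <- fixture_random_conf(6L, seed = 3)
  meta <- fixture_cls_meta()
  p1 <- model_forward(model, conf, meta)$prediction
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(model_forward(back, conf, meta)$prediction, p1)
})

test_that("analytic gradients match finite differences", {
  cfg <- fixture_config(position_update = FALSE)
  model <- init_model(cfg, seed = 7L)
  conf <- fixture_random_conf(6L, seed = 13)
  meta <- fixture_cls_meta()
  fwd <- model_forward(model, conf, meta, keep_cache = TRUE)
  g_raw <- moltask:::cls_grad_raw(1, fwd$prediction, meta$positive_ratio)
  grads <- moltask:::model_backward(model, fwd, meta, g_raw = g_raw)
  loss_of <- function(params) {
    m2 <- model; m2$params <- params
    classification_loss(1, model_forward(m2, conf, meta)$prediction,
                        meta$positive_ratio)
  }
  paths <- list(list("encoder", "W_edge"),
                list("encoder", "element_embedding"),
                list("router", "W"),
                list("task_enc", "ffn", "l1", "W"),
                list("blocks", 1L, "layers", 1L, "attn", "Wq"),
                list("blocks", 1L, "layers", 1L, "attn", "W_bias"),
                list("blocks", 1L, "layers", 1L, "attn", "no_edge_bias"),
                list("blocks", 1L, "layers", 1L, "experts", 2L, "l1", "W"),
                list("blocks", 1L, "layers", 1L, "ln1", "gamma"),
                list("readout", "score", "l1", "W"),
                list("readout", "head_cls", "W"))
  eps <- 1e-5
  withr::with_seed(3, {
    for (path in paths) {
      leaf <- model$params; gleaf <- grads
      for (k in path) { leaf <- leaf[[k]]; gleaf <- gleaf[[k]] }
      for (i in sample(length(leaf), min(2L, length(leaf)))) {
        shift <- function(delta) {
          setr <- function(node, d) {
            if (d > length(path)) { node[i] <- node[i] + delta; return(node) }
            node[[path[[d]]]] <- setr(node[[path[[d]]]], d + 1L)
            node
          }
          setr(model$params, 1L)
        }
        num <- (loss_of(shift(eps)) - loss_of(shift(-eps))) / (2 * eps)
        expect_lt(abs(gleaf[i] - num), 1e-6)
      }
    }
  })
})

test_that("geometry-loss gradients through the sphere fit are exact", {
  cfg <- fixture_config(n_layers_per_block = 0L, n_recycles = 1L)
  model <- init_model(cfg, seed = 8L)
  conf <- perturb_conformation(fixture_random_conf(6L, seed = 21), 0.25,
                               seed = 3L)
  meta <- fixture_reg_meta()
  fwd <- model_forward(model, conf, meta, keep_cache = TRUE)
  P_star <- conf$equilibrium_positions
  P_S <- fwd$trajectory[[2L]]
  g_pos <- sign(P_S - P_star) / length(P_S)
  grads <- moltask:::model_backward(model, fwd, meta, g_raw = 0,
                                    g_pos_final = g_pos)
  loss_of <- function(params) {
    m2 <- model; m2$params <- params
    f <- model_forward(m2, conf, meta)
    forcefield_loss(f$trajectory[[2L]], f$trajectory[[1L]], P_star)
  }
  leaf <- model$params$blocks[[1]]$pos_head$ffn$l1$W
  gleaf <- grads$blocks[[1]]$pos_head$ffn$l1$W
  eps <- 1e-6
  withr::with_seed(4, {
    for (i in sample(length(leaf), 4L)) {
      shift <- function(delta) {
        p <- model$params
        p$blocks[[1]]$pos_head$ffn$l1$W[i] <-
          p$blocks[[1]]$pos_head$ffn$l1$W[i] + delta
        p
      }
      num <- (loss_of(shift(eps)) - loss_of(shift(-eps))) / (2 * eps)
      expect_lt(abs(gleaf[i] - num), 1e-5)
    }
  })
})
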