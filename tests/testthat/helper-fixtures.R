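# Shared fixture builders; everything is generated in code.

# Methane-like tetrahedral conformation (5 atoms, non-planar).
fixture_tetrahedron <- function(scale = 1.1) {
  pos <- rbind(c(0, 0, 0),
               c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    scale / sqrt(3)
  pos[1, ] <- c(0, 0, 0)
  conformation(c(6L, 1L, 1L, 1L, 1L), pos, mol_id = "tetra")
}

# Random well-separated conformation.
fixture_random_conf <- function(n = 8L, seed = 1L, spread = 2.2) {
  withr::with_seed(seed, {
    repeat {
      pos <- matrix(stats::rnorm(n * 3, sd = spread), n, 3L)
      if (min(dist(pos)) > 0.9) break
    }
    conformation(sample(c(6L, 7L, 8L), n, replace = TRUE), pos,
                 mol_id = paste0("rand", seed))
  })
}

# Small model configuration used across model/training tests.
fixture_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_dim = 16L, n_heads = 4L, n_layers_per_block = 1L,
         n_recycles = 2L, n_experts = 3L, d_emb = 8L, Omega = 2L,
         n_basis = 8L, d_id = 4L, max_tasks = 8L),
    list(...))
  do.call(model_config, args)
}

fixture_cls_meta <- function(id = 1L, eta = 0.4)
  task_meta(id, "classification", group = "toxicity", positive_ratio = eta)

fixture_reg_meta <- function(id = 2L)
  task_meta(id, "regression", group = "physicochemical",
            target_mean = 1.5, target_std = 0.7)

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(max(abs(b)), 1e-12), tol)
}
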