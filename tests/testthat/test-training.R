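test_that("geometry loss reduces to mean absolute deviation from target", {
  withr::with_seed(2, {
    for (k in 1:20) {
      n <- sample(3:30, 1)
      P_S <- matrix(rnorm(3 * n), n, 3)
      P_star <- matrix(rnorm(3 * n), n, 3)
      ref1 <- matrix(rnorm(3 * n), n, 3)
      ref2 <- matrix(rnorm(3 * n), n, 3)
      l1 <- forcefield_loss(P_S, ref1, P_star)
      l2 <- forcefield_loss(P_S, ref2, P_star)
      expect_lt(abs(l1 - mean(abs(P_S - P_star))), 1e-12)
      expect_lt(abs(l1 - l2), 1e-12)  # reference state cancels
    }
  })
  expect_equal(forcefield_loss(diag(3), diag(3) * 2, diag(3)), 0)
  expect_error(forcefield_loss(diag(3), diag(3), matrix(0, 2, 3)), "shape")
})

test_that("z-scoring round-trips and standardizes a batch", {
  expect_equal(zscore(3.7, 0, 1), 3.7)
  y <- rnorm(50, 4, 2)
  expect_lt(max(abs(zscore_inverse(zscore(y, 4, 2), 4, 2) - y)), 1e-12)
  z <- zscore(y, mean(y), sd(y))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(zscore(1, 0, 0), "positive")
})

test_that("regression loss is the batch MAE", {
  y <- rnorm(20); p <- y
  expect_equal(regression_loss(y, p), 0)
  expect_equal(regression_loss(y, y + 0.3), 0.3)
  q <- rnorm(20)
  expect_equal(regression_loss(y, q), mean(abs(y - q)))
})

test_that("weighted BCE reduces to standard BCE at balanced ratio", {
  withr::with_seed(5, {
    y <- rbinom(40, 1, 0.5)
    p <- runif(40, 0.01, 0.99)
  })
  standard <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_lt(abs(classification_loss(y, p, 0.5) - standard), 1e-12)
  expect_lt(classification_loss(1, 1 - 1e-9, 0.3), 1e-5)
  expect_error(classification_loss(1, 0.5, 0), "\\(0, 1\\)")
  # class weight masses balance in expectation under the training ratio
  t_plus <- 0.2
  y_big <- rbinom(20000, 1, t_plus)
  w <- ifelse(y_big == 1, 1 / (2 * t_plus), 0)
  w0 <- ifelse(y_big == 0, 1 / (2 * (1 - t_plus)), 0)
  expect_lt(abs(mean(w) - 0.5), 0.03)
  expect_lt(abs(mean(w0) - 0.5), 0.03)
})

test_that("total loss combines terms linearly in gamma", {
  expect_equal(total_loss(1.2, 3.4, 0), 1.2)
  expect_equal(total_loss(1, 1, 1), 2)
  g <- runif(5)
  d <- (total_loss(0.5, 2, g + 0.1) - total_loss(0.5, 2, g)) / 0.1
  expect_lt(max(abs(d - 2)), 1e-9)
  expect_error(total_loss(1, 1, -0.1), ">= 0")
})

test_that("balanced batch sizes interpolate and conserve the total", {
  sizes <- c(1000, 50, 10, 400)
  expect_equal(balanced_batch_sizes(sizes, 0), sizes)
  expect_equal(balanced_batch_sizes(sizes, 1), rep(mean(sizes), 4))
  for (theta in seq(0, 1, by = 0.1))
    expect_lt(abs(sum(balanced_batch_sizes(sizes, theta)) - sum(sizes)),
              1e-9)
  expect_error(balanced_batch_sizes(sizes, 1.5), "\\[0, 1\\]")
})

test_that("task sampling frequencies follow the balanced sizes", {
  sizes <- c(800, 100, 300)
  theta <- 0.5
  probs <- moltask:::task_sampling_probs(sizes, theta)
  withr::with_seed(11, {
    draws <- sample.int(3L, 10000L, replace = TRUE, prob = probs)
  })
  emp <- tabulate(draws, 3L) / 10000
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(emp - probs) <= 3 * se))
})

test_that("training reduces the loss and is reproducible", {
  suite <- make_multitask_suite(30, n_tasks = 2L, coverage = 0.8, seed = 3L)
  cfg <- fixture_config(n_layers_per_block = 0L, n_recycles = 1L,
                        position_update = FALSE)
  model <- init_model(cfg, seed = 1L)
  res1 <- train_model(model, suite$data, steps = 50L, batch_size = 8L,
                      lr = 3e-3, lambda_geo = 0, seed = 5L)
  first <- mean(head(res1$log$loss, 5))
  last <- mean(tail(res1$log$loss, 5))
  expect_lt(last, first)
  res2 <- train_model(model, suite$data, steps = 50L, batch_size = 8L,
                      lr = 3e-3, lambda_geo = 0, seed = 5L)
  expect_identical(res1$log$loss, res2$log$loss)
  expect_identical(res1$model$params, res2$model$params)
  # zero learning rate leaves every weight untouched
  res0 <- train_model(model, suite$data, steps = 3L, batch_size = 4L,
                      lr = 0, lambda_geo = 0, seed = 5L)
  expect_identical(res0$model$params, model$params)
})

test_that("tasks without labels are skipped with a warning", {
  suite <- make_multitask_suite(12, n_tasks = 2L, coverage = 0.5, seed = 4L)
  data <- suite$data
  data$tasks <- c(data$tasks, list(task_meta(3L, "regression",
                                             target_mean = 0,
                                             target_std = 1)))
  data$task_ids <- c(data$task_ids, 3L)
  model <- init_model(fixture_config(n_layers_per_block = 0L,
                                     position_update = FALSE), seed = 2L)
  expect_warning(train_model(model, data, steps = 2L, batch_size = 4L,
                             lambda_geo = 0, seed = 1L),
                 "no labeled molecules")
})

test_that("evaluation reports task-appropriate metrics", {
  suite <- make_multitask_suite(24, n_tasks = 2L, coverage = 1, seed = 6L)
  model <- init_model(fixture_config(n_layers_per_block = 0L,
                                     position_update = FALSE), seed = 3L)
  met <- evaluate_tasks(model, suite$data)
  expect_equal(nrow(met), 2L)
  reg <- met[met$type == "regression", ]
  cls <- met[met$type == "classification", ]
  expect_true(is.finite(reg$mae))
  expect_true(is.finite(cls$auc))
  expect_true(is.na(reg$auc))
})

test_that("relaxation returns the full trajectory with step norms", {
  model <- init_model(fixture_config(n_layers_per_block = 0L,
                                     n_recycles = 3L), seed = 4L)
  conf <- perturb_conformation(fixture_random_conf(7L, seed = 2), 0.3,
                               seed = 9L)
  r <- relax_conformation(model, conf)
  expect_length(r$trajectory, 4L)
  expect_length(r$step_norms, 3L)
  expect_true(all(is.finite(r$step_norms)))
})
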