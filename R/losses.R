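# Loss functions and the task-balancing batch-size rule.

#' Geometry (force-field surrogate) loss
#'
#' Mean absolute deviation of the final coordinate update from the update
#' that would have reached the equilibrium geometry:
#' `mean | (P_S - P_Sm1) - (P_star - P_Sm1) |`. The reference state
#' cancels algebraically, so the value equals `mean |P_S - P_star|` for
#' any `P_Sm1`; the explicit form documents that only the last update is
#' supervised.
#'
#' @param P_S final predicted coordinates (`n x 3`).
#' @param P_Sm1 penultimate coordinates (`n x 3`).
#' @param P_star equilibrium coordinates (`n x 3`).
#' @return non-negative scalar.
#' @export
forcefield_loss <- function(P_S, P_Sm1, P_star) {
  if (!identical(dim(P_S), dim(P_Sm1)) || !identical(dim(P_S), dim(P_star)))
    stop("coordinate matrices must share the same shape")
  mean(abs((P_S - P_Sm1) - (P_star - P_Sm1)))
}

#' Z-score normalization of regression targets
#'
#' @param y targets.
#' @param mu_reg,sigma_reg training-set mean and standard deviation
#'   (`sigma_reg > 0`).
#' @return normalized targets (or, for the inverse, original-scale values).
#' @export
zscore <- function(y, mu_reg, sigma_reg) {
  if (sigma_reg <= 0) stop("sigma_reg must be positive")
  (y - mu_reg) / sigma_reg
}

#' @rdname zscore
#' @param y_norm z-scored values.
#' @export
zscore_inverse <- function(y_norm, mu_reg, sigma_reg) {
  if (sigma_reg <= 0) stop("sigma_reg must be positive")
  y_norm * sigma_reg + mu_reg
}

#' Regression loss: mean absolute error on the z-scored scale
#'
#' @param y_norm z-scored targets.
#' @param p predictions on the same scale.
#' @export
regression_loss <- function(y_norm, p) mean(abs(y_norm - p))

#' Imbalance-weighted binary cross-entropy
#'
#' Binary cross-entropy with the positive class weighted by `1 / (2 t_+)`
#' and the negative class by `1 / (2 (1 - t_+))`, where `t_+` is the
#' positive-label ratio of the training set. At `t_+ = 0.5` this is the
#' standard BCE; in general the expected weight mass of each class under
#' the training distribution is 1/2. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param y 0/1 labels.
#' @param p predicted positive-class probabilities.
#' @param t_plus positive-label ratio, in (0, 1).
#' @return batch-mean loss.
#' @export
classification_loss <- function(y, p, t_plus) {
  if (t_plus <= 0 || t_plus >= 1) stop("t_plus must lie in (0, 1)")
  p <- clamp(p, 1e-7, 1 - 1e-7)
  mean(-(y / (2 * t_plus) * log(p) +
           (1 - y) / (2 * (1 - t_plus)) * log(1 - p)))
}

#' Combined multi-task loss
#'
#' `l_reg + gamma * l_cls`. The geometry loss enters the training
#' objective as a separate term with its own coefficient `lambda_geo`.
#'
#' @param l_reg,l_cls component losses.
#' @param gamma weight of the classification term (>= 0).
#' @export
total_loss <- function(l_reg, l_cls, gamma = 1.0) {
  if (any(gamma < 0)) stop("gamma must be >= 0")
  l_reg + gamma * l_cls
}

#' Task-balanced batch sizes
#'
#' Interpolates each task's dataset size towards the mean:
#' `S~_i = (1 - theta) * S_i + theta * mean(S)`. The total
#' `sum(S~) == sum(S)` for every `theta`, so balancing redistributes
#' rather than inflates sampling effort.
#'
#' @param sizes per-task dataset sizes.
#' @param theta balancing factor in `[0, 1]`; 0 keeps the raw sizes, 1
#'   makes all tasks equal.
#' @return adjusted sizes.
#' @export
balanced_batch_sizes <- function(sizes, theta) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  (1 - theta) * sizes + theta * mean(sizes)
}
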