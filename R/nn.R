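# Minimal dense neural-network primitives with analytic gradients.
# Everything operates on plain matrices; parameters live in nested lists
# and gradients mirror the parameter structure exactly.

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Xavier-style initialization for a dense layer.
init_linear <- function(d_in, d_out, sd = NULL) {
  sd <- sd %||% (1 / sqrt(d_in))
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

linear_fwd <- function(x, p) x %*% p$W + rep(p$b, each = nrow(x))

# Backward of y = x W + b: returns grads for W, b and x.
linear_bwd <- function(x, p, gy) {
  list(W = crossprod(x, gy), b = colSums(gy), x = gy %*% t(p$W))
}

# Two-layer feed-forward block with GeLU, the expert/head building block.
init_ffn <- function(d_in, d_hidden, d_out) {
  list(l1 = init_linear(d_in, d_hidden), l2 = init_linear(d_hidden, d_out))
}

ffn_fwd <- function(x, p) {
  h <- linear_fwd(x, p$l1)
  a <- gelu(h)
  list(out = linear_fwd(a, p$l2), h = h, a = a, x = x)
}

ffn_bwd <- function(cache, p, gy) {
  g2 <- linear_bwd(cache$a, p$l2, gy)
  gh <- g2$x * gelu_grad(cache$h)
  g1 <- linear_bwd(cache$x, p$l1, gh)
  list(grad = list(l1 = list(W = g1$W, b = g1$b),
                   l2 = list(W = g2$W, b = g2$b)),
       gx = g1$x)
}

# Row-wise layer normalization.
init_layernorm <- function(d) list(gamma = rep(1, d), beta = numeric(d))

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = xhat * rep(p$gamma, each = nrow(x)) +
         rep(p$beta, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(cache, p, gy) {
  d <- ncol(cache$xhat)
  gxhat <- gy * rep(p$gamma, each = nrow(gy))
  gx <- (gxhat - rowMeans(gxhat) -
           cache$xhat * rowMeans(gxhat * cache$xhat)) * cache$inv
  list(grad = list(gamma = colSums(gy * cache$xhat), beta = colSums(gy)),
       gx = gx)
}

# ---- parameter-tree utilities -------------------------------------------

# Apply f elementwise to every numeric leaf of a nested parameter list.
tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, tree_map, f = f))
  if (is.numeric(tree)) f(tree) else tree
}

# Combine two parameter trees leaf-by-leaf with f (shapes must match).
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    return(out)
  }
  if (is.numeric(a)) f(a, b) else a
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# Sum of squares over all leaves (for gradient-norm logging/clipping).
tree_sumsq <- function(tree) {
  if (is.list(tree)) return(sum(vapply(tree, tree_sumsq, 0)))
  if (is.numeric(tree)) sum(tree^2) else 0
}

# ---- Adam optimizer over parameter trees --------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
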