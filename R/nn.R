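# Small neural-network utilities on top of the autodiff tape: 3-layer
# perceptrons with ELU hidden activations, parameter containers as nested
# named lists of plain arrays, and an Adam optimizer.

nn_glorot <- function(fi, fo) {
  matrix(stats::runif(fi * fo, -1, 1) * sqrt(6 / (fi + fo)), fi, fo)
}

# dims: c(n_in, hidden..., n_out); returns list of layers $W, $b
nn_init_mlp <- function(dims) {
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(W = nn_glorot(dims[l], dims[l + 1L]),
                        b = numeric(dims[l + 1L]))
  }
  layers
}

# Forward an MLP whose parameters have been converted to tape leaves.
# Hidden layers use ELU; the last layer is linear.
nn_mlp <- function(tape, layers, x) {
  nl <- length(layers)
  h <- x
  for (l in seq_len(nl)) {
    h <- ad_linear(tape, h, layers[[l]]$W, layers[[l]]$b)
    if (l < nl) h <- ad_elu(tape, h)
  }
  h
}

# Recursively convert a nested parameter list into tape leaves (same shape).
ad_leaves <- function(tape, params) {
  if (is.list(params)) {
    lapply(params, function(p) ad_leaves(tape, p))
  } else {
    ad_leaf(tape, params)
  }
}

# Read gradients for a nested leaf structure out of an ad_backward() result.
# Missing gradients (parameter unused in this forward pass) become zeros.
ad_read_grads <- function(grads, leaves) {
  if (is_node(leaves)) {
    g <- grads[[leaves$i]]
    if (is.null(g)) array(0, dim_of(leaves$v)) else g
  } else {
    lapply(leaves, function(l) ad_read_grads(grads, l))
  }
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

param_zero_like <- function(p) {
  if (is.list(p)) lapply(p, param_zero_like) else p * 0
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- param_map2(f, a[[k]], b[[k]])
    out
  } else {
    f(a, b)
  }
}

param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE) else as.numeric(p)
}

param_global_norm <- function(g) sqrt(sum(param_flatten(g)^2))

adam_init <- function(params) {
  list(t = 0L, m = param_zero_like(params), v = param_zero_like(params))
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip = NULL) {
  if (!is.null(clip)) {
    gn <- param_global_norm(grads)
    if (is.finite(gn) && gn > clip) {
      sc <- clip / gn
      grads <- param_map2(function(g, .) g * sc, grads, grads)
    }
  }
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- param_map2(function(m, .) m / bc1, state$m, state$m)
  vh <- param_map2(function(v, .) v / bc2, state$v, state$v)
  upd <- param_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
  params <- param_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
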