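# Geometric transformer contracts: invariant edge features, SE(3)
# equivariance of updates, sink behaviour, pooling, and locality.

rand_states <- function(n, S) {
  list(q = matrix(rnorm(n * S), n, S),
       p = array(rnorm(n * 3 * S), c(n, 3, S)))
}

rotate_states <- function(states, R) {
  p <- states$p
  for (s in seq_len(dim(p)[3])) p[, , s] <- p[, , s] %*% t(R)
  list(q = states$q, p = p)
}

test_that("edge features depend only on scalars and distance when p is zero", {
  set.seed(1)
  coords <- matrix(runif(30, 0, 10), 10, 3)
  lp <- interformer:::init_layer_params(4L, 2L, 2L)
  st <- list(q = matrix(rnorm(40), 10, 4), p = array(0, c(10, 3, 4)))
  g <- build_knn_graph(coords, 3L)
  e1 <- encode_interactions(st, g, lp)
  # rotating coordinates preserves q and d, so features must be identical
  R <- random_rotation()
  g2 <- build_knn_graph(coords %*% t(R), 3L)
  e2 <- encode_interactions(st, g2, lp)
  expect_lt(max(abs(e1 - e2)), 1e-10)
})

test_that("edge features are invariant under global rotation of coords and p", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    coords <- matrix(runif(n * 3, 0, 15), n, 3)
    st <- rand_states(n, 6L)
    lp <- interformer:::init_layer_params(6L, 2L, 2L)
    g <- build_knn_graph(coords, 4L)
    R <- random_rotation()
    g2 <- build_knn_graph(coords %*% t(R), 4L)
    e1 <- encode_interactions(st, g, lp)
    e2 <- encode_interactions(rotate_states(st, R), g2, lp)
    expect_lt(max(abs(e1 - e2)) / max(1, max(abs(e1))), 1e-8)
  }
})

test_that("transformer update is rotation-equivariant and translation-invariant", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    S <- 5L
    coords <- matrix(runif(n * 3, 0, 20), n, 3)
    st <- rand_states(n, S)
    lp <- interformer:::init_layer_params(S, 2L, 2L)
    g <- build_knn_graph(coords, 5L)
    out1 <- transformer_update(st, g, lp, n_key = 2L, n_head = 2L)
    R <- random_rotation()
    tvec <- runif(3, -50, 50)
    g2 <- build_knn_graph(sweep(coords %*% t(R), 2, tvec, "+"), 5L)
    out2 <- transformer_update(rotate_states(st, R), g2, lp,
                               n_key = 2L, n_head = 2L)
    expect_lt(max(abs(out1$q - out2$q)) / max(1, max(abs(out1$q))), 1e-8)
    p1rot <- rotate_states(out1, R)$p
    expect_lt(max(abs(p1rot - out2$p)) / max(1, max(abs(out1$p))), 1e-8)
  }
})

test_that("zero value and gate networks give a pure residual update", {
  set.seed(4)
  n <- 12; S <- 4L
  coords <- matrix(runif(n * 3, 0, 10), n, 3)
  st <- rand_states(n, S)
  lp <- interformer:::init_layer_params(S, 2L, 2L)
  for (l in 1:3) {
    lp$value$net[[l]]$W[] <- 0; lp$value$net[[l]]$b[] <- 0
    lp$vgate[[l]]$W[] <- 0; lp$vgate[[l]]$b[] <- 0
  }
  lp$value$comb$W[] <- 0; lp$value$comb$b[] <- 0
  g <- build_knn_graph(coords, 4L)
  out <- transformer_update(st, g, lp, n_key = 2L, n_head = 2L)
  expect_equal(out$q, st$q, tolerance = 1e-12)
  expect_equal(out$p, st$p, tolerance = 1e-12)
})

test_that("attention weights sum to one over each atom's slots", {
  set.seed(5)
  n <- 9; S <- 4L
  coords <- matrix(runif(n * 3, 0, 8), n, 3)
  st <- rand_states(n, S)
  lp <- interformer:::init_layer_params(S, 3L, 2L)
  g <- build_knn_graph(coords, 5L)
  out <- transformer_update(st, g, lp, n_key = 3L, n_head = 2L)
  sums <- rowsum(out$attn, rep(seq_len(n), each = 5L))
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("sink slots count padding and a lone atom updates from itself only", {
  coords <- matrix(runif(9, 0, 5), 3, 3)
  g <- build_knn_graph(coords, 8L)
  expect_equal(sum(g$sink_mask[1, ]), 6L)  # 2 real neighbours, 6 sinks
  g1 <- build_knn_graph(matrix(c(1, 2, 3), 1, 3), 8L)
  expect_true(all(g1$sink_mask))
  set.seed(6)
  S <- 4L
  lp <- interformer:::init_layer_params(S, 2L, 2L)
  st1 <- rand_states(1, S)
  out <- transformer_update(st1, g1, lp, n_key = 2L, n_head = 2L)
  # same q, different (irrelevant) coordinates: identical update
  g1b <- build_knn_graph(matrix(c(-9, 4, 70), 1, 3), 8L)
  out2 <- transformer_update(st1, g1b, lp, n_key = 2L, n_head = 2L)
  expect_equal(out$q, out2$q, tolerance = 1e-12)
})

test_that("pad_with_sink zeroes exactly the padding rows", {
  coords <- matrix(runif(9, 0, 5), 3, 3)
  g <- build_knn_graph(coords, 4L)
  edges <- matrix(1, 12, 5)
  padded <- pad_with_sink(edges, g)
  mask <- as.vector(t(g$sink_mask))
  expect_true(all(padded[mask, ] == 0))
  expect_true(all(padded[!mask, ] == 1))
})

test_that("residue pooling: singleton residue, order invariance, equivariance", {
  set.seed(7)
  S <- 4L
  pp <- interformer:::init_pool_params(S, 2L)
  # singleton residue: softmax over one atom is 1, result is the projection
  st1 <- rand_states(1, S)
  out1 <- residue_pool(st1, 1L, pp, n_head = 2L)
  manual_q <- cbind(st1$q, st1$q) %*% pp$comb_q$W + rep(pp$comb_q$b, each = 1)
  expect_equal(out1$q, manual_q, tolerance = 1e-12)

  n <- 10
  st <- rand_states(n, S)
  map <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 3L)
  out <- residue_pool(st, map, pp, n_head = 2L)
  # permute atoms within residues: pooled outputs unchanged
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 10L, 6L, 9L, 7L)
  stp <- list(q = st$q[perm, ], p = st$p[perm, , , drop = FALSE])
  outp <- residue_pool(stp, map[perm], pp, n_head = 2L)
  expect_equal(out$q, outp$q, tolerance = 1e-10)
  expect_equal(out$p, outp$p, tolerance = 1e-10)
  # rotation: pooled q invariant, pooled p rotates
  R <- random_rotation()
  outr <- residue_pool(rotate_states(st, R), map, pp, n_head = 2L)
  expect_lt(max(abs(out$q - outr$q)), 1e-10)
  expect_lt(max(abs(rotate_states(out, R)$p - outr$p)), 1e-10)
})

test_that("collapse head outputs lie strictly in (0,1) and zero states give a constant row", {
  set.seed(8)
  hp <- interformer:::init_head_params(4L, 3L)
  rs <- rand_states(6, 4L)
  conf <- collapse_and_predict(rs, hp)
  expect_true(all(conf > 0 & conf < 1))
  z <- list(q = matrix(0, 4, 4), p = array(0, c(4, 3, 4)))
  confz <- collapse_and_predict(z, hp)
  expect_equal(confz, matrix(confz[1, ], 4, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("atoms beyond the receptive field cannot change a residue's output", {
  set.seed(9)
  # two clusters 1000 Angstrom apart; shallow config so hops cannot bridge
  cfg <- small_model_config()
  near <- random_two_chain(n_res = 6, spread = 10)
  far1 <- make_structure(list(list(
    name = "GLY", chain_tag = "Z:1",
    atoms = matrix(c(1000, 0, 0, 1001, 0, 0, 1000, 1, 0), 3, 3, byrow = TRUE))))
  far2 <- make_structure(list(list(
    name = "GLY", chain_tag = "Z:1",
    atoms = matrix(c(1003, 5, 7, 1004, 5, 7, 1003, 6, 7), 3, 3, byrow = TRUE))))
  joint <- function(far) {
    fa <- far$atoms; fa$res_idx <- fa$res_idx + n_residues(near)
    atomic_structure(rbind(near$atoms, fa), rbind(near$residues, far$residues))
  }
  params <- build_model(cfg, seed = 2)
  p1 <- predict(params, joint(far1))
  p2 <- predict(params, joint(far2))
  near_rows <- p1$chain_tag %in% c("A:1", "B:1")
  expect_equal(p1$protein[near_rows], p2$protein[near_rows], tolerance = 1e-12)
})
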