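# The geometric transformer block: invariant edge encoding, equivariant
# multi-head attention over k-nearest-neighbour edges, sink padding, and
# attention-based residue pooling.
#
# Every atom carries a scalar state q (rotation-invariant, S channels) and a
# vector state p (3 x S, rotating with the structure).  Edge features are
# built exclusively from invariants -- q_i, q_j, d_ij, and the contractions
# <p_i, r_ij>, <p_j, r_ij>, <p_i, p_j>, ||p_j|| -- so attention weights and
# gates are invariant, and the vector update
#   p_i <- p_i + sum_h sum_j a_ij^h (g_ij^h (x) r_ij + h_ij^h (.) p_j)
# transforms exactly as a vector under rotation.  Non-existent neighbour
# slots are sink edges: zero neighbour state and zero geometry, competing in
# the softmax like ordinary keys.
#
# Internally vector states live in a combined N x 3S matrix (axis-major
# blocks) so the fused tape operations in autodiff.R keep the graph small;
# the public module surface uses N x 3 x S arrays.

# ---- parameter initialisation ------------------------------------------

# One transformer block: 5 networks of 3 layers (edge encoder, query, key,
# value + scalar combiner, vector gates).
init_layer_params <- function(S, n_key, n_head) {
  F0 <- 6L * S + 2L
  list(
    edge = nn_init_mlp(c(F0, S, S, S)),
    query = nn_init_mlp(c(S, S, S, n_head * n_key)),
    key = nn_init_mlp(c(S, S, S, n_head * n_key)),
    value = list(net = nn_init_mlp(c(S, S, S, n_head * S)),
                 comb = list(W = nn_glorot(n_head * S, S), b = numeric(S))),
    vgate = nn_init_mlp(c(S, S, S, 2L * n_head * S))
  )
}

init_pool_params <- function(S, n_head) {
  list(attn = nn_init_mlp(c(S, S, S, n_head)),
       comb_q = list(W = nn_glorot(n_head * S, S), b = numeric(S)),
       comb_p = list(W = nn_glorot(n_head * S, S)))
}

init_head_params <- function(S, n_channels) {
  nn_init_mlp(c(2L * S, S, S, n_channels))
}

# ---- flattened edge view of a neighbour graph --------------------------

# Edges are ordered atom-major, slot-minor: e = (i - 1) * nn + slot.
flatten_graph <- function(graph) {
  n <- nrow(graph$idx)
  nn <- graph$nn
  list(
    i = rep(seq_len(n), each = nn),
    j = as.vector(t(graph$idx)),
    d = as.vector(t(graph$dist)),
    rx = as.vector(t(graph$rhat_x)),
    ry = as.vector(t(graph$rhat_y)),
    rz = as.vector(t(graph$rhat_z)),
    mask = as.numeric(!as.vector(t(graph$sink_mask))),
    n = n, nn = nn
  )
}

head_cols <- function(h, w) ((h - 1L) * w + 1L):(h * w)

head_sum_matrix <- function(n_head, w) {
  m <- matrix(0, n_head * w, n_head)
  for (h in seq_len(n_head)) m[head_cols(h, w), h] <- 1
  m
}

# ---- tape-level forward pieces -----------------------------------------

# states: list(q = node/matrix N x S, P = node/matrix N x 3S combined)
tf_encode <- function(tp, states, fg, lp) {
  S <- ncol(nval(states$q))
  mask <- fg$mask
  qi <- ad_gather(tp, states$q, fg$i)
  qj <- ad_rowscale(tp, ad_gather(tp, states$q, fg$j), mask)
  Pi <- ad_gather(tp, states$P, fg$i)
  Pj <- ad_rowscale(tp, ad_gather(tp, states$P, fg$j), mask)
  pir <- ad_xyz_dot(tp, Pi, fg$rx, fg$ry, fg$rz, S)
  pjr <- ad_xyz_dot(tp, Pj, fg$rx, fg$ry, fg$rz, S)
  pipj <- ad_xyz_pair_dot(tp, Pi, Pj, S)
  pjn <- ad_xyz_norm(tp, Pj, S)
  dcol <- matrix(fg$d, ncol = 1L)
  # reciprocal distance capped at contact scale: near-coincident atoms in
  # malformed inputs must not blow up the feature range
  invd <- matrix(ifelse(fg$mask > 0, 1 / pmax(fg$d, 0.5), 0), ncol = 1L)
  x <- ad_concat(tp, list(qi, qj, dcol, invd, pir, pjr, pipj, pjn))
  list(edgef = nn_mlp(tp, lp$edge, x), Pj = Pj)
}

tf_attention <- function(tp, states, edgef, fg, lp, n_key, n_head) {
  k <- nn_mlp(tp, lp$key, edgef)
  qq <- nn_mlp(tp, lp$query, states$q)
  qe <- ad_gather(tp, qq, fg$i)
  prod <- ad_mul(tp, qe, k)
  logits <- ad_scale(tp, ad_mm(tp, prod, head_sum_matrix(n_head, n_key)),
                     1 / sqrt(n_key))
  ad_group_softmax(tp, logits, fg$i)
}

tf_update <- function(tp, states, enc, fg, lp, n_key, n_head) {
  S <- ncol(nval(states$q))
  edgef <- enc$edgef
  Pj <- enc$Pj
  a <- tf_attention(tp, states, edgef, fg, lp, n_key, n_head)
  v <- nn_mlp(tp, lp$value$net, edgef)
  gh <- nn_mlp(tp, lp$vgate, edgef)
  heads_q <- vector("list", n_head)
  dP <- NULL
  for (h in seq_len(n_head)) {
    ah <- ad_col(tp, a, h)
    vh <- ad_cols(tp, v, head_cols(h, S))
    heads_q[[h]] <- ad_group_sum(tp, ad_rowscale(tp, vh, ah), fg$i, fg$n)
    g <- ad_cols(tp, gh, head_cols(2L * h - 1L, S))
    hh <- ad_cols(tp, gh, head_cols(2L * h, S))
    upd <- ad_vec_update(tp, g, hh, Pj, fg$rx, fg$ry, fg$rz, ah,
                         fg$i, fg$n, S)
    dP <- if (is.null(dP)) upd else ad_add(tp, dP, upd)
  }
  oq <- ad_addbias(tp, ad_mm(tp, ad_concat(tp, heads_q), lp$value$comb$W),
                   lp$value$comb$b)
  list(q = ad_add(tp, states$q, oq),
       P = ad_add(tp, states$P, dP),
       attn = a)
}

tf_block <- function(tp, states, fg, lp, n_key, n_head) {
  enc <- tf_encode(tp, states, fg, lp)
  tf_update(tp, states, enc, fg, lp, n_key, n_head)
}

# residue pooling: softmax attention over the atoms of each residue, with
# the same invariant weights applied to scalar and vector channels.
tf_pool <- function(tp, states, res_of_atom, n_res, pp, n_head) {
  S <- ncol(nval(states$q))
  logits <- nn_mlp(tp, pp$attn, states$q)
  w <- ad_group_softmax(tp, logits, res_of_atom)
  hq <- vector("list", n_head)
  Pr <- NULL
  for (h in seq_len(n_head)) {
    wh <- ad_col(tp, w, h)
    hq[[h]] <- ad_group_sum(tp, ad_rowscale(tp, states$q, wh),
                            res_of_atom, n_res)
    Ph <- ad_group_sum(tp, ad_rowscale(tp, states$P, wh), res_of_atom, n_res)
    # head block of the (no-bias) vector combiner: bias would break
    # equivariance
    Wh <- ad_rows(tp, pp$comb_p$W, head_cols(h, S))
    Pm <- ad_mm3(tp, Ph, Wh, S)
    Pr <- if (is.null(Pr)) Pm else ad_add(tp, Pr, Pm)
  }
  qr <- ad_addbias(tp, ad_mm(tp, ad_concat(tp, hq), pp$comb_q$W), pp$comb_q$b)
  list(q = qr, P = Pr)
}

# collapse vector states to channel norms and decode confidences
tf_head <- function(tp, res_states, hp) {
  S <- ncol(nval(res_states$q))
  nrm <- ad_xyz_norm(tp, res_states$P, S)
  x <- ad_concat(tp, list(res_states$q, nrm))
  ad_sigmoid(tp, nn_mlp(tp, hp, x))
}

# extra op needed above: single column of a matrix node, as a vector
ad_col <- function(tape, a, j) {
  av <- nval(a)
  v <- av[, j]
  nr <- nrow(av); nc <- ncol(av)
  ad_node(tape, v, .pids(a), function(g) {
    out <- matrix(0, nr, nc)
    out[, j] <- g
    list(out)
  })
}

# ---- plain-value module surface ----------------------------------------

# p: N x 3 x S array -> combined N x 3S matrix (axis-major blocks)
as_pcomb <- function(p) {
  n <- dim(p)[1]; S <- dim(p)[3]
  cbind(matrix(p[, 1, ], n, S), matrix(p[, 2, ], n, S),
        matrix(p[, 3, ], n, S))
}

as_parr <- function(P) {
  S <- ncol(P) / 3L
  n <- nrow(P)
  out <- array(0, c(n, 3L, S))
  out[, 1, ] <- P[, seq_len(S)]
  out[, 2, ] <- P[, S + seq_len(S)]
  out[, 3, ] <- P[, 2L * S + seq_len(S)]
  out
}

#' Initial state tensors for a structure
#' @param n_atoms atom count.
#' @param S state size.
#' @return list with `q` (N x S zeros) and `p` (N x 3 x S zeros); vector
#'   states always start at zero.
#' @export
init_states <- function(n_atoms, S) {
  list(q = matrix(0, n_atoms, S), p = array(0, c(n_atoms, 3, S)))
}

#' Invariant edge encoding of pairwise interactions
#'
#' Encodes every (atom, neighbour) pair from rotation-invariant quantities
#' only: the two scalar states, the distance (plus its reciprocal) and the
#' contractions of the vector states with the unit displacement.  Sink slots
#' encode from zero neighbour state and zero geometry.
#'
#' @param states list with `q` (N x S) and `p` (N x 3 x S).
#' @param graph a [build_knn_graph()] result on the same atoms.
#' @param params one block's parameters (see [build_model()]).
#' @return numeric matrix (N*nn) x S of edge features, atom-major.
#' @export
encode_interactions <- function(states, graph, params) {
  if (nrow(states$q) != nrow(graph$idx)) stop("states/graph atom mismatch")
  tp <- ad_tape()
  st <- list(q = states$q, P = as_pcomb(states$p))
  nval(tf_encode(tp, st, flatten_graph(graph), params)$edgef)
}

#' One geometric transformer update
#'
#' Multi-head attention with queries from the central scalar state and
#' keys/values/gates from the invariant edge features; residual updates for
#' both the scalar and the vector states.  The scalar output is invariant
#' and the vector output equivariant under rigid transforms of the input.
#'
#' @inheritParams encode_interactions
#' @param n_key key width.
#' @param n_head head count.
#' @return list with updated `q`, `p`, and `attn` ((N*nn) x n_head attention
#'   weights, summing to 1 over each atom's slots).
#' @export
transformer_update <- function(states, graph, params, n_key = 3L, n_head = 2L) {
  tp <- ad_tape()
  st <- list(q = states$q, P = as_pcomb(states$p))
  fg <- flatten_graph(graph)
  out <- tf_block(tp, st, fg, params, n_key, n_head)
  if (any(!is.finite(nval(out$q)))) stop("non-finite states after update")
  list(q = nval(out$q),
       p = as_parr(nval(out$P)),
       attn = nval(out$attn))
}

#' Zero out sink slots of a per-edge array
#'
#' Graph construction already flags padding slots ([build_knn_graph()]
#' `sink_mask`) and gives them zero state and zero geometry; this helper
#' applies the same mask to an arbitrary per-edge feature array (atom-major
#' edge order) so downstream code can treat sink rows as the zero-state sink
#' node.
#'
#' @param edges (N*nn) x F matrix of per-edge values.
#' @param graph the [build_knn_graph()] the edges belong to.
#' @return the matrix with sink rows set to zero.
#' @export
pad_with_sink <- function(edges, graph) {
  mask <- as.numeric(!as.vector(t(graph$sink_mask)))
  edges * mask
}

#' Attention-based residue pooling
#'
#' Aggregates atom states to residue states with a local multi-head softmax
#' over the atoms of each residue; the invariant weights are shared between
#' the scalar and vector channels, preserving equivariance.
#'
#' @param states list with `q` (N x S) and `p` (N x 3 x S).
#' @param res_of_atom integer vector mapping each atom to its residue
#'   (1..n_res; every residue must have at least one atom).
#' @param params pooling parameters.
#' @param n_head pooling head count (default 4).
#' @return residue-level states: `q` (R x S), `p` (R x 3 x S).
#' @export
residue_pool <- function(states, res_of_atom, params, n_head = 4L) {
  n_res <- max(res_of_atom)
  if (!all(seq_len(n_res) %in% res_of_atom)) stop("residue without atoms")
  tp <- ad_tape()
  st <- list(q = states$q, P = as_pcomb(states$p))
  out <- tf_pool(tp, st, res_of_atom, n_res, params, n_head)
  list(q = nval(out$q), p = as_parr(nval(out$P)))
}

#' Collapse residue states and predict channel confidences
#'
#' Vector states are collapsed to their channel-wise norms (invariants),
#' concatenated with the scalar state, and decoded by a 3-layer MLP with a
#' sigmoid per channel.
#'
#' @param res_states residue-level states from [residue_pool()].
#' @param params head MLP parameters.
#' @return R x n_channels matrix of confidences, all strictly in (0, 1).
#' @export
collapse_and_predict <- function(res_states, params) {
  tp <- ad_tape()
  st <- list(q = res_states$q, P = as_pcomb(res_states$p))
  nval(tf_head(tp, st, params))
}
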