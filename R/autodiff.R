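# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices.  Every operation evaluates eagerly and records a closure that maps
# the output gradient to gradients of its node-valued arguments.  Arguments
# that are plain matrices/vectors are treated as constants and receive no
# gradient.  This is all the machinery the geometric transformer needs:
# matmul, broadcast bias, elementwise maps, row scaling, gather/scatter,
# grouped sums and grouped softmax.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$val <- vector("list", 512L)
  e$bck <- vector("list", 512L)
  e$par <- vector("list", 512L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

is_node <- function(x) inherits(x, "ad_node")

nval <- function(x) if (is_node(x)) x$v else x

ad_node <- function(tape, value, parents = integer(0), backfn = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$val)) {
    m <- 2L * length(tape$val)
    length(tape$val) <- m
    length(tape$bck) <- m
    length(tape$par) <- m
  }
  tape$val[[n]] <- TRUE   # presence marker; values live in the handles
  if (!is.null(backfn)) {
    tape$bck[[n]] <- backfn
    tape$par[[n]] <- parents
  }
  tape$n <- n
  structure(list(i = n, v = value), class = "ad_node")
}

ad_leaf <- function(tape, value) ad_node(tape, value)

# Collect parent ids / build a backfn that returns gradients in the same
# order, skipping constant arguments.
.pids <- function(...) {
  args <- list(...)
  unlist(lapply(args, function(a) if (is_node(a)) a$i else integer(0)))
}

#' @noRd
ad_backward <- function(tape, loss, seed = 1) {
  grads <- vector("list", tape$n)
  grads[[loss$i]] <- seed
  for (k in seq.int(loss$i, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    bf <- tape$bck[[k]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tape$par[[k]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      pj <- ps[[j]]
      grads[[pj]] <- if (is.null(grads[[pj]])) gj else grads[[pj]] + gj
    }
    grads[k] <- list(NULL)
  }
  grads
}

ad_mm <- function(tape, a, b) {
  av <- nval(a); bv <- nval(b)
  v <- av %*% bv
  bfs <- list()
  if (is_node(a)) bfs <- c(bfs, list(function(g) g %*% t(bv)))
  if (is_node(b)) bfs <- c(bfs, list(function(g) crossprod(av, g)))
  ad_node(tape, v, .pids(a, b), function(g) lapply(bfs, function(f) f(g)))
}

ad_add <- function(tape, a, b) {
  v <- nval(a) + nval(b)
  na <- is_node(a); nb <- is_node(b)
  ad_node(tape, v, .pids(a, b), function(g) {
    out <- list()
    if (na) out <- c(out, list(g))
    if (nb) out <- c(out, list(g))
    out
  })
}

ad_sub <- function(tape, a, b) {
  v <- nval(a) - nval(b)
  na <- is_node(a); nb <- is_node(b)
  ad_node(tape, v, .pids(a, b), function(g) {
    out <- list()
    if (na) out <- c(out, list(g))
    if (nb) out <- c(out, list(-g))
    out
  })
}

ad_mul <- function(tape, a, b) {
  av <- nval(a); bv <- nval(b)
  v <- av * bv
  na <- is_node(a); nb <- is_node(b)
  ad_node(tape, v, .pids(a, b), function(g) {
    out <- list()
    if (na) out <- c(out, list(g * bv))
    if (nb) out <- c(out, list(g * av))
    out
  })
}

ad_scale <- function(tape, a, s) {
  v <- nval(a) * s
  ad_node(tape, v, .pids(a), function(g) list(g * s))
}

# A (n x k) + bias (length k), broadcast over rows.
ad_addbias <- function(tape, a, b) {
  av <- nval(a); bv <- nval(b)
  v <- av + rep(bv, each = nrow(av))
  na <- is_node(a); nb <- is_node(b)
  ad_node(tape, v, .pids(a, b), function(g) {
    out <- list()
    if (na) out <- c(out, list(g))
    if (nb) out <- c(out, list(colSums(g)))
    out
  })
}

# A (n x k) scaled per row by w (length n).
ad_rowscale <- function(tape, a, w) {
  av <- nval(a); wv <- nval(w)
  v <- av * wv
  na <- is_node(a); nw <- is_node(w)
  ad_node(tape, v, .pids(a, w), function(g) {
    out <- list()
    if (na) out <- c(out, list(g * wv))
    if (nw) out <- c(out, list(rowSums(g * av)))
    out
  })
}

ad_elu <- function(tape, a) {
  av <- nval(a)
  v <- av
  neg <- which(av < 0)
  v[neg] <- exp(av[neg]) - 1
  ad_node(tape, v, .pids(a), function(g) {
    gg <- g
    gg[neg] <- g[neg] * (v[neg] + 1)
    list(gg)
  })
}

ad_sigmoid <- function(tape, a) {
  av <- nval(a)
  s <- 1 / (1 + exp(-av))
  ad_node(tape, s, .pids(a), function(g) list(g * s * (1 - s)))
}

ad_log <- function(tape, a) {
  av <- nval(a)
  ad_node(tape, log(av), .pids(a), function(g) list(g / av))
}

ad_sqrt <- function(tape, a) {
  av <- nval(a)
  v <- sqrt(av)
  ad_node(tape, v, .pids(a), function(g) list(g * 0.5 / v))
}

ad_clamp <- function(tape, a, lo, hi) {
  av <- nval(a)
  v <- pmin(pmax(av, lo), hi)
  pass <- av > lo & av < hi
  ad_node(tape, v, .pids(a), function(g) list(g * pass))
}

# Row gather: A[idx, ].  Backward scatter-adds duplicate indices.
ad_gather <- function(tape, a, idx) {
  av <- nval(a)
  v <- av[idx, , drop = FALSE]
  nr <- nrow(av); nc <- ncol(av)
  ad_node(tape, v, .pids(a), function(g) {
    sc <- rowsum(g, group = idx, reorder = FALSE)
    out <- matrix(0, nr, nc)
    out[as.integer(rownames(sc)), ] <- sc
    list(out)
  })
}

# Sum rows of A by integer group labels in 1..ngroups (every group non-empty
# is not required; absent groups yield zero rows).
ad_group_sum <- function(tape, a, groups, ngroups) {
  av <- nval(a)
  sc <- rowsum(av, group = groups, reorder = FALSE)
  v <- matrix(0, ngroups, ncol(av))
  v[as.integer(rownames(sc)), ] <- sc
  ad_node(tape, v, .pids(a), function(g) list(g[groups, , drop = FALSE]))
}

# Column-wise softmax within integer groups (rows sharing a label compete).
ad_group_softmax <- function(tape, a, groups) {
  av <- nval(a)
  x <- av - rep(apply(av, 2, max), each = nrow(av))
  e <- exp(x)
  s <- rowsum(e, group = groups, reorder = FALSE)
  rowmap <- match(groups, as.integer(rownames(s)))
  v <- e / s[rowmap, , drop = FALSE]
  ad_node(tape, v, .pids(a), function(g) {
    gs <- rowsum(g * v, group = groups, reorder = FALSE)
    list(v * (g - gs[rowmap, , drop = FALSE]))
  })
}

ad_cols <- function(tape, a, js) {
  av <- nval(a)
  v <- av[, js, drop = FALSE]
  nc <- ncol(av); nr <- nrow(av)
  ad_node(tape, v, .pids(a), function(g) {
    out <- matrix(0, nr, nc)
    out[, js] <- g
    list(out)
  })
}

ad_concat <- function(tape, args) {
  vals <- lapply(args, nval)
  v <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  keep <- vapply(args, is_node, TRUE)
  ad_node(tape, v, .pids_list(args), function(g) {
    out <- list()
    for (j in seq_along(args)) {
      if (keep[j]) out <- c(out, list(g[, starts[j]:ends[j], drop = FALSE]))
    }
    out
  })
}

.pids_list <- function(args) {
  unlist(lapply(args, function(a) if (is_node(a)) a$i else integer(0)))
}

ad_sum <- function(tape, a) {
  av <- nval(a)
  nr <- nrow(av); nc <- ncol(av)
  ad_node(tape, sum(av), .pids(a), function(g) list(matrix(g, nr, nc)))
}

ad_mean <- function(tape, a) {
  av <- nval(a)
  nr <- nrow(av); nc <- ncol(av)
  ad_node(tape, mean(av), .pids(a), function(g) list(matrix(g / (nr * nc), nr, nc)))
}

# ---- fused operations over combined vector-state layout -----------------
# Vector states are stored as N x 3S matrices with axis-major blocks
# [x(1..S) | y(1..S) | z(1..S)]; these fused ops keep the tape short.

xyz_blocks <- function(S) list(seq_len(S), S + seq_len(S), 2L * S + seq_len(S))

# channel-wise contraction of a combined vector state with a constant
# per-row direction (rx, ry, rz): returns sum_k P_k * r_k  (n x S)
ad_xyz_dot <- function(tape, P, rx, ry, rz, S) {
  Pv <- nval(P)
  b <- xyz_blocks(S)
  v <- Pv[, b[[1]], drop = FALSE] * rx + Pv[, b[[2]], drop = FALSE] * ry +
    Pv[, b[[3]], drop = FALSE] * rz
  ad_node(tape, v, .pids(P), function(g) {
    list(cbind(g * rx, g * ry, g * rz))
  })
}

# channel-wise dot product of two combined vector states (n x S)
ad_xyz_pair_dot <- function(tape, A, B, S) {
  Av <- nval(A); Bv <- nval(B)
  b <- xyz_blocks(S)
  v <- Av[, b[[1]], drop = FALSE] * Bv[, b[[1]], drop = FALSE] +
    Av[, b[[2]], drop = FALSE] * Bv[, b[[2]], drop = FALSE] +
    Av[, b[[3]], drop = FALSE] * Bv[, b[[3]], drop = FALSE]
  na <- is_node(A); nb <- is_node(B)
  ad_node(tape, v, .pids(A, B), function(g) {
    out <- list()
    if (na) out <- c(out, list(cbind(g * Bv[, b[[1]], drop = FALSE],
                                     g * Bv[, b[[2]], drop = FALSE],
                                     g * Bv[, b[[3]], drop = FALSE])))
    if (nb) out <- c(out, list(cbind(g * Av[, b[[1]], drop = FALSE],
                                     g * Av[, b[[2]], drop = FALSE],
                                     g * Av[, b[[3]], drop = FALSE])))
    out
  })
}

# channel-wise Euclidean norm of a combined vector state (n x S)
ad_xyz_norm <- function(tape, A, S, eps = 1e-8) {
  Av <- nval(A)
  b <- xyz_blocks(S)
  v <- sqrt(Av[, b[[1]], drop = FALSE]^2 + Av[, b[[2]], drop = FALSE]^2 +
              Av[, b[[3]], drop = FALSE]^2 + eps)
  ad_node(tape, v, .pids(A), function(g) {
    gv <- g / v
    list(cbind(gv * Av[, b[[1]], drop = FALSE],
               gv * Av[, b[[2]], drop = FALSE],
               gv * Av[, b[[3]], drop = FALSE]))
  })
}

# fused equivariant vector-update head:
#   out = groupsum_i( a * [ g (x) rhat + h (.) Pj ] )      (ngroups x 3S)
# with per-edge invariant gates g, h (E x S), gathered neighbour states Pj
# (E x 3S), constant unit displacements (rx, ry, rz) and attention a (E).
ad_vec_update <- function(tape, g, h, Pj, rx, ry, rz, a, groups, ngroups, S) {
  gv <- nval(g); hv <- nval(h); Pv <- nval(Pj); av <- nval(a)
  b <- xyz_blocks(S)
  contrib <- cbind(gv * rx + hv * Pv[, b[[1]], drop = FALSE],
                   gv * ry + hv * Pv[, b[[2]], drop = FALSE],
                   gv * rz + hv * Pv[, b[[3]], drop = FALSE])
  sc <- rowsum(contrib * av, group = groups, reorder = FALSE)
  v <- matrix(0, ngroups, 3L * S)
  v[as.integer(rownames(sc)), ] <- sc
  ng <- is_node(g); nh <- is_node(h); np <- is_node(Pj); na <- is_node(a)
  ad_node(tape, v, .pids(g, h, Pj, a), function(G) {
    Ge <- G[groups, , drop = FALSE]
    G1 <- Ge[, b[[1]], drop = FALSE]
    G2 <- Ge[, b[[2]], drop = FALSE]
    G3 <- Ge[, b[[3]], drop = FALSE]
    out <- list()
    if (ng) out <- c(out, list(av * (G1 * rx + G2 * ry + G3 * rz)))
    if (nh) {
      out <- c(out, list(av * (G1 * Pv[, b[[1]], drop = FALSE] +
                                 G2 * Pv[, b[[2]], drop = FALSE] +
                                 G3 * Pv[, b[[3]], drop = FALSE])))
    }
    if (np) out <- c(out, list(cbind(G1 * (av * hv), G2 * (av * hv),
                                     G3 * (av * hv))))
    if (na) out <- c(out, list(rowSums(Ge * contrib)))
    out
  })
}

# per-axis matrix product: each axis block of P (n x 3S) times W (S x S')
ad_mm3 <- function(tape, P, W, S) {
  Pv <- nval(P); Wv <- nval(W)
  b <- xyz_blocks(S)
  v <- cbind(Pv[, b[[1]], drop = FALSE] %*% Wv,
             Pv[, b[[2]], drop = FALSE] %*% Wv,
             Pv[, b[[3]], drop = FALSE] %*% Wv)
  So <- ncol(Wv)
  bo <- xyz_blocks(So)
  np <- is_node(P); nw <- is_node(W)
  ad_node(tape, v, .pids(P, W), function(g) {
    g1 <- g[, bo[[1]], drop = FALSE]
    g2 <- g[, bo[[2]], drop = FALSE]
    g3 <- g[, bo[[3]], drop = FALSE]
    out <- list()
    if (np) out <- c(out, list(cbind(g1 %*% t(Wv), g2 %*% t(Wv),
                                     g3 %*% t(Wv))))
    if (nw) {
      out <- c(out, list(crossprod(Pv[, b[[1]], drop = FALSE], g1) +
                           crossprod(Pv[, b[[2]], drop = FALSE], g2) +
                           crossprod(Pv[, b[[3]], drop = FALSE], g3)))
    }
    out
  })
}

# extract rows of a matrix node (constant row set)
ad_rows <- function(tape, a, rows) {
  av <- nval(a)
  v <- av[rows, , drop = FALSE]
  nr <- nrow(av); nc <- ncol(av)
  ad_node(tape, v, .pids(a), function(g) {
    out <- matrix(0, nr, nc)
    out[rows, ] <- g
    list(out)
  })
}

# fused dense layer: A %*% W + bias (bias broadcast over rows)
ad_linear <- function(tape, a, W, b) {
  av <- nval(a); Wv <- nval(W); bv <- nval(b)
  v <- av %*% Wv
  v <- v + rep(bv, each = nrow(v))
  na <- is_node(a); nw <- is_node(W); nb <- is_node(b)
  ad_node(tape, v, .pids(a, W, b), function(g) {
    out <- list()
    if (na) out <- c(out, list(g %*% t(Wv)))
    if (nw) out <- c(out, list(crossprod(av, g)))
    if (nb) out <- c(out, list(colSums(g)))
    out
  })
}
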