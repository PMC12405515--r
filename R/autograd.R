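# Minimal tape-based reverse-mode autodiff on numeric matrices.
#
# Every tensor is an environment holding $value (a matrix), $grad, the
# parent nodes and a backward closure. Ops append nodes to a global tape;
# ag_backward() walks the tape in reverse creation order. Only what the
# bundled networks need is implemented: matmul, broadcast add, elementwise
# arithmetic, a few activations, layer norm, batched softmax attention and
# row gather/concat for patch (strided-convolution) layers.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L

ag_tape_reset <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_new <- function(value, parents = list(), backward = NULL, track = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  class(node) <- "ag_tensor"
  if (track && !is.null(.ag$tape)) {
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- node
    .ag$n <- n
  }
  node
}

ag_const <- function(x) ag_new(as_mat(x), track = FALSE)

ag_param <- function(x) {
  node <- ag_new(as_mat(x), track = FALSE)
  node$is_param <- TRUE
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (.ag$n > 0L) {
    for (i in seq(.ag$n, 1L)) {
      node <- .ag$tape[[i]]
      if (!is.null(node$grad) && !is.null(node$backward)) node$backward(node, node$grad)
    }
  }
  invisible(NULL)
}

ag_matmul <- function(a, b) {
  ag_new(a$value %*% b$value, list(a, b), function(node, g) {
    ag_accum(node$parents[[1L]], g %*% t(node$parents[[2L]]$value))
    ag_accum(node$parents[[2L]], crossprod(node$parents[[1L]]$value, g))
  })
}

# a: n x d matrix; b: same shape, or a 1 x d bias row broadcast over rows,
# or a 1 x 1 scalar.
ag_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    ag_new(av + bv, list(a, b), function(node, g) {
      ag_accum(node$parents[[1L]], g)
      ag_accum(node$parents[[2L]], g)
    })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ag_new(sweep(av, 2L, bv[1L, ], "+"), list(a, b), function(node, g) {
      ag_accum(node$parents[[1L]], g)
      ag_accum(node$parents[[2L]], matrix(colSums(g), 1L))
    })
  } else if (length(bv) == 1L) {
    ag_new(av + bv[1L], list(a, b), function(node, g) {
      ag_accum(node$parents[[1L]], g)
      ag_accum(node$parents[[2L]], matrix(sum(g), 1L, 1L))
    })
  } else stop("ag_add: incompatible shapes")
}

ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

ag_scale <- function(a, s) {
  ag_new(a$value * s, list(a), function(node, g) ag_accum(node$parents[[1L]], g * s))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  stopifnot(identical(dim(av), dim(bv)))
  ag_new(av * bv, list(a, b), function(node, g) {
    ag_accum(node$parents[[1L]], g * node$parents[[2L]]$value)
    ag_accum(node$parents[[2L]], g * node$parents[[1L]]$value)
  })
}

ag_relu <- function(a) {
  ag_new(pmax(a$value, 0), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g * (node$parents[[1L]]$value > 0))
  })
}

ag_silu <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  out <- ag_new(a$value * s, list(a), function(node, g) {
    x <- node$parents[[1L]]$value
    sg <- node$cache_s
    ag_accum(node$parents[[1L]], g * (sg * (1 + x * (1 - sg))))
  })
  out$cache_s <- s
  out
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  out <- ag_new(s, list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g * node$value * (1 - node$value))
  })
  out
}

ag_tanh <- function(a) {
  ag_new(tanh(a$value), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g * (1 - node$value^2))
  })
}

ag_exp <- function(a) {
  ag_new(exp(a$value), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g * node$value)
  })
}

ag_square <- function(a) {
  ag_new(a$value^2, list(a), function(node, g) {
    ag_accum(node$parents[[1L]], 2 * g * node$parents[[1L]]$value)
  })
}

# Smooth |x| is not needed; subgradient 0 at 0 for the L1 pixel loss.
ag_abs <- function(a) {
  ag_new(abs(a$value), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], g * sign(node$parents[[1L]]$value))
  })
}

ag_sum <- function(a) {
  ag_new(matrix(sum(a$value), 1L, 1L), list(a), function(node, g) {
    p <- node$parents[[1L]]
    ag_accum(p, array(g[1L], dim(p$value)))
  })
}

ag_mean <- function(a) {
  n <- length(a$value)
  ag_new(matrix(mean(a$value), 1L, 1L), list(a), function(node, g) {
    p <- node$parents[[1L]]
    ag_accum(p, array(g[1L] / n, dim(p$value)))
  })
}

# Row-wise layer normalization with per-column affine parameters.
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gamma$value[1L, ], "*"), 2L, beta$value[1L, ], "+")
  out <- ag_new(y, list(a, gamma, beta), function(node, g) {
    d <- ncol(node$parents[[1L]]$value)
    xhat_ <- node$cache_xhat
    inv_ <- node$cache_inv
    gm <- node$parents[[2L]]$value[1L, ]
    ag_accum(node$parents[[2L]], matrix(colSums(g * xhat_), 1L))
    ag_accum(node$parents[[3L]], matrix(colSums(g), 1L))
    gx <- sweep(g, 2L, gm, "*")
    t1 <- rowSums(gx) / d
    t2 <- rowSums(gx * xhat_) / d
    ag_accum(node$parents[[1L]], inv_ * (gx - t1 - xhat_ * t2))
  })
  out$cache_xhat <- xhat
  out$cache_inv <- inv
  out
}

# Batched scaled dot-product attention.
# q: (B*Tq) x dk, k/v: (B*Tk) x dk / (B*Tk) x dv, rows grouped by batch item.
ag_attention <- function(q, k, v, n_batch, tq, tk) {
  dk <- ncol(q$value)
  sc <- 1 / sqrt(dk)
  B <- n_batch
  out_v <- matrix(0, B * tq, ncol(v$value))
  attn <- vector("list", B)
  for (b in seq_len(B)) {
    iq <- ((b - 1L) * tq + 1L):(b * tq)
    ik <- ((b - 1L) * tk + 1L):(b * tk)
    s <- (q$value[iq, , drop = FALSE] %*% t(k$value[ik, , drop = FALSE])) * sc
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    a <- e / rowSums(e)
    attn[[b]] <- a
    out_v[iq, ] <- a %*% v$value[ik, , drop = FALSE]
  }
  out <- ag_new(out_v, list(q, k, v), function(node, g) {
    qn <- node$parents[[1L]]; kn <- node$parents[[2L]]; vn <- node$parents[[3L]]
    gq <- array(0, dim(qn$value)); gk <- array(0, dim(kn$value)); gv <- array(0, dim(vn$value))
    for (b in seq_len(B)) {
      iq <- ((b - 1L) * tq + 1L):(b * tq)
      ik <- ((b - 1L) * tk + 1L):(b * tk)
      a <- node$cache_attn[[b]]
      gout <- g[iq, , drop = FALSE]
      gv[ik, ] <- gv[ik, , drop = FALSE] + crossprod(a, gout)
      ga <- gout %*% t(vn$value[ik, , drop = FALSE])
      gs <- a * (ga - rowSums(ga * a))
      gq[iq, ] <- gq[iq, , drop = FALSE] + (gs %*% kn$value[ik, , drop = FALSE]) * sc
      gk[ik, ] <- gk[ik, , drop = FALSE] + crossprod(gs, qn$value[iq, , drop = FALSE]) * sc
    }
    ag_accum(qn, gq); ag_accum(kn, gk); ag_accum(vn, gv)
  })
  out$cache_attn <- attn
  out
}

# Scatter-add g_vec into gp at (possibly duplicated) linear indices.
# order() uses radix sort on integers, so this is O(n log n) without the
# character-rowname overhead of rowsum(). A precomputed plan (for static
# index maps used every training step) skips the sort.
make_scatter_plan <- function(idx_vec) {
  o <- order(idx_vec)
  si <- idx_vec[o]
  ends <- c(which(diff(si) != 0L), length(si))
  list(o = o, ends = ends, cells = si[ends],
       unique = !anyDuplicated(idx_vec))
}

scatter_add <- function(gp, idx_vec, g_vec, plan = NULL) {
  if (is.null(plan)) plan <- make_scatter_plan(idx_vec)
  if (plan$unique) {
    gp[idx_vec] <- gp[idx_vec] + g_vec
    return(gp)
  }
  cs <- cumsum(g_vec[plan$o])
  ends <- plan$ends
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  gp[plan$cells] <- gp[plan$cells] + sums
  gp
}

# Gather rows with repetition: out[i, ] = a[idx[i], ]. Backward scatter-adds
# (direct row assignment when the indices are unique).
ag_gather_rows <- function(a, idx) {
  out <- ag_new(a$value[idx, , drop = FALSE], list(a), function(node, g) {
    p <- node$parents[[1L]]
    gp <- array(0, dim(p$value))
    id <- node$cache_idx
    if (!anyDuplicated(id)) {
      gp[id, ] <- g
    } else {
      np <- nrow(p$value)
      lin <- outer(id, (seq_len(ncol(p$value)) - 1L) * np, "+")
      gp <- scatter_add(gp, as.vector(lin), as.vector(g))
    }
    ag_accum(p, gp)
  })
  out$cache_idx <- idx
  out
}

# Concatenate k source rows into each output row: idx is Tout x k row-index
# matrix; out[i, ] = c(a[idx[i,1], ], ..., a[idx[i,k], ]). Used for
# non-overlapping patch (strided conv) layers and token merging.
ag_gather_concat <- function(a, idx) {
  d <- ncol(a$value)
  k <- ncol(idx)
  outv <- matrix(0, nrow(idx), d * k)
  for (j in seq_len(k)) outv[, ((j - 1L) * d + 1L):(j * d)] <- a$value[idx[, j], , drop = FALSE]
  out <- ag_new(outv, list(a), function(node, g) {
    p <- node$parents[[1L]]
    np <- nrow(p$value)
    gp <- array(0, dim(p$value))
    id <- node$cache_idx
    colshift <- (seq_len(d) - 1L) * np
    for (j in seq_len(k)) {
      gj <- g[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
      lin <- outer(id[, j], colshift, "+")
      gp <- scatter_add(gp, as.vector(lin), as.vector(gj))
    }
    ag_accum(p, gp)
  })
  out$cache_idx <- idx
  out
}

# Inverse of ag_gather_concat for k = number of column slices: split each row
# of a ((T x k*d)) into k rows of d, placed at rows idx[i, j].
ag_split_rows <- function(a, idx, d) {
  k <- ncol(idx)
  n_out <- max(idx)
  outv <- matrix(0, n_out, d)
  for (j in seq_len(k)) outv[idx[, j], ] <- a$value[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
  out <- ag_new(outv, list(a), function(node, g) {
    p <- node$parents[[1L]]
    gp <- array(0, dim(p$value))
    id <- node$cache_idx
    for (j in seq_len(k)) {
      gp[, ((j - 1L) * d + 1L):(j * d)] <- g[id[, j], , drop = FALSE]
    }
    ag_accum(p, gp)
  })
  out$cache_idx <- idx
  out
}

# Fully general rearrangement: out[i] = a[lin[i]] where lin is a matrix of
# linear (column-major) indices into a$value, shaped like the output.
# Backward scatter-adds over duplicated indices. Used to move between pixel,
# patch-token and channel layouts inside the graph.
ag_gather_cells <- function(a, lin, plan = NULL) {
  out <- ag_new(matrix(a$value[as.vector(lin)], nrow(lin), ncol(lin)), list(a), function(node, g) {
    p <- node$parents[[1L]]
    ag_accum(p, scatter_add(array(0, dim(p$value)),
                            as.vector(node$cache_lin), as.vector(g),
                            node$cache_plan))
  })
  out$cache_lin <- lin
  out$cache_plan <- plan
  out
}

ag_transpose <- function(a) {
  ag_new(t(a$value), list(a), function(node, g) {
    ag_accum(node$parents[[1L]], t(g))
  })
}
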