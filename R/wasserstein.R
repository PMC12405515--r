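# Exact empirical Wasserstein distance between uniform point clouds.
# Equal-size sets reduce to an assignment problem (Hungarian algorithm via
# clue::solve_LSAP); unequal sizes are solved exactly by a transportation
# simplex on the integer-scaled problem (supplies n per row of A, demands
# m per column of B, total m*n on both sides).

# Transportation simplex (MODI) with Bland's entering rule.
# supply, demand: integer vectors; C: cost matrix. Returns optimal total
# cost of the integer transportation problem.
transport_simplex <- function(C, supply, demand, max_iter = 100000L) {
  m <- length(supply); n <- length(demand)
  stopifnot(sum(supply) == sum(demand))
  flow <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  # north-west corner start
  i <- 1L; j <- 1L
  s <- supply; d <- demand
  while (i <= m && j <= n) {
    q <- min(s[i], d[j])
    flow[i, j] <- q
    basis[i, j] <- TRUE
    s[i] <- s[i] - q; d[j] <- d[j] - q
    if (i == m && j == n) break
    if (s[i] == 0 && i < m) i <- i + 1L else j <- j + 1L
  }
  # ensure a spanning basis of m+n-1 cells (NW corner can be degenerate
  # but always yields a connected tree by construction)
  for (iter in seq_len(max_iter)) {
    # duals from the basis tree
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1L] <- 0
    repeat {
      changed <- FALSE
      for (ii in seq_len(m)) if (!is.na(u[ii])) {
        js <- which(basis[ii, ] & is.na(v))
        if (length(js)) { v[js] <- C[ii, js] - u[ii]; changed <- TRUE }
      }
      for (jj in seq_len(n)) if (!is.na(v[jj])) {
        is_ <- which(basis[, jj] & is.na(u))
        if (length(is_)) { u[is_] <- C[is_, jj] - v[jj]; changed <- TRUE }
      }
      if (!changed) break
    }
    red <- C - outer(u, v, "+")
    cand <- which(!basis & red < -1e-9)
    if (length(cand) == 0L) break
    ent <- min(cand)  # Bland's rule: smallest linear index
    ei <- ((ent - 1L) %% m) + 1L; ej <- ((ent - 1L) %/% m) + 1L
    # cycle: tree path from col ej back to row ei through basis cells
    # nodes: 1..m rows, m+1..m+n cols
    parent <- rep(0L, m + n)
    seen <- rep(FALSE, m + n)
    seen[ei] <- TRUE
    queue <- ei
    while (length(queue)) {
      node <- queue[1L]; queue <- queue[-1L]
      if (node == m + ej) break
      if (node <= m) {
        nxt <- m + which(basis[node, ])
      } else {
        nxt <- which(basis[, node - m])
      }
      nxt <- nxt[!seen[nxt]]
      # exclude walking back through the entering cell (not in basis yet)
      seen[nxt] <- TRUE
      parent[nxt] <- node
      queue <- c(queue, nxt)
    }
    stopifnot(seen[m + ej])
    path <- m + ej
    while (path[1L] != ei) path <- c(parent[path[1L]], path)
    # cycle edges: entering (ei, ej) '+', then alternate along the path
    cells <- matrix(0L, 0L, 2L)
    for (k in seq_len(length(path) - 1L)) {
      a <- path[k]; b <- path[k + 1L]
      cell <- if (a <= m) c(a, b - m) else c(b, a - m)
      cells <- rbind(cells, cell)
    }
    signs <- rep(c(-1, 1), length.out = nrow(cells))  # first path edge is '-'
    minus <- cells[signs < 0, , drop = FALSE]
    theta <- min(flow[minus])
    for (k in seq_len(nrow(cells))) {
      flow[cells[k, 1L], cells[k, 2L]] <- flow[cells[k, 1L], cells[k, 2L]] + signs[k] * theta
    }
    flow[ei, ej] <- flow[ei, ej] + theta
    basis[ei, ej] <- TRUE
    # leaving: first minus-cell whose flow hit zero (Bland-style)
    left <- FALSE
    for (k in seq_len(nrow(minus))) {
      if (!left && flow[minus[k, 1L], minus[k, 2L]] == 0) {
        basis[minus[k, 1L], minus[k, 2L]] <- FALSE
        left <- TRUE
      }
    }
    stopifnot(left)
  }
  sum(flow * C)
}

#' Exact Wasserstein distance between two embedding sets
#'
#' Empirical W_p with Euclidean ground metric and uniform weights, solved
#' exactly: equal-size sets via the Hungarian algorithm, unequal sizes via
#' a transportation simplex on the integer-scaled coupling polytope.
#'
#' @param A,B numeric matrices (rows = points) or vectors (1-D points).
#' @param p order of the distance (default 1).
#' @param max_pairs guard against accidental huge problems; `|A| * |B|`
#'   must not exceed it.
#' @return scalar W_p.
#' @export
wasserstein_set <- function(A, B, p = 1, max_pairs = 1e6) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 1L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 1L)
  pd_assert(nrow(A) >= 1L && nrow(B) >= 1L, "empty point set")
  pd_assert(ncol(A) == ncol(B), "point dimensions differ")
  m <- nrow(A); n <- nrow(B)
  pd_assert(as.double(m) * n <= max_pairs,
            "problem too large; raise max_pairs to confirm")
  D <- sqrt(cross_dist2(A, B))
  Cp <- D^p
  if (m == n) {
    perm <- clue::solve_LSAP(Cp)
    cost <- mean(Cp[cbind(seq_len(m), as.integer(perm))])
  } else {
    total <- transport_simplex(Cp, supply = rep(n, m), demand = rep(m, n))
    cost <- total / (m * n)
  }
  cost^(1 / p)
}
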