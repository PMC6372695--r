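# -- model builders ----------------------------------------------------------

chain_nodes <- function(pts, cid = 1L, ctype = "smooth_neurite", r = 0.3) {
  n <- nrow(pts)
  tibble::tibble(constituent_id = as.integer(cid), ctype = ctype,
                 node_id = seq_len(n),
                 parent_id = c(NA_integer_, seq_len(n - 1L)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 r = rep_len(r, n))
}

chain_model <- function(pts, ...) tissue_model(chain_nodes(pts, ...))

straight_chain <- function(n = 10, step = 1) {
  cbind(x = seq(0, by = step, length.out = n), y = 0, z = 0)
}

# a soma with one attached dendrite plus one detached (orphan) neurite
soma_dendrite_model <- function() {
  nd <- dplyr::bind_rows(
    tibble::tibble(constituent_id = 1L, ctype = "soma", node_id = 1:2,
                   parent_id = c(NA_integer_, 1L), x = c(0, 1), y = 0, z = 0,
                   r = 5),
    chain_nodes(straight_chain(6), cid = 2L),
    chain_nodes(cbind(x = seq(0, 5), y = 8, z = 0), cid = 3L))
  tissue_model(nd, attachments = tibble::tibble(
    constituent_id = 2L, parent_constituent_id = 1L, parent_node_id = 2L))
}

# trunk that bifurcates twice: root - a - (b, c), b - (d, e), c - (f, g)
trunk_binary_model <- function() {
  nd <- tibble::tibble(
    constituent_id = 1L, ctype = "smooth_neurite", node_id = 1:8,
    parent_id = c(NA, 1, 2, 2, 3, 3, 4, 4),
    x = c(0, 0, -1, 1, -2, -0.5, 0.5, 2),
    y = c(0, 1, 2, 2, 3, 3, 3, 3), z = 0, r = 0.2)
  tissue_model(nd)
}

helix_model <- function(r = 2, c = 1, turns = 1.5, spacing = 0.3,
                        tube_r = 0.3) {
  chain_model(make_helix(r, c, turns = turns, spacing = spacing), r = tube_r)
}

# -- independent oracles -----------------------------------------------------

# maximal unbranched runs enumerated by brute force on an explicit adjacency
# list: collect all simple paths between nodes of degree != 2 whose interior
# nodes all have degree 2
brute_force_segments <- function(edges, n_nodes) {
  adj <- lapply(seq_len(n_nodes), function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  })
  deg <- lengths(adj)
  ends <- which(deg != 2)
  seen <- character(0)
  out <- list()
  for (s in ends) {
    for (nb in adj[[s]]) {
      path <- c(s, nb)
      while (deg[path[length(path)]] == 2) {
        nxt <- setdiff(adj[[path[length(path)]]], path[length(path) - 1])
        path <- c(path, nxt)
      }
      key <- paste(sort(path), collapse = ",")  # node sets are unique in a tree
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- path
      }
    }
  }
  out
}

# Frenet curvature/torsion of an analytic curve r(t) by high-order finite
# differences on a dense parameter grid (independent of the polyline path)
frenet_oracle <- function(fun, t, h = 1e-4) {
  d1 <- (fun(t + h) - fun(t - h)) / (2 * h)
  d2 <- (fun(t + h) - 2 * fun(t) + fun(t - h)) / h^2
  d3 <- (fun(t + 2 * h) - 2 * fun(t + h) + 2 * fun(t - h) -
           fun(t - 2 * h)) / (2 * h^3)
  cr <- c(d1[2] * d2[3] - d1[3] * d2[2],
          d1[3] * d2[1] - d1[1] * d2[3],
          d1[1] * d2[2] - d1[2] * d2[1])
  kappa <- sqrt(sum(cr^2)) / sum(d1^2)^1.5
  tau <- sum(cr * d3) / sum(cr^2)
  c(kappa = kappa, tau = tau)
}

# Kruskal-Wallis H from first principles (ranks, tie correction)
kw_oracle <- function(groups) {
  vals <- unlist(groups)
  rk <- rank(vals)
  N <- length(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * (mean(r) - (N + 1) / 2)^2))
  ties <- table(vals)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exhaustive 4-vs-4 relabeling test on the Welch statistic
welch_permutation_p <- function(a, b) {
  x <- c(a, b)
  idx <- utils::combn(8, 4)
  tstat <- function(u, v) {
    (mean(u) - mean(v)) / sqrt(var(u) / length(u) + var(v) / length(v))
  }
  t_obs <- abs(tstat(a, b))
  ts <- apply(idx, 2, function(k) abs(tstat(x[k], x[-k])))
  mean(ts >= t_obs - 1e-12)
}

rigid_transform <- function(pts, seed = 99) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(9), 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- rnorm(3, sd = 5)
  })
  sweep(pts %*% Q, 2, shift, "+")
}
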