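#' Refine a traced model against the volume
#'
#' Conjugate-gradient minimisation of a per-chain objective balancing image
#' evidence against regularity:
#' negative mean normalised intensity at the nodes, plus `lambda_smooth`
#' times the summed squared second differences along the chain, plus
#' `lambda_length` times the squared deviation of each inter-node spacing
#' from the chain's initial mean spacing. Endpoints are free; the topology
#' is never changed. The objective is tracked across outer iterations and
#' the best iterate is returned; if a later iterate is worse (line-search
#' failure on a rough image) refinement stops with a warning.
#'
#' @param model A traced [tissue_model()].
#' @param vol The `phantom_volume` the model was traced from.
#' @param iterations Outer iterations (each runs a bounded CG cycle).
#' @param lambda_smooth,lambda_length Regularisation weights (intensity is
#'   normalised to `[0, 1]`, lengths in micrometres).
#' @param refine_radii Re-estimate node radii at the refined positions.
#' @return The refined model, with an `objective_trace` attribute (numeric
#'   vector, non-increasing except where refinement stopped early).
#' @export
refine_model <- function(model, vol, iterations = 10, lambda_smooth = 1,
                         lambda_length = 0.2, refine_radii = TRUE) {
  stopifnot(inherits(model, "tissue_model"), inherits(vol, "phantom_volume"))
  rng <- range(vol$data)
  nvol <- list(data = (vol$data - rng[1]) / max(diff(rng), 1e-12),
               origin = vol$origin, voxel_size = vol$voxel_size)
  nd <- model$nodes
  trace_all <- numeric(0)
  bg <- median(vol$data)
  for (cid in unique(nd$constituent_id)) {
    rows <- which(nd$constituent_id == cid)
    sub <- nd[rows, ]
    if (nrow(sub) < 3) next
    sub <- order_tree_rows(sub)
    if (any(duplicated(sub$parent_id, incomparables = NA))) next  # branched: refine per chain only
    P <- node_matrix(sub)
    n <- nrow(P)
    h_target <- polyline_length(P) / (n - 1)
    obj <- function(theta) {
      Q <- matrix(theta, n, 3)
      iv <- interp3(nvol, Q)
      sd2 <- Q[1:(n - 2), , drop = FALSE] - 2 * Q[2:(n - 1), , drop = FALSE] +
        Q[3:n, , drop = FALSE]
      dif <- Q[-1, , drop = FALSE] - Q[-n, , drop = FALSE]
      hl <- sqrt(rowSums(dif^2))
      -mean(iv) + lambda_smooth * sum(rowSums(sd2^2)) +
        lambda_length * sum((hl - h_target)^2)
    }
    grr <- function(theta) {
      Q <- matrix(theta, n, 3)
      eps <- nvol$voxel_size / 2
      G <- matrix(0, n, 3)
      for (k in 1:3) {
        Qp <- Q; Qp[, k] <- Qp[, k] + eps
        Qm <- Q; Qm[, k] <- Qm[, k] - eps
        G[, k] <- -(interp3(nvol, Qp) - interp3(nvol, Qm)) / (2 * eps * n)
      }
      # smoothness term gradient
      sd2 <- Q[1:(n - 2), , drop = FALSE] - 2 * Q[2:(n - 1), , drop = FALSE] +
        Q[3:n, , drop = FALSE]
      Gs <- matrix(0, n, 3)
      Gs[1:(n - 2), ] <- Gs[1:(n - 2), ] + 2 * sd2
      Gs[2:(n - 1), ] <- Gs[2:(n - 1), ] - 4 * sd2
      Gs[3:n, ] <- Gs[3:n, ] + 2 * sd2
      # spacing term gradient
      dif <- Q[-1, , drop = FALSE] - Q[-n, , drop = FALSE]
      hl <- pmax(sqrt(rowSums(dif^2)), 1e-12)
      coef <- 2 * (hl - h_target) / hl
      Gl <- matrix(0, n, 3)
      Gl[-n, ] <- Gl[-n, ] - coef * dif
      Gl[-1, ] <- Gl[-1, ] + coef * dif
      as.vector(G + lambda_smooth * Gs + lambda_length * Gl)
    }
    theta <- as.vector(P)
    best <- theta
    best_f <- obj(theta)
    tr <- best_f
    diverged <- FALSE
    for (it in seq_len(iterations)) {
      res <- optim(theta, obj, grr, method = "CG",
                   control = list(maxit = 5))
      if (res$value > best_f + 1e-12) {
        # line-search failure on a rough image: keep the best iterate and
        # stop; the rejected value never enters the objective trace
        warn("refinement objective increased; returning best iterate")
        diverged <- TRUE
        break
      }
      tr <- c(tr, res$value)
      best_f <- res$value
      best <- res$par
      theta <- res$par
      if (res$convergence == 0) break
    }
    Q <- matrix(best, n, 3)
    nd$x[rows[match(sub$node_id, nd$node_id[rows])]] <- Q[, 1]
    nd$y[rows[match(sub$node_id, nd$node_id[rows])]] <- Q[, 2]
    nd$z[rows[match(sub$node_id, nd$node_id[rows])]] <- Q[, 3]
    if (refine_radii) {
      rr <- vapply(seq_len(n), function(i) {
        estimate_radius(vol, Q[i, ], background = bg)
      }, numeric(1))
      nd$r[rows[match(sub$node_id, nd$node_id[rows])]] <- rr
    }
    trace_all <- c(trace_all, tr)
  }
  model$nodes <- nd
  attr(model, "objective_trace") <- trace_all
  model
}
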