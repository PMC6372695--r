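#' Attach synthetic dendritic spines to neurite constituents
#'
#' Spine counts follow a Poisson law with the given linear density, and
#' attachment positions are uniform in arc length, the simplest stationary
#' model consistent with a spines-per-length density. Two morphologies are
#' mixed: stubby spines are short with node radius roughly proportional to
#' length (a wedge in the length / minimum-radius plane), and mushroom
#' spines are longer with a thin neck that thins as the spine lengthens and
#' a wider head (a triangle domain). Constituent types are re-annotated
#' afterwards, so a neurite that received at least one spine becomes a
#' `spiny_dendrite`.
#'
#' @param model A [tissue_model()].
#' @param density Spines per micrometre of neurite (>= 0).
#' @param stubby_frac Fraction of stubby spines in the mix.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param constituent_ids Neurite constituents to decorate; default all
#'   spiny/smooth neurites.
#' @return The decorated model, with a `spine_truth` attribute: a tibble of
#'   the generated class, length, neck radius and head radius per spine.
#' @export
attach_spines <- function(model, density, stubby_frac = 0.5, seed = NULL,
                          constituent_ids = NULL) {
  stopifnot(inherits(model, "tissue_model"), density >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, attach_spines(
      model, density, stubby_frac, seed = NULL,
      constituent_ids = constituent_ids)))
  }
  nd <- model$nodes
  if (is.null(constituent_ids)) {
    constituent_ids <- unique(nd$constituent_id[
      nd$ctype %in% c("spiny_dendrite", "smooth_neurite")])
  }
  next_cid <- max(nd$constituent_id, 0L)
  truth <- list()
  new_nodes <- list()
  new_att <- list()
  for (cid in constituent_ids) {
    sub <- order_tree_rows(nd[nd$constituent_id == cid, ])
    pts <- node_matrix(sub)
    if (nrow(pts) < 2) next
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seglen))
    total <- s[length(s)]
    n_sp <- rpois(1, density * total)
    if (n_sp == 0) next
    at_s <- runif(n_sp, 0, total)
    for (k in seq_len(n_sp)) {
      # nearest node to the uniform arc-length draw carries the attachment
      i_at <- which.min(abs(s - at_s[k]))
      base <- pts[i_at, ]
      # outward direction roughly perpendicular to the local chain
      i2 <- min(i_at + 1, nrow(pts))
      i1 <- max(i_at - 1, 1)
      tang <- pts[i2, ] - pts[i1, ]
      tang <- tang / sqrt(sum(tang^2))
      v <- rnorm(3)
      out_dir <- v - sum(v * tang) * tang
      out_dir <- out_dir / sqrt(sum(out_dir^2))
      stubby <- runif(1) < stubby_frac
      if (stubby) {
        len <- runif(1, 0.3, 1.0)
        neck_r <- pmax(0.06, 0.35 * len + rnorm(1, 0, 0.02))
        head_r <- neck_r
      } else {
        len <- runif(1, 1.0, 3.0)
        neck_r <- pmax(0.05, pmin(0.3, 0.28 / len + rnorm(1, 0, 0.01)))
        head_r <- runif(1, 0.2, 0.35)
      }
      next_cid <- next_cid + 1L
      n_nodes <- 4L
      frac <- seq(0, 1, length.out = n_nodes)
      radii <- if (stubby) rep(neck_r, n_nodes) else
        c(neck_r, neck_r, head_r, head_r)
      start_r <- sub$r[i_at]
      pos <- sweep(outer(start_r * 0.5 + frac * len, out_dir), 2, base, "+")
      new_nodes[[length(new_nodes) + 1]] <- tibble(
        constituent_id = next_cid, ctype = "spine",
        node_id = seq_len(n_nodes),
        parent_id = c(NA_integer_, seq_len(n_nodes - 1L)),
        x = pos[, 1], y = pos[, 2], z = pos[, 3], r = radii)
      new_att[[length(new_att) + 1]] <- tibble(
        constituent_id = next_cid, parent_constituent_id = as.integer(cid),
        parent_node_id = sub$node_id[i_at])
      truth[[length(truth) + 1]] <- tibble(
        constituent_id = next_cid,
        class = if (stubby) "stubby" else "mushroom",
        length = len, neck_radius = neck_r, head_radius = head_r)
    }
  }
  if (length(new_nodes) > 0) {
    model$nodes <- bind_rows(model$nodes, bind_rows(new_nodes))
    model$attachments <- bind_rows(model$attachments, bind_rows(new_att))
    model <- annotate_constituents(model)
  }
  attr(model, "spine_truth") <- if (length(truth)) bind_rows(truth) else
    tibble(constituent_id = integer(), class = character(),
           length = double(), neck_radius = double(), head_radius = double())
  model
}

#' Specify a synthetic case cohort
#'
#' One row per case: the number of neurite segments, the mean and SD of the
#' per-segment target curvature (a normal draw truncated below at
#' `curvature_floor`), the orphan fraction, and log-normal segment length
#' and fibre radius distributions. The default spec mirrors the published
#' case-level structure of the schizophrenia / control comparison: four
#' cases per group, per-case curvature means of 0.46/0.47/0.60/0.71 against
#' 0.33/0.44/0.37/0.41 micrometres^-1 with matching SDs, roughly 500
#' segments per case, and an orphan fraction near 0.55.
#'
#' @param cases A data frame with columns `case_id`, `group`, `n_segments`,
#'   `curvature_mean`, `curvature_sd`, `orphan_fraction`; `NULL` for the
#'   default 4 + 4 cohort.
#' @param segment_length_meanlog,segment_length_sdlog Log-normal segment
#'   arc-length parameters (micrometres; default median ~ 18 um).
#' @param radius_meanlog,radius_sdlog Log-normal fibre radius parameters
#'   (micrometres; default median ~ 0.4 um).
#' @param step_length Generator step, micrometres.
#' @param start_halfwidth Segment start positions are drawn uniformly in a
#'   cube of this half-width (micrometres) around the origin.
#' @param curvature_floor Lower truncation of per-segment target curvature.
#' @param chirality_bias Passed to [tortuosity_params()]; 0 = achiral.
#' @param seed Integer seed for the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(cases = NULL,
                        segment_length_meanlog = log(18),
                        segment_length_sdlog = 0.45,
                        radius_meanlog = log(0.4), radius_sdlog = 0.5,
                        step_length = 0.5, curvature_floor = 0.05,
                        start_halfwidth = 40, chirality_bias = 0,
                        seed = 1L) {
  if (is.null(cases)) {
    cases <- tibble(
      case_id = c("S1", "S2", "S3", "S4", "N1", "N2", "N3", "N4"),
      group = rep(c("schizophrenia", "control"), each = 4),
      n_segments = 500L,
      curvature_mean = c(0.46, 0.47, 0.60, 0.71, 0.33, 0.44, 0.37, 0.41),
      curvature_sd = c(0.28, 0.32, 0.34, 0.36, 0.22, 0.21, 0.21, 0.23),
      orphan_fraction = 0.55)
  }
  cases <- as_tibble(cases)
  stopifnot(all(cases$curvature_sd > 0), all(cases$n_segments >= 1))
  structure(list(cases = cases,
                 segment_length_meanlog = segment_length_meanlog,
                 segment_length_sdlog = segment_length_sdlog,
                 radius_meanlog = radius_meanlog,
                 radius_sdlog = radius_sdlog,
                 step_length = step_length,
                 curvature_floor = curvature_floor,
                 start_halfwidth = start_halfwidth,
                 chirality_bias = chirality_bias,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of tissue models
#'
#' One [tissue_model()] per case. Each neurite segment is generated as a
#' correlated random walk whose turning-angle spread is calibrated to a
#' per-segment target curvature drawn from the case's distribution;
#' non-orphan segments are attached to a per-case soma constituent, orphans
#' are free-floating (their somata are notionally outside the field).
#' A ground-truth table of the drawn targets accompanies the models for
#' parameter-recovery tests: the pipeline's per-case mean curvature should
#' agree with the mean of the drawn targets up to sampling error.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `models` (named list of tissue models) and `truth`
#'   (tibble: `case_id`, `group`, `constituent_id`, `target_curvature`,
#'   `is_orphan`, `length`, `radius`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    models <- list()
    truth <- list()
    for (ci in seq_len(nrow(spec$cases))) {
      cs <- spec$cases[ci, ]
      n <- cs$n_segments
      targets <- rnorm(n, cs$curvature_mean, cs$curvature_sd)
      # truncated below at the floor and above at what the correlated walk
      # can realise at this step length (E[2|sin(theta/2)|] < 4/pi)
      targets <- pmin(pmax(targets, spec$curvature_floor),
                      1.2 / spec$step_length)
      lens <- pmax(4 * spec$step_length,
                   stats::rlnorm(n, spec$segment_length_meanlog,
                                 spec$segment_length_sdlog))
      radii <- stats::rlnorm(n, spec$radius_meanlog, spec$radius_sdlog)
      orphan <- runif(n) < cs$orphan_fraction
      nodes <- vector("list", n + 1)
      atts <- list()
      # per-case soma the non-orphan neurites hang from; omitted when every
      # segment is an orphan (keeps all-orphan models compact and free of a
      # structure nothing references)
      soma_id <- 1L
      has_soma <- any(!orphan)
      soma_clear <- 8  # soma extent + margin: neurites start outside it
      if (has_soma) {
        nodes[[1]] <- tibble(constituent_id = soma_id, ctype = "soma",
                             node_id = 1:2, parent_id = c(NA_integer_, 1L),
                             x = c(0, 3), y = 0, z = 0, r = c(6, 5))
      }
      draw_start <- function() {
        for (i in 1:100) {
          p <- runif(3, -spec$start_halfwidth, spec$start_halfwidth)
          if (!has_soma || sqrt(sum(p^2)) > soma_clear) return(p)
        }
        p
      }
      for (k in seq_len(n)) {
        pts <- make_tortuous_neurite(
          tortuosity_params(step_length = spec$step_length,
                            target_mean_curvature = targets[k],
                            chirality_bias = spec$chirality_bias),
          length = lens[k],
          start = draw_start())
        cid <- soma_id + k
        nodes[[k + 1]] <- tibble(
          constituent_id = cid, ctype = "smooth_neurite",
          node_id = seq_len(nrow(pts)),
          parent_id = c(NA_integer_, seq_len(nrow(pts) - 1L)),
          x = pts[, 1], y = pts[, 2], z = pts[, 3], r = radii[k])
        if (!orphan[k]) {
          atts[[length(atts) + 1]] <- tibble(
            constituent_id = cid, parent_constituent_id = soma_id,
            parent_node_id = 1L)
        }
      }
      models[[cs$case_id]] <- tissue_model(
        bind_rows(nodes),
        attachments = if (length(atts)) bind_rows(atts),
        case_id = cs$case_id, dataset_id = paste0(cs$case_id, "A"))
      truth[[ci]] <- tibble(
        case_id = cs$case_id, group = cs$group,
        constituent_id = soma_id + seq_len(n),
        target_curvature = targets, is_orphan = orphan,
        length = lens, radius = radii)
    }
    list(models = models, truth = bind_rows(truth),
         cases = spec$cases)
  })
}
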