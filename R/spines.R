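#' Morphometry of dendritic spines
#'
#' For each spine constituent: length measured along the node chain from the
#' base (attachment end) to the tip, minimum and maximum node radius, their
#' ratio (neck-to-head contrast; a large ratio marks a necked mushroom
#' spine), and mean curvature and signed torsion of the chain where the node
#' count allows. Length is a curve parameter, not the Euclidean base-to-tip
#' distance. A zero minimum radius makes the ratio undefined (`NA`, flagged).
#'
#' @param model A [tissue_model()] with spine constituents.
#' @param spacing Resampling spacing for the curvature/torsion estimators;
#'   spines are short, so the default is finer than for neurite segments.
#' @return A tibble, one row per spine: `constituent_id`,
#'   `attached_to`, `case_id`, `dataset_id`, `length`, `min_radius`,
#'   `max_radius`, `radius_ratio`, `ratio_defined`, `curvature`, `torsion`.
#' @export
spine_metrics <- function(model, spacing = 0.2) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  spine_cids <- unique(nd$constituent_id[nd$ctype == "spine"])
  if (length(spine_cids) == 0) {
    return(tibble(constituent_id = integer(), attached_to = integer(),
                  case_id = character(), dataset_id = character(),
                  length = double(), min_radius = double(),
                  max_radius = double(), radius_ratio = double(),
                  ratio_defined = logical(), curvature = double(),
                  torsion = double()))
  }
  att <- model$attachments
  rows <- map(spine_cids, function(cid) {
    sub <- order_tree_rows(nd[nd$constituent_id == cid, ])
    if (nrow(sub) < 2) {
      abort(paste0("spine constituent ", cid, " has fewer than 2 nodes"))
    }
    chain <- longest_root_path(sub)
    pts <- node_matrix(chain)
    geo <- chain_geometry(chain, spacing = spacing)
    mn <- min(sub$r); mx <- max(sub$r)
    a <- att$parent_constituent_id[att$constituent_id == cid]
    tibble(
      constituent_id = as.integer(cid),
      attached_to = if (length(a)) a[1] else NA_integer_,
      case_id = model$case_id, dataset_id = model$dataset_id,
      length = polyline_length(pts),
      min_radius = mn, max_radius = mx,
      radius_ratio = if (mn > 0) mx / mn else NA_real_,
      ratio_defined = mn > 0,
      curvature = geo$mean_curvature, torsion = geo$mean_torsion)
  })
  bind_rows(rows)
}

# deepest root-to-leaf node path of an (ordered) constituent tree
longest_root_path <- function(sub) {
  n <- nrow(sub)
  pos <- setNames(seq_len(n), sub$node_id)
  depth <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(sub$parent_id[i])) {
      j <- pos[[as.character(sub$parent_id[i])]]
      step <- sqrt((sub$x[i] - sub$x[j])^2 + (sub$y[i] - sub$y[j])^2 +
                     (sub$z[i] - sub$z[j])^2)
      depth[i] <- depth[j] + step
    }
  }
  tip <- which.max(depth)
  path <- tip
  while (!is.na(sub$parent_id[path[1]])) {
    path <- c(pos[[as.character(sub$parent_id[path[1]])]], path)
  }
  sub[path, ]
}

#' Spine density of a model
#'
#' The number of spines per unit total arc length of spiny dendrites
#' (spines per micrometre).
#'
#' @param model A [tissue_model()] with annotated spines.
#' @return A single numeric density, micrometres^-1.
#' @export
spine_density <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  n_spines <- length(unique(nd$constituent_id[nd$ctype == "spine"]))
  segs <- split_segments(model)
  spiny <- segs[segs$ctype == "spiny_dendrite", ]
  total_len <- sum(map_dbl(spiny$nodes, ~ polyline_length(node_matrix(.x))))
  if (total_len <= 0) {
    if (n_spines > 0) {
      abort("spines present but zero spiny-dendrite length")
    }
    warn("no spines and no spiny dendrite: density reported as 0")
    return(0)
  }
  n_spines / total_len
}
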