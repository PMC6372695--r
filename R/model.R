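#' Constituent types recognised by the tissue model
#'
#' Traced structures are typed as somata, spiny dendrites, smooth neurites
#' (axon-like processes without spines), blood vessels, dendritic spines, or
#' unclassified.
#'
#' @export
CTYPES <- c("soma", "spiny_dendrite", "smooth_neurite", "blood_vessel",
            "spine", "unclassified")

#' Construct a tissue model
#'
#' A tissue model is the Cartesian coordinate representation of one imaged
#' dataset: every traced constituent (soma, neurite, vessel, spine) is a tree
#' of nodes, each node carrying a 3D position and a local radius, both in
#' micrometres. Spines (and optionally neurites) record the constituent and
#' node they attach to.
#'
#' @param nodes A data frame with columns `constituent_id`, `ctype`,
#'   `node_id`, `parent_id` (`NA` for the root of a constituent), `x`, `y`,
#'   `z`, `r`. Coordinates and radii in micrometres.
#' @param attachments A data frame with columns `constituent_id`,
#'   `parent_constituent_id`, `parent_node_id` recording where a constituent
#'   (a spine, or a neurite rooted on a soma) attaches. May be `NULL`.
#' @param field_of_view A list with elements `center` (length-3 numeric),
#'   `diameter` and `height` (micrometres); the imaged region is a cylinder
#'   about the z axis. `NULL` for unbounded models.
#' @param voxel_size Voxel edge length of the source volume, micrometres.
#' @param case_id,dataset_id Identifier strings.
#'
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(nodes, attachments = NULL, field_of_view = NULL,
                         voxel_size = 0.05, case_id = "", dataset_id = "") {
  nodes <- as_tibble(nodes)
  req <- c("constituent_id", "ctype", "node_id", "parent_id",
           "x", "y", "z", "r")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("nodes is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  nodes <- nodes[req]
  nodes$constituent_id <- as.integer(nodes$constituent_id)
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$ctype <- as.character(nodes$ctype)
  if (is.null(attachments)) {
    attachments <- tibble(constituent_id = integer(),
                          parent_constituent_id = integer(),
                          parent_node_id = integer())
  } else {
    attachments <- as_tibble(attachments)
    attachments$constituent_id <- as.integer(attachments$constituent_id)
    attachments$parent_constituent_id <-
      as.integer(attachments$parent_constituent_id)
    attachments$parent_node_id <- as.integer(attachments$parent_node_id)
  }
  structure(
    list(nodes = nodes, attachments = attachments,
         field_of_view = field_of_view, voxel_size = voxel_size,
         case_id = case_id, dataset_id = dataset_id),
    class = "tissue_model"
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model>", x$case_id,
      if (nzchar(x$dataset_id)) paste0("/", x$dataset_id), "\n")
  cat("  nodes:", nrow(x$nodes),
      " constituents:", length(unique(x$nodes$constituent_id)), "\n")
  tb <- x$nodes %>%
    distinct(.data$constituent_id, .data$ctype) %>%
    count(.data$ctype)
  for (i in seq_len(nrow(tb))) {
    cat("   ", tb$ctype[i], ":", tb$n[i], "\n")
  }
  if (!is.null(x$field_of_view)) {
    cat("  field of view: cylinder d =", x$field_of_view$diameter,
        "um, h =", x$field_of_view$height, "um\n")
  }
  invisible(x)
}

#' Validate a tissue model
#'
#' Checks structural invariants: non-negative radii, finite positions,
#' parent links resolving within the same constituent, each constituent a
#' connected acyclic tree with a single root, spines carrying an attachment
#' record, and (when a field of view is declared) all nodes inside the
#' cylindrical field to within one voxel.
#'
#' @param model A [tissue_model()].
#' @return The model, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  if (nrow(nd) == 0) return(invisible(model))
  if (any(!is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z))) {
    abort("non-finite node position")
  }
  if (any(!is.finite(nd$r) | nd$r < 0)) abort("node radius must be >= 0")
  bad_type <- setdiff(unique(nd$ctype), CTYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown ctype: ", paste(bad_type, collapse = ", ")))
  }
  for (cid in unique(nd$constituent_id)) {
    sub <- nd[nd$constituent_id == cid, ]
    if (anyDuplicated(sub$node_id)) {
      abort(paste0("duplicate node id in constituent ", cid))
    }
    roots <- is.na(sub$parent_id)
    if (sum(roots) != 1) {
      abort(paste0("constituent ", cid, " must have exactly one root"))
    }
    dangling <- !is.na(sub$parent_id) & !(sub$parent_id %in% sub$node_id)
    if (any(dangling)) {
      abort(paste0("dangling parent id in constituent ", cid, ": node ",
                   sub$node_id[which(dangling)[1]]))
    }
    # a tree with one root and every non-root holding a resolvable parent is
    # acyclic iff walking parents from every node reaches the root
    idx <- setNames(seq_len(nrow(sub)), sub$node_id)
    for (i in seq_len(nrow(sub))) {
      seen <- 0L
      j <- i
      while (!is.na(sub$parent_id[j])) {
        j <- idx[[as.character(sub$parent_id[j])]]
        seen <- seen + 1L
        if (seen > nrow(sub)) {
          abort(paste0("cycle detected in constituent ", cid))
        }
      }
    }
  }
  spine_ids <- unique(nd$constituent_id[nd$ctype == "spine"])
  unattached <- setdiff(spine_ids, model$attachments$constituent_id)
  if (length(unattached) > 0) {
    abort(paste0("spine constituent(s) without attachment: ",
                 paste(unattached, collapse = ", ")))
  }
  att <- model$attachments
  if (nrow(att) > 0) {
    ok <- att$parent_constituent_id %in% nd$constituent_id
    if (any(!ok)) abort("attachment references unknown parent constituent")
  }
  fov <- model$field_of_view
  if (!is.null(fov)) {
    tol <- model$voxel_size
    dx <- nd$x - fov$center[1]
    dy <- nd$y - fov$center[2]
    radial <- sqrt(dx^2 + dy^2)
    axial <- abs(nd$z - fov$center[3])
    if (any(radial > fov$diameter / 2 + tol) ||
        any(axial > fov$height / 2 + tol)) {
      abort("node outside the declared field of view")
    }
  }
  invisible(model)
}

#' Annotate constituent types from spine attachments
#'
#' A neurite is typed `spiny_dendrite` exactly when at least one spine
#' attaches to it, and `smooth_neurite` otherwise. Somata, vessels and
#' spines keep their types.
#'
#' @param model A [tissue_model()].
#' @return The model with `ctype` updated.
#' @export
annotate_constituents <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  spine_cids <- unique(nd$constituent_id[nd$ctype == "spine"])
  spiny <- unique(model$attachments$parent_constituent_id[
    model$attachments$constituent_id %in% spine_cids])
  neurite <- nd$ctype %in% c("spiny_dendrite", "smooth_neurite",
                             "unclassified")
  nd$ctype[neurite] <-
    ifelse(nd$constituent_id[neurite] %in% spiny,
           "spiny_dendrite", "smooth_neurite")
  model$nodes <- nd
  model
}

#' Arc length of an ordered chain of points
#'
#' @param pts Numeric matrix with 3 columns (x, y, z), one row per point.
#' @return Total polyline length (micrometres for model coordinates).
#' @export
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

node_matrix <- function(nodes) {
  cbind(x = nodes$x, y = nodes$y, z = nodes$z)
}
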