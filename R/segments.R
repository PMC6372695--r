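#' Split neurite trees into unbranched segments
#'
#' Neurites are divided into segments at each ramification point: a segment
#' is a maximal node chain whose interior nodes have exactly two neighbours.
#' Branch-point nodes are duplicated as endpoints of every incident segment,
#' so each segment has a geometric endpoint and curvature is defined right up
#' to the branch. Somata, vessels and spines are skipped.
#'
#' @param model A [tissue_model()].
#' @return A tibble with one row per segment: `segment_id`,
#'   `constituent_id`, `ctype`, `case_id`, `dataset_id`, `n_nodes`,
#'   `is_orphan` (`NA` until [flag_orphans()]), and a `nodes` list-column of
#'   per-node tibbles (`node_id`, `x`, `y`, `z`, `r`) in chain order.
#' @export
split_segments <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  neurite_cids <- unique(nd$constituent_id[
    nd$ctype %in% c("spiny_dendrite", "smooth_neurite")])
  segs <- list()
  for (cid in neurite_cids) {
    sub <- nd[nd$constituent_id == cid, ]
    n <- nrow(sub)
    if (n < 2) next
    pos <- setNames(seq_len(n), sub$node_id)
    # undirected adjacency from parent links
    adj <- vector("list", n)
    for (i in seq_len(n)) {
      if (!is.na(sub$parent_id[i])) {
        j <- pos[[as.character(sub$parent_id[i])]]
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
    deg <- lengths(adj)
    # walk from every non-interior node (terminal or ramification point)
    edge_seen <- new.env(parent = emptyenv())
    ekey <- function(a, b) paste0(min(a, b), "-", max(a, b))
    starts <- which(deg != 2)
    if (length(starts) == 0) starts <- 1L  # pure 2-regular cannot occur in a tree
    for (s in starts) {
      for (nb in adj[[s]]) {
        if (exists(ekey(s, nb), envir = edge_seen)) next
        chain <- c(s, nb)
        assign(ekey(s, nb), TRUE, envir = edge_seen)
        while (deg[tail(chain, 1)] == 2) {
          cur <- tail(chain, 1)
          nxt <- setdiff(adj[[cur]], chain[length(chain) - 1])
          assign(ekey(cur, nxt), TRUE, envir = edge_seen)
          chain <- c(chain, nxt)
        }
        segs[[length(segs) + 1]] <- list(
          constituent_id = cid, ctype = sub$ctype[1],
          nodes = sub[chain, c("node_id", "x", "y", "z", "r")])
      }
    }
  }
  if (length(segs) == 0) {
    return(tibble(segment_id = integer(), constituent_id = integer(),
                  ctype = character(), case_id = character(),
                  dataset_id = character(), n_nodes = integer(),
                  is_orphan = logical(), nodes = list()))
  }
  tibble(
    segment_id = seq_along(segs),
    constituent_id = map_int(segs, ~ as.integer(.x$constituent_id)),
    ctype = map_chr(segs, "ctype"),
    case_id = model$case_id,
    dataset_id = model$dataset_id,
    n_nodes = map_int(segs, ~ nrow(.x$nodes)),
    is_orphan = NA,
    nodes = map(segs, "nodes"))
}

#' Flag orphan neurite segments
#'
#' A segment is an orphan when its constituent is not connected, through the
#' model's attachment graph, to any constituent containing a soma node.
#' Orphan neurites are distal parts of arbors whose somata lie outside the
#' imaged field of view.
#'
#' @param model The [tissue_model()] the segments came from.
#' @param segments Output of [split_segments()].
#' @return `segments` with `is_orphan` filled in.
#' @export
flag_orphans <- function(model, segments) {
  stopifnot(inherits(model, "tissue_model"))
  nd <- model$nodes
  soma_cids <- unique(nd$constituent_id[nd$ctype == "soma"])
  # undirected connectivity over constituents via attachments
  att <- model$attachments
  cids <- unique(nd$constituent_id)
  comp <- setNames(seq_along(cids), cids)  # union-find by label propagation
  if (nrow(att) > 0) {
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in seq_len(nrow(att))) {
        a <- as.character(att$constituent_id[i])
        b <- as.character(att$parent_constituent_id[i])
        if (comp[[a]] != comp[[b]]) {
          lo <- min(comp[[a]], comp[[b]])
          comp[comp == comp[[a]] | comp == comp[[b]]] <- lo
          changed <- TRUE
        }
      }
    }
  }
  soma_comps <- unique(comp[as.character(soma_cids)])
  segments$is_orphan <-
    !(comp[as.character(segments$constituent_id)] %in% soma_comps)
  segments
}
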