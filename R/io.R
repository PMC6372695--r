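# SWC type-code map. Standard codes 1-4 plus two custom codes: SWC has no
# vessel or spine code, so 7 = blood vessel and 8 = spine keep files loadable
# by generic SWC tools while preserving the typing.
SWC_TYPE_TO_CTYPE <- c("0" = "unclassified", "1" = "soma",
                       "2" = "smooth_neurite", "3" = "spiny_dendrite",
                       "4" = "spiny_dendrite", "7" = "blood_vessel",
                       "8" = "spine")
CTYPE_TO_SWC_TYPE <- c(unclassified = 0L, soma = 1L, smooth_neurite = 2L,
                       spiny_dendrite = 3L, blood_vessel = 7L, spine = 8L)

#' Read a tissue model from file
#'
#' Two formats are supported. `"swc"` is the standard 7-column neuron
#' morphology interchange format (`id type x y z radius parent`, `#`
#' comments); connected subtrees whose SWC type differs from their parent's
#' become separate constituents attached at the parent node, which is how
#' spines riding on a dendrite and dendrites rooted on a soma are recovered.
#' `"native"` is the package's lossless tab-separated node-graph format (one
#' row per node: constituent id, ctype, node id, parent id, x, y, z, r) with
#' metadata in `#!` header lines and constituent attachments in a
#' `<path>.attachments.tsv` sidecar. All lengths are micrometres.
#'
#' @param path File to read.
#' @param format `"swc"` or `"native"`.
#' @return A validated [tissue_model()].
#' @export
read_model <- function(path, format = c("swc", "native")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "swc") read_model_swc(path) else read_model_native(path)
}

read_model_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  recs <- lines[keep]
  n <- length(recs)
  if (n == 0) {
    return(tissue_model(tibble(constituent_id = integer(), ctype = character(),
                               node_id = integer(), parent_id = integer(),
                               x = double(), y = double(), z = double(),
                               r = double())))
  }
  fields <- strsplit(trimws(recs), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad) > 0) {
    abort(paste0("malformed SWC record at line ", lineno[bad[1]],
                 ": expected 7 fields, got ", lengths(fields)[bad[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  nonnum <- which(apply(m, 1, function(row) any(is.na(row))))
  if (length(nonnum) > 0) {
    abort(paste0("malformed SWC record at line ", lineno[nonnum[1]],
                 ": non-numeric field"))
  }
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  parent <- as.integer(m[, 7])
  # SWC requires parents to be defined before use
  defined <- logical(0)
  pos <- setNames(seq_len(n), id)
  for (i in seq_len(n)) {
    if (parent[i] != -1 && !(as.character(parent[i]) %in% names(defined)) &&
        !(parent[i] %in% id[seq_len(i - 1)])) {
      abort(paste0("structural error at line ", lineno[i], ": parent id ",
                   parent[i], " not defined earlier in file"))
    }
  }
  ctype <- unname(SWC_TYPE_TO_CTYPE[as.character(type)])
  ctype[is.na(ctype)] <- "unclassified"

  # constituent = maximal connected run of one ctype; crossing to a parent of
  # a different ctype starts a new constituent attached at that parent node
  cid <- integer(n)
  att <- list()
  next_cid <- 0L
  for (i in seq_len(n)) {
    if (parent[i] == -1) {
      next_cid <- next_cid + 1L
      cid[i] <- next_cid
    } else {
      pi <- pos[[as.character(parent[i])]]
      if (ctype[pi] == ctype[i]) {
        cid[i] <- cid[pi]
      } else {
        next_cid <- next_cid + 1L
        cid[i] <- next_cid
        att[[length(att) + 1]] <- tibble(
          constituent_id = next_cid,
          parent_constituent_id = cid[pi],
          parent_node_id = id[pi])
      }
    }
  }
  parent_in <- parent
  for (i in seq_len(n)) {
    if (parent[i] != -1 && cid[pos[[as.character(parent[i])]]] != cid[i]) {
      parent_in[i] <- -1L  # root of its own constituent
    }
  }
  nodes <- tibble(constituent_id = cid, ctype = ctype, node_id = id,
                  parent_id = ifelse(parent_in == -1L, NA_integer_,
                                     parent_in),
                  x = m[, 3], y = m[, 4], z = m[, 5], r = m[, 6])
  model <- tissue_model(nodes, attachments = if (length(att)) bind_rows(att))
  validate_model(model)
  model
}

read_model_native <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#!", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#!\\s*", "", ln), "\t")[[1]]
    if (length(kv) >= 2) meta[[kv[1]]] <- kv[-1]
  }
  nodes <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  att_path <- paste0(path, ".attachments.tsv")
  att <- NULL
  if (file.exists(att_path)) {
    att <- readr::read_tsv(att_path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  }
  fov <- NULL
  if (!is.null(meta$fov_center)) {
    fov <- list(center = as.numeric(meta$fov_center),
                diameter = as.numeric(meta$fov_diameter[1]),
                height = as.numeric(meta$fov_height[1]))
  }
  model <- tissue_model(
    nodes, attachments = att, field_of_view = fov,
    voxel_size = if (!is.null(meta$voxel_size))
      as.numeric(meta$voxel_size[1]) else 0.05,
    case_id = if (!is.null(meta$case_id)) meta$case_id[1] else "",
    dataset_id = if (!is.null(meta$dataset_id)) meta$dataset_id[1] else "")
  validate_model(model)
  model
}

#' Write a tissue model to file
#'
#' The native format round-trips a model losslessly (radii and coordinates
#' written at full double precision). SWC output renumbers nodes globally;
#' constituents with an attachment record are emitted as child subtrees of
#' their attachment node (spines as type 8), so generic SWC tools see one
#' connected tree per neuron, and the attachment is recoverable from the
#' parent link plus the type change.
#'
#' @param model A [tissue_model()].
#' @param path Output file.
#' @param format `"swc"` or `"native"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("swc", "native")) {
  format <- arg_match(format)
  stopifnot(inherits(model, "tissue_model"))
  if (format == "swc") write_model_swc(model, path)
  else write_model_native(model, path)
  invisible(path)
}

write_model_swc <- function(model, path) {
  nd <- model$nodes
  out <- c("# SWC export (lengths in micrometres)",
           "# type codes: 1 soma, 2 smooth neurite, 3 spiny dendrite,",
           "#             7 blood vessel (custom), 8 spine (custom)")
  if (nrow(nd) == 0) {
    writeLines(out, path)
    return()
  }
  att <- model$attachments
  # global ids: number nodes consecutively, constituents ordered so that a
  # constituent follows the one it attaches to
  cids <- unique(nd$constituent_id)
  deps <- setNames(rep(NA_integer_, length(cids)), cids)
  if (nrow(att) > 0) {
    deps[as.character(att$constituent_id)] <- att$parent_constituent_id
  }
  ordered <- integer(0)
  remaining <- cids
  while (length(remaining) > 0) {
    ready <- remaining[is.na(deps[as.character(remaining)]) |
                         deps[as.character(remaining)] %in% ordered]
    if (length(ready) == 0) ready <- remaining[1]  # tolerate odd cycles
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  gid <- 0L
  gmap <- new.env(parent = emptyenv())  # "cid.nid" -> global id
  rows <- character(nrow(nd))
  k <- 0L
  for (cid in ordered) {
    sub <- nd[nd$constituent_id == cid, ]
    sub <- order_tree_rows(sub)
    a <- att[att$constituent_id == cid, ]
    for (i in seq_len(nrow(sub))) {
      gid <- gid + 1L
      assign(paste0(cid, ".", sub$node_id[i]), gid, envir = gmap)
      if (is.na(sub$parent_id[i])) {
        gp <- if (nrow(a) == 1) {
          get(paste0(a$parent_constituent_id, ".", a$parent_node_id),
              envir = gmap)
        } else -1L
      } else {
        gp <- get(paste0(cid, ".", sub$parent_id[i]), envir = gmap)
      }
      k <- k + 1L
      rows[k] <- sprintf("%d %d %.17g %.17g %.17g %.17g %d", gid,
                         CTYPE_TO_SWC_TYPE[[sub$ctype[i]]],
                         sub$x[i], sub$y[i], sub$z[i], sub$r[i], gp)
    }
  }
  writeLines(c(out, rows), path)
}

# reorder rows of one constituent so every parent precedes its children
order_tree_rows <- function(sub) {
  n <- nrow(sub)
  pos <- setNames(seq_len(n), sub$node_id)
  done <- logical(n)
  ord <- integer(n)
  k <- 0L
  queue <- which(is.na(sub$parent_id))
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    if (done[i]) next
    done[i] <- TRUE; k <- k + 1L; ord[k] <- i
    kids <- which(!is.na(sub$parent_id) & sub$parent_id == sub$node_id[i])
    queue <- c(queue, kids)
  }
  sub[ord[seq_len(k)], ]
}

write_model_native <- function(model, path) {
  meta <- c(
    paste0("#! case_id\t", model$case_id),
    paste0("#! dataset_id\t", model$dataset_id),
    paste0("#! voxel_size\t", format(model$voxel_size, digits = 17)))
  if (!is.null(model$field_of_view)) {
    fov <- model$field_of_view
    meta <- c(meta,
              paste0("#! fov_center\t",
                     paste(format(fov$center, digits = 17), collapse = "\t")),
              paste0("#! fov_diameter\t", format(fov$diameter, digits = 17)),
              paste0("#! fov_height\t", format(fov$height, digits = 17)))
  }
  nd <- model$nodes
  hdr <- paste(names(nd), collapse = "\t")
  body <- sprintf("%d\t%s\t%d\t%s\t%.17g\t%.17g\t%.17g\t%.17g",
                  nd$constituent_id, nd$ctype, nd$node_id,
                  ifelse(is.na(nd$parent_id), "NA",
                         as.character(nd$parent_id)),
                  nd$x, nd$y, nd$z, nd$r)
  writeLines(c(meta, hdr, body), path)
  att <- model$attachments
  if (nrow(att) > 0) {
    readr::write_tsv(att, paste0(path, ".attachments.tsv"), progress = FALSE)
  }
}
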