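# Skeleton construction, SWC input/output, resampling at uniform arclength
# spacing, and along-arbor (geodesic) distances.

#' Construct a Skeleton
#'
#' @param nodes data.frame with columns `node_id`, `parent_id` (`NA` for the
#'   root), `x`, `y`, `z` in nm, and optionally `radius` (nm) and `label`
#'   (`dendrite`, `axon`, `soma`, `unlabeled`).
#' @param neuronId identifier for the neuron.
#' @return A validated [Skeleton-class].
#' @export
skeleton <- function(nodes, neuronId = "neuron") {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$radius)) nodes$radius <- NA_real_
  if (is.null(nodes$label)) nodes$label <- "unlabeled"
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  new("Skeleton", nodes = nodes[, c("node_id", "parent_id", "x", "y", "z",
                                    "radius", "label")],
      neuronId = as.character(neuronId))
}

setMethod("show", "Skeleton", function(object) {
  nd <- object@nodes
  cat(sprintf("Skeleton '%s': %d nodes, %.1f um cable\n", object@neuronId,
              nrow(nd), cableLength(object) / 1000))
  print(table(nd$label))
})

#' Node coordinates of a skeleton
#' @param skel a [Skeleton-class].
#' @return numeric matrix with columns x, y, z (nm).
#' @export
nodeCoords <- function(skel) {
  as.matrix(skel@nodes[, c("x", "y", "z")])
}

# SWC integer type codes <-> labels (standard 7-column dialect).
.swcTypeToLabel <- function(type) {
  lab <- c("1" = "soma", "2" = "axon", "3" = "dendrite")[as.character(type)]
  lab[is.na(lab)] <- "unlabeled"
  unname(lab)
}
.labelToSwcType <- function(label) {
  t <- c(soma = 1L, axon = 2L, dendrite = 3L)[label]
  t[is.na(t)] <- 0L
  unname(t)
}

#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC: `id type x y z radius parent`, `#` comments,
#' parent -1 for the root. Cycles and dangling parent references are
#' rejected with the offending node ids.
#'
#' @param path file path.
#' @param neuronId neuron identifier; defaults to the file name.
#' @return A [Skeleton-class].
#' @export
readSWC <- function(path, neuronId = NULL) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "type", "x", "y", "z",
                                         "radius", "parent_id"))
  if (is.null(neuronId)) neuronId <- sub("\\.swc$", "", basename(path))
  skeleton(data.frame(node_id = tab$node_id,
                      parent_id = ifelse(tab$parent_id < 0, NA_integer_,
                                         tab$parent_id),
                      x = tab$x, y = tab$y, z = tab$z,
                      radius = tab$radius,
                      label = .swcTypeToLabel(tab$type)),
           neuronId = neuronId)
}

#' Write a skeleton to an SWC file
#' @param skel a [Skeleton-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(skel, path) {
  nd <- skel@nodes
  out <- data.frame(nd$node_id, .labelToSwcType(nd$label),
                    nd$x, nd$y, nd$z,
                    ifelse(is.na(nd$radius), 1, nd$radius),
                    ifelse(is.na(nd$parent_id), -1L, nd$parent_id))
  writeLines(c("# SWC skeleton (nm)",
               apply(out, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Total cable length of a skeleton
#' @param skel a [Skeleton-class].
#' @return length in nm.
#' @export
cableLength <- function(skel) {
  nd <- skel@nodes
  pidx <- match(nd$parent_id, nd$node_id)
  keep <- !is.na(pidx)
  xyz <- nodeCoords(skel)
  sum(sqrt(rowSums((xyz[keep, , drop = FALSE] -
                    xyz[pidx[keep], , drop = FALSE])^2)))
}

# Decompose a skeleton into unbranched paths. Returns a list of integer
# row-index vectors; each path runs from a critical node (root or branch
# point) to the next critical node or leaf, inclusive.
skeletonPaths <- function(skel) {
  nd <- skel@nodes
  pidx <- match(nd$parent_id, nd$node_id)
  nChild <- tabulate(pidx[!is.na(pidx)], nbins = nrow(nd))
  root <- which(is.na(pidx))
  critical <- is.na(pidx) | nChild > 1L
  children <- split(which(!is.na(pidx)), pidx[!is.na(pidx)])
  paths <- list()
  stack <- root
  while (length(stack)) {
    start <- stack[1]; stack <- stack[-1]
    for (ch in children[[as.character(start)]]) {
      path <- c(start, ch)
      while (nChild[path[length(path)]] == 1L && !critical[path[length(path)]]) {
        path <- c(path, children[[as.character(path[length(path)])]])
      }
      paths[[length(paths) + 1L]] <- path
      if (nChild[path[length(path)]] >= 1L) stack <- c(stack, path[length(path)])
    }
  }
  paths
}

#' Resample a skeleton at uniform arclength spacing
#'
#' Nodes are placed along each unbranched path at approximately uniform
#' arclength intervals of `spacing` nm; the root, branch points and leaves
#' are preserved exactly, as is the tree topology. After resampling, node
#' density is proportional to cable density, so node-based centroids and
#' medians are arclength-weighted.
#'
#' @param skel a [Skeleton-class].
#' @param spacing target node spacing in nm (default 400).
#' @return A resampled [Skeleton-class] (new node ids).
#' @export
resampleSkeleton <- function(skel, spacing = 400) {
  if (spacing <= 0) stop("spacing must be positive")
  nd <- skel@nodes
  xyz <- nodeCoords(skel)
  paths <- skeletonPaths(skel)
  rootRow <- which(is.na(match(nd$parent_id, nd$node_id)))
  # map: original critical row -> new node id
  newId <- 0L
  critId <- integer(nrow(nd))
  rows <- list()
  addRow <- function(x, y, z, radius, label, parent) {
    newId <<- newId + 1L
    rows[[newId]] <<- data.frame(node_id = newId, parent_id = parent,
                                 x = x, y = y, z = z, radius = radius,
                                 label = label)
    newId
  }
  critId[rootRow] <- addRow(nd$x[rootRow], nd$y[rootRow], nd$z[rootRow],
                            nd$radius[rootRow], nd$label[rootRow],
                            NA_integer_)
  for (path in paths) {
    seg <- xyz[path, , drop = FALSE]
    dl <- sqrt(rowSums(diff(seg)^2))
    cum <- c(0, cumsum(dl))
    L <- cum[length(cum)]
    nSeg <- max(1L, round(L / spacing))
    sNew <- seq(0, L, length.out = nSeg + 1L)
    prev <- critId[path[1]]
    if (prev == 0L) stop("internal error: path start not yet emitted")
    for (s in sNew[-1]) {
      # locate s on the original polyline
      j <- max(which(cum <= s + 1e-9))
      j <- min(j, length(cum) - 1L)
      t <- if (dl[j] > 0) (s - cum[j]) / dl[j] else 0
      p <- seg[j, ] * (1 - t) + seg[j + 1L, ] * t
      srcRow <- path[if (t < 0.5) j else j + 1L]
      prev <- addRow(p[1], p[2], p[3], nd$radius[srcRow], nd$label[srcRow],
                     prev)
    }
    # the last emitted node realizes the path's terminal critical node
    tail <- path[length(path)]
    critId[tail] <- prev
  }
  skeleton(do.call(rbind, rows), neuronId = skel@neuronId)
}

#' Along-arbor distances from one node to all nodes
#'
#' Geodesic (along-skeleton) distance over the undirected tree, with edge
#' weights equal to Euclidean segment lengths.
#'
#' @param skel a [Skeleton-class].
#' @param fromRow row index of the start node in `skel@nodes`.
#' @return numeric vector of distances (nm), one per node row.
#' @export
geodesicDistances <- function(skel, fromRow) {
  nd <- skel@nodes
  n <- nrow(nd)
  xyz <- nodeCoords(skel)
  pidx <- match(nd$parent_id, nd$node_id)
  edgeLen <- sqrt(rowSums((xyz - xyz[ifelse(is.na(pidx), 1L, pidx), ])^2))
  adj <- vector("list", n)
  for (i in which(!is.na(pidx))) {
    p <- pidx[i]
    adj[[i]] <- rbind(adj[[i]], c(p, edgeLen[i]))
    adj[[p]] <- rbind(adj[[p]], c(i, edgeLen[i]))
  }
  d <- rep(NA_real_, n)
  d[fromRow] <- 0
  frontier <- fromRow
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (is.na(d[u])) { d[u] <- d[v] + nb[r, 2]; nxt <- c(nxt, u) }
      }
    }
    frontier <- nxt
  }
  d
}
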