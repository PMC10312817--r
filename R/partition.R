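## Fiber partitioning: minimal balanced coloring, input trees, quotient graphs.
##
## A coloring is "balanced" (equitable) when every node of a cell receives the
## same total input, per source cell and channel, as every other node of that
## cell. The coarsest such coloring is the fiber partition: its cells are
## exactly the classes of nodes with isomorphic input trees, and they are the
## groups guaranteed to synchronize under admissible dynamics.

#' Minimal (coarsest) balanced coloring of a network
#'
#' Iterative refinement from the all-one-cell coloring: nodes are repeatedly
#' split by their input profile (total incoming weight per current source
#' cell, kept separate per channel) until a fixed point. The fixed point is
#' the unique coarsest balanced coloring, independent of refinement order.
#'
#' @param net a `locomotion_network`
#' @param channel `"chem"`, `"gap"` or `"both"` (both channels, kept distinct
#'   in the input profile)
#' @param weighted use edge weights (`TRUE`) or edge counts (`FALSE`)
#' @return a `coloring` object: integer vector of dense cell ids (1..k) named
#'   by node, with attributes `cells` (list of node-name vectors, ordered by
#'   (size, lexicographically smallest member)), `channel` and `weighted`
#' @export
minimal_balanced_coloring <- function(net, channel = c("both", "chem", "gap"),
                                      weighted = TRUE) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  n <- length(nm)
  if (n == 0L) stop("empty network")
  mats <- channel_matrices(net, channel, weighted)
  col <- rep(1L, n)
  repeat {
    sig <- input_signatures(mats, col)
    new_col <- as.integer(factor(paste(col, sig, sep = "|")))
    if (length(unique(new_col)) == length(unique(col))) break
    col <- new_col
  }
  new_coloring(col, nm, channel, weighted)
}

channel_matrices <- function(net, channel, weighted) {
  chs <- if (channel == "both") c("chem", "gap") else channel
  lapply(stats::setNames(chs, chs), function(ch)
    adjacency_matrix(net, ch, binary = !weighted))
}

## per-node signature string: sorted (channel, source cell, total weight)
input_signatures <- function(mats, col) {
  n <- length(col)
  parts <- lapply(names(mats), function(ch) {
    A <- mats[[ch]]
    ## S[c, i] = total input into i from cell c
    S <- rowsum(A, group = col)
    apply(S, 2, function(x) {
      nz <- which(x != 0)
      if (!length(nz)) return("")
      paste(ch, rownames(S)[nz], format(x[nz], digits = 15), collapse = ";")
    })
  })
  do.call(paste, c(parts, sep = "||"))
}

new_coloring <- function(col, nm, channel, weighted) {
  ## canonical cell ids: order cells by (size, lexicographically smallest member)
  cells <- split(nm, col)
  ord <- order(lengths(cells), vapply(cells, min, character(1)))
  cells <- cells[ord]
  names(cells) <- NULL
  ids <- integer(length(nm))
  for (k in seq_along(cells)) ids[match(cells[[k]], nm)] <- k
  structure(stats::setNames(ids, nm), cells = cells,
            channel = channel, weighted = weighted, class = "coloring")
}

#' Construct a coloring from an explicit cell list
#' @param cells list of character vectors partitioning the node set
#' @param net the network the coloring refers to
#' @param channel,weighted bookkeeping tags (what the coloring was computed on)
#' @return a `coloring`
#' @export
as_coloring <- function(cells, net, channel = "both", weighted = TRUE) {
  nm <- network_nodes(net)
  flat <- unlist(cells, use.names = FALSE)
  if (!setequal(flat, nm) || length(flat) != length(nm)) {
    stop("cells must partition the node set")
  }
  col <- integer(length(nm))
  for (k in seq_along(cells)) col[match(cells[[k]], nm)] <- k
  new_coloring(col, nm, channel, weighted)
}

#' @export
print.coloring <- function(x, ...) {
  cells <- coloring_cells(x)
  cat(sprintf("coloring: %d cells over %d nodes (%s, %s)\n",
              length(cells), length(x), attr(x, "channel"),
              if (attr(x, "weighted")) "weighted" else "binary"))
  for (k in seq_along(cells)) {
    cat(sprintf("  [%d] %s\n", k, paste(cells[[k]], collapse = " ")))
  }
  invisible(x)
}

#' Cells of a coloring
#' @param coloring a `coloring`
#' @return list of character vectors
#' @export
coloring_cells <- function(coloring) attr(coloring, "cells")

#' Number of cells
#' @param coloring a `coloring`
#' @return integer
#' @export
n_cells <- function(coloring) length(coloring_cells(coloring))

#' Is a coloring balanced (equitable)?
#'
#' True iff, for every pair of cells (Ci, Cj), every node of Ci receives the
#' same total (weighted) input from Cj — checked per channel.
#'
#' @param net a `locomotion_network`
#' @param coloring a `coloring` (or named integer vector) covering all nodes
#' @inheritParams minimal_balanced_coloring
#' @return logical
#' @export
is_balanced <- function(net, coloring, channel = c("both", "chem", "gap"),
                        weighted = TRUE) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  if (!setequal(names(coloring), nm)) stop("coloring does not cover the node set")
  col <- as.integer(coloring[nm])
  mats <- channel_matrices(net, channel, weighted)
  for (A in mats) {
    S <- rowsum(A, group = col)      # cells x nodes input table
    for (cell in unique(col)) {
      block <- S[, col == cell, drop = FALSE]
      if (ncol(block) > 1L &&
          max(abs(block - block[, 1])) > 1e-9 * max(1, max(abs(block)))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Input tree of a node
#'
#' The input tree of `v` collects all walks terminating at `v`: layer 0 is the
#' root, layer i holds one entry per length-i walk (an edge of integer weight
#' w contributes w parallel entries). Entries are stored as per-node walk
#' counts; `a` is the layer-count sequence a_0 = 1, a_{i+1} = sum of weighted
#' in-degrees over layer-i entries.
#'
#' @param net a `locomotion_network`
#' @param node root node name
#' @param depth number of layers below the root (>= 0); default n - 1, which
#'   suffices to distinguish all non-isomorphic input trees
#' @inheritParams minimal_balanced_coloring
#' @return an `input_tree`: list with `root`, `depth`, `a` (numeric vector of
#'   length depth + 1) and `layers` (list of named walk-count vectors)
#' @export
input_tree <- function(net, node, depth = NULL,
                       channel = c("both", "chem", "gap"), weighted = TRUE) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  if (!node %in% nm) stop("unknown node: ", node)
  if (is.null(depth)) depth <- length(nm) - 1L
  if (depth < 0) stop("depth must be >= 0")
  A <- Reduce(`+`, channel_matrices(net, channel, weighted))
  cvec <- stats::setNames(numeric(length(nm)), nm)
  cvec[node] <- 1
  a <- numeric(depth + 1L)
  a[1] <- 1
  layers <- vector("list", depth + 1L)
  layers[[1]] <- cvec[cvec > 0]
  for (i in seq_len(depth)) {
    cvec <- drop(A %*% cvec)        # c_{i+1}[u] = sum_m w(u -> m) c_i[m]
    a[i + 1L] <- sum(cvec)
    layers[[i + 1L]] <- cvec[cvec > 0]
  }
  structure(list(root = node, depth = depth, a = a, layers = layers,
                 net = net, channel = channel, weighted = weighted),
            class = "input_tree")
}

#' @export
print.input_tree <- function(x, ...) {
  cat(sprintf("input_tree of %s, depth %d; a = (%s)\n", x$root, x$depth,
              paste(format(x$a, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Layer-wise rooted-tree isomorphism of two input trees
#'
#' Implemented as iterated in-neighborhood colour refinement on the disjoint
#' union of the two host networks: after d rounds two roots get equal colours
#' iff their depth-d input trees are isomorphic (ignoring node labels, with
#' edge weights respected as multiplicities/labels).
#'
#' @param t1,t2 `input_tree` objects of equal depth
#' @return logical
#' @export
trees_isomorphic <- function(t1, t2) {
  if (t1$depth != t2$depth) stop("input trees have different depths")
  if (t1$channel != t2$channel || t1$weighted != t2$weighted) {
    stop("input trees computed under different channel/weight settings")
  }
  same_net <- identical(t1$net$edges, t2$net$edges) &&
    identical(t1$net$nodes$name, t2$net$nodes$name)
  if (same_net) {
    sig <- refinement_signatures(list(channel_matrices(t1$net, t1$channel, t1$weighted)),
                                 t1$depth)[[1]]
    return(sig[t1$root] == sig[t2$root])
  }
  sigs <- refinement_signatures(list(channel_matrices(t1$net, t1$channel, t1$weighted),
                                     channel_matrices(t2$net, t2$channel, t2$weighted)),
                                t1$depth)
  sigs[[1]][t1$root] == sigs[[2]][t2$root]
}

## d rounds of joint colour refinement over several node-disjoint graphs;
## returns per-graph vectors of final colour ids (comparable across graphs)
refinement_signatures <- function(mat_sets, depth) {
  ncols <- vapply(mat_sets, function(m) ncol(m[[1]]), integer(1))
  offs <- cumsum(c(0L, utils::head(ncols, -1L)))
  col <- rep(1L, sum(ncols))
  for (i in seq_len(depth)) {
    sigs <- unlist(lapply(seq_along(mat_sets), function(g) {
      local_col <- col[offs[g] + seq_len(ncols[g])]
      mats <- mat_sets[[g]]
      vapply(seq_len(ncols[g]), function(v) {
        parts <- lapply(names(mats), function(ch) {
          w <- mats[[ch]][, v]
          nz <- which(w != 0)
          if (!length(nz)) return(character(0))
          ## an edge of weight w stands for w parallel walk entries, so the
          ## tree invariant is the total weight per (channel, child colour)
          tot <- tapply(w[nz], local_col[nz], sum)
          sort(paste(ch, names(tot), format(tot, digits = 15)))
        })
        paste(unlist(parts), collapse = ";")
      }, character(1))
    }), use.names = FALSE)
    col <- as.integer(factor(sigs))
  }
  lapply(seq_along(mat_sets), function(g) {
    stats::setNames(col[offs[g] + seq_len(ncols[g])], colnames(mat_sets[[g]][[1]]))
  })
}

#' Quotient (base) graph of a balanced coloring
#'
#' Collapses every cell onto one representative node. The weight of the base
#' edge from cell Cj to cell Ci is the common total input any node of Ci
#' receives from Cj, so every node's weighted in-neighborhood by colour equals
#' its base node's in-neighborhood (the lifting property). The gap channel of
#' a base may be asymmetric when fibers differ in size; it is kept as directed
#' weights in that case.
#'
#' @param net a `locomotion_network`
#' @param coloring a balanced `coloring`
#' @param cell_names optional character vector naming the base nodes (default
#'   `"C1".."Ck"` in canonical cell order)
#' @return a `locomotion_network` on one node per cell
#' @export
base_graph <- function(net, coloring, cell_names = NULL) {
  channel <- attr(coloring, "channel") %||% "both"
  weighted <- attr(coloring, "weighted") %||% TRUE
  if (!is_balanced(net, coloring, channel, weighted)) {
    stop("coloring is not balanced; no quotient exists")
  }
  cells <- coloring_cells(coloring)
  k <- length(cells)
  if (is.null(cell_names)) cell_names <- sprintf("C%d", seq_len(k))
  nm <- network_nodes(net)
  col <- coloring[nm]
  reps <- vapply(cells, min, character(1))   # lexicographic representative
  edges <- list()
  for (ch in intersect(c("chem", "gap"), unique(net$edges$channel))) {
    A <- adjacency_matrix(net, ch, binary = !weighted)
    S <- rowsum(A, group = col)              # cell x node input totals
    B <- S[, reps, drop = FALSE]             # cell_j -> cell_i weights
    idx <- which(B != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges[[ch]] <- data.frame(source = cell_names[as.integer(rownames(B))[idx[, 1]]],
                                target = cell_names[idx[, 2]],
                                weight = B[idx], channel = ch,
                                stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  ## cell attributes from representatives
  rep_rows <- net$nodes[match(reps, net$nodes$name), ]
  nodes <- data.frame(name = cell_names, role = rep_rows$role,
                      Vs = rep_rows$Vs, pair = NA_character_,
                      stringsAsFactors = FALSE)
  b <- locomotion_network(edges, nodes = nodes, allow_asymmetric_gap = TRUE)
  attr(b, "cell_members") <- stats::setNames(cells, cell_names)
  b
}

#' Does one coloring refine another?
#' @param fine,coarse `coloring` objects over the same node set
#' @return TRUE iff every cell of `fine` lies inside one cell of `coarse`
#' @export
refines <- function(fine, coarse) {
  nm <- names(fine)
  all(vapply(coloring_cells(fine), function(cell) {
    length(unique(coarse[cell])) == 1L
  }, logical(1)))
}
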