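## Circuits, fiber building blocks (FBBs) and fiber numbers |n, l>.
##
## An FBB is the elementary sub-network responsible for the synchronization of
## one fiber: the fiber itself, everything feeding it, the shortest loop
## through it, and (for composite blocks) the shortest paths stitching
## disconnected pieces together. Its input tree is summarized by two fiber
## numbers: |n> — the branching ratio (asymptotic growth of layer counts,
## equal to the spectral radius of the block's adjacency restricted to the
## root's in-component; irrational values mark "Fibonacci" nested-loop
## blocks) — and |l> — the number of edge-distinct trails terminating at the
## collapsed fiber in the multiplicity-free base.

resolve_cell <- function(coloring, fiber_cell) {
  cells <- coloring_cells(coloring)
  if (is.numeric(fiber_cell)) {
    if (fiber_cell < 1 || fiber_cell > length(cells)) stop("unknown cell id ", fiber_cell)
    return(as.integer(fiber_cell))
  }
  hit <- which(vapply(cells, function(c) fiber_cell[1] %in% c, logical(1)))
  if (!length(hit)) stop("unknown cell or node: ", fiber_cell[1])
  hit
}

#' Circuit of a fiber
#'
#' The base graph restricted to the cells that appear in the fiber's input
#' tree, i.e. the cells from which the fiber is reachable (including itself),
#' with their interconnecting base edges.
#'
#' @param net a `locomotion_network`
#' @param coloring a balanced `coloring`
#' @param fiber_cell cell id (integer) or the name of any node in the fiber
#' @return a `locomotion_network` on the collapsed cells (names `C<k>`), with
#'   attribute `cell_members`
#' @export
extract_circuit <- function(net, coloring, fiber_cell) {
  k <- resolve_cell(coloring, fiber_cell)
  b <- base_graph(net, coloring)
  root <- sprintf("C%d", k)
  g <- as_igraph(b, directed = TRUE)
  anc <- igraph::subcomponent(g, root, mode = "in")   # walks into the root
  keep <- igraph::V(g)$name[anc]
  circ <- induced_network(b, keep, allow_asymmetric_gap = TRUE)
  attr(circ, "cell_members") <- attr(b, "cell_members")[keep]
  attr(circ, "root") <- root
  circ
}

#' Fiber building block of a fiber
#'
#' Induced subgraph of the parent network on: (1) the fiber's nodes, (2) their
#' immediate in-neighbors, (3) the nodes of the shortest non-self loop through
#' a fiber node, and (4), when the above leaves several weakly disconnected
#' pieces, the nodes of the shortest (undirected) path connecting each pair of
#' pieces — such blocks are flagged composite. Non-fiber nodes with no
#' incoming edges inside the block are the block's regulators; fiber nodes
#' feeding back into their own fiber are reported separately as `feedback`.
#'
#' @inheritParams extract_circuit
#' @return a `fiber_building_block`: list with `fiber` (node names), `block`
#'   (a `locomotion_network`), `regulators`, `feedback`, `composite` flag and
#'   `rules` (which of rules 1-4 contributed nodes)
#' @export
extract_fbb <- function(net, coloring, fiber_cell) {
  k <- resolve_cell(coloring, fiber_cell)
  fiber <- coloring_cells(coloring)[[k]]
  g <- as_igraph(net, directed = TRUE)
  nm <- network_nodes(net)

  in_nb <- unique(unlist(lapply(fiber, function(v)
    igraph::neighbors(g, v, mode = "in")$name)))
  rules <- c(`1` = TRUE, `2` = length(setdiff(in_nb, fiber)) > 0,
             `3` = FALSE, `4` = FALSE)
  keep <- union(fiber, in_nb)

  loop <- shortest_fiber_loop(g, fiber)
  if (!is.null(loop)) {
    rules[["3"]] <- length(setdiff(loop, keep)) > 0
    keep <- union(keep, loop)
  }

  composite <- FALSE
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub, mode = "weak")
  if (comp$no > 1L) {
    bridge <- connect_components(g, sub, comp)
    if (length(setdiff(bridge, keep))) {
      composite <- TRUE
      rules[["4"]] <- TRUE
      keep <- union(keep, bridge)
    }
  }

  block <- induced_network(net, keep)
  structure(list(fiber = sort(fiber), block = block,
                 regulators = fbb_regulators(block, fiber),
                 feedback = fbb_feedback(block, fiber),
                 composite = composite, rules = rules),
            class = "fiber_building_block")
}

#' @export
print.fiber_building_block <- function(x, ...) {
  cat(sprintf("fiber_building_block: fiber {%s}; %d block nodes; %d regulators%s\n",
              paste(x$fiber, collapse = ", "), nrow(x$block$nodes),
              length(x$regulators), if (x$composite) " (composite)" else ""))
  invisible(x)
}

## shortest directed loop (length >= 2) through any fiber node; ties broken
## by (length, lexicographic node sequence)
shortest_fiber_loop <- function(g, fiber) {
  best <- NULL
  for (v in sort(fiber)) {
    outs <- igraph::neighbors(g, v, mode = "out")$name
    outs <- setdiff(outs, v)                 # self-loops excluded
    for (w in sort(outs)) {
      sp <- suppressWarnings(igraph::shortest_paths(g, from = w, to = v,
                                                    mode = "out",
                                                    output = "vpath"))
      path <- sp$vpath[[1]]$name
      if (!length(path)) next
      cyc <- c(v, path)                      # v -> w -> ... -> v
      if (is.null(best) || length(cyc) < length(best) ||
          (length(cyc) == length(best) &&
           paste(cyc, collapse = ",") < paste(best, collapse = ","))) {
        best <- cyc
      }
    }
  }
  best
}

## shortest undirected connecting path between every pair of weak components
connect_components <- function(g, sub, comp) {
  groups <- split(igraph::V(sub)$name, comp$membership)
  extra <- character(0)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      best <- NULL
      for (u in sort(groups[[i]])) {
        sp <- suppressWarnings(igraph::shortest_paths(g, from = u,
                                                      to = sort(groups[[j]]),
                                                      mode = "all",
                                                      output = "vpath"))
        for (p in sp$vpath) {
          pn <- p$name
          if (!length(pn)) next
          if (is.null(best) || length(pn) < length(best) ||
              (length(pn) == length(best) &&
               paste(pn, collapse = ",") < paste(best, collapse = ","))) {
            best <- pn
          }
        }
      }
      if (!is.null(best)) extra <- union(extra, best)
    }
  }
  extra
}

## regulators proper: non-fiber nodes that only send edges inside the block.
## Fiber nodes feeding back into their own fiber are tracked separately (the
## two notions are sometimes conflated, but a self-contained loop block such
## as a plain cycle has zero regulators).
fbb_regulators <- function(block, fiber) {
  e <- block$edges
  inside <- setdiff(network_nodes(block), fiber)
  sort(inside[vapply(inside, function(v) !any(e$target == v), logical(1))])
}

fbb_feedback <- function(block, fiber) {
  e <- block$edges
  sort(intersect(fiber, e$source[e$target %in% fiber]))
}

#' Branching ratio |n> of a block's input tree
#'
#' Computed two ways and required to agree within `tol`: (a) the limit of
#' consecutive input-tree layer counts a_{i+1}/a_i for the fiber's
#' representative node, and (b) the spectral radius (dense Perron eigenvalue)
#' of the weighted adjacency restricted to the nodes lying on walks into the
#' root. Returns 0 when the input tree is finite (acyclic in-component). If
#' the layer-ratio sequence has not settled within `max_depth` layers the
#' estimate is flagged (attribute `converged = FALSE`) and both values are
#' attached.
#'
#' @param block a `locomotion_network` or `fiber_building_block`
#' @param root_fiber node name(s) of the fiber the tree is rooted in
#'   (defaults to the block's fiber)
#' @inheritParams minimal_balanced_coloring
#' @param tol agreement tolerance between the two estimates
#' @param max_depth maximum number of layers for the layer-ratio estimate
#' @return nonnegative number with attributes `layer_estimate`,
#'   `spectral_estimate`, `converged`
#' @export
branching_ratio <- function(block, root_fiber = NULL,
                            channel = c("both", "chem", "gap"),
                            weighted = TRUE, tol = 1e-6, max_depth = 10000L) {
  channel <- match.arg(channel)
  if (inherits(block, "fiber_building_block")) {
    if (is.null(root_fiber)) root_fiber <- block$fiber
    block <- block$block
  }
  if (is.null(root_fiber)) stop("root_fiber is required for a bare network")
  root <- sort(root_fiber)[1]
  A <- Reduce(`+`, channel_matrices(block, channel, weighted))

  ## in-component of the root (nodes with walks into it)
  g <- as_igraph(block, directed = TRUE)
  anc <- igraph::V(g)$name[igraph::subcomponent(g, root, mode = "in")]
  B <- A[anc, anc, drop = FALSE]

  ## an acyclic in-component means a finite input tree: both estimates are 0
  gs <- igraph::induced_subgraph(g, anc)
  if (igraph::is_dag(gs) && all(diag(B) == 0)) {
    return(structure(0, layer_estimate = 0, spectral_estimate = 0,
                     converged = TRUE))
  }

  spectral <- spectral_radius(B)

  ## layer-count ratio with running normalization; the stop criterion is
  ## strict (practically machine precision) so that slowly drifting ratios
  ## are reported as non-converged instead of stopping early
  cvec <- stats::setNames(numeric(length(anc)), anc)
  cvec[root] <- 1
  ratio <- NA_real_
  converged <- FALSE
  stable <- 0L
  for (i in seq_len(max_depth)) {
    cvec <- drop(B %*% cvec)
    s <- sum(cvec)
    if (s == 0) { ratio <- 0; converged <- TRUE; break }   # finite tree
    new_ratio <- s                    # c was normalized to sum 1
    cvec <- cvec / s
    if (is.finite(ratio) && abs(new_ratio - ratio) < 1e-11 * max(1, new_ratio)) {
      stable <- stable + 1L
      if (stable >= 10L) { ratio <- new_ratio; converged <- TRUE; break }
    } else stable <- 0L
    ratio <- new_ratio
  }
  if (!converged && ratio != 0) {
    warning("layer-ratio estimate did not converge within ", max_depth,
            " layers; reporting the spectral estimate")
  }
  value <- if (converged) ratio else spectral
  if (converged && abs(ratio - spectral) > max(tol, tol * spectral)) {
    stop(sprintf("branching-ratio estimates disagree: layers %.8g vs spectral %.8g",
                 ratio, spectral))
  }
  structure(value, layer_estimate = ratio, spectral_estimate = spectral,
            converged = converged)
}

## spectral radius (Perron root) of a nonnegative matrix; a dense eigenvalue
## solve is exact and immune to the slow power-iteration convergence of
## imprimitive or defective blocks
spectral_radius <- function(B) {
  if (nrow(B) == 0L) return(0)
  max(0, max(Mod(eigen(B, only.values = TRUE)$values)))
}

#' Trail count |l> terminating at a root
#'
#' Counts edge-distinct walks (trails) that terminate at `root`, in the
#' unweighted (multiplicity-free) graph with the root's outgoing edges
#' removed. Exhaustive enumeration by reverse depth-first search over the
#' edge set.
#'
#' @param net a `locomotion_network` (typically an FBB base)
#' @param root node at which trails terminate
#' @inheritParams minimal_balanced_coloring
#' @param max_edges refuse enumeration on graphs with more distinct edges
#' @return integer trail count; attribute `trails` holds the trails (as
#'   `"a->b->root"` strings) when there are at most 100
#' @export
trail_count <- function(net, root, channel = c("both", "chem", "gap"),
                        max_edges = 40L) {
  channel <- match.arg(channel)
  e <- net$edges
  if (channel != "both") e <- e[e$channel == channel, , drop = FALSE]
  ## multiplicity disregarded; root's outgoing edges removed; self-loops at
  ## the root would be outgoing, other self-loops cannot reach the root twice
  key <- unique(paste(e$source, e$target, sep = "\r"))
  parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
  if (is.null(parts)) parts <- matrix(character(0), 0, 2)
  keep <- parts[, 1] != root
  src <- parts[keep, 1]; dst <- parts[keep, 2]
  m <- length(src)
  if (m > max_edges) stop("block has ", m, " edges; trail enumeration limited to ", max_edges)
  if (!root %in% network_nodes(net)) stop("unknown root: ", root)
  trails <- character(0)
  count <- 0L
  used <- logical(m)
  recurse <- function(v, seq_nodes) {
    incoming <- which(dst == v & !used)
    for (k in incoming) {
      count <<- count + 1L
      if (count <= 100L) trails[count] <<- paste(c(src[k], seq_nodes), collapse = "->")
      used[k] <<- TRUE
      recurse(src[k], c(src[k], seq_nodes))
      used[k] <<- FALSE
    }
  }
  recurse(root, root)
  structure(count, trails = if (count <= 100L) trails else NULL)
}

#' Fiber numbers and multilayer expression of a fiber
#'
#' Layer 1 is the main FBB's fiber numbers; each subsequent layer holds the
#' fiber numbers of the blocks of the previous layer's regulators, each fiber
#' visited at most once. `|n>` is the branching ratio, `|l>` the trail count
#' in the block's multiplicity-free base (the regulator count is reported
#' alongside, since both conventions appear in the field), and blocks with a
#' non-integer `|n>` are flagged Fibonacci.
#'
#' @inheritParams extract_circuit
#' @return list with `numbers` (a `fiber_numbers` for the main block),
#'   `expression` (a `multilayer_expression`), and `fbb` (the main
#'   `fiber_building_block`)
#' @export
classify_fbb <- function(net, coloring, fiber_cell) {
  k <- resolve_cell(coloring, fiber_cell)
  main <- fbb_numbers(net, coloring, k)
  layers <- list(list(main$numbers))
  seen <- k
  frontier <- main$regulator_cells
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    if (!length(frontier)) break
    layer <- lapply(sort(frontier), function(cell) fbb_numbers(net, coloring, cell))
    seen <- c(seen, sort(frontier))
    layers <- c(layers, list(lapply(layer, `[[`, "numbers")))
    frontier <- unique(unlist(lapply(layer, `[[`, "regulator_cells")))
  }
  expr <- structure(layers, class = "multilayer_expression")
  list(numbers = main$numbers, expression = expr, fbb = main$fbb)
}

## fiber numbers of one cell's FBB, plus the cells of its regulators
fbb_numbers <- function(net, coloring, cell_id) {
  fbb <- extract_fbb(net, coloring, cell_id)
  n <- branching_ratio(fbb)
  ## trails are counted on the multiplicity-free base of the block
  sub_col <- coloring[network_nodes(fbb$block)]
  sub_cells <- split(names(sub_col), sub_col)
  names(sub_cells) <- NULL
  block_col <- as_coloring(sub_cells, fbb$block,
                           channel = attr(coloring, "channel") %||% "both",
                           weighted = FALSE)
  base_ok <- is_balanced(fbb$block, block_col,
                         attr(coloring, "channel") %||% "both", weighted = FALSE)
  if (base_ok) {
    b <- base_graph(fbb$block, block_col)
    members <- attr(b, "cell_members")
    root <- names(members)[vapply(members, function(m) fbb$fiber[1] %in% m, logical(1))]
    ell <- trail_count(b, root)
  } else {
    ## the block seen in isolation need not be balanced under the parent
    ## coloring (external inputs are cut); fall back to counting trails into
    ## the fiber's representative in the multiplicity-free block itself
    ell <- trail_count(fbb$block, sort(fbb$fiber)[1])
  }
  numbers <- fiber_numbers(as.numeric(n), as.integer(ell),
                           length(fbb$regulators))
  reg_cells <- unique(coloring[fbb$regulators])
  ## fiber nodes acting as their own regulators do not add a layer
  reg_cells <- setdiff(reg_cells, coloring[fbb$fiber[1]])
  list(numbers = numbers, fbb = fbb, regulator_cells = reg_cells)
}

#' Fiber-number pair |n, l>
#' @param n branching ratio (nonnegative)
#' @param ell_trails trail count
#' @param ell_regulators regulator count (alternative reading of |l>)
#' @param tolerance integer-classification tolerance for `n`
#' @return a `fiber_numbers` object; `fibonacci` is TRUE iff `n` is not an
#'   integer within `tolerance`
#' @export
fiber_numbers <- function(n, ell_trails, ell_regulators = NA_integer_,
                          tolerance = 1e-6) {
  stopifnot(n >= 0, ell_trails >= 0)
  structure(list(n = as.numeric(n), ell_trails = as.integer(ell_trails),
                 ell_regulators = as.integer(ell_regulators),
                 fibonacci = abs(n - round(n)) > tolerance),
            class = "fiber_numbers")
}

#' @export
format.fiber_numbers <- function(x, ...) {
  n_str <- if (x$fibonacci) sprintf("%.3f", x$n) else sprintf("%d", as.integer(round(x$n)))
  sprintf("|%s,%d\u27e9", n_str, x$ell_trails)
}

#' @export
print.fiber_numbers <- function(x, ...) {
  cat(format(x), if (x$fibonacci) " (Fibonacci)" else "", "\n", sep = "")
  invisible(x)
}

#' Render a multilayer expression
#'
#' Layers are joined with the direct-sum sign, blocks within a layer with `+`.
#' @param x a `multilayer_expression`
#' @param ... unused
#' @return character scalar
#' @export
format.multilayer_expression <- function(x, ...) {
  paste(vapply(x, function(layer)
    paste(vapply(layer, format, character(1)), collapse = "+"),
    character(1)), collapse = "\u2295")
}

#' @export
print.multilayer_expression <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
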