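V_EXC <- 0      # excitatory reversal potential (V)
V_INH <- -0.07  # inhibitory reversal potential (V)

#' Construct a locomotion-style neuronal network
#'
#' A `locomotion_network` is a directed, weighted multigraph with two coupling
#' channels: `chem` (chemical synapses, directed) and `gap` (gap junctions,
#' undirected, stored internally as two directed edges of equal weight).
#' Parallel edges are collapsed into a single edge whose weight is the summed
#' multiplicity, which is exactly how the adjacency matrices consume them.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `channel` (`"chem"` or `"gap"`). Gap edges may be given once per pair;
#'   they are symmetrized. An optional `sign` column (`"exc"`/`"inh"`) sets the
#'   reversal-potential class of the *source* node.
#' @param nodes optional character vector of node names (to declare isolated
#'   nodes) or a data.frame with columns `name` and optionally `role`
#'   (`"interneuron"`, `"motorneuron"` or `"generic"`), `Vs` (reversal
#'   potential in volts) and `pair` (left-right pair tag).
#' @param validate check invariants (default `TRUE`).
#' @param allow_asymmetric_gap permit an asymmetric gap channel; only used
#'   internally for quotient (base) graphs, where collapsed gap weights need
#'   not be symmetric when fibers differ in size.
#' @return object of class `locomotion_network` with components `nodes`
#'   (data.frame `name`, `role`, `Vs`, `pair`) and `edges` (data.frame
#'   `source`, `target`, `weight`, `channel`). Nodes are kept in lexicographic
#'   order, the canonical order used by all matrix outputs.
#' @export
locomotion_network <- function(edges = NULL, nodes = NULL, validate = TRUE,
                               allow_asymmetric_gap = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), channel = character())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  needed <- c("source", "target", "weight", "channel")
  if (!all(needed %in% names(edges))) {
    stop("edges must have columns source, target, weight, channel")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  edges$channel <- as.character(edges$channel)

  sign_col <- if ("sign" %in% names(edges)) as.character(edges$sign) else NULL
  edges_core <- edges[needed]

  node_df <- normalize_node_table(nodes, edges_core)

  if (!is.null(sign_col)) {
    inh <- unique(edges_core$source[sign_col == "inh" & edges_core$channel == "chem"])
    node_df$Vs[node_df$name %in% inh] <- V_INH
  }

  if (validate) {
    if (anyDuplicated(node_df$name)) stop("node names must be unique")
    bad <- setdiff(c(edges_core$source, edges_core$target), node_df$name)
    if (length(bad)) stop("dangling edge endpoints: ", paste(bad, collapse = ", "))
    if (any(!is.finite(edges_core$weight)) || any(edges_core$weight <= 0)) {
      stop("edge weights must be positive finite numbers")
    }
    if (!all(edges_core$channel %in% c("chem", "gap"))) {
      stop("channel must be 'chem' or 'gap'")
    }
  }

  ## collapse parallel edges: multiplicity is weight
  edges_core <- collapse_parallel(edges_core)
  ## symmetrize gap channel
  gap <- edges_core[edges_core$channel == "gap", , drop = FALSE]
  if (nrow(gap) && !allow_asymmetric_gap) {
    edges_core <- rbind(edges_core[edges_core$channel == "chem", , drop = FALSE],
                        symmetrize_gap(gap))
  }
  edges_core <- order_edges(edges_core)
  rownames(edges_core) <- NULL

  net <- structure(list(nodes = node_df, edges = edges_core,
                        asymmetric_gap = allow_asymmetric_gap),
                   class = "locomotion_network")
  if (validate && !allow_asymmetric_gap) validate_network(net)
  net
}

normalize_node_table <- function(nodes, edges) {
  if (is.null(nodes)) {
    nm <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(name = nm, stringsAsFactors = FALSE)
  } else if (is.character(nodes)) {
    nodes <- data.frame(name = sort(unique(c(nodes, edges$source, edges$target))),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!"name" %in% names(nodes)) stop("nodes data.frame needs a 'name' column")
    extra <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
    if (length(extra)) {
      add <- data.frame(name = extra, stringsAsFactors = FALSE)
      for (col in setdiff(names(nodes), "name")) add[[col]] <- NA
      nodes <- rbind(nodes, add)
    }
  }
  if (!"role" %in% names(nodes)) nodes$role <- "generic"
  if (!"Vs" %in% names(nodes)) nodes$Vs <- V_EXC
  if (!"pair" %in% names(nodes)) nodes$pair <- NA_character_
  nodes$role[is.na(nodes$role)] <- "generic"
  nodes$Vs[is.na(nodes$Vs)] <- V_EXC
  nodes <- nodes[order(nodes$name), c("name", "role", "Vs", "pair")]
  rownames(nodes) <- NULL
  nodes
}

collapse_parallel <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(edges$source, edges$target, edges$channel, sep = "\r")
  w <- tapply(edges$weight, key, sum)
  parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  data.frame(source = parts[, 1], target = parts[, 2],
             weight = as.numeric(w), channel = parts[, 3],
             stringsAsFactors = FALSE)
}

## gap edges are undirected: keep, for every unordered pair, the union of the
## stated directions; equal weights in both directions are required if both
## were stated, otherwise the single stated weight is mirrored.
symmetrize_gap <- function(gap) {
  a <- pmin(gap$source, gap$target)
  b <- pmax(gap$source, gap$target)
  key <- paste(a, b, sep = "\r")
  out <- lapply(split(seq_len(nrow(gap)), key), function(idx) {
    w <- unique(gap$weight[idx])
    if (length(w) != 1L) {
      stop("asymmetric gap pair ", gap$source[idx[1]], " - ", gap$target[idx[1]],
           ": weights ", paste(gap$weight[idx], collapse = " vs "))
    }
    u <- gap$source[idx[1]]; v <- gap$target[idx[1]]
    if (u == v) {
      data.frame(source = u, target = v, weight = w, channel = "gap",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = c(u, v), target = c(v, u), weight = w,
                 channel = "gap", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

order_edges <- function(edges) {
  edges[order(edges$channel, edges$source, edges$target), , drop = FALSE]
}

validate_network <- function(net) {
  gap <- net$edges[net$edges$channel == "gap", , drop = FALSE]
  if (nrow(gap)) {
    fwd <- paste(gap$source, gap$target, gap$weight)
    rev <- paste(gap$target, gap$source, gap$weight)
    if (!setequal(fwd, rev)) stop("gap channel is not symmetric")
  }
  invisible(TRUE)
}

#' @export
print.locomotion_network <- function(x, ...) {
  nc <- sum(x$edges$channel == "chem")
  ng <- sum(x$edges$channel == "gap")
  cat(sprintf("locomotion_network: %d nodes, %d chem edges, %d gap half-edges\n",
              nrow(x$nodes), nc, ng))
  invisible(x)
}

#' Network node names (canonical lexicographic order)
#' @param net a `locomotion_network`
#' @return character vector
#' @export
network_nodes <- function(net) net$nodes$name

#' Channel adjacency matrix
#'
#' Entry `(j, i)` is the total weight of edges `j -> i` for the requested
#' channel, so the i-th *column* holds the inputs of node i (the convention
#' consumed by the admissible ODE couplings). Gap matrices are symmetric.
#'
#' @param net a `locomotion_network`
#' @param channel `"chem"`, `"gap"` or `"both"` (sum of the two)
#' @param binary collapse positive weights to 1
#' @param order optional explicit node order (default: lexicographic)
#' @return square numeric matrix with node-name dimnames
#' @export
adjacency_matrix <- function(net, channel = c("chem", "gap", "both"),
                             binary = FALSE, order = NULL) {
  channel <- match.arg(channel)
  nm <- if (is.null(order)) network_nodes(net) else order
  if (!setequal(nm, network_nodes(net)) || length(nm) != nrow(net$nodes)) {
    stop("order must be a permutation of the node names")
  }
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  e <- net$edges
  if (channel != "both") e <- e[e$channel == channel, , drop = FALSE]
  if (nrow(e)) {
    idx <- cbind(match(e$source, nm), match(e$target, nm))
    for (k in seq_len(nrow(e))) A[idx[k, 1], idx[k, 2]] <- A[idx[k, 1], idx[k, 2]] + e$weight[k]
  }
  if (binary) A[A > 0] <- 1
  A
}

#' Read a network from disk
#'
#' Edge-list TSV dialect: tab-separated columns `source target weight channel`
#' with optional `sign` (`exc`/`inh`, applied to the source node). Adjacency
#' CSV dialect: square matrix with node names as header row and first column;
#' `channel` selects which channel the matrix describes.
#'
#' @param path file path
#' @param dialect `"tsv"` (edge list) or `"adjacency_csv"`
#' @param nodes optional node declaration passed to [locomotion_network()]
#'   (lets a file with no edges still declare nodes)
#' @param channel channel label for the adjacency CSV dialect
#' @return a `locomotion_network`
#' @export
read_network <- function(path, dialect = c("tsv", "adjacency_csv"),
                         nodes = NULL, channel = "chem") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    needed <- c("source", "target", "weight", "channel")
    if (!all(needed %in% names(raw))) {
      stop("malformed edge-list TSV ", path, ": need columns ",
           paste(needed, collapse = ", "))
    }
    if (nrow(raw)) {
      w <- suppressWarnings(as.numeric(raw$weight))
      if (any(is.na(w))) {
        stop("parse error in ", path, " line ",
             which(is.na(w))[1] + 1L, ": non-numeric weight")
      }
      raw$weight <- w
    } else {
      raw$weight <- numeric(0)
    }
    locomotion_network(raw, nodes = nodes)
  } else {
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "double"
    network_from_adjacency(m, channel = channel)
  }
}

#' Build a network from an adjacency matrix
#' @param m square matrix, entry `(j,i)` = weight of `j -> i`; dimnames used
#'   as node names (defaults to `n1..nk`)
#' @param channel `"chem"` or `"gap"`
#' @param nodes optional node table
#' @return a `locomotion_network`
#' @export
network_from_adjacency <- function(m, channel = "chem", nodes = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("n%d", seq_len(nrow(m)))
  }
  idx <- which(m != 0, arr.ind = TRUE)
  if (channel == "gap") {
    if (!isTRUE(all.equal(m, t(m)))) stop("gap adjacency must be symmetric")
    idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  }
  edges <- data.frame(source = rownames(m)[idx[, 1]],
                      target = colnames(m)[idx[, 2]],
                      weight = m[idx], channel = channel,
                      stringsAsFactors = FALSE)
  locomotion_network(edges, nodes = if (is.null(nodes)) rownames(m) else nodes)
}

#' Write a network as edge-list TSV
#'
#' Gap edges are written once per unordered pair; chemical `sign` is derived
#' from the source node's reversal potential. Round-trips through
#' [read_network()] to an equal edge multiset.
#'
#' @param net a `locomotion_network`
#' @param path output path
#' @export
write_network <- function(net, path) {
  e <- net$edges
  gap <- e[e$channel == "gap", , drop = FALSE]
  gap <- gap[gap$source <= gap$target, , drop = FALSE]
  e <- rbind(e[e$channel == "chem", , drop = FALSE], gap)
  vs <- stats::setNames(net$nodes$Vs, net$nodes$name)
  e$sign <- ifelse(e$channel == "chem" & vs[e$source] < -0.035, "inh", "exc")
  e <- e[order(e$channel, e$source, e$target), ]
  utils::write.table(format(e, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## igraph view of one channel (or both), used for path/loop/component queries
as_igraph <- function(net, channel = "both", directed = TRUE) {
  e <- net$edges
  if (channel != "both") e <- e[e$channel == channel, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("source", "target", "weight")],
    directed = directed,
    vertices = data.frame(name = network_nodes(net))
  )
  g
}

## induced subgraph on a node set, keeping both channels
induced_network <- function(net, keep, allow_asymmetric_gap = net$asymmetric_gap %||% FALSE) {
  e <- net$edges
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  nd <- net$nodes[net$nodes$name %in% keep, , drop = FALSE]
  locomotion_network(e, nodes = nd, allow_asymmetric_gap = allow_asymmetric_gap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
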