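## Automorphism group and orbit partitioning.
##
## An automorphism is a node permutation P with P A P^-1 = A for every
## (weighted) channel adjacency A: it must preserve inputs *and* outputs.
## Orbits — the classes of nodes exchangeable by some automorphism — are
## therefore always contained in fibers, which only constrain inputs.
## The search is exact backtracking with equitable-partition pruning: a node
## can only map to a node in the same doubly-balanced (in + out profile)
## refinement cell, and partial assignments are checked against all channel
## adjacencies as they grow.

#' All automorphisms of a network channel
#'
#' Exhaustive backtracking enumeration of the automorphism group. Intended
#' for the small (tens of nodes) networks this package targets; refuses
#' networks above `max_nodes` and groups above `max_count` elements.
#'
#' @param net a `locomotion_network`
#' @inheritParams minimal_balanced_coloring
#' @param max_nodes refuse larger networks (whole-connectome orbit
#'   computation is out of reach for exact search)
#' @param max_count abort if the group has more elements than this
#' @return list of permutations, each a named character vector mapping
#'   node -> image; always contains the identity
#' @export
automorphisms <- function(net, channel = c("both", "chem", "gap"),
                          weighted = TRUE, max_nodes = 64L, max_count = 1e5) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  if (length(nm) > max_nodes) {
    stop("network has ", length(nm), " nodes; exact automorphism search is ",
         "limited to ", max_nodes)
  }
  mats <- channel_matrices(net, channel, weighted)
  cells <- double_refinement(mats)
  found <- list()
  collect <- function(p) {
    if (length(found) >= max_count) stop("automorphism group larger than max_count")
    found[[length(found) + 1L]] <<- stats::setNames(nm[p], nm)
    TRUE  # keep searching
  }
  search_automorphisms(mats, cells, visit = collect)
  found
}

#' Check one permutation against the automorphism contract
#' @param net a `locomotion_network`
#' @param perm named character vector node -> image
#' @inheritParams minimal_balanced_coloring
#' @return TRUE iff permuting rows and columns leaves every channel adjacency
#'   unchanged
#' @export
is_automorphism <- function(net, perm, channel = c("both", "chem", "gap"),
                            weighted = TRUE) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  p <- match(perm[nm], nm)
  if (anyNA(p) || anyDuplicated(p)) return(FALSE)
  mats <- channel_matrices(net, channel, weighted)
  all(vapply(mats, function(A) identical(all.equal(A[p, p], A,
                                                   check.attributes = FALSE), TRUE),
             logical(1)))
}

#' Orbit coloring (automorphism-group partition)
#'
#' Cells are the orbits of the automorphism group action, obtained by
#' union-find closure over discovered automorphisms. For every candidate pair
#' not yet merged, a targeted backtracking search asks whether *some*
#' automorphism maps one to the other; each discovered automorphism merges
#' all of its node/image pairs at once. The result is a balanced coloring
#' that refines the fiber coloring.
#'
#' @inheritParams automorphisms
#' @return a `coloring`
#' @export
orbit_coloring <- function(net, channel = c("both", "chem", "gap"),
                           weighted = TRUE, max_nodes = 64L) {
  channel <- match.arg(channel)
  nm <- network_nodes(net)
  n <- length(nm)
  if (n > max_nodes) {
    stop("network has ", n, " nodes; exact orbit computation is limited to ",
         max_nodes)
  }
  mats <- channel_matrices(net, channel, weighted)
  cells <- double_refinement(mats)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || cells[i] != cells[j] || find(i) == find(j)) next
      got <- NULL
      search_automorphisms(mats, cells, force = c(i, j),
                           visit = function(p) { got <<- p; FALSE })
      if (!is.null(got)) for (k in seq_len(n)) union(k, got[k])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  new_coloring(as.integer(factor(roots)), nm, channel, weighted)
}

## equitable refinement on (in, out) profiles jointly: the automorphism
## candidate partition. Returns integer cell ids.
double_refinement <- function(mats) {
  n <- ncol(mats[[1]])
  col <- rep(1L, n)
  repeat {
    sig <- vapply(seq_len(n), function(v) {
      parts <- lapply(names(mats), function(ch) {
        A <- mats[[ch]]
        win <- A[, v]; wout <- A[v, ]
        c(sort(paste("i", ch, col[win != 0], format(win[win != 0], digits = 15))),
          sort(paste("o", ch, col[wout != 0], format(wout[wout != 0], digits = 15))))
      })
      paste(unlist(parts), collapse = ";")
    }, character(1))
    new_col <- as.integer(factor(paste(col, sig)))
    if (length(unique(new_col)) == length(unique(col))) return(new_col)
    col <- new_col
  }
}

## Backtracking over images. `visit(p)` is called with each complete
## permutation (integer image vector); return FALSE from visit to stop.
## `force = c(i, j)` preassigns image j to node i.
search_automorphisms <- function(mats, cells, visit, force = NULL) {
  n <- length(cells)
  ord <- order(cells, seq_len(n))       # fill small cells first
  if (!is.null(force)) ord <- c(force[1], setdiff(ord, force[1]))
  p <- integer(n)
  used <- logical(n)
  consistent <- function(v, w, assigned) {
    for (A in mats) {
      if (A[v, v] != A[w, w]) return(FALSE)
      for (u in assigned) {
        if (A[v, u] != A[w, p[u]] || A[u, v] != A[p[u], w]) return(FALSE)
      }
    }
    TRUE
  }
  alive <- TRUE
  recurse <- function(k, assigned) {
    if (!alive) return()
    if (k > n) {
      if (!visit(p)) alive <<- FALSE
      return()
    }
    v <- ord[k]
    cand <- if (!is.null(force) && v == force[1]) force[2] else which(cells == cells[v] & !used)
    for (w in cand) {
      if (used[w] || cells[w] != cells[v]) next
      if (!consistent(v, w, assigned)) next
      p[v] <<- w; used[w] <<- TRUE
      recurse(k + 1L, c(assigned, v))
      used[w] <<- FALSE
      if (!alive) return()
    }
  }
  recurse(1L, integer(0))
  invisible(NULL)
}
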