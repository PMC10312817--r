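## Shared builders and independent oracles used across the suite.

chem_net <- function(src, dst, w = 1, nodes = NULL) {
  locomotion_network(data.frame(source = src, target = dst,
                                weight = w, channel = "chem"),
                     nodes = nodes)
}

gap_net <- function(src, dst, w = 1, nodes = NULL) {
  locomotion_network(data.frame(source = src, target = dst,
                                weight = w, channel = "gap"),
                     nodes = nodes)
}

## a small identifiable base used by many lift tests: 4 nodes, distinct
## weighted input profiles
identifiable_base <- function() {
  chem_net(c("A", "A", "B", "C", "D"), c("B", "C", "C", "D", "A"),
           w = c(1, 2, 1, 1, 1))
}

## random identifiable base on n nodes: a weighted cycle with distinct
## weights plus a few random chords (retry until identifiable)
random_base <- function(n, seed) {
  set.seed(seed)
  nm <- sprintf("b%02d", seq_len(n))
  for (attempt in 1:20) {
    e <- data.frame(source = nm, target = nm[c(2:n, 1)],
                    weight = seq_len(n), channel = "chem",
                    stringsAsFactors = FALSE)
    k <- sample(0:2, 1)
    if (k > 0) {
      extra <- data.frame(source = sample(nm, k, replace = TRUE),
                          target = sample(nm, k, replace = TRUE),
                          weight = sample(1:3, k, replace = TRUE),
                          channel = "chem", stringsAsFactors = FALSE)
      e <- rbind(e, extra)
    }
    base <- locomotion_network(e)
    if (n_cells(minimal_balanced_coloring(base)) == n) return(base)
  }
  stop("could not build an identifiable base")
}

## independent trail-count oracle: plain recursion with an explicit edge-set,
## structured differently from the package implementation (forward walks
## from every start node instead of reverse DFS)
oracle_trail_count <- function(net, root, channel = "both") {
  e <- net$edges
  if (channel != "both") e <- e[e$channel == channel, , drop = FALSE]
  edges <- unique(paste(e$source, e$target, sep = ">"))
  edges <- edges[!startsWith(edges, paste0(root, ">"))]
  src <- sub(">.*", "", edges)
  dst <- sub(".*>", "", edges)
  count <- 0L
  walk <- function(at, used) {
    if (at == root) count <<- count + 1L
    ## a trail may pass through the root only as its final node
    if (at == root) return(invisible(NULL))
    nxt <- which(src == at & !used)
    for (k in nxt) {
      used2 <- used; used2[k] <- TRUE
      walk(dst[k], used2)
    }
  }
  for (s in unique(src)) {
    nxt <- which(src == s)
    for (k in nxt) {
      used <- logical(length(edges)); used[k] <- TRUE
      walk(dst[k], used)
    }
  }
  count
}

## all permutations of 1..n (n small), for brute-force automorphism checks
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

## brute-force automorphism count straight from the P A P^-1 = A contract
brute_autom_count <- function(net, channel) {
  A <- adjacency_matrix(net, channel)
  n <- nrow(A)
  sum(vapply(all_perms(n), function(p) {
    P <- diag(n)[p, , drop = FALSE]
    isTRUE(all.equal(P %*% A %*% solve(P), A, check.attributes = FALSE))
  }, logical(1)))
}

## maximum within-cell trajectory spread of a simulation
max_cell_spread <- function(sim, coloring) {
  max(vapply(coloring_cells(coloring), function(cell) {
    if (length(cell) < 2L) return(0)
    max(apply(sim$V[cell, , drop = FALSE], 2, function(x) diff(range(x))))
  }, numeric(1)))
}
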