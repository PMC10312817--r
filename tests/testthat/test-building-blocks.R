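test_that("trail counts match the worked three-node example and an oracle", {
  cyan <- toy_networks()$cyan
  tc <- trail_count(cyan, "C")
  expect_equal(as.integer(tc), 6L)
  expect_setequal(attr(tc, "trails"),
                  c("M->C", "P->C", "M->P->C", "P->M->C",
                    "P->M->P->C", "M->P->M->C"))
  ## single edge
  expect_equal(as.integer(trail_count(chem_net("u", "v"), "v")), 1L)
  ## random 5-node digraphs vs an independent recursion
  for (seed in 1:40) {
    set.seed(seed + 1000)
    nm <- letters[1:5]
    m <- sample(4:8, 1)
    e <- unique(data.frame(source = sample(nm, m, replace = TRUE),
                           target = sample(nm, m, replace = TRUE),
                           stringsAsFactors = FALSE))
    e <- e[e$source != e$target, , drop = FALSE]
    if (!nrow(e)) next
    net <- chem_net(e$source, e$target, nodes = nm)
    root <- sample(nm, 1)
    expect_equal(as.integer(trail_count(net, root)),
                 oracle_trail_count(net, root))
  }
  ## enumeration refuses oversized blocks
  fx <- locomotion_fixture(1)$network
  expect_error(trail_count(fx, "VA01", max_edges = 5), "limited")
})

test_that("branching ratios match closed forms and the spectral oracle", {
  toys <- toy_networks()
  ## acyclic block: finite tree, ratio 0
  expect_equal(as.numeric(branching_ratio(chem_net(c("a", "b"), c("b", "c")), "c")), 0)
  ## unit self-loop: constant layers, ratio 1
  loop <- chem_net("a", "a")
  expect_equal(as.numeric(branching_ratio(loop, "a")), 1)
  ## golden-ratio two-node base [[1,1],[1,0]]
  gold <- branching_ratio(toys$fibonacci_bases$golden$network, "a")
  expect_equal(as.numeric(gold), (1 + sqrt(5)) / 2, tolerance = 1e-7)
  expect_lt(abs(attr(gold, "layer_estimate") - attr(gold, "spectral_estimate")), 1e-6)
  ## the nested-loop base [[1,8],[1,0]] gives (1+sqrt(33))/2 = 3.3723...
  expect_equal(as.numeric(branching_ratio(toys$fibonacci_bases$nested33$network, "a")),
               (1 + sqrt(33)) / 2, tolerance = 1e-7)
  ## integer control [[1,2],[1,0]] gives 2
  expect_equal(as.numeric(branching_ratio(toys$fibonacci_bases$integer2$network, "a")),
               2, tolerance = 1e-7)
  ## estimates agree against a dense eigenvalue oracle on random blocks
  for (seed in 1:20) {
    set.seed(seed + 500)
    n <- sample(2:4, 1)
    m <- matrix(sample(0:2, n * n, replace = TRUE), n)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    if (all(m == 0)) next
    net <- network_from_adjacency(m, "chem")
    br <- suppressWarnings(branching_ratio(net, "a"))
    g <- igraph::graph_from_adjacency_matrix(t(m) > 0)
    anc <- igraph::V(g)$name[igraph::subcomponent(g, "a", mode = "out")]
    rho <- if (length(anc)) max(Mod(eigen(m[anc, anc, drop = FALSE])$values)) else 0
    ## a finite (nilpotent) in-component means ratio 0
    if (rho < 1e-9) rho <- 0
    expect_equal(as.numeric(br), rho, tolerance = 1e-6)
  }
})

test_that("the Fibonacci flag marks exactly the non-integer ratios", {
  ## sweep all 2x2 integer matrices with entries <= 3 and a reachable cycle
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    m <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    dimnames(m) <- list(c("a", "b"), c("a", "b"))
    if (sum(m) == 0) next
    net <- network_from_adjacency(m, "chem")
    br <- suppressWarnings(branching_ratio(net, "a"))
    lam <- max(0, Re(eigen(m)$values))   # Perron root, nonneg matrix
    g <- igraph::graph_from_adjacency_matrix(t(m) > 0)
    anc <- igraph::V(g)$name[igraph::subcomponent(g, "a", mode = "out")]
    lam_anc <- if (length(anc)) max(Mod(eigen(m[anc, anc, drop = FALSE])$values)) else 0
    fib_expected <- abs(lam_anc - round(lam_anc)) > 1e-6
    expect_equal(fiber_numbers(as.numeric(br), 0)$fibonacci, fib_expected)
  }
})

test_that("FBB extraction applies the four membership rules", {
  ## isolated fiber: block is the fiber alone, no regulators
  iso <- locomotion_network(nodes = c("f1", "f2"))
  col <- minimal_balanced_coloring(iso)
  fbb <- extract_fbb(iso, col, 1)
  expect_setequal(network_nodes(fbb$block), c("f1", "f2"))
  expect_equal(length(fbb$regulators), 0L)
  expect_false(fbb$composite)

  ## fiber {v} with in-neighbor u and the 2-loop u <-> v: both loop edges
  ## belong to the block
  net <- chem_net(c("u", "v"), c("v", "u"))
  singles <- as_coloring(list("u", "v"), net, channel = "chem")
  fbb2 <- extract_fbb(net, singles, "v")
  expect_setequal(network_nodes(fbb2$block), c("u", "v"))
  A <- adjacency_matrix(fbb2$block, "chem")
  expect_equal(A["u", "v"], 1)
  expect_equal(A["v", "u"], 1)

  ## composite: the two feeder arms {a -> f1} and {b -> f2} are disconnected
  ## inside the raw block; the shortest connecting path a - m - b is added
  net3 <- chem_net(c("m", "m", "a", "b"), c("a", "b", "f1", "f2"))
  col3 <- as_coloring(list(c("f1", "f2"), c("a", "b"), "m"), net3,
                      channel = "chem", weighted = FALSE)
  expect_true(is_balanced(net3, col3, "chem", weighted = FALSE))
  fbb3 <- extract_fbb(net3, col3, "f1")
  expect_true(fbb3$composite)
  expect_true("m" %in% network_nodes(fbb3$block))
  expect_equal(fbb3$regulators, "m")
})

test_that("regulators are pure feeders; fiber feedback is reported apart", {
  ## r feeds the fiber {f1, f2} and receives nothing inside the block
  net <- chem_net(c("r", "r"), c("f1", "f2"))
  col <- as_coloring(list(c("f1", "f2"), "r"), net, channel = "chem")
  fbb <- extract_fbb(net, col, "f1")
  expect_equal(fbb$regulators, "r")
  expect_equal(fbb$feedback, character(0))
  ## a self-contained cycle fiber has feedback nodes but zero regulators
  sq <- chem_net(c("a", "b", "c", "d"), c("b", "c", "d", "a"), 2)
  colq <- minimal_balanced_coloring(sq, "chem")
  fbbq <- extract_fbb(sq, colq, "a")
  expect_equal(length(fbbq$regulators), 0L)
  expect_setequal(fbbq$feedback, c("a", "b", "c", "d"))
})

test_that("classification assembles multilayer expressions", {
  ## 4-node square with in-degree 2 everywhere and no external input: |2,0>
  sq <- chem_net(c("a", "b", "c", "d"), c("b", "c", "d", "a"), 2)
  col <- minimal_balanced_coloring(sq, "chem")
  expect_equal(n_cells(col), 1L)
  cls <- classify_fbb(sq, col, "a")
  expect_equal(cls$numbers$n, 2)
  expect_equal(cls$numbers$ell_trails, 0L)
  expect_equal(cls$numbers$ell_regulators, 0L)
  expect_false(cls$numbers$fibonacci)
  expect_equal(format(cls$expression), "|2,0\u27e9")

  ## a regulator chain unrolls into one expression layer per upstream fiber
  chain <- chem_net(c("r", "r", "u"), c("f1", "f2", "r"))
  colc <- as_coloring(list(c("f1", "f2"), "r", "u"), chain, channel = "chem")
  cls2 <- classify_fbb(chain, colc, "f1")
  expect_equal(length(cls2$expression), 3L)
  expect_match(format(cls2$expression), "\u2295")

  ## fixture: every fiber classifies without error, ratio estimates agree
  fx <- locomotion_fixture(1)
  for (k in seq_len(n_cells(fx$coloring))) {
    cls <- classify_fbb(fx$network, fx$coloring, k)
    br <- branching_ratio(cls$fbb)
    expect_lt(abs(attr(br, "layer_estimate") - attr(br, "spectral_estimate")),
              1e-6)
  }
})

test_that("circuits retain exactly the cells reaching the fiber", {
  ## fiber fed by {X, Y} with Y fed by X: three collapsed cells
  net <- chem_net(c("X", "Y", "X", "Z"), c("F", "F", "Y", "W"))
  col <- as_coloring(list("F", "X", "Y", "Z", "W"), net, channel = "chem")
  circ <- extract_circuit(net, col, "F")
  expect_equal(nrow(circ$nodes), 3L)
  ## a fiber with no inputs collapses to a single node
  circ2 <- extract_circuit(net, col, "Z")
  expect_equal(nrow(circ2$nodes), 1L)
})
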