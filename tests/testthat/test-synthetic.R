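test_that("single-node self-loop lift keeps in-weight and one cell", {
  base <- chem_net("A", "A")
  lift <- planted_lift(lift_spec(base, c(A = 3), seed = 2, identifiable = FALSE))
  A <- adjacency_matrix(lift$network, "chem")
  expect_equal(unname(colSums(A)), rep(1, 3))
  expect_equal(n_cells(minimal_balanced_coloring(lift$network, "chem")), 1L)
})

test_that("identifiable lifts are recovered across a seeded sweep", {
  base <- identifiable_base()
  sizes <- c(A = 2, B = 3, C = 2, D = 1)
  for (seed in 1:50) {
    lift <- planted_lift(lift_spec(base, sizes, seed = seed))
    expect_true(is_balanced(lift$network, lift$coloring))
    mbc <- minimal_balanced_coloring(lift$network)
    expect_equal(lapply(coloring_cells(mbc), sort),
                 lapply(coloring_cells(lift$coloring), sort))
  }
})

test_that("gap channels of lifts stay symmetric, with flagged odd fallback", {
  base <- locomotion_network(rbind(
    data.frame(source = "A", target = "B", weight = 1, channel = "chem"),
    data.frame(source = c("A", "B"), target = c("A", "B"), weight = c(2, 1),
               channel = "gap")))
  ## even within-fiber demand: clean circulant
  l1 <- planted_lift(lift_spec(base, c(A = 3, B = 4), identifiable = FALSE, seed = 1))
  G <- adjacency_matrix(l1$network, "gap")
  expect_equal(G, t(G))
  expect_false(l1$fallback_gap)
  expect_true(is_balanced(l1$network, l1$coloring))
  ## odd demand on an odd fiber: self-pairing fallback, flagged, still balanced
  l2 <- planted_lift(lift_spec(base, c(A = 3, B = 3), identifiable = FALSE, seed = 1))
  expect_true(l2$fallback_gap)
  expect_true(is_balanced(l2$network, l2$coloring))
  G2 <- adjacency_matrix(l2$network, "gap")
  expect_equal(G2, t(G2))
  ## cross-fiber gap between unequal fibers is refused
  base2 <- locomotion_network(
    data.frame(source = "A", target = "B", weight = 1, channel = "gap"))
  expect_error(planted_lift(lift_spec(base2, c(A = 2, B = 3),
                                      identifiable = FALSE, seed = 1)),
               "unequal size")
})

test_that("non-identifiable bases are rejected by the spec constructor", {
  ## two parallel source nodes with identical outputs cannot be told apart
  amb <- chem_net(c("X", "Y"), c("F", "F"))
  expect_error(lift_spec(amb, c(X = 1, Y = 1, F = 2)), "not identifiable")
})

test_that("the locomotion fixture has the advertised structure", {
  fx <- locomotion_fixture(8)
  net <- fx$network
  expect_gte(nrow(net$nodes), 15L)
  expect_lte(nrow(net$nodes), 30L)
  ## every left-right interneuron pair shares a cell
  for (pair in c("AVB", "PVC", "RIB")) {
    both <- paste0(pair, c("L", "R"))
    expect_equal(length(unique(fx$coloring[both])), 1L)
  }
  ## balanced with at most 8 cells, recovered by the partitioner
  expect_true(is_balanced(net, fx$coloring))
  expect_lte(n_cells(fx$coloring), 8L)
  mbc <- minimal_balanced_coloring(net)
  expect_equal(n_cells(mbc), n_cells(fx$coloring))
  ## orbit coloring refines fiber coloring
  orb <- orbit_coloring(net)
  expect_true(refines(orb, fx$coloring))
  ## roles present for protocol frequency assignment
  expect_setequal(unique(net$nodes$role), c("interneuron", "motorneuron"))
})

test_that("weight perturbation is zero-mean, structure- and symmetry-preserving", {
  fx <- locomotion_fixture(1)
  ## sd = 0: identity
  expect_identical(perturb_weights(fx$network, 0, seed = 5), fx$network)
  pert <- perturb_weights(fx$network, 0.05, seed = 5)
  ## zero pattern unchanged, all weights positive
  expect_equal(paste(pert$edges$source, pert$edges$target, pert$edges$channel),
               paste(fx$network$edges$source, fx$network$edges$target,
                     fx$network$edges$channel))
  expect_true(all(pert$edges$weight > 0))
  ## gap stays symmetric
  G <- adjacency_matrix(pert, "gap")
  expect_equal(G, t(G))
  ## deterministic under the seed
  expect_identical(perturb_weights(fx$network, 0.05, seed = 5)$edges, pert$edges)
  expect_error(perturb_weights(fx$network, -1), "sd")
})

test_that("perturbation deltas match the stated normal distribution", {
  ## large sample: many chem edges across many seeds
  base <- identifiable_base()
  lift <- planted_lift(lift_spec(base, c(A = 5, B = 5, C = 5, D = 5), seed = 1))
  deltas <- unlist(lapply(1:40, function(seed) {
    p <- perturb_weights(lift$network, 0.05, seed = seed, floor = NULL)
    p$edges$weight - lift$network$edges$weight
  }))
  n <- length(deltas)
  expect_gt(n, 1000)
  ## sample mean within 3 standard errors of 0
  expect_lt(abs(mean(deltas)), 3 * 0.05 / sqrt(n))
  ## Kolmogorov-Smirnov against N(0, 0.05^2)
  ks <- suppressWarnings(stats::ks.test(deltas, "pnorm", 0, 0.05))
  expect_gt(ks$p.value, 0.01)
})

test_that("protocols encode the three test setups", {
  fx <- locomotion_fixture(1)
  p2 <- model_params("chem2")
  ## test 1: no stimulus; seeded initial conditions near rest / s_eq
  pr1 <- simulation_protocol(1, fx$network, fx$coloring, p2)
  expect_null(pr1$stimulus)
  st <- pr1$init(3)
  n <- nrow(fx$network$nodes)
  expect_equal(length(st), 2L * n)
  expect_lt(max(abs(st[1:n] - p2$V_rest)), 1e-3)
  expect_true(all(st[n + 1:n] >= 0 & st[n + 1:n] <= 1))
  expect_identical(pr1$init(3), st)              # seeded determinism

  ## test 2: 90% + 5% drive at 2 Hz interneurons; gap gets a 1 Hz motor group
  pr2 <- simulation_protocol(2, fx$network, fx$coloring, model_params("chem1"),
                             I_star = 10e-12)
  tab <- pr2$stimulus$table
  driven <- tab[tab$I_drive > 0, ]
  expect_equal(unique(driven$I_drive), 9e-12)
  expect_equal(unique(driven$I_osc), 0.5e-12)
  expect_equal(unique(driven$freq), 2)
  prg <- simulation_protocol(2, fx$network, fx$coloring, model_params("gap"),
                             I_star = 10e-12)
  tabg <- prg$stimulus$table[prg$stimulus$table$I_drive > 0, ]
  expect_setequal(unique(tabg$freq), c(1, 2))

  ## test 3: 0.1 pA + 0.5 pA (2/1 Hz) + 0.01 pA noise = 0.61 pA max amplitude
  pr3 <- simulation_protocol(3, fx$network, fx$coloring, p2,
                             targets = c("AVBL", "AVBR", "PVCL", "PVCR",
                                         "RIBL", "RIBR"))
  t3 <- pr3$stimulus$table[pr3$stimulus$table$I_drive > 0, ]
  expect_equal(max(t3$I_drive + t3$I_osc + t3$noise_amp), 0.61e-12)
  expect_equal(pr3$sd_sweep, seq(0, 0.1, by = 0.01))
  expect_equal(pr3$replicates, 10L)
  expect_error(simulation_protocol(4, fx$network, fx$coloring, p2), "unknown test")
})

test_that("an unperturbed deterministic replicate reproduces the mask exactly", {
  ## the test-3 comparison degenerates to zero when sd = 0 and the drive is
  ## deterministic
  fx <- locomotion_fixture(1)
  p <- model_params("gap")
  stim <- make_stimulus(fx$network, fx$coloring, c("AVBL", "AVBR"),
                        I_drive = 0.1e-12, I_osc = 0.5e-12, freq = 2, seed = 2)
  run <- function(net) {
    sim <- simulate_network(net, p, stim, duration = 1.5)
    los_matrix(sim, window = 0.5)
  }
  ref <- run(fx$network)
  mask <- (unclass(ref) >= 1 - 1e-3) * 1
  reps <- lapply(1:3, function(k) run(perturb_weights(fx$network, 0, seed = k)))
  avg <- Reduce(`+`, lapply(reps, unclass)) / 3
  expect_equal(masked_difference(avg, mask, fx$coloring), 0)
})
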