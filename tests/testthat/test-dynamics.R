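test_that("model parameters carry the standard calibration", {
  p <- model_params("chem2")
  expect_equal(p$alpha_leak, 10)
  expect_equal(p$alpha_gap, 100)
  expect_equal(p$alpha_chem, 100)
  expect_equal(p$alpha_ext, 1e12)             # 1 / 1 pF
  expect_equal(p$s_eq, 1 / 11)
  expect_equal(p$s_eq, p$a_r / (p$a_r + 2 * p$a_d))
})

test_that("threshold voltages solve the stationarity system", {
  iso <- locomotion_network(nodes = "n1")
  for (m in c("gap", "chem1", "chem2")) {
    p <- model_params(m)
    ## isolated neuron at zero drive rests at V_rest
    expect_equal(unname(threshold_voltages(iso, p, 0)), p$V_rest)
    ## 1 pA shifts the 1x1 system by I/(C alpha_leak) = 0.1 V
    expect_equal(unname(threshold_voltages(iso, p, 1e-12)), p$V_rest + 0.1)
  }
  ## self-consistency: rhs at (V_threshold, s_eq) vanishes on the fixture
  fx <- locomotion_fixture(1)
  nm <- network_nodes(fx$network)
  Id <- stats::setNames(rep(0, length(nm)), nm)
  Id[c("AVBL", "AVBR")] <- 2e-12
  for (m in c("gap", "chem1", "chem2")) {
    p <- model_params(m)
    Vt <- threshold_voltages(fx$network, p, Id)
    state <- if (m == "chem2") c(unname(Vt), rep(p$s_eq, length(nm))) else unname(Vt)
    deriv <- neuron_rhs(state, 0, fx$network, p, I_ext = Id, V_threshold = Vt)
    expect_lt(max(abs(deriv)), 1e-12)
  }
})

test_that("rhs vanishes at rest and gap coupling is antisymmetric", {
  empty <- locomotion_network(nodes = c("a", "b"))
  p <- model_params("gap")
  expect_equal(neuron_rhs(rep(p$V_rest, 2), 0, empty, p), c(0, 0))
  ## two-neuron gap pair, 1 mV apart: equal and opposite coupling terms
  pair <- gap_net("a", "b", 3)
  V <- c(p$V_rest + 1e-3, p$V_rest)
  d <- neuron_rhs(V, 0, pair, p, V_threshold = threshold_voltages(pair, p))
  leak <- -p$alpha_leak * (V - p$V_rest)
  coup <- d - leak
  expect_equal(coup[1], -p$alpha_gap * 3 * 1e-3)
  expect_equal(coup[2], +p$alpha_gap * 3 * 1e-3)
  ## dimension guard
  expect_error(neuron_rhs(1:3, 0, pair, model_params("chem2"),
                          V_threshold = threshold_voltages(pair, model_params("chem2"))))
})

test_that("integration reproduces the closed-form leak decay", {
  iso <- locomotion_network(nodes = "n")
  p <- model_params("gap")
  ## constant at rest with no input
  still <- simulate_network(iso, p, duration = 0.2)
  expect_equal(max(abs(still$V - p$V_rest)), 0)
  ## 10 mV offset decays exponentially at alpha_leak
  sim <- simulate_network(iso, p, init = p$V_rest + 10e-3, duration = 0.5)
  analytic <- p$V_rest + 10e-3 * exp(-p$alpha_leak * sim$time)
  expect_lt(max(abs(sim$V[1, ] - analytic)) / 10e-3, 1e-8)
})

test_that("an undriven gap network settles into global synchrony at rest", {
  fx <- locomotion_fixture(2)
  e <- fx$network$edges
  gap_only <- locomotion_network(e[e$channel == "gap", ], nodes = fx$network$nodes)
  p <- model_params("gap")
  set.seed(42)
  nm <- network_nodes(gap_only)
  init <- stats::setNames(stats::rnorm(length(nm), p$V_rest, 5e-3), nm)
  sim <- simulate_network(gap_only, p, init = init, duration = 2)
  final <- sim$V[, ncol(sim$V)]
  expect_lt(diff(range(final)), 1e-9)
  expect_lt(max(abs(final - p$V_rest)), 1e-9)
})

test_that("same-fiber nodes follow identical trajectories under balanced drive", {
  ## the core admissibility property, on a planted lift and the locomotion
  ## fixture, for all three models
  fx <- locomotion_fixture(1)
  lift <- planted_lift(lift_spec(identifiable_base(),
                                 c(A = 2, B = 3, C = 2, D = 1), seed = 3))
  cases <- list(list(net = fx$network, col = fx$coloring,
                     targets = c("AVBL", "AVBR", "PVCL", "PVCR")),
                list(net = lift$network, col = lift$coloring,
                     targets = coloring_cells(lift$coloring)[[2]]))
  for (cs in cases) {
    nm <- network_nodes(cs$net)
    V0 <- -0.035 + 0.002 * as.integer(cs$col[nm])
    names(V0) <- nm
    for (m in c("gap", "chem1", "chem2")) {
      p <- model_params(m)
      stim <- make_stimulus(cs$net, cs$col, cs$targets,
                            I_drive = 2e-12, I_osc = 1e-12, freq = 2,
                            noise_amp = 0.1e-12, seed = 7)
      sim <- simulate_network(cs$net, p, stim, init = V0, duration = 0.25)
      expect_equal(max_cell_spread(sim, cs$col), 0)
    }
  }
})

test_that("chem2 synaptic variables stay inside [0, 1]", {
  fx <- locomotion_fixture(1)
  p <- model_params("chem2")
  stim <- make_stimulus(fx$network, fx$coloring,
                        c("AVBL", "AVBR"), I_drive = 2e-12, seed = 2)
  nm <- network_nodes(fx$network)
  init <- c(rep(-0.035, length(nm)), runif(length(nm)))
  sim <- simulate_network(fx$network, p, stim, init = init, duration = 0.5)
  expect_true(all(sim$s >= 0 & sim$s <= 1))
})

test_that("halving dt changes noise-free trajectories at 4th order", {
  net <- chem_net(c("a", "b"), c("b", "a"), 2,
                  nodes = data.frame(name = c("a", "b"), role = "interneuron"))
  p <- model_params("chem1")
  col <- minimal_balanced_coloring(net, "chem")
  stim <- make_stimulus(net, col, c("a", "b"), I_drive = 1e-12,
                        I_osc = 0.5e-12, freq = 5, seed = 1)
  run <- function(dt) simulate_network(net, p, stim, init = c(-0.05, -0.02),
                                       duration = 0.1, dt = dt)
  ref <- run(2.5e-5)
  e1 <- max(abs(run(2e-4)$V[, 501] - ref$V[, 4001]))
  e2 <- max(abs(run(1e-4)$V[, 1001] - ref$V[, 4001]))
  expect_gt(e1 / e2, 8)   # ~16 for a 4th-order scheme
})

test_that("seeded noise makes runs reproducible and bounded", {
  fx <- locomotion_fixture(1)
  p <- model_params("gap")
  stim <- make_stimulus(fx$network, fx$coloring, c("AVBL", "AVBR"),
                        I_drive = 1e-12, noise_amp = 0.1e-12, seed = 11)
  s1 <- simulate_network(fx$network, p, stim, duration = 0.2)
  s2 <- simulate_network(fx$network, p, stim, duration = 0.2)
  expect_identical(s1$V, s2$V)
  s3 <- simulate_network(fx$network, p, stim, duration = 0.2, seed = 99)
  expect_false(identical(s1$V, s3$V))
  ## the rescaled random walk fills exactly its amplitude band
  paths <- fibersync:::noise_paths(stim, 2000, 1e-4, 11)
  driven <- rowSums(abs(paths)) > 0
  expect_equal(max(paths[driven, ]), 0.1e-12)
  expect_equal(min(paths[driven, ]), -0.1e-12)
})

test_that("balanced-mode stimuli must cover whole cells uniformly", {
  fx <- locomotion_fixture(1)
  expect_error(make_stimulus(fx$network, fx$coloring, "AVBL", I_drive = 1e-12),
               "splits fiber cell")
  expect_error(make_stimulus(fx$network, fx$coloring, c("AVBL", "AVBR"),
                             I_drive = c(AVBL = 1e-12, AVBR = 2e-12)),
               "differ within")
  ## empty targets: all-zero stimulus
  z <- make_stimulus(fx$network, fx$coloring)
  expect_true(all(z$table$I_drive == 0 & z$table$I_osc == 0))
  ## unbalanced mode permits split-cell drive
  s <- make_stimulus(fx$network, NULL, "AVBL", I_drive = 1e-12, balanced = FALSE)
  expect_equal(sum(s$table$I_drive > 0), 1L)
})
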