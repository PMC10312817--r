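const_result <- function(values, duration = 2, dt = 1e-3) {
  tt <- seq(0, duration, by = dt)
  V <- do.call(rbind, lapply(values, function(v) rep(v, length(tt))))
  rownames(V) <- names(values)
  structure(list(time = tt, V = V), class = "simulation_result")
}

test_that("LoS kernel calibration: bounds, identity and the 0.61 offset", {
  res <- const_result(c(a = -0.035, b = -0.035, c = -0.035 + 0.1e-3,
                        d = -0.035 + 10e-3))
  L <- los_matrix(res, window = 1, sigma = 0.1e-3)
  expect_equal(unname(diag(L)), rep(1, 4))
  expect_equal(L, t(L))
  expect_true(all(L >= 0 & L <= 1))
  ## identical signals
  expect_equal(L["a", "b"], 1)
  ## offset of exactly one kernel width: exp(-1/2) ~ 0.61
  expect_equal(L["a", "c"], exp(-0.5))
  expect_equal(round(L["a", "c"], 2), 0.61)
  ## 100-sigma offset: kernel tail indistinguishable from zero
  expect_lt(L["a", "d"], 1e-300)
  ## monotone decreasing in the offset
  offs <- c(0, 0.5e-3, 1e-3, 2e-3)
  vals <- vapply(offs, function(o) {
    r <- const_result(c(x = 0, y = o))
    los_matrix(r, sigma = 0.1e-3)["x", "y"]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  ## window validation
  expect_error(los_matrix(res, window = 10), "longer than")
})

test_that("ideal matrices are cell-block matrices", {
  net <- locomotion_network(nodes = c("a", "b", "c"))
  singles <- as_coloring(list("a", "b", "c"), net)
  expect_equal(unclass(ideal_matrix(singles)), diag(3), ignore_attr = TRUE)
  onecell <- as_coloring(list(c("a", "b", "c")), net)
  expect_true(all(ideal_matrix(onecell) == 1))
  two <- as_coloring(list(c("a", "b"), "c"), net)
  M <- ideal_matrix(two)
  expect_equal(M["a", "b"], 1)
  expect_equal(M["a", "c"], 0)
  expect_equal(M["b", "c"], 0)
})

test_that("agreement scores follow the normalized subtraction", {
  net <- locomotion_network(nodes = letters[1:5])
  col <- as_coloring(list(c("a", "b"), c("c", "d"), "e"), net)
  ideal <- ideal_matrix(col)
  ## perfect agreement
  expect_equal(agreement_score(ideal, ideal), 0)
  ## one extra synchronized off-diagonal pair: -2 / (2 * 20) = -0.05
  extra <- unclass(ideal)
  extra["a", "c"] <- extra["c", "a"] <- 1
  extra <- structure(extra, class = c("synchrony_matrix", "matrix"))
  expect_equal(agreement_score(extra, ideal), -2 / 40)
  ## one missing within-fiber pair: +0.05
  missing <- unclass(ideal)
  missing["a", "b"] <- missing["b", "a"] <- 0.2
  missing <- structure(missing, class = c("synchrony_matrix", "matrix"))
  expect_equal(agreement_score(missing, ideal), +2 / 40)
  ## binarization tolerance: 0.9995 counts as synchronized at the default
  near <- unclass(ideal)
  near[near == 1] <- 0.9995
  diag(near) <- 1
  near <- structure(near, class = c("synchrony_matrix", "matrix"))
  expect_equal(agreement_score(near, ideal), 0)
})

test_that("masked differences average over within-cell entries only", {
  net <- locomotion_network(nodes = c("a", "b", "c", "d"))
  col <- as_coloring(list(c("a", "b"), c("c", "d")), net)
  mask <- ideal_matrix(col)
  expect_equal(masked_difference(mask, mask, col), 0)
  half <- unclass(mask)
  half[half == 1] <- 0.5
  diag(half) <- 1
  ## within-cell off-diagonal entries are 0.5 where the mask is 1
  expect_equal(masked_difference(half, mask, col), 0.5)
  ## cross-cell entries do not contribute
  noisy <- half
  noisy["a", "c"] <- noisy["c", "a"] <- 0.9
  expect_equal(masked_difference(noisy, mask, col), 0.5)
})

test_that("PLV detects phase locking and rejects independent phases", {
  tt <- seq(0, 2, by = 1e-4)
  mk <- function(...) {
    V <- rbind(...)
    structure(list(time = tt, V = V), class = "simulation_result")
  }
  ## identical sinusoids and constant phase shift both score 1
  s <- sin(2 * pi * 3 * tt)
  P1 <- plv_matrix(mk(a = s, b = s))
  expect_equal(P1["a", "b"], 1, tolerance = 1e-6)
  P2 <- plv_matrix(mk(a = s, b = sin(2 * pi * 3 * tt - pi / 3)))
  expect_equal(P2["a", "b"], 1, tolerance = 1e-3)
  ## identical constants: defined as 1; differing constants: flagged 0
  P3 <- plv_matrix(mk(a = rep(1, length(tt)), b = rep(1, length(tt)),
                      c = rep(2, length(tt))))
  expect_equal(P3["a", "b"], 1)
  expect_equal(P3["a", "c"], 0)
  expect_true(length(attr(P3, "flagged")) > 0)
  ## independent random-phase processes decorrelate (Monte-Carlo)
  set.seed(1)
  win <- seq(0, 1, by = 1e-4)
  vals <- vapply(1:100, function(k) {
    x <- as.numeric(stats::filter(rnorm(length(win)), 0.99, "recursive"))
    y <- as.numeric(stats::filter(rnorm(length(win)), 0.99, "recursive"))
    r <- structure(list(time = win, V = rbind(a = x, b = y)),
                   class = "simulation_result")
    plv_matrix(r, window = 1)["a", "b"]
  }, numeric(1))
  expect_lt(mean(vals), 0.2)
  ## bounds and symmetry
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("driven fixture runs agree with the fiber prediction (never positive)", {
  ## the test-2 style pipeline on a planted lift: balanced drive below
  ## instability must never report missing within-fiber synchrony
  fx <- locomotion_fixture(1)
  p <- model_params("chem1")
  thr <- instability_threshold(fx$network, p, c("AVBL", "AVBR", "PVCL", "PVCR"),
                               I_max = 20e-12, step = 0.5e-12)
  I_star <- if (is.na(thr$threshold)) 20e-12 else thr$threshold
  stim <- make_stimulus(fx$network, fx$coloring,
                        c("AVBL", "AVBR", "PVCL", "PVCR"),
                        I_drive = 0.9 * I_star, I_osc = 0.05 * I_star,
                        freq = 2, seed = 3)
  sim <- simulate_network(fx$network, p, stim, duration = 2)
  los <- los_matrix(sim, window = 1)
  score <- agreement_score(los, ideal_matrix(fx$coloring, order = rownames(los)))
  expect_lte(score, 0)
})
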