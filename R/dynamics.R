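## Admissible ODE models: gap junction (linear diffusive voltage coupling),
## Chem type I (sigmoid-gated synaptic current) and Chem type II (synaptic
## activity variable s with first-order kinetics). All couplings read the
## i-th column of the channel adjacency — a node is driven by its inputs
## only, which is what makes the models admissible to the fibration: nodes
## with isomorphic input trees receiving balanced stimuli follow identical
## equations.
##
## Units are SI throughout (volts, seconds, amperes, farads); convenience
## I/O in mV and pA happens at the interface level only.

#' Model parameters for the admissible ODEs
#'
#' Defaults follow the standard C. elegans single-compartment calibration:
#' leak rate `alpha_leak` = gL*S/C = 10 /s, coupling rates `alpha_gap` =
#' `alpha_chem` = 100 /s, external gain `alpha_ext` = 1/C with C = 1 pF,
#' sigmoid steepness `gamma` = 125 /V, synaptic rise/decay `a_r` = 1 /s,
#' `a_d` = 5 /s, resting potential `V_rest` = -35 mV. The synaptic
#' equilibrium `s_eq = a_r / (a_r + 2 a_d)` is derived, not settable.
#'
#' @param model `"gap"`, `"chem1"` or `"chem2"`
#' @param alpha_leak,alpha_gap,alpha_chem rate constants (1/s)
#' @param capacitance membrane capacitance (F); `alpha_ext = 1/capacitance`
#' @param gamma sigmoid steepness (1/V)
#' @param a_r,a_d synaptic rise and decay rates (1/s, chem2)
#' @param V_rest resting potential (V)
#' @return a `model_params` list (includes derived `alpha_ext` and `s_eq`)
#' @export
model_params <- function(model = c("gap", "chem1", "chem2"),
                         alpha_leak = 10, alpha_gap = 100, alpha_chem = 100,
                         capacitance = 1e-12, gamma = 125,
                         a_r = 1, a_d = 5, V_rest = -35e-3) {
  model <- match.arg(model)
  stopifnot(alpha_leak > 0, alpha_gap > 0, alpha_chem > 0,
            capacitance > 0, a_r > 0, a_d > 0)
  structure(list(model = model, alpha_leak = alpha_leak,
                 alpha_gap = alpha_gap, alpha_chem = alpha_chem,
                 alpha_ext = 1 / capacitance, gamma = gamma,
                 a_r = a_r, a_d = a_d, V_rest = V_rest,
                 s_eq = a_r / (a_r + 2 * a_d)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params(%s): alpha_leak=%g alpha_gap=%g alpha_chem=%g gamma=%g V_rest=%g V s_eq=%.4f\n",
              x$model, x$alpha_leak, x$alpha_gap, x$alpha_chem, x$gamma,
              x$V_rest, x$s_eq))
  invisible(x)
}

## which channels a model couples through
model_channels <- function(params) {
  switch(params$model, gap = "gap", chem1 = "chem", chem2 = "chem")
}

## sigmoid-at-equilibrium weight: 0.5 for chem1, s_eq for chem2, 0 for gap
model_c <- function(params) {
  switch(params$model, gap = 0, chem1 = 0.5, chem2 = params$s_eq)
}

#' Equilibrium threshold voltages
#'
#' Solves the linear stationarity system A V = b obtained by setting the
#' model's voltage equations to zero with the sigmoid pinned at 0.5 (and, for
#' chem2, s at `s_eq`): `A_ii = 1 + (1/alpha_leak) (sum_j alpha_gap
#' Agap_ji + c alpha_chem Achem_ji)`, `A_ij = -(alpha_gap/alpha_leak)
#' Agap_ji` off the diagonal, and `b_i = V_rest + (1/alpha_leak) (sum_j c
#' alpha_chem Achem_ji Vs_j + alpha_ext I_i)`. The solution centers each
#' node's sigmoid and anchors the stability analysis.
#'
#' @param net a `locomotion_network`
#' @param params a `model_params`
#' @param I_drive per-node constant drive (A): scalar, or vector named by
#'   node (missing nodes get 0)
#' @return named vector of threshold voltages (V)
#' @export
threshold_voltages <- function(net, params, I_drive = 0) {
  nm <- network_nodes(net)
  n <- length(nm)
  I <- expand_node_vector(I_drive, nm)
  ch <- model_channels(params)
  cc <- model_c(params)
  Agap <- if (params$model == "gap") adjacency_matrix(net, "gap") else
    matrix(0, n, n, dimnames = list(nm, nm))
  Achem <- if (ch == "chem") adjacency_matrix(net, "chem") else
    matrix(0, n, n, dimnames = list(nm, nm))
  Vs <- stats::setNames(net$nodes$Vs, net$nodes$name)[nm]

  gap_in <- colSums(Agap)
  chem_in <- colSums(Achem)
  A <- -(params$alpha_gap / params$alpha_leak) * t(Agap)
  diag(A) <- 1 + (params$alpha_gap * gap_in + cc * params$alpha_chem * chem_in) /
    params$alpha_leak
  b <- params$V_rest +
    (cc * params$alpha_chem * drop(crossprod(Achem, Vs)) + params$alpha_ext * I) /
    params$alpha_leak
  V <- tryCatch(solve(A, b), error = function(e)
    stop("singular threshold system for model ", params$model,
         " (channels: ", ch, "): ", conditionMessage(e)))
  stats::setNames(drop(V), nm)
}

expand_node_vector <- function(x, nm) {
  if (length(x) == 1L && is.null(names(x))) return(stats::setNames(rep(x, length(nm)), nm))
  out <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(names(x))) {
    unknown <- setdiff(names(x), nm)
    if (length(unknown)) stop("unknown nodes: ", paste(unknown, collapse = ", "))
    out[names(x)] <- x
  } else {
    if (length(x) != length(nm)) stop("length mismatch for node vector")
    out[] <- x
  }
  out
}

#' Right-hand side of an admissible model
#'
#' Exact implementation of the three coupled systems: the leak `-alpha_leak
#' (V - V_rest)`, diffusive gap coupling `-alpha_gap sum_j Agap_ji (V_i -
#' V_j)`, sigmoid-gated chem coupling `-alpha_chem sum_j Achem_ji Phi(V_j)
#' (V_i - Vs_j)` (type I) or `s_j` in place of `Phi(V_j)` (type II) together
#' with `s_i' = a_r Phi(V_i)(1 - s_i) - a_d s_i`, and external current
#' `alpha_ext I_i`. The sigmoid `Phi` is centered at each node's threshold
#' voltage.
#'
#' @param state numeric vector: `V` (length n) for gap/chem1, `c(V, s)`
#'   (length 2n) for chem2
#' @param t time (s), used only to evaluate a time-dependent stimulus
#' @param net a `locomotion_network`
#' @param params a `model_params`
#' @param I_ext external current: vector (A) per node, or function of t
#'   returning one
#' @param V_threshold sigmoid centers; defaults to the equilibrium solve with
#'   the constant part of `I_ext`
#' @param cache optional precomputed [rhs_cache()]
#' @return state derivative (V/s, and 1/s for the s block)
#' @export
neuron_rhs <- function(state, t, net, params, I_ext = 0, V_threshold = NULL,
                       cache = NULL) {
  if (is.null(cache)) cache <- rhs_cache(net, params, V_threshold, I_ext)
  dim_needed <- if (params$model == "chem2") 2L * cache$n else cache$n
  if (length(state) != dim_needed) {
    stop("state has length ", length(state), ", expected ", dim_needed,
         " for model ", params$model)
  }
  I <- if (is.function(I_ext)) I_ext(t) else expand_node_vector(I_ext, cache$nm)
  rhs_eval(state, I, cache)
}

## precompute everything the inner RK4 loop needs
rhs_cache <- function(net, params, V_threshold = NULL, I_ext_const = 0) {
  nm <- network_nodes(net)
  n <- length(nm)
  if (is.null(V_threshold)) {
    Ic <- if (is.function(I_ext_const)) stop("V_threshold required for functional stimulus")
    else expand_node_vector(I_ext_const, nm)
    V_threshold <- threshold_voltages(net, params, Ic)
  }
  Vs <- stats::setNames(net$nodes$Vs, net$nodes$name)[nm]
  out <- list(nm = nm, n = n, params = params, Vthr = V_threshold[nm], Vs = Vs)
  if (params$model == "gap") {
    Agap <- adjacency_matrix(net, "gap")
    out$gap_deg <- colSums(Agap)
    out$AgapT <- t(Agap)
  } else {
    Achem <- adjacency_matrix(net, "chem")
    out$AchemT <- t(Achem)             # row i = inputs of node i
    out$AchemT_Vs <- t(Achem * Vs)     # weight * source reversal potential
  }
  out
}

rhs_eval <- function(state, I, cache) {
  p <- cache$params
  n <- cache$n
  V <- state[seq_len(n)]
  leak <- -p$alpha_leak * (V - p$V_rest)
  ext <- p$alpha_ext * I
  if (p$model == "gap") {
    coup <- cache$gap_deg * V - drop(cache$AgapT %*% V)
    return(unname(leak - p$alpha_gap * coup + ext))
  }
  if (p$model == "chem1") {
    phi <- sigmoid(V, cache$Vthr, p$gamma)
    coup <- V * drop(cache$AchemT %*% phi) - drop(cache$AchemT_Vs %*% phi)
    return(unname(leak - p$alpha_chem * coup + ext))
  }
  ## chem2
  s <- state[n + seq_len(n)]
  coup <- V * drop(cache$AchemT %*% s) - drop(cache$AchemT_Vs %*% s)
  phi <- sigmoid(V, cache$Vthr, p$gamma)
  dV <- leak - p$alpha_chem * coup + ext
  ds <- p$a_r * phi * (1 - s) - p$a_d * s
  unname(c(dV, ds))
}

sigmoid <- function(V, Vthr, gamma) 1 / (1 + exp(-gamma * (V - Vthr)))

#' Balanced external stimulus specification
#'
#' Per-node drive `I(t) = I_drive + I_osc sin(2 pi f t + phase) + noise(t)`,
#' where the noise is a seeded Gaussian random walk rescaled into
#' `[-noise_amp, +noise_amp]`, shared within each stimulated cell. In
#' balanced mode (the default) the stimulus must not split a fiber cell:
#' targeting part of a cell, or giving two nodes of one cell different
#' parameters, is rejected, because it would break the input symmetry the
#' fibration predicts synchrony from.
#'
#' @param net a `locomotion_network`
#' @param coloring the fiber `coloring` stimulus balance is checked against
#' @param targets node names receiving the stimulus (empty = no stimulus)
#' @param I_drive,I_osc constant and oscillation amplitude (A); scalar or
#'   named per-target
#' @param freq oscillation frequency (Hz); scalar or named per-target
#' @param noise_amp random-walk amplitude bound (A)
#' @param phase oscillation phase (rad)
#' @param seed integer seed for the noise paths
#' @param balanced enforce cell-constant stimuli
#' @return a `stimulus_spec`: data.frame (node, I_drive, I_osc, freq,
#'   noise_amp, phase, noise_group) plus the seed
#' @export
make_stimulus <- function(net, coloring = NULL, targets = character(0),
                          I_drive = 0, I_osc = 0, freq = 0, noise_amp = 0,
                          phase = 0, seed = 1L, balanced = !is.null(coloring)) {
  nm <- network_nodes(net)
  unknown <- setdiff(targets, nm)
  if (length(unknown)) stop("unknown target nodes: ", paste(unknown, collapse = ", "))
  spec <- data.frame(node = nm,
                     I_drive = 0, I_osc = 0, freq = 0, noise_amp = 0, phase = 0,
                     noise_group = NA_integer_, stringsAsFactors = FALSE)
  fill <- function(col, val) {
    v <- if (!is.null(names(val))) {
      if (!all(targets %in% names(val))) stop("named ", col, " must cover all targets")
      val[targets]
    } else rep(val, length.out = length(targets))
    spec[[col]][match(targets, nm)] <<- as.numeric(v)
  }
  if (length(targets)) {
    fill("I_drive", I_drive); fill("I_osc", I_osc); fill("freq", freq)
    fill("noise_amp", noise_amp); fill("phase", phase)
  }
  if (balanced) {
    if (is.null(coloring)) stop("balanced mode needs a coloring")
    for (cell in coloring_cells(coloring)) {
      hit <- intersect(cell, targets)
      if (!length(hit)) next
      if (length(hit) < length(cell)) {
        stop("stimulus splits fiber cell {", paste(cell, collapse = ", "),
             "}: only {", paste(hit, collapse = ", "), "} targeted")
      }
      block <- spec[match(cell, nm), c("I_drive", "I_osc", "freq", "noise_amp", "phase")]
      if (nrow(unique(block)) != 1L) {
        stop("stimulus parameters differ within fiber cell {",
             paste(cell, collapse = ", "), "}")
      }
    }
  }
  ## noise shared within a cell (balanced) or per node otherwise
  driven <- which(spec$noise_amp > 0)
  if (length(driven)) {
    grp <- if (!is.null(coloring)) as.integer(coloring[nm][driven])
    else seq_along(driven)
    spec$noise_group[driven] <- as.integer(factor(grp))
  }
  structure(list(table = spec, seed = as.integer(seed)), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  act <- x$table[x$table$I_drive != 0 | x$table$I_osc != 0 | x$table$noise_amp != 0, ]
  cat(sprintf("stimulus_spec: %d driven nodes (seed %d)\n", nrow(act), x$seed))
  if (nrow(act)) print(act, row.names = FALSE)
  invisible(x)
}

## constant part of a stimulus, as a named vector
stimulus_drive <- function(stimulus, nm) {
  if (is.null(stimulus)) return(stats::setNames(numeric(length(nm)), nm))
  stats::setNames(stimulus$table$I_drive, stimulus$table$node)[nm]
}

#' Simulate an admissible model
#'
#' Fixed-step 4th-order Runge-Kutta at `dt` (default 0.1 ms). Noise-free runs
#' are fully deterministic; with noise, each stimulated cell gets one seeded
#' Gaussian random walk advanced with sqrt(dt) increments and min-max
#' rescaled into its amplitude band, held constant within each step. The
#' same seed always reproduces the same trajectories.
#'
#' @param net a `locomotion_network`
#' @param params a `model_params`
#' @param stimulus a `stimulus_spec` or NULL (no external input)
#' @param init initial state: named vector of voltages (V), or `c(V, s)` for
#'   chem2; scalar recycles. Defaults to `V_rest` (and `s_eq`).
#' @param duration simulated time (s)
#' @param dt integration step (s)
#' @param seed overrides the stimulus seed for the noise paths
#' @param record_every store every k-th step (1 = all)
#' @return a `simulation_result`: `time` (s), `V` (nodes x time, V),
#'   `s` (chem2 only), `params`, `stimulus`, `seed`
#' @export
simulate_network <- function(net, params, stimulus = NULL, init = NULL,
                             duration = 1, dt = 1e-4, seed = NULL,
                             record_every = 1L) {
  stopifnot(duration > 0, dt > 0)
  nm <- network_nodes(net)
  n <- length(nm)
  Idrive <- stimulus_drive(stimulus, nm)
  cache <- rhs_cache(net, params, I_ext_const = Idrive)

  state <- init_state(init, nm, params)
  nstep <- ceiling(duration / dt)
  seed <- if (is.null(seed)) (if (is.null(stimulus)) 1L else stimulus$seed) else as.integer(seed)

  ## time-dependent stimulus lookup tables
  tgrid <- seq(0, by = dt, length.out = nstep + 1L)
  Iosc <- if (is.null(stimulus)) NULL else stimulus$table
  noise <- noise_paths(stimulus, nstep, dt, seed)

  I_at <- function(k, frac_dt) {          # stimulus at t = (k - 1 + frac_dt) * dt
    tt <- (k - 1L + frac_dt) * dt
    I <- Idrive
    if (!is.null(Iosc)) {
      osc <- Iosc$I_osc != 0
      if (any(osc)) {
        I[osc] <- I[osc] + Iosc$I_osc[osc] *
          sin(2 * pi * Iosc$freq[osc] * tt + Iosc$phase[osc])
      }
      if (!is.null(noise)) I <- I + noise[, min(k, nstep)]
    }
    I
  }

  keep <- seq(1L, nstep + 1L, by = record_every)
  V_out <- matrix(NA_real_, n, length(keep), dimnames = list(nm, NULL))
  s_out <- if (params$model == "chem2")
    matrix(NA_real_, n, length(keep), dimnames = list(nm, NULL)) else NULL
  store <- function(slot, st) {
    V_out[, slot] <<- st[seq_len(n)]
    if (!is.null(s_out)) s_out[, slot] <<- st[n + seq_len(n)]
  }
  store(1L, state)
  slot <- 1L
  for (k in seq_len(nstep)) {
    I0 <- I_at(k, 0); Ih <- I_at(k, 0.5); I1 <- I_at(k, 1)
    k1 <- rhs_eval(state, I0, cache)
    k2 <- rhs_eval(state + dt / 2 * k1, Ih, cache)
    k3 <- rhs_eval(state + dt / 2 * k2, Ih, cache)
    k4 <- rhs_eval(state + dt * k3, I1, cache)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state))) {
      stop(sprintf("simulation diverged (NaN/overflow) at t = %.6f s", k * dt))
    }
    if (k %% record_every == 0L) {
      slot <- slot + 1L
      if (slot <= length(keep)) store(slot, state)
    }
  }
  structure(list(time = tgrid[keep], V = V_out, s = s_out,
                 params = params, stimulus = stimulus, seed = seed,
                 dt = dt, V_threshold = cache$Vthr),
            class = "simulation_result")
}

init_state <- function(init, nm, params) {
  n <- length(nm)
  dim_needed <- if (params$model == "chem2") 2L * n else n
  if (is.null(init)) {
    state <- rep(params$V_rest, n)
    if (params$model == "chem2") state <- c(state, rep(params$s_eq, n))
    return(state)
  }
  if (length(init) == 1L) return(rep(init, dim_needed))
  if (!is.null(names(init)) && length(init) == n) {
    state <- init[nm]
    if (params$model == "chem2") state <- c(state, rep(params$s_eq, n))
    return(unname(state))
  }
  if (length(init) != dim_needed) {
    stop("init has length ", length(init), ", expected ", dim_needed,
         " for model ", params$model)
  }
  unname(init)
}

## one rescaled Gaussian random walk per noise group; matrix nodes x steps
noise_paths <- function(stimulus, nstep, dt, seed) {
  if (is.null(stimulus)) return(NULL)
  tab <- stimulus$table
  if (!any(tab$noise_amp > 0)) return(NULL)
  groups <- sort(unique(tab$noise_group[!is.na(tab$noise_group)]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  paths <- lapply(groups, function(g) {
    w <- cumsum(stats::rnorm(nstep) * sqrt(dt))
    rng <- range(w)
    if (diff(rng) == 0) return(rep(0, nstep))
    2 * (w - rng[1]) / diff(rng) - 1      # in [-1, 1]
  })
  out <- matrix(0, nrow(tab), nstep)
  for (i in seq_len(nrow(tab))) {
    if (!is.na(tab$noise_group[i]) && tab$noise_amp[i] > 0) {
      out[i, ] <- tab$noise_amp[i] * paths[[match(tab$noise_group[i], groups)]]
    }
  }
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %s model, %d nodes, t in [0, %.4g] s (dt %.1e, %d samples)\n",
              x$params$model, nrow(x$V), max(x$time), x$dt, length(x$time)))
  invisible(x)
}
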