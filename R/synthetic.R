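## Synthetic inputs: planted fibration lifts, a locomotion-like left-right
## symmetric fixture, small reference toys, weight perturbation, and the
## three simulation-test protocols (free-running, driven-below-instability,
## and weight-perturbation robustness).

#' Lift specification
#'
#' @param base a `locomotion_network` (the base of the fibration)
#' @param sizes named positive integers: fiber size per base node
#' @param seed integer seed for the random tail assignment
#' @param identifiable require the base's own minimal balanced coloring to be
#'   discrete, which guarantees the lift's coarsest balanced coloring is
#'   exactly the planted fiber partition
#' @return a `lift_spec`
#' @export
lift_spec <- function(base, sizes, seed = 1L, identifiable = TRUE) {
  nm <- network_nodes(base)
  if (is.null(names(sizes))) {
    if (length(sizes) != length(nm)) stop("sizes must be named or cover all base nodes")
    names(sizes) <- nm
  }
  if (!setequal(names(sizes), nm)) stop("sizes must name every base node")
  if (any(sizes < 1)) stop("fiber sizes must be >= 1")
  if (identifiable) {
    mbc <- minimal_balanced_coloring(base, "both", weighted = TRUE)
    if (n_cells(mbc) != length(nm)) {
      stop("base is not identifiable: its minimal balanced coloring has ",
           n_cells(mbc), " < ", length(nm), " cells")
    }
  }
  structure(list(base = base, sizes = sizes[nm], seed = as.integer(seed),
                 identifiable = identifiable),
            class = "lift_spec")
}

#' Planted fibration lift
#'
#' Expands every base node b into `sizes[b]` nodes. Each base chemical edge
#' x -> b of integer weight w is realized so that every lifted node of b
#' receives total weight w from fiber(x), with the tails drawn uniformly at
#' random (seeded). Gap edges are lifted symmetrically and deterministically:
#' within-fiber gap weight w becomes a circulant of offsets (self-pairings
#' with a flag when parity makes w-regularity impossible), and cross-fiber
#' gap demands equal fiber sizes (circulant matching). The planted coloring
#' is balanced by construction, and on an identifiable base it is exactly the
#' minimal balanced coloring of the lift.
#'
#' @param spec a `lift_spec` (or a base network, with `sizes` given)
#' @param sizes,seed used when `spec` is a bare network
#' @return list with `network` (the lift), `coloring` (planted fibers) and
#'   `fallback_gap` flag
#' @export
planted_lift <- function(spec, sizes = NULL, seed = 1L) {
  if (!inherits(spec, "lift_spec")) spec <- lift_spec(spec, sizes, seed)
  base <- spec$base
  sizes <- spec$sizes
  nm <- network_nodes(base)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  members <- lapply(stats::setNames(nm, nm), function(b) {
    if (sizes[b] == 1L) b else sprintf("%s_%d", b, seq_len(sizes[b]))
  })

  edges <- list()
  fallback <- FALSE
  e <- base$edges
  chem <- e[e$channel == "chem", , drop = FALSE]
  for (k in seq_len(nrow(chem))) {
    x <- chem$source[k]; b <- chem$target[k]; w <- chem$weight[k]
    tails_pool <- members[[x]]
    for (head in members[[b]]) {
      if (abs(w - round(w)) < 1e-12) {
        picks <- sample(tails_pool, round(w), replace = TRUE)
        tab <- table(picks)
        edges[[length(edges) + 1L]] <-
          data.frame(source = names(tab), target = head,
                     weight = as.numeric(tab), channel = "chem",
                     stringsAsFactors = FALSE)
      } else {
        edges[[length(edges) + 1L]] <-
          data.frame(source = sample(tails_pool, 1L), target = head,
                     weight = w, channel = "chem", stringsAsFactors = FALSE)
      }
    }
  }

  gap <- e[e$channel == "gap", , drop = FALSE]
  gap <- gap[gap$source <= gap$target, , drop = FALSE]   # one row per pair
  for (k in seq_len(nrow(gap))) {
    x <- gap$source[k]; b <- gap$target[k]; w <- gap$weight[k]
    lifted <- lift_gap_edge(members[[x]], members[[b]], w, x == b)
    fallback <- fallback || attr(lifted, "fallback")
    if (nrow(lifted)) edges[[length(edges) + 1L]] <- lifted
  }

  node_df <- data.frame(name = unlist(members, use.names = FALSE),
                        role = rep(base$nodes$role[match(nm, base$nodes$name)],
                                   sizes[nm]),
                        Vs = rep(base$nodes$Vs[match(nm, base$nodes$name)],
                                 sizes[nm]),
                        pair = NA_character_, stringsAsFactors = FALSE)
  net <- locomotion_network(do.call(rbind, edges), nodes = node_df)
  coloring <- as_coloring(unname(members), net, channel = "both", weighted = TRUE)
  list(network = net, coloring = coloring, fallback_gap = fallback)
}

## symmetric lift of one base gap edge; returns gap edge rows (one direction;
## locomotion_network symmetrizes)
lift_gap_edge <- function(mx, mb, w, within) {
  fallback <- FALSE
  rows <- list()
  add <- function(u, v, wt) rows[[length(rows) + 1L]] <<-
    data.frame(source = u, target = v, weight = wt, channel = "gap",
               stringsAsFactors = FALSE)
  if (within) {
    s <- length(mb)
    if (s == 1L) {
      add(mb, mb, w)
    } else {
      w_int <- round(w)
      half <- w_int %/% 2
      for (o in seq_len(half)) {
        oo <- ((o - 1L) %% (s - 1L)) + 1L   # wrap long demands
        for (i in seq_len(s)) {
          j <- ((i - 1L + oo) %% s) + 1L
          if (i < j) add(mb[i], mb[j], 1) else add(mb[j], mb[i], 1)
        }
      }
      if (w_int %% 2 == 1L) {
        if (s %% 2 == 0L) {
          for (i in seq_len(s / 2)) add(mb[i], mb[i + s / 2], 1)
        } else {
          ## odd demand on an odd fiber: no perfect matching exists; fall
          ## back to self-pairings (gap self-loops), flagged
          fallback <- TRUE
          for (i in seq_len(s)) add(mb[i], mb[i], 1)
        }
      }
    }
  } else {
    if (length(mx) != length(mb)) {
      stop("cross-fiber gap edge between fibers of unequal size (",
           length(mx), " vs ", length(mb), ") cannot be lifted symmetrically")
    }
    s <- length(mb)
    for (o in seq_len(round(w)) - 1L) {
      for (i in seq_len(s)) add(mx[i], mb[((i - 1L + o) %% s) + 1L], 1)
    }
  }
  out <- if (length(rows)) collapse_parallel(do.call(rbind, rows)) else
    data.frame(source = character(), target = character(),
               weight = numeric(), channel = character())
  attr(out, "fallback") <- fallback
  out
}

#' Locomotion-like left-right symmetric fixture
#'
#' A 20-neuron network shaped like the worm's forward locomotion circuit:
#' three left-right interneuron pairs (AVB-, PVC-, RIB-like) driving four
#' motor-neuron classes (DB, VB, DA, VA-like) through the chemical channel,
#' with gap junctions inside the interneuron pairs and motor classes. Built
#' as a planted lift of an identifiable 7-node base, so the planted coloring
#' (7 cells; every left-right pair shares a cell) is the minimal balanced
#' coloring.
#'
#' @param seed integer seed for the lift's random tail assignment
#' @return list with `network`, `coloring` and `base`
#' @export
locomotion_fixture <- function(seed = 1L) {
  inter <- c("AVB", "PVC", "RIB")
  motor <- c("DB", "VB", "DA", "VA")
  nodes <- data.frame(name = c(inter, motor),
                      role = c(rep("interneuron", 3), rep("motorneuron", 4)),
                      Vs = V_EXC, pair = NA_character_,
                      stringsAsFactors = FALSE)
  chem <- data.frame(
    source = c("PVC", "AVB", "RIB", "AVB", "AVB", "PVC", "AVB", "RIB", "DA", "PVC"),
    target = c("AVB", "RIB", "AVB", "DB", "VB", "VB", "DA", "DA", "VA", "VA"),
    weight = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1),
    channel = "chem", stringsAsFactors = FALSE)
  gap <- data.frame(
    source = c("AVB", "PVC", "RIB", "DB", "VB", "VA"),
    target = c("AVB", "PVC", "RIB", "DB", "VB", "VA"),
    weight = c(1, 1, 1, 2, 2, 2),
    channel = "gap", stringsAsFactors = FALSE)
  base <- locomotion_network(rbind(chem, gap), nodes = nodes)
  sizes <- c(AVB = 2L, PVC = 2L, RIB = 2L, DB = 3L, VB = 4L, DA = 3L, VA = 4L)
  lift <- planted_lift(lift_spec(base, sizes, seed = seed))
  net <- rename_fixture_nodes(lift$network, inter)
  coloring <- as_coloring(lapply(coloring_cells(lift$coloring), relabel_lr, inter = inter),
                          net, channel = "both", weighted = TRUE)
  list(network = net, coloring = coloring, base = base)
}

relabel_lr <- function(cell, inter) vapply(cell, relabel_one, character(1), inter = inter)

relabel_one <- function(nm, inter) {
  parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) return(nm)
  if (parts[1] %in% inter) {
    paste0(parts[1], c("L", "R")[as.integer(parts[2])])
  } else {
    sprintf("%s%02d", parts[1], as.integer(parts[2]))
  }
}

rename_fixture_nodes <- function(net, inter) {
  nm <- network_nodes(net)
  new <- vapply(nm, relabel_one, character(1), inter = inter)
  map <- stats::setNames(new, nm)
  e <- net$edges
  e$source <- unname(map[e$source]); e$target <- unname(map[e$target])
  nd <- net$nodes; nd$name <- unname(map[nd$name])
  pairs <- sub("[LR]$", "", nd$name)
  nd$pair <- ifelse(grepl("[LR]$", nd$name) & pairs %in% inter, pairs, NA_character_)
  locomotion_network(e, nodes = nd)
}

#' Small reference networks
#'
#' Named fixtures used across the examples and tests:
#' * `cyan`: the three-node trail toy (nodes C, M, P; edges M->C, P->C,
#'   M->P, P->M) whose six trails into C calibrate the trail count.
#' * `fibonacci_bases`: two-node integer adjacencies with nested loops and
#'   irrational branching ratios, including `[[1,1],[1,0]]` (golden ratio)
#'   and `[[1,8],[1,0]]` (ratio (1+sqrt(33))/2 = 3.3723...), plus an integer
#'   control `[[1,2],[1,0]]`.
#' * `counterexample_directed`: 5-node graph whose fiber partition is
#'   strictly coarser than its orbit partition (a node pair with identical
#'   inputs but different out-degrees).
#' * `counterexample_undirected`: disjoint 3-cycle and 4-cycle (gap
#'   channel): one fiber — every node sees two same-colour neighbours — but
#'   two orbits, since no automorphism exchanges the cycles.
#' * `layer_example`: rooted weighted graph whose input tree has layer
#'   counts a = (1, 3, 11) — its two layer-2 source nodes have weighted
#'   in-degrees 3 and 4 (the 4 appearing twice).
#'
#' @return named list of fixtures (`fibonacci_bases` is itself a named list
#'   with `matrix` and `network` entries)
#' @export
toy_networks <- function() {
  cyan <- locomotion_network(data.frame(
    source = c("M", "P", "M", "P"), target = c("C", "C", "P", "M"),
    weight = 1, channel = "chem"))

  fib_mats <- list(golden = matrix(c(1, 1, 1, 0), 2, byrow = TRUE),
                   nested33 = matrix(c(1, 8, 1, 0), 2, byrow = TRUE),
                   integer2 = matrix(c(1, 2, 1, 0), 2, byrow = TRUE))
  fib <- lapply(fib_mats, function(m) {
    dimnames(m) <- list(c("a", "b"), c("a", "b"))
    list(matrix = m, network = network_from_adjacency(m, channel = "chem"))
  })

  counter_dir <- locomotion_network(data.frame(
    source = c("r", "r", "u", "u", "v"),
    target = c("u", "v", "p", "q", "p"),
    weight = 1, channel = "chem"))

  tri <- c("x1", "x2", "x3"); sq <- c("y1", "y2", "y3", "y4")
  counter_und <- locomotion_network(data.frame(
    source = c(tri, sq),
    target = c(tri[c(2, 3, 1)], sq[c(2, 3, 4, 1)]),
    weight = 1, channel = "gap"))

  layer_example <- locomotion_network(data.frame(
    source = c("M", "P", "X", "X"), target = c("C", "C", "M", "P"),
    weight = c(1, 2, 3, 4), channel = "chem"))

  list(cyan = cyan, fibonacci_bases = fib,
       counterexample_directed = counter_dir,
       counterexample_undirected = counter_und,
       layer_example = layer_example)
}

#' Perturb edge weights
#'
#' Adds an independent zero-mean Gaussian of standard deviation `sd` to every
#' nonzero weight (gap pairs jointly, keeping the channel symmetric). The
#' zero pattern is preserved: perturbed weights are clipped at a small
#' positive floor rather than allowed to change sign, since a negative
#' conductance is unphysical (`floor = NULL` disables clipping).
#'
#' @param net a `locomotion_network`
#' @param sd perturbation standard deviation (weight units)
#' @param seed integer seed
#' @param floor smallest allowed weight (default 1e-6)
#' @return perturbed `locomotion_network`
#' @export
perturb_weights <- function(net, sd, seed = 1L, floor = 1e-6) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(net)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  e <- net$edges
  chem_idx <- which(e$channel == "chem")
  e$weight[chem_idx] <- e$weight[chem_idx] + stats::rnorm(length(chem_idx), 0, sd)
  gap_idx <- which(e$channel == "gap")
  if (length(gap_idx)) {
    a <- pmin(e$source[gap_idx], e$target[gap_idx])
    b <- pmax(e$source[gap_idx], e$target[gap_idx])
    key <- paste(a, b)
    for (k in unique(key)) {
      e$weight[gap_idx[key == k]] <- e$weight[gap_idx[key == k]][1] + stats::rnorm(1, 0, sd)
    }
  }
  if (!is.null(floor)) e$weight <- pmax(e$weight, floor)
  if (any(e$weight <= 0)) stop("perturbation produced non-positive weights; set a floor")
  locomotion_network(e, nodes = net$nodes)
}

#' Simulation-test protocols
#'
#' Bundles the run configuration of the three simulation tests:
#' * test 1 (free running): no stimulus; initial voltages
#'   N(V_rest, `init_sd_V`) and, for chem2, synaptic variables
#'   N(s_eq, `init_sd_s`).
#' * test 2 (driven below instability): constant drive at 90% of the
#'   instability threshold `I_star` plus a sinusoid of amplitude 5% of
#'   `I_star`, 2 Hz into interneuron targets and 1 Hz into motor-neuron
#'   targets; gap networks get a second motor-neuron drive group (they
#'   globally synchronize under a single drive).
#' * test 3 (weight robustness): 0.1 pA constant + 0.5 pA sinusoid
#'   (2 Hz interneurons / 1 Hz motor neurons) + 0.01 pA noise band (max
#'   amplitude 0.61 pA), V(0) = -35 mV, s(0) = s_eq, a weight-perturbation
#'   sd sweep with replicates to average.
#'
#' @param test_id 1, 2 or 3
#' @param net a `locomotion_network`
#' @param coloring fiber `coloring` (stimuli are balanced against it)
#' @param params a `model_params`
#' @param targets stimulated nodes (whole cells); defaults to all interneuron
#'   pairs for tests 2-3
#' @param I_star instability threshold (A) for test 2; required for chem
#'   models unless supplied, defaulted for gap models (stable at any drive)
#' @param overrides named list overriding any generated field
#' @return a `protocol` list: `stimulus`, `init` (function(seed) -> state),
#'   `duration`, `dt`, and for test 3 `sd_sweep`, `replicates`
#' @export
simulation_protocol <- function(test_id, net, coloring, params,
                                targets = NULL, I_star = NULL,
                                overrides = list()) {
  if (!test_id %in% 1:3) stop("unknown test id: ", test_id)
  nm <- network_nodes(net)
  roles <- stats::setNames(net$nodes$role, net$nodes$name)
  if (is.null(targets) && test_id >= 2) {
    targets <- nm[roles[nm] == "interneuron"]
    if (!length(targets)) stop("no interneuron targets available; supply targets")
  }
  proto <- list(test = test_id, duration = 5, dt = 1e-4, params = params)

  if (test_id == 1) {
    sd_V <- overrides$init_sd_V %||% 0.1e-3     # volts
    sd_s <- overrides$init_sd_s %||% 0.1
    proto$stimulus <- NULL
    proto$init <- function(seed) {
      set.seed(seed)
      V <- stats::rnorm(length(nm), params$V_rest, sd_V)
      if (params$model == "chem2") {
        s <- pmin(pmax(stats::rnorm(length(nm), params$s_eq, sd_s), 0), 1)
        c(V, s)
      } else V
    }
  } else if (test_id == 2) {
    if (is.null(I_star)) {
      if (params$model == "gap") I_star <- overrides$I_star_gap %||% 10e-12
      else stop("test 2 needs the instability threshold I_star for chem models")
    }
    freq <- ifelse(roles[targets] == "interneuron", 2, 1)
    names(freq) <- targets
    if (params$model == "gap") {
      ## add one motor-neuron cell as a second, slower drive group
      motor_cells <- Filter(function(cell) all(roles[cell] == "motorneuron"),
                            coloring_cells(coloring))
      if (length(motor_cells) && !any(unlist(motor_cells) %in% targets)) {
        second <- motor_cells[[1]]
        targets <- c(targets, second)
        freq <- c(freq, stats::setNames(rep(1, length(second)), second))
      }
    }
    proto$stimulus <- make_stimulus(net, coloring, targets,
                                    I_drive = 0.9 * I_star,
                                    I_osc = 0.05 * I_star,
                                    freq = freq, noise_amp = 0,
                                    seed = overrides$seed %||% 1L)
    proto$init <- function(seed) NULL            # equilibrium defaults
  } else {
    freq <- ifelse(roles[targets] == "interneuron", 2, 1)
    names(freq) <- targets
    proto$stimulus <- make_stimulus(net, coloring, targets,
                                    I_drive = 0.1e-12, I_osc = 0.5e-12,
                                    freq = freq, noise_amp = 0.01e-12,
                                    seed = overrides$seed %||% 1L)
    proto$init <- function(seed) {
      V <- rep(-35e-3, length(nm))
      if (params$model == "chem2") c(V, rep(params$s_eq, length(nm))) else V
    }
    proto$sd_sweep <- overrides$sd_sweep %||% seq(0, 0.1, by = 0.01)
    proto$replicates <- overrides$replicates %||% 10L
  }
  for (f in setdiff(names(overrides),
                    c("init_sd_V", "init_sd_s", "I_star_gap", "seed",
                      "sd_sweep", "replicates"))) {
    proto[[f]] <- overrides[[f]]
  }
  structure(proto, class = "protocol")
}
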