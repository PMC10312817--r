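## End-to-end orchestration: partition -> blocks -> stability -> simulate ->
## synchrony, with artifacts written to disk and a run report collecting
## them. All randomness is funnelled through one master seed, expanded
## deterministically per stage.

#' Run the structure-to-dynamics pipeline
#'
#' Executes the requested stages in dependency order on one network.
#' Identical configuration and seed reproduce identical reports (noise-free
#' stages bit-identically). A stage failure marks the stage and skips its
#' dependents.
#'
#' @param config either a path to a YAML file or a list with fields:
#'   `network` (a `locomotion_network` or a TSV path), `stages` (subset of
#'   `c("partition", "blocks", "stability", "simulate", "synchrony")`),
#'   `model` (`"gap"`, `"chem1"`, `"chem2"`), `channel`, `weighted`,
#'   `targets`, `protocol` (1, 2 or 3), `duration`, `dt`, `I_max`, `seed`,
#'   `out_dir` (artifacts are written there when set)
#' @return a `run_report`: config snapshot, per-stage outputs, seeds,
#'   artifact paths and package version
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  cfg$stages <- cfg$stages %||% c("partition", "blocks", "stability",
                                  "simulate", "synchrony")
  cfg$channel <- cfg$channel %||% "both"
  cfg$weighted <- cfg$weighted %||% TRUE
  cfg$model <- cfg$model %||% "chem1"
  cfg$protocol <- cfg$protocol %||% 2
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  net <- cfg$network
  if (is.character(net)) net <- read_network(net)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ## per-stage seeds derived from the master seed
  stage_seed <- function(k) (cfg$seed * 101L + k) %% .Machine$integer.max

  report <- list(config = cfg[setdiff(names(cfg), "network")],
                 seed = cfg$seed, stages = list(), artifacts = character(0),
                 version = as.character(utils::packageVersion("fibersync")))
  failed <- FALSE
  run_stage <- function(name, fn) {
    if (failed || !name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     message = conditionMessage(res))
      failed <<- TRUE
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  coloring <- NULL; params <- NULL; stim <- NULL; sim <- NULL; thr <- NULL

  run_stage("partition", function() {
    coloring <<- minimal_balanced_coloring(net, cfg$channel, cfg$weighted)
    out <- list(n_cells = n_cells(coloring), cells = coloring_cells(coloring))
    if (isTRUE(cfg$orbits)) {
      orb <- orbit_coloring(net, cfg$channel, cfg$weighted)
      out$n_orbit_cells <- n_cells(orb)
      out$orbit_cells <- coloring_cells(orb)
    }
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "coloring.json")
      write_coloring(coloring, p)
      report$artifacts <<- c(report$artifacts, p)
    }
    out
  })

  run_stage("blocks", function() {
    blocks <- lapply(seq_len(n_cells(coloring)), function(k) {
      cls <- classify_fbb(net, coloring, k)
      list(cell = k, fiber = cls$fbb$fiber, n = cls$numbers$n,
           ell_trails = cls$numbers$ell_trails,
           ell_regulators = cls$numbers$ell_regulators,
           fibonacci = cls$numbers$fibonacci,
           composite = cls$fbb$composite,
           expression = format(cls$expression))
    })
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "blocks.json")
      jsonlite::write_json(blocks, p, auto_unbox = TRUE, digits = NA)
      report$artifacts <<- c(report$artifacts, p)
    }
    list(blocks = blocks)
  })

  run_stage("stability", function() {
    params <<- model_params(cfg$model)
    targets <- cfg$targets %||% {
      roles <- stats::setNames(net$nodes$role, net$nodes$name)
      network_nodes(net)[roles == "interneuron"]
    }
    rep_ <- instability_threshold(net, params, targets,
                                  I_max = cfg$I_max %||% 500e-12,
                                  step = cfg$step %||% 0.1e-12)
    thr <<- rep_
    list(threshold = rep_$threshold, targets = targets)
  })

  run_stage("simulate", function() {
    if (is.null(params)) params <<- model_params(cfg$model)
    I_star <- if (!is.null(thr) && !is.na(thr$threshold)) thr$threshold else NULL
    proto <- simulation_protocol(cfg$protocol, net, coloring, params,
                                 targets = cfg$targets,
                                 I_star = cfg$I_star %||% I_star,
                                 overrides = cfg$overrides %||% list())
    dur <- cfg$duration %||% proto$duration
    sim <<- simulate_network(net, params, proto$stimulus,
                             init = proto$init(stage_seed(4L)),
                             duration = dur, dt = cfg$dt %||% proto$dt,
                             seed = stage_seed(5L))
    list(duration = dur, model = params$model)
  })

  run_stage("synchrony", function() {
    win <- min(1, max(sim$time) / 2)
    los <- los_matrix(sim, window = win)
    ideal <- ideal_matrix(coloring, order = rownames(los))
    score <- agreement_score(los, ideal)
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, "los.csv")
      utils::write.csv(format(unclass(los), digits = 17), p)
      report$artifacts <<- c(report$artifacts, p)
    }
    list(agreement = score, los = los)
  })

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d, fibersync %s)\n", x$seed, x$version))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    extra <- if (st$status == "failed") paste(" -", st$message)
    else if (nm == "partition") sprintf(" - %d cells", st$n_cells)
    else if (nm == "stability") sprintf(" - threshold %s",
                                        format(st$threshold))
    else if (nm == "synchrony") sprintf(" - agreement %.4g", st$agreement)
    else ""
    cat(sprintf("  %-10s %s%s\n", nm, st$status, extra))
  }
  invisible(x)
}

#' Write a coloring as JSON
#' @param coloring a `coloring`
#' @param path output path
#' @export
write_coloring <- function(coloring, path) {
  cells <- coloring_cells(coloring)
  names(cells) <- as.character(seq_along(cells) - 1L)
  jsonlite::write_json(list(channel = attr(coloring, "channel"),
                            weighted = attr(coloring, "weighted"),
                            cells = cells),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a coloring written by [write_coloring()]
#' @param path JSON path
#' @param net the network the coloring belongs to
#' @return a `coloring`
#' @export
read_coloring <- function(path, net) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- lapply(obj$cells, as.character)
  names(cells) <- NULL
  as_coloring(cells, net, channel = obj$channel, weighted = obj$weighted)
}

#' Summarize several run reports as a long table
#'
#' @param reports list of `run_report`s (or a single one)
#' @return data.frame with one row per report: model, network label, edge
#'   type, fiber cells, instability threshold (pA) and agreement score
#' @export
summarize_runs <- function(reports) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report")
  rows <- lapply(reports, function(r) {
    data.frame(
      model = r$config$model %||% NA_character_,
      network = r$config$label %||% NA_character_,
      edge_type = if (isTRUE(r$config$weighted)) "integer" else "binary",
      n_cells = r$stages$partition$n_cells %||% NA_integer_,
      threshold_pA = if (!is.null(r$stages$stability$threshold))
        r$stages$stability$threshold * 1e12 else NA_real_,
      agreement = r$stages$synchrony$agreement %||% NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
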