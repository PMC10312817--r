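## Linear stability at the threshold-voltage equilibrium.
##
## The gap Jacobian is -alpha_leak I - alpha_gap L (L the gap Laplacian),
## independent of the drive: the gap model is stable under any external
## stimulus. The chemical Jacobians are obtained by differentiating the
## model equations at V = V_threshold (sigmoid = 1/2, sigmoid' = gamma/4,
## s = s_eq); the drive enters only through V_threshold, so the leading
## eigenvalue moves linearly with the injected current and can cross zero.

#' Jacobian of an admissible model at equilibrium
#'
#' @param net a `locomotion_network`
#' @param params a `model_params`
#' @param I_drive constant drive (A) used for the equilibrium solve
#' @return dense Jacobian matrix (n x n for gap/chem1, 2n x 2n for chem2),
#'   with named rows/columns (`V:` and `s:` prefixes for chem2)
#' @export
jacobian_matrix <- function(net, params, I_drive = 0) {
  nm <- network_nodes(net)
  n <- length(nm)
  if (params$model == "gap") {
    W <- adjacency_matrix(net, "gap")
    L <- diag(colSums(W), n) - W           # symmetric: colSums == rowSums
    J <- -params$alpha_leak * diag(n) - params$alpha_gap * L
    dimnames(J) <- list(nm, nm)
    return(J)
  }
  Vthr <- threshold_voltages(net, params, I_drive)
  A <- adjacency_matrix(net, "chem")       # A[j, i] = weight j -> i
  Vs <- stats::setNames(net$nodes$Vs, net$nodes$name)[nm]
  gamma <- params$gamma
  phi <- 0.5
  dphi <- gamma * phi * (1 - phi)          # gamma / 4
  if (params$model == "chem1") {
    ## dVdot_i/dV_j = delta_ij (-alpha_leak - alpha_chem sum_k A[k,i] phi)
    ##               - alpha_chem A[j,i] phi' (V_i - Vs_j)
    D <- -params$alpha_leak - params$alpha_chem * phi * colSums(A)
    M <- -params$alpha_chem * dphi * t(A) *
      outer(Vthr, Vs, `-`)                 # [i, j] = (V_i - Vs_j)
    J <- M
    diag(J) <- diag(J) + D
    dimnames(J) <- list(nm, nm)
    return(J)
  }
  ## chem2: state (V, s)
  s_eq <- params$s_eq
  JVV <- diag(-params$alpha_leak - params$alpha_chem * s_eq * colSums(A), n)
  JVs <- -params$alpha_chem * t(A) * outer(Vthr, Vs, `-`)
  JsV <- diag(params$a_r * dphi * (1 - s_eq), n)
  Jss <- diag(-params$a_r * phi - params$a_d, n)
  J <- rbind(cbind(JVV, JVs), cbind(JsV, Jss))
  lab <- c(paste0("V:", nm), paste0("s:", nm))
  dimnames(J) <- list(lab, lab)
  J
}

## finite-difference Jacobian of the rhs at the equilibrium; test oracle
fd_jacobian <- function(net, params, I_drive = 0, h = 1e-8) {
  nm <- network_nodes(net)
  Ic <- expand_node_vector(I_drive, nm)
  Vthr <- threshold_voltages(net, params, Ic)
  cache <- rhs_cache(net, params, Vthr, Ic)
  n <- length(nm)
  state <- if (params$model == "chem2") c(Vthr, rep(params$s_eq, n)) else unname(Vthr)
  m <- length(state)
  J <- matrix(0, m, m)
  for (j in seq_len(m)) {
    hj <- h * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + hj
    dn <- state; dn[j] <- dn[j] - hj
    J[, j] <- (rhs_eval(up, Ic, cache) - rhs_eval(dn, Ic, cache)) / (2 * hj)
  }
  J
}

#' Instability threshold of the external drive
#'
#' Scans the constant drive on the target cells from 0 to `I_max` in steps of
#' `step` and bisects the first sign change of the largest real part of the
#' Jacobian spectrum down to `bisect_tol`. "Positive" means real part above
#' `eig_tol`. Gap models never destabilize (their Jacobian does not depend on
#' the drive) and report no threshold.
#'
#' @param net a `locomotion_network`
#' @param params a `model_params`
#' @param targets node names receiving the drive (should be whole fiber
#'   cells; each target receives the same current)
#' @param I_max scan ceiling (A), default 500 pA
#' @param step coarse scan step (A), default 0.1 pA
#' @param bisect_tol bisection resolution (A), default 0.01 pA
#' @param eig_tol positivity tolerance on the real part (1/s)
#' @return a `stability_report`: `threshold` (A, or NA if none up to
#'   `I_max`), `grid`, `max_real` per grid point, and the settings
#' @export
instability_threshold <- function(net, params, targets,
                                  I_max = 500e-12, step = 0.1e-12,
                                  bisect_tol = 0.01e-12, eig_tol = 1e-9) {
  nm <- network_nodes(net)
  unknown <- setdiff(targets, nm)
  if (length(unknown)) stop("unknown targets: ", paste(unknown, collapse = ", "))
  max_re <- function(I) {
    Iv <- stats::setNames(numeric(length(nm)), nm)
    Iv[targets] <- I
    max(Re(eigen(jacobian_matrix(net, params, Iv), only.values = TRUE)$values))
  }
  if (params$model == "gap") {
    lam <- max_re(0)
    return(structure(list(model = params$model, targets = targets,
                          threshold = NA_real_, I_max = I_max,
                          grid = 0, max_real = lam, eig_tol = eig_tol,
                          note = "gap Jacobian independent of external drive"),
                     class = "stability_report"))
  }
  grid <- seq(0, I_max, by = step)
  lo <- NA_real_; hi <- NA_real_
  vals <- numeric(0); scanned <- numeric(0)
  prev <- max_re(grid[1])
  vals[1] <- prev; scanned[1] <- grid[1]
  for (k in seq_along(grid)[-1]) {
    cur <- max_re(grid[k])
    vals[k] <- cur; scanned[k] <- grid[k]
    if (prev <= eig_tol && cur > eig_tol) {
      lo <- grid[k - 1]; hi <- grid[k]
      break
    }
    prev <- cur
  }
  threshold <- NA_real_
  if (!is.na(lo)) {
    while (hi - lo > bisect_tol) {
      mid <- (lo + hi) / 2
      if (max_re(mid) > eig_tol) hi <- mid else lo <- mid
    }
    threshold <- hi
  }
  structure(list(model = params$model, targets = targets,
                 threshold = threshold, I_max = I_max,
                 grid = scanned, max_real = vals, eig_tol = eig_tol),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  thr <- if (is.na(x$threshold)) sprintf("none up to %.3g pA", x$I_max * 1e12)
  else sprintf("%.4g pA", x$threshold * 1e12)
  cat(sprintf("stability_report (%s, targets %s): instability threshold %s\n",
              x$model, paste(x$targets, collapse = "+"), thr))
  invisible(x)
}
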