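#' Paired cellularity observations between two imaging time points
#'
#' @param N_start,N_end nodal cellularity fields in cell-fraction units, on
#'   the same mesh.
#' @param interval_days days between the two acquisitions (> 0).
#' @param pair_label one of `"T01"`, `"T12"`, `"T02"` (or any label).
#' @param roi_nodes integer indices of the nodes entering the misfit; defaults
#'   to all nodes where either field is positive (union of the two tumor
#'   extents, so residual predicted mass outside a shrinking tumor is
#'   penalized).
#' @return object of class `observation_pair`.
#' @export
observation_pair <- function(N_start, N_end, interval_days, pair_label = "T01",
                             roi_nodes = NULL) {
  stopifnot(length(N_start) == length(N_end), interval_days > 0)
  if (is.null(roi_nodes))
    roi_nodes <- which(N_start > 0 | N_end > 0)
  structure(list(N_start = N_start, N_end = N_end,
                 interval_days = interval_days, pair_label = pair_label,
                 roi_nodes = as.integer(roi_nodes)),
            class = "observation_pair")
}

# Closed-form logistic initialization: at each node with usable signal at
# both time points, invert the logistic flow (diffusion ignored) for a nodal
# rate, then take each region's median (robust to noisy voxels near 0 or
# capacity, whose inverted rates explode). A node that starts with signal but
# ends below `floor` is a detection-censored observation: the inversion is
# evaluated at the floor itself, giving the least-negative rate consistent
# with the data (the misfit is flat below it, so the estimate stays at this
# bound rather than at an arbitrary box constraint). Nodes with no signal at
# the start carry no information and are skipped; regions with no usable node
# start at 0.
logistic_init_k <- function(pair, mesh, partition, bounds, floor = 1e-4) {
  Ns <- pmin(pmax(pair$N_start, 0), 1 - 1e-12)
  Ne <- pmin(pmax(pair$N_end, floor), 1 - 1e-12)
  ok <- Ns > floor
  k_node <- rep(NA_real_, length(Ns))
  k_node[ok] <- (log(Ne[ok] / (1 - Ne[ok])) - log(Ns[ok] / (1 - Ns[ok]))) /
    pair$interval_days
  k0 <- numeric(partition$n_regions)
  for (r in seq_len(partition$n_regions)) {
    el <- partition$elements[partition$region_of_element == r]
    nodes <- unique(as.vector(mesh$triangles[el, , drop = FALSE]))
    v <- k_node[nodes]
    v <- v[is.finite(v)]
    k0[r] <- if (length(v)) stats::median(v) else 0
  }
  pmin(pmax(k0, bounds[1]), bounds[2])
}

# regional k -> per-element field (elements outside the partition get 0)
k_regions_to_elements <- function(k_regions, partition, n_elements) {
  k_elem <- numeric(n_elements)
  k_elem[partition$elements] <- k_regions[partition$region_of_element]
  k_elem
}

forward_for_pair <- function(k_regions, D0, pair, mesh, partition, params,
                             store = FALSE) {
  p <- params; p$D0 <- D0
  k_elem <- k_regions_to_elements(k_regions, partition, nrow(mesh$triangles))
  run_forward(pair$N_start, k_elem, mesh, p, pair$interval_days,
              record_days = c(0, pair$interval_days),
              store_trajectory = store)
}

#' Model-data misfit for one time-point pair
#'
#' Least-squares misfit `0.5 * sum((N_model(T) - N_end)^2)` over the ROI
#' nodes, with the model run forward from `N_start` over the pair interval in
#' cell-fraction units.
#'
#' @param k_regions proliferation rate per region, 1/day.
#' @param D0 global stress-free diffusion, mm^2/day.
#' @param pair an `observation_pair`.
#' @param mesh a `tri_mesh`.
#' @param partition a `region_partition`.
#' @param params a `model_params`.
#' @return scalar misfit.
#' @export
misfit <- function(k_regions, D0, pair, mesh, partition, params) {
  fw <- forward_for_pair(k_regions, D0, pair, mesh, partition, params)
  r <- fw$N[pair$roi_nodes, ncol(fw$N)] - pair$N_end[pair$roi_nodes]
  0.5 * sum(r^2)
}

#' Adjoint-state gradient of the misfit with respect to regional rates
#'
#' Differentiates the discrete operator-split scheme exactly (analytic
#' logistic flow, backward-Euler diffusion) with one backward sweep, holding
#' the per-step stress-damped diffusion field fixed. The gradient is exact
#' when the mechanics is decoupled (`gamma = 0`); with coupling on, the
#' neglected sensitivity of the diffusion field to the cell field introduces a
#' bounded approximation.
#'
#' @inheritParams misfit
#' @param forward optional stored forward run (from `run_forward(...,
#'   store_trajectory = TRUE)`); recomputed when missing.
#' @return gradient, one value per region.
#' @export
adjoint_gradient_k <- function(k_regions, D0, pair, mesh, partition, params,
                               forward = NULL) {
  if (is.null(forward))
    forward <- forward_for_pair(k_regions, D0, pair, mesh, partition, params,
                                store = TRUE)
  if (is.null(forward$trajectory)) stop("forward run has no stored trajectory")
  tr <- forward$trajectory
  ops <- fem_operators(mesh)
  dt <- params$dt
  nsteps <- tr$nsteps
  k_node <- tr$k_node

  lam <- numeric(ops$n)
  NT <- tr$N[, nsteps + 1]
  lam[pair$roi_nodes] <- NT[pair$roi_nodes] - pair$N_end[pair$roi_nodes]
  g_node <- numeric(ops$n)
  ea <- exp(k_node * dt)
  fac_env <- new.env(parent = emptyenv())
  for (s in nsteps:1) {
    fac <- diffusion_factor(ops, tr$D[, s], dt, fac_env)
    y <- as.vector(Matrix::solve(fac, lam))
    mu <- ops$mlump * y
    Nn <- tr$N[, s]
    w <- 1 + Nn * (ea - 1)
    g_node <- g_node + dt * Nn * (1 - Nn) * ea / w^2 * mu
    lam <- ea / w^2 * mu
  }
  Pn <- node_element_weights(mesh)
  g_elem <- as.vector(Matrix::crossprod(Pn, g_node))
  g_reg <- numeric(partition$n_regions)
  acc <- tapply(g_elem[partition$elements], partition$region_of_element, sum)
  g_reg[as.integer(names(acc))] <- acc
  g_reg
}

#' Forward finite-difference gradient of the misfit in D0
#'
#' Uses a 1 percent relative perturbation of `D0`; at `D0 = 0` an absolute
#' perturbation of 1e-6 mm^2/day is used instead.
#'
#' @inheritParams misfit
#' @param f0 optional precomputed `misfit(k_regions, D0, ...)`.
#' @return scalar gradient.
#' @export
fd_gradient_D0 <- function(k_regions, D0, pair, mesh, partition, params,
                           f0 = NULL) {
  stopifnot(D0 >= 0)
  h <- if (D0 > 0) 0.01 * D0 else 1e-6
  if (is.null(f0)) f0 <- misfit(k_regions, D0, pair, mesh, partition, params)
  f1 <- misfit(k_regions, D0 + h, pair, mesh, partition, params)
  (f1 - f0) / h
}

#' Estimate regional proliferation rates and global diffusion for a pair
#'
#' Bound-constrained quasi-Newton (L-BFGS-B) minimization of the model-data
#' misfit over the regional proliferation rates (adjoint-state gradients) and
#' the global diffusion coefficient (1 percent forward-difference gradient).
#'
#' @param pair an `observation_pair`.
#' @param mesh a `tri_mesh`.
#' @param partition a `region_partition`.
#' @param params a `model_params`.
#' @param init list with `k` (scalar or per-region; by default a closed-form
#'   logistic inversion of the paired observations, diffusion ignored) and
#'   `D0` (default 1e-2 mm^2/day).
#' @param bounds list with `k = c(lo, hi)` (default `c(-1, 1)` 1/day) and
#'   `D0 = c(lo, hi)` (default `c(0, 1)` mm^2/day).
#' @param control passed to [stats::optim()]; the defaults (`factr = 1e7`,
#'   `pgtol = 1e-8`, `maxit = 500`) stop well below a 1e-6 relative objective
#'   decrease, with a projected-gradient tolerance of 1e-8.
#' @param seed unused (the estimator is deterministic); kept for interface
#'   stability.
#' @return object of class `prolif_fit` with `k_regions` (1/day), `D0_hat`
#'   (mm^2/day), `objective`, `objective_trace`, `converged`, `n_iterations`.
#' @export
estimate_proliferation <- function(pair, mesh, partition, params,
                                   init = list(), bounds = list(),
                                   control = list(), seed = 0L) {
  nr <- partition$n_regions
  bk <- if (is.null(bounds$k)) c(-1, 1) else bounds$k
  bD <- if (is.null(bounds$D0)) c(0, 1) else bounds$D0
  k0 <- if (is.null(init$k)) logistic_init_k(pair, mesh, partition, bk)
        else rep(init$k, length.out = nr)
  D00 <- if (is.null(init$D0)) 1e-2 else init$D0
  stopifnot(all(k0 >= bk[1] & k0 <= bk[2]), D00 >= bD[1], D00 <= bD[2])
  ctrl <- utils::modifyList(
    list(maxit = 500L, factr = 1e7, pgtol = 1e-8),
    control)

  cache <- new.env(parent = emptyenv())
  cache$trace <- numeric(0)
  run_fw <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      fw <- forward_for_pair(par[seq_len(nr)], par[nr + 1], pair, mesh,
                             partition, params, store = TRUE)
      r <- fw$N[pair$roi_nodes, ncol(fw$N)] - pair$N_end[pair$roi_nodes]
      cache$key <- key
      cache$fw <- fw
      cache$J <- 0.5 * sum(r^2)
    }
    cache
  }
  fn <- function(par) {
    cc <- run_fw(par)
    cache$trace <- c(cache$trace, cc$J)
    cc$J
  }
  gr <- function(par) {
    cc <- run_fw(par)
    gk <- adjoint_gradient_k(par[seq_len(nr)], par[nr + 1], pair, mesh,
                             partition, params, forward = cc$fw)
    gD <- fd_gradient_D0(par[seq_len(nr)], par[nr + 1], pair, mesh,
                         partition, params, f0 = cc$J)
    c(gk, gD)
  }
  fit <- stats::optim(c(k0, D00), fn, gr, method = "L-BFGS-B",
                      lower = c(rep(bk[1], nr), bD[1]),
                      upper = c(rep(bk[2], nr), bD[2]),
                      control = ctrl)
  structure(list(
    k_regions = fit$par[seq_len(nr)],
    D0_hat = fit$par[nr + 1],
    objective = fit$value,
    objective_trace = cummin(cache$trace),
    converged = fit$convergence == 0L,
    n_iterations = unname(fit$counts["function"]),
    message = fit$message,
    pair_label = pair$pair_label,
    partition = partition
  ), class = "prolif_fit")
}

#' @export
print.prolif_fit <- function(x, ...) {
  cat(sprintf(
    "<prolif_fit> %s: %d regions, k in [%.3f, %.3f] /day, D0 = %.4g mm^2/day, J = %.3g (%s, %d evals)\n",
    x$pair_label, length(x$k_regions), min(x$k_regions), max(x$k_regions),
    x$D0_hat, x$objective, if (x$converged) "converged" else "not converged",
    x$n_iterations))
  invisible(x)
}
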