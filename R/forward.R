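#' Biophysical model parameters
#'
#' Bundles the global parameters of the mechanically coupled reaction-diffusion
#' growth model: `D0` the stress-free tumor cell diffusion (mm^2/day), `gamma`
#' the stress-diffusion coupling (1/kPa), `lam` the cell-density force coupling
#' in the elasticity equation, `E` Young's modulus (kPa, scalar or per
#' element), `nu` Poisson's ratio, `theta` the cellular carrying capacity
#' (cells/voxel) and `dt` the time step in days.
#'
#' @param D0 stress-free diffusion, mm^2/day.
#' @param gamma stress-damping coupling constant, 1/kPa. `gamma = 0` decouples
#'   the mechanics from the cell diffusion.
#' @param lam expansive force coupling per unit cell fraction gradient.
#' @param E Young's modulus, kPa (scalar or one value per element).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param theta carrying capacity, cells/voxel (may be `NULL` when working in
#'   cell-fraction units).
#' @param dt time step, days.
#' @return object of class `model_params`.
#' @export
model_params <- function(D0 = 1e-2, gamma = 1.0, lam = 1e-3, E = 2.0,
                         nu = 0.45, theta = NULL, dt = 1) {
  stopifnot(D0 >= 0, gamma >= 0, all(E > 0), nu > 0, nu < 0.5, dt > 0)
  structure(list(D0 = D0, gamma = gamma, lam = lam, E = E, nu = nu,
                 theta = theta, dt = dt), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> D0=%g mm^2/day, gamma=%g, lambda=%g, E=%g kPa, nu=%g, dt=%g day\n",
    x$D0, x$gamma, x$lam, mean(x$E), x$nu, x$dt))
  invisible(x)
}

# Scalar diffusion/mass operators on the P1 mesh.
# Lumped mass (area/3 per adjacent element) keeps the reaction pointwise and
# the adjoint diagonal; the stiffness is stored as per-element triplets so
# K(D) assembles in one vectorized sparseMatrix call per time step.
fem_operators <- function(mesh) {
  if (!is.null(mesh$cache) && !is.null(mesh$cache$ops)) return(mesh$cache$ops)
  ops <- fem_operators_impl(mesh)
  if (!is.null(mesh$cache)) mesh$cache$ops <- ops
  ops
}

fem_operators_impl <- function(mesh) {
  tris <- mesh$triangles
  m <- nrow(tris); n <- nrow(mesh$nodes)
  mlump <- as.vector(Matrix::sparseMatrix(
    i = as.vector(tris), j = rep(1L, 3L * m),
    x = rep(mesh$areas / 3, times = 3), dims = c(n, 1L)))
  # per-element 3x3 stiffness without D: A * (b_i b_j + c_i c_j), grouped by
  # element so x = rep(D, each = 9) * kbase lines up
  li <- rep(1:3, times = 3)
  lj <- rep(1:3, each = 3)
  i9 <- as.vector(t(tris[, li]))   # element-major ordering
  j9 <- as.vector(t(tris[, lj]))
  kb <- matrix(0, m, 9)
  for (q in 1:9) {
    kb[, q] <- mesh$areas * (mesh$grad_b[, li[q]] * mesh$grad_b[, lj[q]] +
                             mesh$grad_c[, li[q]] * mesh$grad_c[, lj[q]])
  }
  kbase <- as.vector(t(kb))
  ops <- list(n = n, m = m, mlump = mlump, i9 = i9, j9 = j9, kbase = kbase)

  # symmetric template of A = M + dt K and a scatter matrix mapping the
  # upper-triangle element triplets straight into the template's x slot, so
  # per-step assembly is a single sparse matrix-vector product
  K1 <- Matrix::sparseMatrix(i = i9, j = j9, x = kbase, dims = c(n, n))
  As <- Matrix::forceSymmetric(Matrix::Diagonal(x = mlump) + K1)
  colptr <- As@p
  keyA <- (rep(seq_len(n), times = diff(colptr)) - 1) * n + (As@i + 1)
  sel <- which(i9 <= j9)
  keyT <- (j9[sel] - 1) * n + i9[sel]
  pos <- match(keyT, keyA)
  ops$upper_sel <- sel
  ops$scatter <- Matrix::sparseMatrix(i = pos, j = seq_along(sel), x = 1,
                                      dims = c(length(As@x), length(sel)))
  mass_x <- numeric(length(As@x))
  dkey <- (seq_len(n) - 1) * n + seq_len(n)
  mass_x[match(dkey, keyA)] <- mlump
  ops$template <- As
  ops$mass_x <- mass_x
  ops
}

assemble_stiffness <- function(ops, D_elem) {
  Matrix::sparseMatrix(i = ops$i9, j = ops$j9,
                       x = rep(D_elem, each = 9L) * ops$kbase,
                       dims = c(ops$n, ops$n))
}

# A = M + dt K(D) assembled in-place on the cached symmetric template
assemble_system <- function(ops, D_elem, dt) {
  vals <- (rep(D_elem, each = 9L) * ops$kbase)[ops$upper_sel]
  A <- ops$template
  A@x <- ops$mass_x + dt * as.vector(ops$scatter %*% vals)
  A
}

# Plane-strain linear elasticity operator with u = 0 on the mesh boundary.
# Factorized once per (mesh, E, nu); only the right-hand side changes as the
# cell field evolves.
elasticity_operator <- function(mesh, params) {
  key <- paste(format(c(params$E, params$nu), digits = 15), collapse = ",")
  if (!is.null(mesh$cache) && identical(mesh$cache$elast_key, key))
    return(mesh$cache$elast_op)
  op <- elasticity_operator_impl(mesh, params)
  if (!is.null(mesh$cache)) {
    mesh$cache$elast_key <- key
    mesh$cache$elast_op <- op
  }
  op
}

elasticity_operator_impl <- function(mesh, params) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  E <- if (length(params$E) == 1L) rep(params$E, m) else params$E
  stopifnot(length(E) == m)
  nu <- params$nu
  d11 <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  d12 <- E * nu / ((1 + nu) * (1 - 2 * nu))
  d33 <- E / (2 * (1 + nu))
  b <- mesh$grad_b; cc <- mesh$grad_c; A <- mesh$areas
  tris <- mesh$triangles
  ii <- jj <- xx <- vector("list", 36)
  q <- 0
  for (a in 1:3) for (bb_ in 1:3) {
    ga <- tris[, a]; gb <- tris[, bb_]
    kxx <- A * (d11 * b[, a] * b[, bb_] + d33 * cc[, a] * cc[, bb_])
    kxy <- A * (d12 * b[, a] * cc[, bb_] + d33 * cc[, a] * b[, bb_])
    kyx <- A * (d12 * cc[, a] * b[, bb_] + d33 * b[, a] * cc[, bb_])
    kyy <- A * (d11 * cc[, a] * cc[, bb_] + d33 * b[, a] * b[, bb_])
    ii[[q + 1]] <- 2 * ga - 1; jj[[q + 1]] <- 2 * gb - 1; xx[[q + 1]] <- kxx
    ii[[q + 2]] <- 2 * ga - 1; jj[[q + 2]] <- 2 * gb;     xx[[q + 2]] <- kxy
    ii[[q + 3]] <- 2 * ga;     jj[[q + 3]] <- 2 * gb - 1; xx[[q + 3]] <- kyx
    ii[[q + 4]] <- 2 * ga;     jj[[q + 4]] <- 2 * gb;     xx[[q + 4]] <- kyy
    q <- q + 4
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(2 * n, 2 * n))
  fixed <- sort(c(2 * mesh$boundary_nodes - 1, 2 * mesh$boundary_nodes))
  free <- setdiff(seq_len(2 * n), fixed)
  if (length(free) == 0L) stop("singular elasticity system: no free degrees of freedom")
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  fac <- Matrix::Cholesky(Kff, LDL = FALSE)
  list(fac = fac, free = free, n = n,
       d11 = d11, d12 = d12, d33 = d33, nu = nu)
}

#' Solve quasi-static tissue elasticity for a given cell field
#'
#' Solves the plane-strain linear elastic equilibrium driven by the gradient of
#' the tumor cell field (an expansive body force proportional to `lam`), with
#' zero displacement on the outer mesh boundary, and returns element stresses
#' and von Mises stress.
#'
#' @param mesh a `tri_mesh`.
#' @param N_field nodal cell field (cell-fraction units).
#' @param params a `model_params`.
#' @param op optional cached operator from a previous call (internal reuse).
#' @return object of class `mech_state`: `displacement` (n x 2, mm), `stress`
#'   (m x 3: sigma_xx, sigma_yy, sigma_xy, kPa), `von_mises` (per element).
#' @export
solve_elasticity <- function(mesh, N_field, params, op = NULL) {
  stopifnot(length(N_field) == nrow(mesh$nodes))
  if (is.null(op)) op <- elasticity_operator(mesh, params)
  tris <- mesh$triangles; m <- nrow(tris); n <- nrow(mesh$nodes)
  # element-wise gradient of N
  gNx <- rowSums(mesh$grad_b * matrix(N_field[tris], m, 3))
  gNy <- rowSums(mesh$grad_c * matrix(N_field[tris], m, 3))
  # weak form a(u, v) = -lambda * integral grad(N) . v
  rhs <- numeric(2 * n)
  contrib_x <- -params$lam * gNx * mesh$areas / 3
  contrib_y <- -params$lam * gNy * mesh$areas / 3
  for (a in 1:3) {
    rhs_idx <- 2 * tris[, a] - 1
    rhs[rhs_idx] <- rhs[rhs_idx] + contrib_x
    rhs[rhs_idx + 1] <- rhs[rhs_idx + 1] + contrib_y
  }
  u <- numeric(2 * n)
  u[op$free] <- as.vector(Matrix::solve(op$fac, rhs[op$free]))
  ux <- u[seq(1, 2 * n, by = 2)]; uy <- u[seq(2, 2 * n, by = 2)]
  exx <- rowSums(mesh$grad_b * matrix(ux[tris], m, 3))
  eyy <- rowSums(mesh$grad_c * matrix(uy[tris], m, 3))
  gxy <- rowSums(mesh$grad_c * matrix(ux[tris], m, 3)) +
         rowSums(mesh$grad_b * matrix(uy[tris], m, 3))
  sxx <- op$d11 * exx + op$d12 * eyy
  syy <- op$d12 * exx + op$d11 * eyy
  sxy <- op$d33 * gxy
  vm <- von_mises_plane_strain(sxx, syy, sxy, op$nu)
  structure(list(displacement = cbind(ux, uy),
                 stress = cbind(sigma_xx = sxx, sigma_yy = syy, sigma_xy = sxy),
                 von_mises = vm), class = "mech_state")
}

#' von Mises stress under plane strain
#'
#' Uses the plane-strain out-of-plane stress `sigma_zz = nu * (sigma_xx +
#' sigma_yy)` in the full 3D distortional stress formula.
#'
#' @param sigma_xx,sigma_yy,sigma_xy in-plane stress components.
#' @param nu Poisson's ratio.
#' @return von Mises stress, same shape as the inputs.
#' @export
von_mises_plane_strain <- function(sigma_xx, sigma_yy, sigma_xy, nu) {
  szz <- nu * (sigma_xx + sigma_yy)
  sqrt(0.5 * ((sigma_xx - sigma_yy)^2 + (sigma_yy - szz)^2 +
              (szz - sigma_xx)^2) + 3 * sigma_xy^2)
}

#' Stress-damped cell diffusion
#'
#' `D = D0 * exp(-gamma * sigma_vm)` per element.
#'
#' @param D0 stress-free diffusion, mm^2/day.
#' @param gamma coupling constant.
#' @param von_mises_field per-element von Mises stress.
#' @return per-element diffusion coefficients in (0, D0].
#' @export
damped_diffusion <- function(D0, gamma, von_mises_field) {
  stopifnot(D0 >= 0, gamma >= 0)
  D0 * exp(-gamma * von_mises_field)
}

# One operator-split time step in cell-fraction units (theta = 1):
#   reaction: analytic logistic flow at the current N with nodal rate k,
#   diffusion: backward Euler on the lumped-mass FEM system, natural
#   (no-flux) boundary condition.
step_cell <- function(N, k_node, D_elem, ops, dt, fac_env = NULL) {
  ea <- exp(k_node * dt)
  w <- 1 + N * (ea - 1)
  Nstar <- N * ea / w
  fac <- diffusion_factor(ops, D_elem, dt, fac_env)
  as.vector(Matrix::solve(fac, ops$mlump * Nstar))
}

# Cholesky factor of M + dt K(D); the symbolic analysis is reused across time
# steps through fac_env since the sparsity pattern never changes.
diffusion_factor <- function(ops, D_elem, dt, fac_env = NULL) {
  A <- assemble_system(ops, D_elem, dt)
  if (is.null(fac_env)) return(Matrix::Cholesky(A, LDL = FALSE))
  if (is.null(fac_env$ch)) fac_env$ch <- Matrix::Cholesky(A, LDL = FALSE)
  else fac_env$ch <- Matrix::update(fac_env$ch, A)
  fac_env$ch
}

#' Advance the cell field by one time step
#'
#' Operator-split update: the logistic reaction is advanced with its analytic
#' flow evaluated at the current field, then diffusion is advanced implicitly
#' (backward Euler on the FEM system) under a no-flux boundary condition.
#'
#' @param N nodal cell field, cell-fraction units in `[0, 1]`.
#' @param k_field per-element proliferation rates, 1/day.
#' @param D_field per-element diffusion coefficients, mm^2/day.
#' @param mesh a `tri_mesh`.
#' @param params a `model_params` (supplies `dt`).
#' @return the nodal field after `dt` days.
#' @export
step_cell_state <- function(N, k_field, D_field, mesh, params) {
  ops <- fem_operators(mesh)
  k_node <- as.vector(node_element_weights(mesh) %*% k_field)
  step_cell(N, k_node, D_field, ops, params$dt)
}

#' Run the coupled growth model forward in time
#'
#' At every time step the elasticity problem is solved for the current cell
#' field, the von Mises stress damps the diffusion coefficient, and the
#' reaction-diffusion system is advanced by `dt`. With `gamma = 0` the
#' mechanics is bypassed and the trajectory equals a pure reaction-diffusion
#' run.
#'
#' @param N0 initial nodal cell field (cell-fraction units, in `[0, 1]`).
#' @param k_field per-element proliferation rates, 1/day (signed).
#' @param mesh a `tri_mesh`.
#' @param params a `model_params`.
#' @param t_end end time in days (multiple of `params$dt`).
#' @param record_days days at which to record the field (default `c(0, t_end)`).
#' @param store_trajectory keep the field and diffusion field at every step
#'   (needed by the adjoint gradient).
#' @return object of class `cell_state_series`: `times`, `N` (nodes x times
#'   matrix), `D_field` (per-element diffusion at the last step), and, when
#'   stored, `trajectory` with per-step fields.
#' @export
run_forward <- function(N0, k_field, mesh, params, t_end,
                        record_days = NULL, store_trajectory = FALSE) {
  dt <- params$dt
  nsteps <- round(t_end / dt)
  if (abs(nsteps * dt - t_end) > 1e-9)
    stop("t_end must be a multiple of params$dt")
  if (is.null(record_days)) record_days <- c(0, t_end)
  rec_steps <- round(record_days / dt)
  if (any(abs(rec_steps * dt - record_days) > 1e-9) ||
      any(rec_steps < 0 | rec_steps > nsteps))
    stop("record_days must be multiples of dt within [0, t_end]")
  ops <- fem_operators(mesh)
  k_node <- as.vector(node_element_weights(mesh) %*% k_field)
  mech_on <- params$gamma > 0
  elast_op <- if (mech_on) elasticity_operator(mesh, params) else NULL

  N <- N0
  out <- matrix(NA_real_, length(N0), length(rec_steps))
  if (0 %in% rec_steps) out[, which(rec_steps == 0)] <- N
  traj_N <- if (store_trajectory) matrix(NA_real_, length(N0), nsteps + 1) else NULL
  traj_D <- if (store_trajectory) matrix(NA_real_, nrow(mesh$triangles), nsteps) else NULL
  if (store_trajectory) traj_N[, 1] <- N
  D_elem <- rep(params$D0, nrow(mesh$triangles))
  viol_max <- 0; viol_day <- NA_real_
  fac_env <- new.env(parent = emptyenv())
  for (s in seq_len(nsteps)) {
    if (mech_on) {
      mech <- solve_elasticity(mesh, N, params, op = elast_op)
      D_elem <- damped_diffusion(params$D0, params$gamma, mech$von_mises)
    }
    N <- step_cell(N, k_node, D_elem, ops, dt, fac_env)
    viol <- max(0, max(N) - 1, -min(N))
    if (viol > viol_max) { viol_max <- viol; viol_day <- s * dt }
    if (viol > 1e-9)
      warning(sprintf("cell fraction left [0,1] by %.3g at day %g; clamped",
                      viol, s * dt))
    N <- pmin(pmax(N, 0), 1)
    if (store_trajectory) { traj_N[, s + 1] <- N; traj_D[, s] <- D_elem }
    hit <- which(rec_steps == s)
    if (length(hit)) out[, hit] <- N
  }
  res <- structure(list(times = record_days, N = out, D_field = D_elem,
                        k_field = k_field, params = params,
                        max_violation = viol_max, violation_day = viol_day),
                   class = "cell_state_series")
  if (store_trajectory) res$trajectory <- list(N = traj_N, D = traj_D,
                                               k_node = k_node, nsteps = nsteps)
  res
}

#' @export
print.cell_state_series <- function(x, ...) {
  cat(sprintf("<cell_state_series> %d nodes, recorded at days %s\n",
              nrow(x$N), paste(x$times, collapse = ", ")))
  invisible(x)
}
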