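test_that("von Mises stress under plane strain matches direct evaluation", {
  expect_equal(von_mises_plane_strain(0, 0, 0, 0.45), 0)
  expect_equal(von_mises_plane_strain(1, 0, 0, 0.45), sqrt(0.7525))
  s <- 0.37  # pure shear
  expect_equal(von_mises_plane_strain(0, 0, s, 0.3), s * sqrt(3))
  # vectorized
  expect_length(von_mises_plane_strain(c(1, 2), c(0, 1), c(0, 0), 0.45), 2)
})

test_that("stress damping of diffusion is exponential, bounded and monotone", {
  expect_equal(damped_diffusion(0.01, 0, c(0, 5, 50)), rep(0.01, 3))
  expect_equal(damped_diffusion(0.01, 2, log(2) / 2), 0.005)
  vm <- seq(0, 20, by = 0.5)
  D <- damped_diffusion(0.01, 1, vm)
  expect_true(all(diff(D) < 0))
  expect_true(all(D > 0 & D <= 0.01))
})

test_that("elasticity returns zero displacement for zero forcing", {
  fx <- fx_inverse()
  p <- model_params(theta = 1)
  mech <- solve_elasticity(fx$mesh, rep(0.4, nrow(fx$mesh$nodes)), p)
  expect_equal(max(abs(mech$displacement)), 0, tolerance = 1e-12)
  expect_equal(max(mech$von_mises), 0, tolerance = 1e-12)
  # lambda = 0 decouples the cell field entirely
  p0 <- model_params(lam = 0, theta = 1)
  mech0 <- solve_elasticity(fx$mesh, fx$N0, p0)
  expect_equal(max(abs(mech0$displacement)), 0, tolerance = 1e-15)
})

test_that("a radially symmetric cell blob yields a mirror-symmetric displacement field", {
  # oracle: solve on the mesh reflected through the vertical axis; the
  # displacement of the reflected problem must be the reflection of the
  # original displacement (u_x antisymmetric, u_y symmetric), to solver
  # precision
  mask <- matrix(TRUE, 25, 25)
  mesh <- build_mesh(mask, c(1, 1), 1.5)
  ctr <- colMeans(apply(mesh$nodes, 2, range))
  r2 <- (mesh$nodes[, 1] - ctr[1])^2 + (mesh$nodes[, 2] - ctr[2])^2
  N <- 0.6 * exp(-r2 / 18)
  mech <- solve_elasticity(mesh, N, model_params(theta = 1))

  mesh2 <- mesh
  mesh2$nodes[, 1] <- 2 * ctr[1] - mesh$nodes[, 1]
  mesh2$triangles <- mesh$triangles[, c(1, 3, 2)]   # restore CCW orientation
  geom <- prolifmap:::tri_geometry(mesh2$nodes, mesh2$triangles)
  mesh2$areas <- geom$area; mesh2$grad_b <- geom$b; mesh2$grad_c <- geom$c
  mesh2$centroids <- geom$centroid
  mesh2$cache <- new.env(parent = emptyenv())
  expect_true(all(mesh2$areas > 0))
  mech2 <- solve_elasticity(mesh2, N, model_params(theta = 1))  # N is radial
  scale <- max(abs(mech$displacement[, 1]))
  expect_gt(scale, 0)
  expect_lt(max(abs(mech2$displacement[, 1] + mech$displacement[, 1])) / scale,
            1e-8)
  expect_lt(max(abs(mech2$displacement[, 2] - mech$displacement[, 2])) / scale,
            1e-8)
})

test_that("a single step is the identity when nothing drives the system", {
  fx <- fx_inverse()
  m <- nrow(fx$mesh$triangles)
  N1 <- step_cell_state(fx$N0, rep(0, m), rep(0, m), fx$mesh, model_params(theta = 1))
  expect_equal(N1, fx$N0, tolerance = 1e-12)
})

test_that("diffusion conserves total cell number under the no-flux boundary", {
  fx <- fx_inverse()
  params <- model_params(D0 = 0.05, gamma = 0, theta = 1)
  fw <- run_forward(fx$N0, rep(0, nrow(fx$mesh$triangles)), fx$mesh, params, 29)
  ops <- prolifmap:::fem_operators(fx$mesh)
  m0 <- sum(ops$mlump * fw$N[, 1])
  m1 <- sum(ops$mlump * fw$N[, 2])
  expect_lt(abs(m1 - m0) / m0, 1e-8)
})

test_that("pure logistic dynamics follow the closed form within 1 percent", {
  fx <- fx_inverse()
  params <- model_params(D0 = 0, gamma = 0, theta = 1)
  for (k in c(-0.1, 0.1)) {
    fw <- run_forward(rep(0.5, nrow(fx$mesh$nodes)),
                      rep(k, nrow(fx$mesh$triangles)), fx$mesh, params, 29)
    exact <- 0.5 * exp(k * 29) / (1 + 0.5 * (exp(k * 29) - 1))
    expect_lt(max(abs(fw$N[, 2] - exact)) / exact, 0.01)
  }
})

test_that("gamma = 0 reproduces the pure reaction-diffusion trajectory", {
  fx <- fx_recovery()
  p_dec <- model_params(D0 = 1e-3, gamma = 0, lam = 0.7, theta = 1)
  p_ref <- model_params(D0 = 1e-3, gamma = 0, lam = 0, theta = 1)
  fw1 <- run_forward(fx$series$N_nodal[, 1], fx$k_elem, fx$mesh, p_dec, 10)
  fw2 <- run_forward(fx$series$N_nodal[, 1], fx$k_elem, fx$mesh, p_ref, 10)
  expect_identical(fw1$N, fw2$N)
})

test_that("everywhere-negative proliferation cannot increase total cell number", {
  fx <- fx_inverse()
  params <- model_params(D0 = 5e-3, gamma = 0, theta = 1)
  fw <- run_forward(fx$N0, rep(-0.08, nrow(fx$mesh$triangles)), fx$mesh, params,
                    20, record_days = 0:20)
  ops <- prolifmap:::fem_operators(fx$mesh)
  totals <- colSums(ops$mlump * fw$N)
  expect_true(all(diff(totals) <= 1e-12))
  # against a fine-step oracle
  params_f <- model_params(D0 = 5e-3, gamma = 0, dt = 0.1, theta = 1)
  fwf <- run_forward(fx$N0, rep(-0.08, nrow(fx$mesh$triangles)), fx$mesh,
                     params_f, 20)
  expect_lt(max(abs(fw$N[, 21] - fwf$N[, 2])) / max(fwf$N[, 2]), 0.01)
})

test_that("t_end = 0 returns the initial state and bad steps error", {
  fx <- fx_inverse()
  params <- model_params(theta = 1)
  fw <- run_forward(fx$N0, rep(0, nrow(fx$mesh$triangles)), fx$mesh, params, 0,
                    record_days = 0)
  expect_equal(fw$N[, 1], fx$N0)
  expect_error(run_forward(fx$N0, rep(0, nrow(fx$mesh$triangles)), fx$mesh,
                           params, 10.5), "multiple")
})

test_that("the field stays within physical bounds and mechanics only slows spread", {
  fx <- fx_inverse()
  m <- nrow(fx$mesh$triangles)
  p_grow <- model_params(D0 = 0.02, gamma = 0, theta = 1)
  fw <- run_forward(fx$N0, rep(0.3, m), fx$mesh, p_grow, 29)
  expect_true(all(fw$N >= 0 & fw$N <= 1))
  # identical k: coupled run spreads no more mass outside the tumor
  p0 <- model_params(D0 = 0.05, gamma = 0, lam = 0.2, theta = 1)
  p1 <- model_params(D0 = 0.05, gamma = 20, lam = 0.2, theta = 1)
  f0 <- run_forward(fx$N0, rep(0, m), fx$mesh, p0, 29)
  f1 <- run_forward(fx$N0, rep(0, m), fx$mesh, p1, 29)
  outside <- !fx$mesh$node_in_roi
  expect_lt(sum(f1$N[outside, 2]), sum(f0$N[outside, 2]))
})

test_that("halving the mesh edge or the time step changes the solution only slightly", {
  ph <- make_phantom(c(48, 48), c(1, 1), tumor_spec = list(radius_mm = 10),
                     k_field_spec = list(mode = "uniform", k = -0.05), D0 = 0.02)
  dom <- mesh_domain_mask(ph$roi_mask, ph$domain_mask, c(1, 1), 10)
  f0 <- function(x, y) {
    r <- sqrt((x - ph$tumor_center[1])^2 + (y - ph$tumor_center[2])^2) / 10
    ifelse(r < 1, 0.75 * cos(pi * pmin(r, 1) / 2)^2, 0)
  }
  run_at <- function(edge, dt) {
    mesh <- build_mesh(dom, c(1, 1), edge, roi_mask = ph$roi_mask)
    p <- model_params(D0 = 0.02, gamma = 0, dt = dt, theta = 1)
    ke <- prolifmap:::image_at_elements(ph$true_k_map, mesh)
    fw <- run_forward(f0(mesh$nodes[, 1], mesh$nodes[, 2]), ke, mesh, p, 29)
    nodal_to_raster(fw$N[, 2], mesh, c(48, 48), c(1, 1), fill = NA)
  }
  l2 <- function(a, b) {
    px <- ph$roi_mask & !is.na(a) & !is.na(b)
    sqrt(sum((a[px] - b[px])^2)) / sqrt(sum(b[px]^2))
  }
  expect_lt(l2(run_at(1.5, 1), run_at(0.75, 1)), 0.02)
  expect_lt(l2(run_at(1.5, 1), run_at(1.5, 0.5)), 0.01)
})
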