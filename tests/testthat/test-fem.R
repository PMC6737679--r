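test_that("neo-Hookean stress matches finite differences of the energy", {
  mu <- 1000
  K <- 3400
  F <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  P <- F %*% neo_hookean_stress(F, mu, K)
  h <- 1e-6
  P_fd <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    Fp <- F; Fp[a, b] <- Fp[a, b] + h
    Fm <- F; Fm[a, b] <- Fm[a, b] - h
    P_fd[a, b] <- (neo_hookean_energy(Fp, mu, K) -
                     neo_hookean_energy(Fm, mu, K)) / (2 * h)
  }
  expect_lt(max(abs(P - P_fd)) / max(abs(P)), 1e-6)
  # same check on a non-diagonal deformation
  set.seed(1)
  F2 <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  P2 <- F2 %*% neo_hookean_stress(F2, mu, K)
  for (a in 1:3) for (b in 1:3) {
    Fp <- F2; Fp[a, b] <- Fp[a, b] + h
    Fm <- F2; Fm[a, b] <- Fm[a, b] - h
    P_fd[a, b] <- (neo_hookean_energy(Fp, mu, K) -
                     neo_hookean_energy(Fm, mu, K)) / (2 * h)
  }
  expect_lt(max(abs(P2 - P_fd)) / max(abs(P2)), 1e-5)
})

test_that("neo-Hookean stress vanishes for rigid motions and rejects inversion", {
  expect_equal(neo_hookean_stress(diag(3), 1000, 3400), matrix(0, 3, 3))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_lt(max(abs(neo_hookean_stress(R, 1000, 3400))), 1e-9)
  expect_error(neo_hookean_stress(diag(c(-1, 1, 1)), 1000, 3400), "inversion")
})

test_that("material parameters derive mu from K and nu", {
  pm <- material_params()
  expect_equal(unname(pm$K), c(3400, 50000))
  expect_equal(unname(pm$mu),
               3 * c(3400, 50000) * (1 - 2 * 0.45) / (2 * (1 + 0.45)))
  expect_error(material_params(nu = 0.5), "Poisson")
  expect_error(material_params(K = c(fat = -1, fgt = 1)), "positive")
})

test_that("internal forces vanish for undeformed and translated states", {
  mesh <- column_mesh(4L)
  pm <- material_params()
  f0 <- internal_forces(mesh, mesh$nodes, pm)
  expect_lt(max(abs(f0)), 1e-10)
  f1 <- internal_forces(mesh, sweep(mesh$nodes, 2, c(5, -3, 11), "+"), pm)
  expect_lt(max(abs(f1)), 1e-10)
})

test_that("single-element forces match hand assembly from the stress", {
  # one regular tet, uniaxial stretch along x
  X <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  mesh <- structure(list(nodes = X, tets = matrix(1:4, 1), label = 1L,
                         fixed = rep(FALSE, 4), nipple_node = NA_integer_,
                         edge_mm = 10), class = "tet_mesh")
  pm <- material_params()
  lam <- 1.2
  x <- X
  x[, 1] <- x[, 1] * lam
  f <- internal_forces(mesh, x, pm)
  # independent assembly: f_i = -V0 P grad(N_i)
  Xm <- t(X[2:4, ] - rep(1, 3) %*% t(X[1, ])) * 1e-3
  xm <- t(x[2:4, ] - rep(1, 3) %*% t(x[1, ])) * 1e-3
  F <- xm %*% solve(Xm)
  P <- F %*% neo_hookean_stress(F, pm$mu[["fat"]], pm$K[["fat"]])
  V0 <- det(Xm) / 6
  H <- -V0 * P %*% t(solve(Xm))
  hand <- rbind(-rowSums(H), t(H))
  expect_equal(f, hand, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(colSums(f))), 1e-12)   # forces balance
})

test_that("column under self-weight matches the linear closed form", {
  mesh <- column_mesh(20L)
  pm <- material_params()
  g <- 5e-4                       # small strain regime
  st <- solve_static(mesh, pm, gravity = c(0, g, 0))
  L <- diff(range(mesh$nodes[, 2])) * 1e-3
  tip <- which(mesh$nodes[, 2] == max(mesh$nodes[, 2]))
  tip_disp <- mean(displacement(st)[tip, 2])
  closed <- 1000 * g * L^2 / (2 * pm$E[["fat"]]) * 1e3
  expect_lt(abs(tip_disp - closed) / closed, 0.05)
})

test_that("displacements scale inversely with moduli in the linear limit", {
  mesh <- column_mesh(10L)
  g <- 2e-4
  u1 <- displacement(solve_static(mesh, material_params(),
                                  gravity = c(0, g, 0)))
  u10 <- displacement(solve_static(mesh,
                                   material_params(K = c(fat = 34000,
                                                         fgt = 500000)),
                                   gravity = c(0, g, 0)))
  ratio <- max(abs(u10)) / max(abs(u1))
  expect_lt(abs(ratio - 0.1) / 0.1, 0.1)
})

test_that("zero gravity produces zero displacement; damping kills energy", {
  mesh <- column_mesh(6L)
  st <- solve_static(mesh, material_params(), gravity = c(0, 0, 0))
  expect_lt(max(abs(displacement(st))), 1e-9)
  st2 <- solve_static(mesh, material_params(), gravity = c(0, 1, 0))
  ke <- st2$diagnostics$ke_history
  expect_lt(ke[length(ke)], 1e-12)
  expect_true(st2$converged)
  expect_error(solve_static(mesh, material_params(), gravity = c(0, 1, 0),
                            options = solver_options(max_steps = 50L,
                                                     ramp_steps = 10L)),
               "no convergence")
  unfixed <- mesh
  unfixed$fixed[] <- FALSE
  expect_error(solve_static(unfixed, material_params()), "fixed boundary")
})

test_that("solutions are equivariant under an exact frame rotation", {
  mesh <- column_mesh(8L)
  pm <- material_params()
  st <- solve_static(mesh, pm, gravity = c(0, 0.5, 0))
  rmesh <- mesh
  rmesh$nodes <- rot90z(mesh$nodes)
  # the base plane rotates with the mesh; flags are node-aligned
  remarked <- mark_fixed_boundary(rmesh,
                                  plane_point = c(max(rmesh$nodes[, 1]), 0, 0),
                                  plane_normal = c(1, 0, 0), tol_mm = 1e-6)
  expect_identical(remarked$fixed, mesh$fixed)
  rmesh$fixed <- mesh$fixed
  st2 <- solve_static(rmesh, pm, gravity = c(-0.5, 0, 0))
  expect_lt(max(abs(rot90z(st$current_nodes) - st2$current_nodes)), 1e-6)
})
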