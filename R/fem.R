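#' Neo-Hookean material parameters per tissue
#'
#' The tissue bulk moduli default to 3400 Pa (fat) and 50,000 Pa
#' (fibroglandular). The bulk modulus K and Poisson ratio nu determine the
#' shear modulus mu = 3 K (1 - 2 nu) / (2 (1 + nu)) and small-strain Young
#' modulus E = 2 mu (1 + nu). nu defaults to 0.45 (configurable up to 0.49
#' for near-incompressibility); tissue density defaults to 1000 kg/m^3.
#'
#' @param K Named bulk moduli in Pa, `c(fat = ..., fgt = ...)`.
#' @param nu Poisson ratio, in (0, 0.5).
#' @param rho Tissue mass density, kg/m^3.
#' @return Object of class `material_params` with derived `mu` and `E`.
#' @export
material_params <- function(K = c(fat = 3400, fgt = 50000), nu = 0.45,
                            rho = 1000) {
  if (any(K <= 0)) stopf("bulk moduli must be positive")
  if (nu <= 0 || nu >= 0.5) stopf("Poisson ratio must be in (0, 0.5)")
  mu <- 3 * K * (1 - 2 * nu) / (2 * (1 + nu))
  structure(list(K = K, nu = nu, mu = mu, E = 2 * mu * (1 + nu), rho = rho),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> nu=%.3g rho=%g kg/m3\n", x$nu, x$rho))
  for (t in names(x$K))
    cat(sprintf("  %s: K=%g Pa, mu=%.4g Pa, E=%.4g Pa\n",
                t, x$K[[t]], x$mu[[t]], x$E[[t]]))
  invisible(x)
}

#' Second Piola-Kirchhoff stress of the neo-Hookean model
#'
#' Strain energy `Psi = mu/2 (J^{-2/3} I1 - 3) + K/2 (J - 1)^2` with
#' `J = det F`, `I1 = tr(F'F)`. The returned stress is
#' `S = mu J^{-2/3} (I - I1/3 C^{-1}) + K J (J - 1) C^{-1}`, symmetric, and
#' zero for any rotation `F`.
#'
#' @param F 3x3 deformation gradient with `det F > 0`.
#' @param mu,K Shear and bulk moduli (Pa).
#' @return Symmetric 3x3 second Piola-Kirchhoff stress (Pa).
#' @export
neo_hookean_stress <- function(F, mu, K) {
  J <- det(F)
  if (J <= 0) stopf("element inversion: det F = %.4g <= 0", J)
  C <- t(F) %*% F
  Ci <- solve(C)
  I1 <- sum(diag(C))
  S <- mu * J^(-2 / 3) * (diag(3) - I1 / 3 * Ci) + K * J * (J - 1) * Ci
  (S + t(S)) / 2
}

#' Neo-Hookean strain energy density
#' @inheritParams neo_hookean_stress
#' @return Scalar energy density (Pa).
#' @export
neo_hookean_energy <- function(F, mu, K) {
  J <- det(F)
  if (J <= 0) stopf("element inversion: det F = %.4g <= 0", J)
  mu / 2 * (J^(-2 / 3) * sum(F^2) - 3) + K / 2 * (J - 1)^2
}

per_element_materials <- function(mesh, params) {
  lab <- mesh$label
  list(mu = unname(params$mu[ifelse(lab == 2L, "fgt", "fat")]),
       K = unname(params$K[ifelse(lab == 2L, "fgt", "fat")]))
}

#' Internal nodal forces of a deformed mesh
#'
#' Assembles the per-element first Piola-Kirchhoff forces (precomputed
#' reference shape-function gradients, one-point quadrature on linear
#' tetrahedra) into nodal forces. Forces sum to zero over all nodes.
#'
#' @param mesh A labeled `tet_mesh` (reference configuration, mm).
#' @param current_nodes_mm Deformed node positions (mm).
#' @param params [material_params()].
#' @return n x 3 matrix of nodal forces in Newtons.
#' @export
internal_forces <- function(mesh, current_nodes_mm, params) {
  mat <- per_element_materials(mesh, params)
  out <- internal_forces_cpp(mesh$nodes * 1e-3, current_nodes_mm * 1e-3,
                             mesh$tets, mat$mu, mat$K)
  if (!isTRUE(out$ok))
    stopf("element inversion in element %d", out$bad_element)
  out$forces
}

#' Solver options for the TLED dynamic relaxation
#'
#' @param dt_safety Fraction of the estimated critical time step.
#' @param damping Mass-proportional damping coefficient (1/s); `NULL` =
#'   critical damping of the lowest-mode estimate
#'   `pi sqrt(E_min / rho) / L_gravity`.
#' @param tol_v Velocity convergence tolerance (m/s).
#' @param tol_f_rel Residual-force tolerance as a fraction of the total
#'   gravity load.
#' @param max_steps Step cap; exceeding it is an error.
#' @param ramp_steps Steps over which the load ramps from 0 to full.
#' @param check_every Steps between convergence checks.
#' @param dt Explicit time step (s); `NULL` = estimated from the mesh.
#' @param allow_unconverged Return (with a warning) instead of erroring when
#'   `max_steps` is hit.
#' @return List of class `solver_options`.
#' @export
solver_options <- function(dt_safety = 0.4, damping = NULL, tol_v = 1e-6,
                           tol_f_rel = 1e-4, max_steps = 200000L,
                           ramp_steps = 2000L, check_every = 200L,
                           dt = NULL, allow_unconverged = FALSE) {
  structure(list(dt_safety = dt_safety, damping = damping, tol_v = tol_v,
                 tol_f_rel = tol_f_rel, max_steps = as.integer(max_steps),
                 ramp_steps = as.integer(ramp_steps),
                 check_every = as.integer(check_every), dt = dt,
                 allow_unconverged = allow_unconverged),
            class = "solver_options")
}

# critical-time-step estimate: min element altitude / dilatational wave speed
estimate_dt <- function(mesh, params, safety) {
  mat <- per_element_materials(mesh, params)
  X <- mesh$nodes * 1e-3
  t <- mesh$tets
  v <- abs(tet_volumes(X, t))
  area <- function(a, b, d) {
    e1 <- X[b, , drop = FALSE] - X[a, , drop = FALSE]
    e2 <- X[d, , drop = FALSE] - X[a, , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sqrt(rowSums(cr^2)) / 2
  }
  amax <- pmax(area(t[, 2], t[, 3], t[, 4]), area(t[, 1], t[, 3], t[, 4]),
               area(t[, 1], t[, 2], t[, 4]), area(t[, 1], t[, 2], t[, 3]))
  hmin <- 3 * v / amax
  cw <- sqrt((mat$K + 4 / 3 * mat$mu) / params$rho)
  safety * min(hmin / cw)
}

#' Quasi-static gravity deformation by TLED dynamic relaxation
#'
#' Central-difference explicit integration of the damped equations of motion
#' (total Lagrangian formulation, neo-Hookean elements, lumped mass, gravity
#' ramped over the first `ramp_steps` steps) until the maximum nodal velocity
#' and residual force fall below tolerance. Deterministic for fixed inputs.
#'
#' @param mesh A labeled `tet_mesh` with a marked fixed boundary.
#' @param params [material_params()].
#' @param gravity Gravity vector in m/s^2 (e.g. `c(0, 9.81, 0)` pulls the
#'   breast anteriorly = prone; `c(0, -9.81, 0)` posteriorly = supine).
#' @param load_factor Scale in \[0, 1\] applied to `gravity`.
#' @param options [solver_options()].
#' @param init_nodes_mm Optional initial guess (mm) for the deformed
#'   configuration (defaults to the reference nodes).
#' @return Object of class `deformation_state`: `reference_nodes`,
#'   `current_nodes` (mm), `load_factor`, `converged`, `steps`, and
#'   `diagnostics` (residual/kinetic-energy histories, dt, damping, min J).
#' @export
solve_static <- function(mesh, params, gravity = c(0, 9.81, 0),
                         load_factor = 1, options = solver_options(),
                         init_nodes_mm = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(params, "material_params"))
  if (!any(mesh$fixed)) stopf("fixed boundary must be marked before solving")
  mat <- per_element_materials(mesh, params)
  X <- mesh$nodes * 1e-3
  x0 <- (init_nodes_mm %||% mesh$nodes) * 1e-3
  dt <- options$dt %||% estimate_dt(mesh, params, options$dt_safety)
  damping <- options$damping
  if (is.null(damping)) {
    g <- sqrt(sum(gravity^2))
    dirg <- if (g > 0) gravity / g else c(0, 1, 0)
    span <- diff(range(X %*% dirg))
    Emin <- min(unname(params$E))
    damping <- pi * sqrt(Emin / params$rho) / max(span, 1e-6)
  }
  gnorm <- sqrt(sum(gravity^2)) * load_factor
  tol_f <- if (gnorm > 0) {
    masses <- abs(tet_volumes(X, mesh$tets)) * params$rho
    options$tol_f_rel * sum(masses) * gnorm
  } else {
    options$tol_f_rel
  }
  res <- tled_solve_cpp(X, mesh$tets, mat$mu, mat$K, params$rho, mesh$fixed,
                        gravity, load_factor, dt, damping, options$tol_v,
                        tol_f, options$max_steps, options$ramp_steps,
                        options$check_every, x0)
  if (!isTRUE(res$ok))
    stopf("solver failed (%s) at element %d", res$reason, res$bad_element)
  if (!res$converged) {
    msg <- sprintf(
      "no convergence in %d steps (resid %.3g, tol %.3g); residual history: %s",
      res$steps, res$max_resid, tol_f,
      paste(signif(utils::tail(res$resid_history, 5), 3), collapse = ", "))
    if (options$allow_unconverged) warnf(msg) else stopf(msg)
  }
  structure(list(mesh = mesh, reference_nodes = mesh$nodes,
                 current_nodes = res$x * 1e3, load_factor = load_factor,
                 converged = res$converged, steps = res$steps,
                 diagnostics = list(resid_history = res$resid_history,
                                    ke_history = res$ke_history,
                                    max_resid = res$max_resid,
                                    max_v = res$max_v, min_J = res$min_J,
                                    dt = dt, damping = damping,
                                    tol_f = tol_f)),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  u <- x$current_nodes - x$reference_nodes
  cat(sprintf(
    "<deformation_state> lambda=%.3g | %s in %d steps | max |u| %.2f mm | min J %.3f\n",
    x$load_factor, if (x$converged) "converged" else "NOT converged",
    x$steps, max(sqrt(rowSums(u^2))), x$diagnostics$min_J))
  invisible(x)
}

#' Nodal displacements of a deformation state (mm)
#' @param state A `deformation_state`.
#' @return n x 3 matrix `current - reference` in mm.
#' @export
displacement <- function(state) state$current_nodes - state$reference_nodes
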