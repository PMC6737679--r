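#' Breast depth at the nipple line
#'
#' Operationalizes the ultrasound "breast depth": the distance (cm) from the
#' chest-wall plane to the anterior-most node lying within a thin sagittal
#' slab around the nipple's lateral position, measured along the anterior
#' axis. This matches the geometry of a supine ultrasound exam, where the
#' probe sits on the skin above the nipple.
#'
#' @param mesh A `tet_mesh` with `nipple_node` set (see [set_nipple_node()]).
#' @param nodes_mm Node positions to measure (defaults to `mesh$nodes`;
#'   pass a deformed configuration to track depth through loading).
#' @param chest_point,anterior Chest plane point and anterior unit axis (mm).
#' @param lateral Lateral unit axis defining the sagittal slab.
#' @param slab_mm Slab half-width around the nipple line.
#' @return Depth in cm.
#' @export
breast_depth <- function(mesh, nodes_mm = mesh$nodes,
                         chest_point = c(0, 0, 0), anterior = c(0, 1, 0),
                         lateral = c(1, 0, 0), slab_mm = 6) {
  if (is.na(mesh$nipple_node)) stopf("mesh has no nipple node; call set_nipple_node()")
  ant <- unit(anterior)
  lat <- unit(lateral)
  latpos <- as.vector(nodes_mm %*% lat)
  keep <- abs(latpos - latpos[mesh$nipple_node]) <= slab_mm
  d <- as.vector(sweep(nodes_mm[keep, , drop = FALSE], 2, chest_point) %*% ant)
  max(d) / 10
}

#' Estimate the zero-gravity (rest) configuration
#'
#' Fixed-point iteration for the unloaded shape: starting from the observed
#' prone nodes `X_obs`, each iterate simulates prone gravity from the current
#' rest candidate `X_k` and corrects `X_{k+1} = X_k + alpha (X_obs - x_k)`
#' until the simulated prone shape matches the observation within `tol_mm`.
#' If the residual increases for 3 consecutive iterations, `alpha` is halved;
#' below `alpha = 0.05` the estimation aborts.
#'
#' @param mesh Prone `tet_mesh` (observed configuration) with fixed boundary.
#' @param params [material_params()].
#' @param gravity Prone gravity vector (m/s^2), anterior-pointing.
#' @param options [solver_options()].
#' @param alpha Initial relaxation factor in (0, 1].
#' @param tol_mm Stopping tolerance on the maximum nodal mismatch.
#' @param max_iter Iteration cap.
#' @return List of class `zero_gravity_fit`: `mesh` (rest configuration),
#'   `residual_history` (mm), `iterations`, `converged`, and `prone_check`
#'   (the simulated prone nodes from the final rest estimate).
#' @export
estimate_zero_gravity <- function(mesh, params, gravity = c(0, 9.81, 0),
                                  options = solver_options(), alpha = 1,
                                  tol_mm = 0.5, max_iter = 20L) {
  X_obs <- mesh$nodes
  X <- X_obs
  hist <- numeric(0)
  inc_run <- 0L
  sim <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cand <- mesh
    cand$nodes <- X
    st <- solve_static(cand, params, gravity, options = options,
                       init_nodes_mm = if (it == 1) NULL else sim)
    sim <- st$current_nodes
    resid <- max(sqrt(rowSums((X_obs - sim)^2)))
    hist <- c(hist, resid)
    if (resid < tol_mm) { converged <- TRUE; break }
    if (length(hist) > 1 && resid > hist[length(hist) - 1]) {
      inc_run <- inc_run + 1L
      if (inc_run >= 3L) {
        alpha <- alpha / 2
        inc_run <- 0L
        if (alpha < 0.05)
          stopf("zero-gravity estimation diverged (alpha < 0.05); residuals: %s",
                paste(signif(hist, 3), collapse = ", "))
      }
    } else {
      inc_run <- 0L
    }
    X <- X + alpha * (X_obs - sim)
  }
  out <- mesh
  out$nodes <- X
  structure(list(mesh = out, residual_history = hist, iterations = length(hist),
                 converged = converged, prone_check = sim),
            class = "zero_gravity_fit")
}

#' Load the rest mesh toward supine until a target breast depth
#'
#' The supine (inverse-gravity) configuration is found by bisection on the
#' gravity load factor lambda in \[0, 1\]: breast depth decreases
#' monotonically with supine load, and the iteration stops when the deformed
#' depth matches the ultrasound-measured breast depth within `depth_tol_cm`.
#' Each bisection step is a fully converged static solve. If even full
#' gravity leaves the breast deeper than the target, lambda = 1 is returned
#' with a warning.
#'
#' @param zg_mesh Zero-gravity `tet_mesh` (from [estimate_zero_gravity()]).
#' @param params [material_params()].
#' @param target_depth_cm Ultrasound breast depth to match (cm).
#' @param gravity Supine gravity vector (m/s^2), posterior-pointing.
#' @param options [solver_options()].
#' @param depth_tol_cm Matching tolerance (default 0.05 cm).
#' @param chest_point,anterior,lateral,slab_mm Passed to [breast_depth()].
#' @param max_iter Bisection cap.
#' @return List of class `supine_fit`: `nodes` (deformed supine positions,
#'   mm), `load_factor`, `achieved_depth_cm`, `history` (lambda vs depth),
#'   and the final `state`.
#' @export
load_supine_until_depth <- function(zg_mesh, params, target_depth_cm,
                                    gravity = c(0, -9.81, 0),
                                    options = solver_options(),
                                    depth_tol_cm = 0.05,
                                    chest_point = c(0, 0, 0),
                                    anterior = c(0, 1, 0),
                                    lateral = c(1, 0, 0), slab_mm = 6,
                                    max_iter = 25L) {
  depth_of <- function(nodes)
    breast_depth(zg_mesh, nodes, chest_point, anterior, lateral, slab_mm)
  d0 <- depth_of(zg_mesh$nodes)
  hist <- data.frame(lambda = 0, depth = d0)
  if (target_depth_cm > d0 + depth_tol_cm)
    stopf("target depth %.2f cm exceeds zero-gravity depth %.2f cm",
          target_depth_cm, d0)
  if (abs(d0 - target_depth_cm) <= depth_tol_cm) {
    return(structure(list(nodes = zg_mesh$nodes, load_factor = 0,
                          achieved_depth_cm = d0, history = hist,
                          state = NULL), class = "supine_fit"))
  }
  solve_at <- function(lam, init)
    solve_static(zg_mesh, params, gravity, load_factor = lam,
                 options = options, init_nodes_mm = init)
  st1 <- solve_at(1, NULL)
  d1 <- depth_of(st1$current_nodes)
  hist <- rbind(hist, data.frame(lambda = 1, depth = d1))
  if (d1 > target_depth_cm + depth_tol_cm) {
    warnf("full inverse gravity insufficient: depth %.2f cm > target %.2f cm",
          d1, target_depth_cm)
    return(structure(list(nodes = st1$current_nodes, load_factor = 1,
                          achieved_depth_cm = d1, history = hist,
                          state = st1), class = "supine_fit"))
  }
  lo <- 0; hi <- 1
  best <- st1; best_d <- d1; best_lam <- 1
  init <- st1$current_nodes
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    st <- solve_at(mid, init)
    d <- depth_of(st$current_nodes)
    hist <- rbind(hist, data.frame(lambda = mid, depth = d))
    init <- st$current_nodes
    best <- st; best_d <- d; best_lam <- mid
    if (abs(d - target_depth_cm) <= depth_tol_cm) break
    if (d > target_depth_cm) lo <- mid else hi <- mid
  }
  structure(list(nodes = best$current_nodes, load_factor = best_lam,
                 achieved_depth_cm = best_d, history = hist, state = best),
            class = "supine_fit")
}

#' Warp the prone label volume into the supine configuration
#'
#' Piecewise-linear displacement interpolation: every voxel center of the
#' output grid is located in the deformed (supine) mesh, mapped back to the
#' prone configuration through the element's barycentric coordinates, and
#' assigned the nearest-neighbor prone label (0 background, 1 fat, 2
#' fibroglandular). Voxels outside the mesh are background.
#'
#' @param prone_mesh The prone `tet_mesh` (reference nodes).
#' @param supine_nodes_mm Deformed node positions sharing the mesh topology.
#' @param fgt_mask,breast_mask Prone-grid logical masks.
#' @param spacing,origin Grid geometry (mm), also used for the output grid.
#' @param max_unmapped Error if more than this fraction of the expected
#'   in-mesh voxels could not be mapped.
#' @return Integer label array on the same grid, in the supine configuration.
#' @export
warp_labels <- function(prone_mesh, supine_nodes_mm, fgt_mask, breast_mask,
                        spacing, origin = c(0, 0, 0), max_unmapped = 0.05) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  labels <- array(0L, dim(breast_mask))
  labels[breast_mask] <- 1L
  labels[fgt_mask & breast_mask] <- 2L
  out <- warp_labels_cpp(supine_nodes_mm, prone_mesh$nodes, prone_mesh$tets,
                         as.integer(labels), dim(labels), spacing, origin)
  expected <- mesh_volume(prone_mesh, supine_nodes_mm) / voxel_volume_mm3(spacing)
  unmapped <- max(0, 1 - out$n_inside / expected)
  if (unmapped > max_unmapped)
    stopf("%.1f%% of in-mesh voxels unmapped (limit %.0f%%)",
          100 * unmapped, 100 * max_unmapped)
  array(out$labels, dim(labels))
}

#' Run the full prone-to-supine deformation for one mesh
#'
#' Convenience driver: estimates the zero-gravity configuration from the
#' prone mesh, then loads it toward supine until the target breast depth.
#'
#' @inheritParams estimate_zero_gravity
#' @param target_depth_cm Ultrasound breast depth (cm).
#' @param gravity_prone,gravity_supine Gravity vectors (m/s^2).
#' @param ... Passed to [load_supine_until_depth()].
#' @return List of class `gravity_stages`: `prone_mesh`, `zero_gravity_mesh`,
#'   `supine_nodes`, `load_factor`, per-stage `depths` (cm), and the
#'   iteration histories.
#' @export
deform_prone_to_supine <- function(mesh, params, target_depth_cm,
                                   gravity_prone = c(0, 9.81, 0),
                                   gravity_supine = c(0, -9.81, 0),
                                   options = solver_options(),
                                   alpha = 1, tol_mm = 0.5, max_iter = 20L,
                                   ...) {
  zg <- estimate_zero_gravity(mesh, params, gravity_prone, options,
                              alpha = alpha, tol_mm = tol_mm,
                              max_iter = max_iter)
  sup <- load_supine_until_depth(zg$mesh, params, target_depth_cm,
                                 gravity = gravity_supine, options = options,
                                 ...)
  structure(list(prone_mesh = mesh, zero_gravity_mesh = zg$mesh,
                 supine_nodes = sup$nodes, load_factor = sup$load_factor,
                 depths = c(prone = breast_depth(mesh),
                            zero_gravity = breast_depth(zg$mesh),
                            supine = sup$achieved_depth_cm),
                 zero_gravity_history = zg$residual_history,
                 supine_history = sup$history),
            class = "gravity_stages")
}
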