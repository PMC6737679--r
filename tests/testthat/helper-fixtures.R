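# Shared fixtures, built once per test run and cached across files.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env)
}

phantom_fixture <- function() cached("phantom", generate_phantom(phantom_spec()))

segmentation_fixture <- function() cached("seg", {
  ph <- phantom_fixture()
  segment_breast(ph$image, chest_mask = ph$chest_mask)
})

breast_mesh_fixture <- function(edge = 8) cached(paste0("mesh", edge), {
  ph <- phantom_fixture()
  seg <- segmentation_fixture()
  surf <- extract_surface(seg$breast_mask, spacing = ph$image$spacing,
                          origin = ph$image$origin)
  mesh <- suppressWarnings(
    label_elements(tetrahedralize(surf, edge), seg$fgt_mask, seg$breast_mask,
                   ph$image$spacing, ph$image$origin))
  mesh <- mark_fixed_boundary(mesh, ph$chest_plane$point,
                              ph$chest_plane$normal, tol_mm = 0.51 * edge)
  set_nipple_node(mesh, ph$nipple_mm)
})

prone_state_fixture <- function() cached("prone_state",
  solve_static(breast_mesh_fixture(), material_params(),
               gravity = c(0, 9.81, 0)))

# round-trip fixtures: treat the lattice mesh as the REST shape, simulate
# prone gravity to get an observed prone mesh with known rest configuration
prone_observed_fixture <- function() cached("prone_observed", {
  mesh <- breast_mesh_fixture()
  st <- prone_state_fixture()
  prone <- mesh
  prone$nodes <- st$current_nodes
  prone
})

zero_gravity_fixture <- function() cached("zg_fit",
  estimate_zero_gravity(prone_observed_fixture(), material_params()))

# analytic closed box surface (12 outward-oriented triangles)
box_surface <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corner index by bits x + 2y + 4z (1-based rows of v)
  f <- rbind(c(1, 5, 7), c(1, 7, 3),    # -x face? indices: see mapping below
             c(2, 4, 8), c(2, 8, 6),
             c(1, 2, 6), c(1, 6, 5),
             c(3, 7, 8), c(3, 8, 4),
             c(1, 3, 4), c(1, 4, 2),
             c(5, 6, 8), c(5, 8, 7))
  structure(list(vertices = v, faces = f, spacing = c(1, 1, 1)),
            class = "tri_surface")
}

# rectangular column of 2 x cells_y x 2 lattice cells (cell edge w mm) along
# +y, fixed at its y = 0 base
column_mesh <- function(cells_y = 20L, w = 10) {
  surf <- box_surface(c(0, 0, 0), c(2 * w, cells_y * w, 2 * w))
  mesh <- tetrahedralize(surf, w)
  mark_fixed_boundary(mesh, plane_point = c(0, 0, 0),
                      plane_normal = c(0, 1, 0), tol_mm = 1e-6)
}

sphere_mask <- function(n = 48L, r = 20) {
  x <- seq_len(n) - (n + 1) / 2
  outer(outer(x^2, x^2, "+"), x^2, "+") <= r^2
}

rot90z <- function(p) cbind(-p[, 2], p[, 1], p[, 3])
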