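test_that("isosurface of a voxelized sphere matches the analytic sphere", {
  r <- 20
  surf <- extract_surface(sphere_mask(48L, r))
  expect_lt(abs(surface_area(surf) - 4 * pi * r^2) / (4 * pi * r^2), 0.03)
  expect_equal(euler_characteristic(surf), 2)
  expect_true(is_closed_surface(surf))
  expect_lt(abs(surface_volume(surf) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
            0.03)
})

test_that("surface extraction handles degenerate inputs", {
  m1 <- array(FALSE, c(5, 5, 5))
  m1[3, 3, 3] <- TRUE
  s1 <- suppressWarnings(extract_surface(m1))
  expect_true(is_closed_surface(s1))
  expect_gt(surface_volume(s1), 0)
  expect_error(extract_surface(array(FALSE, c(4, 4, 4))), "empty")
  two <- array(FALSE, c(7, 7, 7))
  two[2, 2, 2] <- TRUE
  two[6, 6, 6] <- TRUE
  expect_error(extract_surface(two), "components")
})

test_that("lattice tetrahedralization fills analytic volumes", {
  h <- 1 / 12
  cube <- extract_surface(array(TRUE, c(12, 12, 12)), spacing = c(h, h, h),
                          smooth_passes = 0)
  mcube <- tetrahedralize(cube, 0.1)
  expect_lt(abs(mesh_volume(mcube) - 1), 0.03)
  expect_true(all(tet_volumes(mcube$nodes, mcube$tets) > 0))
  expect_equal(max(mcube$tets), nrow(mcube$nodes))  # no unreferenced nodes
  r <- 20
  msph <- tetrahedralize(extract_surface(sphere_mask(48L, r)), 2.5)
  expect_lt(abs(mesh_volume(msph) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
            0.03)
  # open surface rejected
  open_surf <- cube
  open_surf$faces <- open_surf$faces[-1, ]
  expect_error(tetrahedralize(open_surf, 0.1), "closed")
})

test_that("halving the lattice edge changes the mesh volume < 1%", {
  surf <- extract_surface(sphere_mask(48L, 20))
  v1 <- mesh_volume(tetrahedralize(surf, 5))
  v2 <- mesh_volume(tetrahedralize(surf, 2.5))
  expect_lt(abs(v2 - v1) / v1, 0.01)
})

test_that("element labeling matches the voxel fractions", {
  ph <- phantom_fixture()
  seg <- segmentation_fixture()
  mesh <- breast_mesh_fixture()
  vols <- abs(tet_volumes(mesh$nodes, mesh$tets))
  mesh_frac <- sum(vols[mesh$label == 2]) / sum(vols)
  vox_frac <- sum(seg$fgt_mask) / sum(seg$breast_mask)
  expect_lt(abs(mesh_frac - vox_frac), 0.03)
  # degenerate labelings
  empty <- array(FALSE, dim(seg$breast_mask))
  m_fat <- suppressWarnings(label_elements(mesh, empty, seg$breast_mask,
                                           ph$image$spacing, ph$image$origin))
  expect_true(all(m_fat$label == 1L))
  m_fgt <- suppressWarnings(label_elements(mesh, seg$breast_mask,
                                           seg$breast_mask,
                                           ph$image$spacing, ph$image$origin))
  expect_gt(mean(m_fgt$label == 2L), 0.95)
})

test_that("fixed-boundary marking is plane-based and translation-invariant", {
  mesh <- breast_mesh_fixture()
  base <- mesh$nodes[mesh$fixed, ]
  expect_gte(sum(mesh$fixed), 3)
  expect_true(all(abs(base[, 2]) <= 0.51 * mesh$edge_mm))
  shifted <- mesh
  shifted$nodes <- sweep(mesh$nodes, 2, c(13, -5, 2), "+")
  shifted <- mark_fixed_boundary(shifted, plane_point = c(13, -5, 2),
                                 plane_normal = c(0, 1, 0),
                                 tol_mm = 0.51 * mesh$edge_mm)
  expect_identical(shifted$fixed, mesh$fixed)
  expect_error(mark_fixed_boundary(mesh, plane_point = c(0, -500, 0),
                                   tol_mm = 0.1), "no nodes")
})

test_that("lattice meshes have sane element quality", {
  q <- mesh_quality(breast_mesh_fixture())
  expect_equal(q$n_inverted, 0)
  expect_gt(q$min_dihedral_deg, 30)  # Kuhn tets: min dihedral 45 deg in theory
})
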