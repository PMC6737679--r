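# simple synthetic supine label block: fat slab with an FGT band, "skin"
# facing +y
synthetic_labels <- function() {
  gs <- c(21, 40, 21)
  labels <- array(0L, gs)
  labels[4:18, 5:35, 4:18] <- 1L          # breast tissue
  labels[4:18, 15:25, 4:18] <- 2L         # fibroglandular band
  list(labels = labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
       nipple = c(10, 34, 10))            # world mm of anterior surface point
}

test_that("ROI box lands at the configured depth below the skin", {
  s <- synthetic_labels()
  roi <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                   depth_cm = 0.5, width_cm = 1.0, height_cm = 0.5)
  expect_equal(attr(roi, "slice"), 11)       # nipple sagittal slice
  expect_equal(attr(roi, "skin_index"), 35)  # anterior-most tissue voxel
  jr <- attr(roi, "depth_index_range")
  expect_equal(jr[2], 30)                    # 5 mm below the skin
  expect_equal(jr[2] - jr[1] + 1, 5)         # 0.5 cm at 1 mm voxels
  kr <- attr(roi, "inplane_index_range")
  expect_equal(kr, c(6, 16))                 # 1 cm centered on the nipple
  expect_equal(nrow(roi), 5 * 11)
})

test_that("local density reflects the box content exactly", {
  s <- synthetic_labels()
  all_fgt <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                       depth_cm = 1.0, width_cm = 0.6, height_cm = 0.4)
  expect_equal(local_percent_density(s$labels, all_fgt), 100)
  all_fat <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                       depth_cm = 0.1, width_cm = 0.6, height_cm = 0.4)
  expect_equal(local_percent_density(s$labels, all_fat), 0)
  # half-FGT box straddling the band edge at j = 25: rows 22..29, 4 of 8 FGT
  half <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                    depth_cm = 0.6, width_cm = 0.6, height_cm = 0.8)
  expect_equal(local_percent_density(s$labels, half), 50)
  expect_error(local_percent_density(s$labels, half[0, , drop = FALSE]),
               "empty")
})

test_that("ROI placement validates depth and grid bounds", {
  s <- synthetic_labels()
  expect_error(place_roi(s$labels, s$spacing, s$origin, s$nipple,
                         depth_cm = 3.5), "posterior")
  expect_error(place_roi(s$labels, s$spacing, s$origin, s$nipple,
                         depth_cm = 0.5, width_cm = 5), "exceeds the grid")
  expect_error(place_roi(s$labels, s$spacing, s$origin, c(100, 100, 100),
                         depth_cm = 0.5), "outside")
  expect_error(place_roi(s$labels, s$spacing, s$origin, s$nipple,
                         depth_cm = 0.5, width_cm = -1), "positive")
})

test_that("the volumetric ROI variant extends across slices", {
  s <- synthetic_labels()
  flat <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                    depth_cm = 1.0, width_cm = 0.6, height_cm = 0.4)
  vol <- place_roi(s$labels, s$spacing, s$origin, s$nipple,
                   depth_cm = 1.0, width_cm = 0.6, height_cm = 0.4,
                   thickness_cm = 0.6)
  expect_equal(length(unique(flat[, 1])), 1L)
  expect_equal(length(unique(vol[, 1])), 7L)
  expect_equal(nrow(vol), 7L * nrow(flat))
  # inside the homogeneous FGT band both variants agree
  expect_equal(local_percent_density(s$labels, vol),
               local_percent_density(s$labels, flat))
})

test_that("local density is invariant to rigid translation of volume + ROI", {
  s <- synthetic_labels()
  roi <- place_roi(s$labels, s$spacing, s$origin, s$nipple, depth_cm = 0.6,
                   width_cm = 0.6, height_cm = 0.8)
  d1 <- local_percent_density(s$labels, roi)
  origin2 <- s$origin + c(7, -3, 2)
  roi2 <- place_roi(s$labels, s$spacing, origin2, s$nipple + c(7, -3, 2),
                    depth_cm = 0.6, width_cm = 0.6, height_cm = 0.8)
  expect_equal(local_percent_density(s$labels, roi2), d1)
})

test_that("ROI density on the deformed phantom hits the retroareolar core", {
  ph <- phantom_fixture()
  seg <- segmentation_fixture()
  mesh <- breast_mesh_fixture()
  zg <- zero_gravity_fixture()$mesh
  st <- solve_static(zg, material_params(), gravity = c(0, -9.81, 0),
                     load_factor = 1)
  w <- warp_labels(mesh, st$current_nodes, seg$fgt_mask, seg$breast_mask,
                   ph$image$spacing, ph$image$origin)
  nip <- st$current_nodes[mesh$nipple_node, ]
  roi <- place_roi(w, ph$image$spacing, ph$image$origin, nip, depth_cm = 1.41)
  ld <- local_percent_density(w, roi)
  # the ROI depth of the study lands inside the phantom's dense core
  expect_gt(ld, 50)
})
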