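test_that("growcut matches a brute-force cellular automaton oracle", {
  dims <- c(20, 20, 20)
  vol <- array(0, dims)
  vol[1:10, , ] <- 1000
  withr::with_seed(7, {
    vol <- vol + array(rnorm(prod(dims), sd = 40), dims)
  })
  lab <- array(0L, dims)
  lab[4, 9, 11] <- 1L
  lab[16, 12, 6] <- 2L

  seg <- growcut_segment(volume3d(vol, spacing = 1), seed_image(lab))
  oracle <- growcut_oracle(vol, lab)
  expect_identical(as.vector(seg$labels), as.vector(oracle$label))
  expect_equal(as.vector(seg$strength), as.vector(oracle$strength),
               tolerance = 1e-12)
  expect_true(seg$converged)
})

test_that("sharp two-compartment phantom splits exactly at the boundary", {
  dims <- c(20, 20, 20)
  vol <- array(0, dims)
  vol[1:10, , ] <- 1000
  lab <- array(0L, dims)
  lab[5, 10, 10] <- 1L
  lab[15, 10, 10] <- 2L
  seg <- growcut_segment(volume3d(vol, spacing = 1), seed_image(lab))
  expect_identical(seg$mask, vol == 1000)
})

test_that("growcut honours seed conservation and strength monotonicity", {
  dims <- c(12, 12, 12)
  vol <- withr::with_seed(3, array(runif(prod(dims)), dims))
  lab <- array(0L, dims)
  lab[2, 2, 2] <- 1L
  lab[11, 11, 11] <- 2L
  seeds <- seed_image(lab)
  seg <- growcut_segment(volume3d(vol, spacing = 1), seeds)
  expect_true(seg$converged)
  # seeded voxels with strength 1 never change label
  expect_identical(seg$labels[lab != 0L], lab[lab != 0L])
  expect_true(all(seg$strength[lab != 0L] == 1))
  # strengths are bounded and non-negative; every voxel got labelled
  expect_true(all(seg$strength >= 0 & seg$strength <= 1))
  expect_true(all(seg$labels %in% c(1L, 2L)))
  # strength after fewer iterations is nowhere above the converged state
  seg1 <- suppressWarnings(
    growcut_segment(volume3d(vol, spacing = 1), seeds, max_iters = 2L))
  expect_true(all(seg$strength - seg1$strength >= -1e-12))
})

test_that("growcut rejects degenerate seed images", {
  vol <- volume3d(array(1, c(5, 5, 5)), spacing = 1)
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  expect_error(growcut_segment(vol, seed_image(lab)), "background")
  lab[3, 3, 3] <- 2L
  expect_error(growcut_segment(vol, seed_image(lab)), "foreground")
  lab2 <- array(0L, c(4, 4, 4))
  lab2[1, 1, 1] <- 1L; lab2[4, 4, 4] <- 2L
  expect_error(growcut_segment(vol, seed_image(lab2)), "shape")
})

test_that("morphological cleanup matches a brute-force oracle", {
  dims <- c(12, 12, 12)
  m <- array(FALSE, dims)
  m[3:9, 3:9, 3:9] <- TRUE
  m[10, 6, 6] <- TRUE  # single-voxel spur
  for (r in c(1, 2)) {
    expect_identical(morph_cleanup(m, erode_r = r),
                     morph_oracle(m, r, dilate = FALSE))
    expect_identical(morph_cleanup(m, dilate_r = r),
                     morph_oracle(m, r, dilate = TRUE))
  }
  # opening with a blunt-tipped ball removes the spur but keeps the cube
  # interior (a face-backed single-voxel spur survives openings whose
  # discrete ball itself ends in a single-voxel tip, e.g. r = 1 or 2)
  opened <- morph_cleanup(m, erode_r = 2.3, dilate_r = 2.3)
  expect_false(opened[10, 6, 6])
  expect_true(all(opened[4:8, 4:8, 4:8]))
})

test_that("cleanup identity, largest-component and emptying contracts", {
  dims <- c(15, 15, 15)
  m <- array(FALSE, dims)
  m[2:11, 2:11, 2:11] <- TRUE      # 1000 voxels
  m[14, 14, 13:14] <- TRUE         # small distant component
  expect_identical(morph_cleanup(m), m)
  kept <- morph_cleanup(m, keep_largest = TRUE)
  expect_true(all(kept[2:11, 2:11, 2:11]))
  expect_false(any(kept[14, 14, ]))
  thin <- array(FALSE, dims); thin[5, 5, 5] <- TRUE
  expect_error(morph_cleanup(thin, erode_r = 1), "emptied")
})

test_that("isosurface of a rasterized sphere has the analytic area", {
  sph <- sphere_mesh(4000)
  r <- rasterize(sph, spacing = 0.05)
  surf <- extract_surface(r$mask, spacing = 0.05, origin = r$volume$origin)
  expect_true(is_closed_mesh(surf))
  expect_lt(abs(mesh_area(surf) - 4 * pi) / (4 * pi), 0.05)
  expect_lt(abs(mesh_volume(surf) - 4 * pi / 3) / (4 * pi / 3), 0.05)
})

test_that("single-voxel isosurface is closed with sub-voxel volume", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  s <- extract_surface(m, spacing = 0.1, smooth_sigma = 0)
  expect_true(is_closed_mesh(s))
  v <- mesh_volume(s)
  # a midpoint-interpolated isosurface encloses between the inscribed
  # octahedron (s^3/6) and the full voxel cube (s^3)
  expect_gt(v, 0.1^3 / 6 - 1e-12)
  expect_lt(v, 0.1^3 + 1e-12)
  expect_equal(colMeans(s$vertices), rep(0.25, 3), tolerance = 1e-9)
  expect_error(extract_surface(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("isosurface vertices stay within the mask bounding box", {
  m <- array(FALSE, c(10, 12, 9))
  m[4:7, 3:9, 2:6] <- TRUE
  s <- extract_surface(m, spacing = 1, smooth_sigma = 0.5)
  # bbox of foreground voxel centres expanded by one voxel
  lo <- c(4, 3, 2) - 0.5 - 1
  hi <- c(7, 9, 6) - 0.5 + 1
  expect_true(all(sweep(s$vertices, 2, lo, ">=")))
  expect_true(all(sweep(s$vertices, 2, hi, "<=")))
})

test_that("pipeline recovers the phantom surface to sub-voxel accuracy", {
  tpl <- tpl_mid()
  mesh <- template_mesh(tpl)
  r <- rasterize(mesh, spacing = 0.096, fg = 1000, bg = 0,
                 noise_sd = 50, seed = 12)
  seeds <- seeds_from_mask(r$mask)
  seg <- growcut_segment(r$volume, seeds)
  expect_true(seg$converged)
  expect_gte(dice_coefficient(seg$mask, r$mask), 0.95)
  surf <- extract_surface(morph_cleanup(seg, keep_largest = TRUE))
  expect_lt(surface_distance(surf, mesh)$symmetric_mean, 0.096)
})
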