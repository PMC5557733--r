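test_that("fitting the template to itself is a fixed point", {
  tpl <- tpl_mid()
  fit <- fit_template(tpl, template_mesh(tpl), template_landmarks(tpl))
  expect_lt(max(abs(fit$nodes - tpl$nodes)), 1e-6)
  expect_lt(fit$diagnostics$mean_dist_mm, 1e-9)
  expect_identical(nrow(fit$nodes), tpl$node_count)
})

test_that("a known smooth deformation is recovered at zero noise", {
  tpl <- tpl_mid()
  ef <- effect_field(c("angular_process", "coronoid_process"),
                     dx = c(-0.2, 0.1), dy = c(0.05, -0.1))
  sp <- simulate_specimen(tpl, ef, noise_sd = 0, landmark_jitter_sd = 0,
                          seed = 3)
  fit <- fit_template(tpl, sp$mesh, sp$landmarks)
  truth <- tpl$nodes + evaluate_effect_field(ef, tpl$nodes, tpl)
  rms <- sqrt(mean((fit$nodes - truth)^2))
  expect_lt(rms, 0.02)
})

test_that("node count is preserved regardless of target tessellation", {
  tpl <- tpl_small()
  sp <- simulate_specimen(tpl, NULL, noise_sd = 0.05,
                          landmark_jitter_sd = 0, seed = 6)
  # re-tessellate the target through the voxel pipeline
  r <- rasterize(sp$mesh, spacing = 0.12)
  surf <- extract_surface(r$mask, spacing = 0.12, origin = r$volume$origin)
  expect_false(nrow(surf$vertices) == tpl$node_count)
  fit <- fit_template(tpl, surf, sp$landmarks)
  expect_identical(nrow(fit$nodes), tpl$node_count)
})

test_that("fit progress is monotone on noise-free targets", {
  tpl <- tpl_small()
  ef <- effect_field("condyle", dx = 0.15, dz = 0.1)
  sp <- simulate_specimen(tpl, ef, noise_sd = 0, landmark_jitter_sd = 0,
                          seed = 8)
  fit <- fit_template(tpl, sp$mesh, sp$landmarks, n_iters = 4L)
  d <- fit$diagnostics$per_iteration[, "mean"]
  expect_true(all(diff(d) <= 1e-12))
})

test_that("fitting is equivariant under rigid motion", {
  tpl <- tpl_small()
  sp <- simulate_specimen(tpl, NULL, noise_sd = 0.05,
                          landmark_jitter_sd = 0.02, seed = 10)
  fit0 <- fit_template(tpl, sp$mesh, sp$landmarks)
  mo <- rigid_motion(31)
  sp2 <- move_specimen(sp, mo)
  fit1 <- fit_template(tpl, sp2$mesh, sp2$landmarks)
  expect_lt(max(abs(fit1$nodes - move_points(fit0$nodes, mo))), 1e-6)
})

test_that("a hopeless fit trips the projection gate", {
  tpl <- tpl_small()
  far <- template_mesh(tpl)
  far$vertices <- far$vertices * 0.1   # target 10x smaller than template
  lms <- template_landmarks(tpl)
  expect_error(fit_template(tpl, far, lms, max_gate_mm = 0.5), "failed")
})

test_that("fit_quality reports exact distances and edge resolution", {
  tpl <- tpl_small()
  model <- as_homogeneous_model(tpl$nodes, tpl)
  q0 <- fit_quality(model, template_mesh(tpl), tpl)
  expect_lt(q0$mean_dist_mm, 1e-12)
  expect_lt(q0$sd_dist_mm, 1e-12)

  # nodes translated off a known surface by 0.1 mm
  shifted <- as_homogeneous_model(tpl$nodes + rep(c(0.1, 0, 0),
                                                  each = nrow(tpl$nodes)),
                                  tpl)
  # distance to the original surface is at most 0.1 (exactly 0.1 where the
  # surface is locally planar and normal to x)
  q1 <- fit_quality(shifted, template_mesh(tpl), tpl)
  expect_lte(q1$mean_dist_mm, 0.1 + 1e-9)
  expect_gt(q1$mean_dist_mm, 0.05)

  # plane target: exact forced distance
  plane <- surface_mesh(rbind(c(-50, 0, -50), c(50, 0, -50), c(50, 0, 50),
                              c(-50, 0, 50)),
                        rbind(c(1, 2, 3), c(1, 3, 4)))
  pts <- cbind(seq(-1, 1, length.out = 10), 0.1, seq(-1, 1, length.out = 10))
  pm <- structure(list(nodes = pts, template_id = NULL,
                       diagnostics = list()), class = "homogeneous_model")
  d <- closest_points(pts, plane)$distance
  expect_equal(d, rep(0.1, 10), tolerance = 1e-12)
})
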