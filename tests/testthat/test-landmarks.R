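test_that("landmark validation reports missing, extra and duplicates", {
  tpl <- tpl_small()
  lms <- template_landmarks(tpl)
  v <- validate_landmarks(lms, tpl)
  expect_true(v$ok)

  v2 <- validate_landmarks(lms[lms$name != "mental_foramen", ], tpl)
  expect_false(v2$ok)
  expect_identical(v2$missing, "mental_foramen")

  dup <- rbind(as.data.frame(lms), as.data.frame(lms)[1, ])
  v3 <- validate_landmarks(dup, tpl)
  expect_false(v3$ok)
  expect_identical(v3$duplicated, dup$name[1])

  bad <- lms; bad$x[3] <- NaN
  v4 <- validate_landmarks(bad, tpl)
  expect_false(v4$ok)
  expect_identical(v4$nonfinite, lms$name[3])

  extra <- rbind(as.data.frame(lms),
                 data.frame(name = "spurious", x = 0, y = 0, z = 0))
  expect_identical(validate_landmarks(extra, tpl)$extra, "spurious")
})

test_that("the standardized frame has the stated geometric properties", {
  tpl <- tpl_small()
  lms <- template_landmarks(tpl)
  fr <- build_frame(lms)
  expect_lt(max(abs(fr$axes %*% t(fr$axes) - diag(3))), 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)

  std <- apply_frame(lms, fr)
  expect_lt(max(abs(mandmap:::lm_point(std, "mental_foramen"))), 1e-12)
  # occlusal y-coordinates, centred, are the least-squares plane residuals
  roles <- attr(lms, "roles")
  occ <- mandmap:::lm_coords(lms)[roles$occlusal, ]
  cc <- sweep(occ, 2, colMeans(occ))
  nrm <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 3]
  resid <- cc %*% nrm
  occ_y <- std$y[match(roles$occlusal, std$name)]
  got <- occ_y - mean(occ_y)
  expect_true(max(abs(got - resid)) < 1e-9 || max(abs(got + resid)) < 1e-9)
  expect_lt(abs(mean(resid)), 1e-10)
  # superior reference above the plane, posterior reference at +z, x = 0
  expect_gt(std$y[std$name == roles$superior], 0)
  expect_gt(std$z[std$name == roles$posterior], 0)
  expect_lt(abs(std$x[std$name == roles$posterior]), 1e-12)
})

test_that("coplanar occlusal landmarks get exactly zero residuals", {
  # synthetic set with a perfectly flat occlusal plane
  df <- tibble::tibble(
    name = c("mental_foramen", "o1", "o2", "o3", "o4", "post", "sup"),
    x = c(0.5, 0.3, -0.3, 0.3, -0.3, 0, 0),
    y = c(-0.2, 1, 1, 1, 1, 0.8, 3),
    z = c(-3, -0.5, -0.5, -1.5, -1.5, 6, 2))
  ls <- landmark_set(df, roles = list(occlusal = c("o1", "o2", "o3", "o4"),
                                      posterior = "post", superior = "sup"))
  std <- apply_frame(ls, build_frame(ls))
  expect_lt(max(abs(std$y[std$name %in% c("o1", "o2", "o3", "o4")] -
                    mean(std$y[std$name %in% c("o1", "o2", "o3", "o4")]))),
            1e-12)
})

test_that("frame construction rejects degenerate configurations", {
  df <- tibble::tibble(
    name = c("mental_foramen", "o1", "o2", "o3", "post", "sup"),
    x = c(0, 0, 0, 0, 0, 0),
    y = c(0, 1, 1, 1, 1, 2),
    z = c(0, 0, 1, 2, 5, 1))   # collinear occlusal landmarks
  ls <- landmark_set(df, roles = list(occlusal = c("o1", "o2", "o3"),
                                      posterior = "post", superior = "sup"))
  expect_error(build_frame(ls), "collinear")
  expect_error(build_frame(ls[ls$name != "mental_foramen", ]),
               "mental_foramen")
})

test_that("apply_frame is rigid and the identity frame is a no-op", {
  tpl <- tpl_small()
  mesh <- template_mesh(tpl)
  idf <- structure(list(origin = c(0, 0, 0), axes = diag(3)),
                   class = "coordinate_frame")
  expect_equal(apply_frame(mesh, idf)$vertices, mesh$vertices)

  lms <- template_landmarks(tpl)
  fr <- build_frame(lms)
  p0 <- mandmap:::lm_coords(lms)
  p1 <- mandmap:::lm_coords(apply_frame(lms, fr))
  d0 <- as.vector(dist(p0[1:20, ]))
  d1 <- as.vector(dist(p1[1:20, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("standardization is idempotent", {
  tpl <- tpl_small()
  lms <- apply_frame(template_landmarks(tpl),
                     build_frame(template_landmarks(tpl)))
  fr2 <- build_frame(lms)
  expect_lt(max(abs(fr2$origin)), 1e-9)
  expect_lt(max(abs(fr2$axes - diag(3))), 1e-9)
})

test_that("landmark reliability equals the brute-force pairwise mean", {
  tpl <- tpl_small()
  base <- template_landmarks(tpl)
  reps <- lapply(1:3, function(i) {
    l <- base
    p <- withr::with_seed(100 + i,
                          matrix(rnorm(nrow(l) * 3, sd = 0.03), ncol = 3))
    l$x <- l$x + p[, 1]; l$y <- l$y + p[, 2]; l$z <- l$z + p[, 3]
    l
  })
  rel <- landmark_reliability(reps)
  # brute force over the three pairs
  pj <- lapply(reps, mandmap:::lm_coords)
  manual <- (sqrt(rowSums((pj[[1]] - pj[[2]])^2)) +
             sqrt(rowSums((pj[[1]] - pj[[3]])^2)) +
             sqrt(rowSums((pj[[2]] - pj[[3]])^2))) / 3
  expect_equal(rel$per_landmark$mean_error_mm, unname(manual),
               tolerance = 1e-12)
  expect_equal(rel$grand_mean_mm, mean(manual), tolerance = 1e-12)

  expect_equal(landmark_reliability(list(base, base))$grand_mean_mm, 0)
  two <- landmark_reliability(list(base, within(as.data.frame(base),
                                                x[1] <- x[1] + 0.1)))
  expect_equal(two$per_landmark$mean_error_mm[1], 0.1, tolerance = 1e-12)
  expect_true(all(two$per_landmark$mean_error_mm[-1] == 0))
  expect_error(landmark_reliability(list(base)), "at least 2")
  other <- base; other$name[1] <- "renamed"
  expect_error(landmark_reliability(list(base, other)), "mismatch")
})
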