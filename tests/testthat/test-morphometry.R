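mk_models <- function(tpl, values) {
  lapply(values, function(v) {
    as_homogeneous_model(matrix(v, tpl$node_count, 3), tpl)
  })
}

test_that("averaging equals the brute-force per-node arithmetic", {
  tpl <- tpl_small()
  set.seed(14)
  models <- lapply(1:4, function(i) {
    as_homogeneous_model(tpl$nodes +
                           matrix(rnorm(length(tpl$nodes), sd = 0.05),
                                  ncol = 3), tpl)
  })
  avg <- average_model(models)
  arr <- sapply(models, function(m) m$nodes, simplify = "array")
  expect_equal(avg$mean, apply(arr, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(avg$sd, apply(arr, c(1, 2), sd), tolerance = 1e-12)

  same <- average_model(models[c(1, 1)])
  expect_equal(same$mean, models[[1]]$nodes)
  expect_true(all(same$sd == 0))

  # two models symmetric about the template average back to it
  d <- matrix(rnorm(length(tpl$nodes), sd = 0.1), ncol = 3)
  sym <- average_model(list(as_homogeneous_model(tpl$nodes + d, tpl),
                            as_homogeneous_model(tpl$nodes - d, tpl)))
  expect_equal(sym$mean, tpl$nodes, tolerance = 1e-12)
  expect_error(average_model(models[1]), ">= 2")
})

test_that("difference maps subtract means and are antisymmetric", {
  tpl <- tpl_small()
  set.seed(15)
  ma <- mk_models(tpl, list(1, 2))
  mb <- lapply(list(1, 2), function(v) {
    as_homogeneous_model(matrix(v, tpl$node_count, 3) +
                           rep(c(0, -0.1, 0), each = tpl$node_count), tpl)
  })
  a <- average_model(ma, "A"); b <- average_model(mb, "B")
  d <- difference_map(a, b)
  expect_true(all(abs(d$delta[, "y"] - 0.1) < 1e-12))
  expect_true(all(abs(d$delta[, c("x", "z")]) < 1e-12))
  expect_equal(difference_map(b, a)$delta, -d$delta)
  expect_true(all(difference_map(a, a)$delta == 0))
})

test_that("per-node t statistics match the stats::t.test oracle", {
  tpl <- fixture("tpl_tiny", function() make_template(120L))
  set.seed(16)
  n1 <- 7; n2 <- 9
  ga <- lapply(seq_len(n1), function(i) {
    as_homogeneous_model(matrix(rnorm(tpl$node_count * 3), ncol = 3), tpl)
  })
  gb <- lapply(seq_len(n2), function(i) {
    as_homogeneous_model(matrix(rnorm(tpl$node_count * 3, mean = 0.2),
                                ncol = 3), tpl)
  })
  sig <- significance_map(ga, gb)
  sigw <- significance_map(ga, gb, variant = "welch")
  A <- sapply(ga, function(m) m$nodes, simplify = "array")
  B <- sapply(gb, function(m) m$nodes, simplify = "array")
  idx <- cbind(sample(tpl$node_count, 1000, replace = TRUE),
               sample(3, 1000, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    x <- A[idx[k, 1], idx[k, 2], ]
    y <- B[idx[k, 1], idx[k, 2], ]
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(unname(sig$t[idx[k, 1], idx[k, 2]]), unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(sig$p[idx[k, 1], idx[k, 2]]), tt$p.value, tolerance = 1e-8)
    tw <- t.test(x, y, var.equal = FALSE)
    expect_equal(unname(sigw$p[idx[k, 1], idx[k, 2]]), tw$p.value, tolerance = 1e-8)
  }
})

test_that("textbook example and degenerate inputs behave as specified", {
  tpl <- fixture("tpl_tiny", function() make_template(120L))
  sig <- significance_map(mk_models(tpl, list(1, 2, 3)),
                          mk_models(tpl, list(4, 5, 6)))
  expect_equal(unname(sig$t[1, 1]), -3.674235, tolerance = 1e-6)
  expect_equal(unname(sig$p[1, 1]), 2 * pt(-3.674235, 4), tolerance = 1e-6)
  expect_identical(unname(sig$category[1, 1]), "p05")

  same <- significance_map(mk_models(tpl, list(1, 1)),
                           mk_models(tpl, list(1, 1)))
  expect_true(all(same$t == 0) && all(same$p == 1))

  deg <- significance_map(mk_models(tpl, list(1, 1)),
                          mk_models(tpl, list(2, 2)))
  expect_true(all(deg$degenerate))
  expect_true(all(is.na(deg$p)))
  expect_true(all(is.na(deg$category)))

  expect_error(significance_map(mk_models(tpl, list(1)),
                                mk_models(tpl, list(1, 2))), ">= 2")
})

test_that("p-value banding follows the published thresholds", {
  expect_identical(categorize_p(0.03), "p05")
  expect_identical(categorize_p(0.00005), "p0001")
  expect_identical(categorize_p(0.2), "ns")
  expect_identical(categorize_p(0.01), "p01")
  expect_identical(categorize_p(0.001), "p001")
  expect_identical(categorize_p(0.0001), "p0001")
  expect_identical(categorize_p(1), "ns")
  expect_identical(categorize_p(0), "p0001")
  expect_error(categorize_p(1.2), "\\[0, 1\\]")
  expect_error(categorize_p(-0.1), "\\[0, 1\\]")
})

test_that("map categories always agree with their p-values", {
  tpl <- tpl_small()
  st <- simulate_groups(tpl, effect_field("condyle", dy = 0.1),
                        noise_sd = 0.05, n_a = 4, n_b = 4, seed = 17)
  sig <- significance_map(lapply(st$group_a, `[[`, "mesh"),
                          lapply(st$group_b, `[[`, "mesh"))
  for (cat in names(mandmap:::P_THRESHOLDS)) {
    sel <- !is.na(sig$category) & sig$category == cat
    if (any(sel)) {
      expect_true(all(sig$p[sel] <= mandmap:::P_THRESHOLDS[[cat]]))
    }
  }
  sel_ns <- !is.na(sig$category) & sig$category == "ns"
  expect_true(all(sig$p[sel_ns] > 0.05))
})

test_that("accentuation is the stated linear extrapolation", {
  tpl <- tpl_small()
  set.seed(18)
  ma <- lapply(1:2, function(i) {
    as_homogeneous_model(tpl$nodes + matrix(rnorm(length(tpl$nodes),
                                                  sd = 0.02), ncol = 3), tpl)
  })
  mb <- lapply(1:2, function(i) {
    as_homogeneous_model(tpl$nodes + matrix(rnorm(length(tpl$nodes),
                                                  sd = 0.02), ncol = 3), tpl)
  })
  ref <- average_model(ma, "ref"); grp <- average_model(mb, "grp")
  expect_equal(accentuate(ref, grp, k = 1)$nodes, grp$mean)
  expect_equal(accentuate(ref, grp, k = 0)$nodes, ref$mean)
  acc2 <- accentuate(ref, grp, k = 2)
  expect_equal(acc2$nodes - ref$mean, 2 * (grp$mean - ref$mean),
               tolerance = 1e-12)
  # fixed point
  expect_equal(accentuate(ref, ref, k = 5)$nodes, ref$mean)
  expect_error(accentuate(ref, grp, k = -1), "k")
})

test_that("region summary reports the injected effect and flips with groups", {
  tpl <- tpl_mid()
  ef <- effect_field("angular_process", dx = -0.2)
  st <- simulate_groups(tpl, ef, noise_sd = 0.02, landmark_jitter_sd = 0,
                        n_a = 7, n_b = 9, seed = 19)
  ma <- lapply(st$group_a, `[[`, "mesh")
  mb <- lapply(st$group_b, `[[`, "mesh")
  sig <- significance_map(ma, mb)
  d_sd_hd <- difference_map(average_model(mb, "SD"), average_model(ma, "HD"))
  rs <- region_summary(d_sd_hd, sig, tpl)
  cell <- rs[rs$region == "angular_process" & rs$surface == "lateral" &
               rs$axis == "x", ]
  expect_identical(cell$direction, "Inward")
  expect_identical(cell$significance, "****")
  # swapping groups flips the direction word
  d_hd_sd <- difference_map(average_model(ma, "HD"), average_model(mb, "SD"))
  rs2 <- region_summary(d_hd_sd, sig, tpl)
  cell2 <- rs2[rs2$region == "angular_process" & rs2$surface == "lateral" &
                 rs2$axis == "x", ]
  expect_identical(cell2$direction, "Outward")

  # effect-free noise-free groups: every p is 1 and every row NS
  st0 <- simulate_groups(tpl, NULL, noise_sd = 0, landmark_jitter_sd = 0,
                         n_a = 3, n_b = 3, seed = 20)
  sig0 <- significance_map(lapply(st0$group_a, `[[`, "mesh"),
                           lapply(st0$group_b, `[[`, "mesh"))
  expect_true(all(sig0$p == 1))
  d0 <- difference_map(average_model(lapply(st0$group_a, `[[`, "mesh")),
                       average_model(lapply(st0$group_b, `[[`, "mesh")))
  rs0 <- region_summary(d0, sig0, tpl)
  expect_true(all(rs0$direction == "NS"))
})

test_that("statistical power grows with effect amplitude", {
  tpl <- tpl_small()
  amps <- c(0.02, 0.05, 0.1)
  reps <- 50
  sel <- tpl$atlas$region == "condyle"
  counts <- matrix(0, reps, length(amps))
  for (r in seq_len(reps)) {
    for (a in seq_along(amps)) {
      st <- simulate_groups(tpl, effect_field("condyle", dy = amps[a]),
                            noise_sd = 0.05, landmark_jitter_sd = 0,
                            n_a = 5, n_b = 5, seed = 5000 + r)
      sig <- significance_map(lapply(st$group_a, `[[`, "mesh"),
                              lapply(st$group_b, `[[`, "mesh"))
      counts[r, a] <- sum(sig$p[sel, "y"] <= 0.05, na.rm = TRUE)
    }
  }
  expect_true(all(diff(colMeans(counts)) > 0))
  # majority ordering across replicates, pairwise
  expect_gt(mean(counts[, 2] >= counts[, 1]), 0.5)
  expect_gt(mean(counts[, 3] >= counts[, 2]), 0.5)
})
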