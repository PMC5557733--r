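small_cfg <- function(seed = 7) {
  list(synthetic = list(node_count = 800, n_a = 3, n_b = 3,
                        noise_sd = 0.03, landmark_jitter_sd = 0.01,
                        effect = list(region = "angular_process",
                                      dx = -0.2)),
       seed = seed)
}

test_that("a synthetic study produces the full artifact set", {
  out <- withr::local_tempdir()
  rep <- run_study(small_cfg(), out_dir = out)
  files <- list.files(out)
  expect_setequal(
    intersect(files, c("diff_x.ply", "diff_y.ply", "diff_z.ply",
                       "p_x.ply", "p_y.ply", "p_z.ply")),
    c("diff_x.ply", "diff_y.ply", "diff_z.ply",
      "p_x.ply", "p_y.ply", "p_z.ply"))
  expect_true(all(c("accentuated.ply", "region_summary.csv",
                    "manifest.json") %in% files))
  expect_s3_class(rep$region_summary, "tbl_df")
  expect_identical(nrow(rep$average_a$mean), 800L)
  # manifest re-describes the run
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$seed, 7L)
  expect_identical(man$n, c(3L, 3L))
  # maps carry the colour channels and scalar properties
  pm <- read_ply(file.path(out, "p_y.ply"))
  expect_true(all(c("py", "red", "green", "blue") %in%
                    names(pm$properties)))
  expect_true(all(pm$properties$py >= 0 & pm$properties$py <= 1))
})

test_that("rerunning with the same seed is byte-identical", {
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  run_study(small_cfg(), out_dir = o1)
  run_study(small_cfg(), out_dir = o2)
  f1 <- file.path(o1, "region_summary.csv")
  f2 <- file.path(o2, "region_summary.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d1 <- file.path(o1, "diff_x.ply"); d2 <- file.path(o2, "diff_x.ply")
  expect_identical(readBin(d1, "raw", file.size(d1)),
                   readBin(d2, "raw", file.size(d2)))
})

test_that("invalid configurations are rejected before any compute", {
  cfg <- small_cfg()
  cfg$synthetic$n_a <- 1
  expect_error(run_study(cfg), ">= 2")
  cfg2 <- small_cfg()
  cfg2$thresholds <- c(0.01, 0.05)
  expect_error(run_study(cfg2), "decreasing")
  cfg3 <- list(group_a = list(list(mesh = "missing.stl",
                                   landmarks = "missing.csv")),
               group_b = list())
  expect_error(run_study(cfg3), "at least 2")
})

test_that("a file-based study reproduces the in-memory pipeline", {
  dir <- withr::local_tempdir()
  tpl <- make_template(600L)
  tpath <- file.path(dir, "template.ply")
  write_template(tpl, tpath)
  st <- simulate_groups(tpl, effect_field("condyle", dy = 0.15),
                        noise_sd = 0.02, landmark_jitter_sd = 0.01,
                        n_a = 4, n_b = 4, seed = 3)
  cfg <- list(template = tpath, seed = 3,
              group_a = list(), group_b = list())
  write_spec <- function(s, tag) {
    mp <- file.path(dir, paste0(tag, ".stl"))
    lp <- file.path(dir, paste0(tag, ".json"))
    write_mesh(s$mesh, mp)
    write_landmarks(s$landmarks, lp)
    list(mesh = mp, landmarks = lp)
  }
  cfg$group_a <- lapply(seq_along(st$group_a), function(i) {
    write_spec(st$group_a[[i]], paste0("a", i))
  })
  cfg$group_b <- lapply(seq_along(st$group_b), function(i) {
    write_spec(st$group_b[[i]], paste0("b", i))
  })
  rep <- run_study(cfg)
  expect_identical(nrow(rep$average_a$mean), 600L)

  # the file-based run must reproduce the equivalent in-memory pipeline
  # (STL stores float32, so coordinates agree to ~1e-6 mm)
  fitf <- function(s) {
    fr <- build_frame(s$landmarks)
    fit_template(tpl, apply_frame(s$mesh, fr), apply_frame(s$landmarks, fr))
  }
  ma <- lapply(st$group_a, fitf)
  mb <- lapply(st$group_b, fitf)
  expect_lt(max(abs(rep$average_a$mean - average_model(ma)$mean)), 1e-4)
  expect_lt(max(abs(rep$average_b$mean - average_model(mb)$mean)), 1e-4)
  sig <- significance_map(ma, mb)
  agree <- abs(rep$significance$p - sig$p)
  expect_lt(stats::median(agree, na.rm = TRUE), 1e-3)
})
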