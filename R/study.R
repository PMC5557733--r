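# Study orchestration: validated configuration in, full pipeline out
# (standardize -> fit -> average -> maps -> accentuate -> region summary),
# with every artifact written alongside a manifest.

#' Validate a study configuration
#'
#' A study configuration is a named list with either a \code{synthetic}
#' block (template/effect/noise parameters for a simulated study) or two
#' specimen lists \code{group_a}/\code{group_b} whose entries give
#' \code{mesh} and \code{landmarks} paths. Optional fields:
#' \code{labels} (default HD/SD), \code{template} (path to a template
#' PLY), \code{fit} (lambda, n_iters, smooth_weight), \code{variant}
#' ("student"/"welch"), \code{fdr}, \code{accentuation_k} (default 2),
#' \code{seed}, \code{out_dir}.
#'
#' @param config named list.
#' @return the completed config (defaults filled), or an error.
#' @export
study_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config$labels <- config$labels %||% c("HD", "SD")
  config$variant <- config$variant %||% "student"
  config$fdr <- isTRUE(config$fdr)
  config$accentuation_k <- config$accentuation_k %||% 2
  config$seed <- as.integer(config$seed %||% 1L)
  config$fit <- config$fit %||% list()
  config$fit$lambda <- config$fit$lambda %||% 0
  config$fit$n_iters <- config$fit$n_iters %||% 3L
  config$fit$smooth_weight <- config$fit$smooth_weight %||% 0.5
  thr <- config$thresholds %||% unname(P_THRESHOLDS)
  if (any(diff(thr) >= 0) || any(thr <= 0) || any(thr >= 1)) {
    stopf("thresholds must be strictly decreasing and inside (0, 1)")
  }
  config$thresholds <- thr

  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    sy$node_count <- sy$node_count %||% 12186L
    sy$n_a <- sy$n_a %||% 7L
    sy$n_b <- sy$n_b %||% 9L
    sy$noise_sd <- sy$noise_sd %||% 0.1
    sy$landmark_jitter_sd <- sy$landmark_jitter_sd %||% 0.05
    if (sy$n_a < 2L || sy$n_b < 2L) {
      stopf("each group needs >= 2 specimens")
    }
    config$synthetic <- sy
  } else {
    for (g in c("group_a", "group_b")) {
      if (length(config[[g]]) < 2L) {
        stopf("%s must list at least 2 specimens", g)
      }
      for (sp in config[[g]]) {
        for (f in c("mesh", "landmarks")) {
          if (is.null(sp[[f]]) || !file.exists(sp[[f]])) {
            stopf("unresolvable %s path in %s", f, g)
          }
        }
      }
    }
  }
  config
}

#' Run a full two-group morphometry study
#'
#' Standardizes every specimen into its landmark frame, fits the template,
#' averages the groups, computes displacement and significance maps, the
#' accentuated group-B average, and the per-region summary; writes the six
#' per-axis map files, the accentuated model, the summary CSV and a
#' manifest to \code{out_dir} (when given). Deterministic for a fixed
#' config and seed.
#'
#' @param config a study configuration (list or path; see
#'   \code{study_config}).
#' @param out_dir output directory (overrides config; NULL keeps results
#'   in memory only).
#' @return a \code{study_report} list: template, models, averages,
#'   difference map (A - B), significance map, accentuated model, region
#'   summary, fit diagnostics and manifest.
#' @export
run_study <- function(config, out_dir = NULL) {
  config <- study_config(config)
  out_dir <- out_dir %||% config$out_dir

  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    template <- make_template(node_count = sy$node_count)
    eff <- if (!is.null(sy$effect)) {
      effect_field(region = sy$effect$region, dx = sy$effect$dx %||% 0,
                   dy = sy$effect$dy %||% 0, dz = sy$effect$dz %||% 0,
                   falloff = sy$effect$falloff %||% 1.5)
    } else NULL
    study <- simulate_groups(template, effect = eff,
                             noise_sd = sy$noise_sd,
                             landmark_jitter_sd = sy$landmark_jitter_sd,
                             n_a = sy$n_a, n_b = sy$n_b,
                             seed = config$seed, labels = config$labels)
    specs_a <- study$group_a
    specs_b <- study$group_b
  } else {
    template <- if (!is.null(config$template)) read_template(config$template)
                else make_template()
    load_spec <- function(sp) {
      list(mesh = read_mesh(sp$mesh),
           landmarks = read_landmarks(sp$landmarks,
                                      roles = .schema_roles(template)))
    }
    specs_a <- lapply(config$group_a, load_spec)
    specs_b <- lapply(config$group_b, load_spec)
  }

  fit_one <- function(sp, id) {
    fr <- build_frame(sp$landmarks)
    mesh <- apply_frame(sp$mesh, fr)
    lms <- apply_frame(sp$landmarks, fr)
    tryCatch(
      fit_template(template, mesh, lms,
                   lambda = config$fit$lambda,
                   n_iters = config$fit$n_iters,
                   smooth_weight = config$fit$smooth_weight),
      error = function(e) stopf("stage fit failed for specimen %s: %s",
                                id, conditionMessage(e)))
  }
  models_a <- lapply(seq_along(specs_a), function(i) {
    fit_one(specs_a[[i]], paste0(config$labels[1], i))
  })
  models_b <- lapply(seq_along(specs_b), function(i) {
    fit_one(specs_b[[i]], paste0(config$labels[2], i))
  })

  avg_a <- average_model(models_a, label = config$labels[1])
  avg_b <- average_model(models_b, label = config$labels[2])
  diff_ab <- difference_map(avg_a, avg_b)     # figure convention: A - B
  diff_ba <- difference_map(avg_b, avg_a)     # table convention: B vs A
  sig <- significance_map(models_a, models_b, variant = config$variant,
                          fdr = config$fdr)
  acc <- accentuate(avg_a, avg_b, k = config$accentuation_k)
  summary_tbl <- region_summary(diff_ba, sig, template)

  report <- structure(list(
    template = template,
    models_a = models_a, models_b = models_b,
    average_a = avg_a, average_b = avg_b,
    difference = diff_ab, significance = sig,
    accentuated = acc, region_summary = summary_tbl,
    config = config), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_study_maps(report, out_dir)
  }
  report
}

.schema_roles <- function(template) {
  s <- template$landmark_schema
  list(occlusal = s$name[s$occlusal_plane],
       posterior = s$name[s$posterior_ref][1],
       superior = s$name[s$superior_ref][1])
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s (n=%d) vs %s (n=%d), template %s\n",
              x$config$labels[1], length(x$models_a),
              x$config$labels[2], length(x$models_b),
              x$template$template_id))
  ns <- sum(x$region_summary$direction != "NS")
  cat(sprintf("  %d of %d region/surface/axis cells significant\n",
              ns, nrow(x$region_summary)))
  invisible(x)
}

# paper-style palettes
.sig_palette <- c(ns = "#C8C8C8", p05 = "#2055FF", p01 = "#FFB6C1",
                  p001 = "#DE3163", p0001 = "#800080")

.sig_colors <- function(categories) {
  cols <- .sig_palette[ifelse(is.na(categories), "ns", categories)]
  t(grDevices::col2rgb(cols))
}

.diverging_colors <- function(v) {
  m <- max(abs(v), 1e-12)
  u <- pmax(-1, pmin(1, v / m))
  # blue (negative) - white - red (positive)
  r <- ifelse(u >= 0, 255, round(255 * (1 + u)))
  b <- ifelse(u <= 0, 255, round(255 * (1 - u)))
  g <- round(255 * (1 - abs(u)))
  cbind(r, g, b)
}

#' Write the per-axis study maps and tables to a directory
#'
#' Emits diff_x/diff_y/diff_z.ply (per-vertex displacement, diverging
#' red/blue colours, red = group A greater), p_x/p_y/p_z.ply (per-vertex
#' p-values, the four-band significance palette), accentuated.ply,
#' region_summary.csv, a formatted region_summary.txt, and manifest.json.
#'
#' @param report a \code{study_report}.
#' @param out_dir output directory.
#' @return the directory, invisibly.
#' @export
write_study_maps <- function(report, out_dir) {
  base <- surface_mesh(report$average_a$mean, report$template$faces)
  for (ax in 1:3) {
    axn <- AXIS_NAMES[ax]
    dv <- report$difference$delta[, ax]
    write_ply(base, file.path(out_dir, sprintf("diff_%s.ply", axn)),
              scalars = stats::setNames(list(dv), paste0("d", axn)),
              colors = .diverging_colors(dv))
    pv <- report$significance$p[, ax]
    write_ply(base, file.path(out_dir, sprintf("p_%s.ply", axn)),
              scalars = stats::setNames(list(ifelse(is.na(pv), 1, pv)),
                                        paste0("p", axn)),
              colors = .sig_colors(report$significance$category[, ax]))
  }
  write_ply(surface_mesh(report$accentuated$nodes, report$template$faces),
            file.path(out_dir, "accentuated.ply"))
  utils::write.csv(as.data.frame(report$region_summary),
                   file.path(out_dir, "region_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_region_summary(report$region_summary),
             file.path(out_dir, "region_summary.txt"))
  manifest <- list(
    package = "mandmap",
    version = as.character(utils::packageVersion("mandmap")),
    seed = report$config$seed,
    labels = report$config$labels,
    template_id = report$template$template_id,
    n = c(length(report$models_a), length(report$models_b)),
    parameters = report$config[c("variant", "fdr", "accentuation_k",
                                 "thresholds", "fit")],
    outputs = c(sprintf("diff_%s.ply", AXIS_NAMES),
                sprintf("p_%s.ply", AXIS_NAMES),
                "accentuated.ply", "region_summary.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Format a region summary as a fixed-width text table
#'
#' One row per (region, surface) with direction word and stars per axis,
#' mirroring the published table layout.
#'
#' @param tbl a region summary tibble.
#' @return character vector of lines.
#' @export
format_region_summary <- function(tbl) {
  key <- paste(tbl$region, tbl$surface, sep = " / ")
  cells <- unique(key)
  fmt1 <- function(k, ax) {
    r <- tbl[key == k & tbl$axis == ax, ]
    if (!nrow(r) || r$direction == "NS") "NS"
    else paste(r$direction, r$significance)
  }
  lines <- sprintf("%-42s %-16s %-16s %-16s", "Region / Surface",
                   "X (transverse)", "Y (vertical)", "Z (antero-post.)")
  for (k in cells) {
    lines <- c(lines, sprintf("%-42s %-16s %-16s %-16s", k,
                              fmt1(k, "x"), fmt1(k, "y"), fmt1(k, "z")))
  }
  lines
}
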