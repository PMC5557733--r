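# Group morphometry: per-node averaged models, HD-minus-SD style
# displacement maps, per-node per-axis two-sample t significance
# probability maps, accentuated averages, and per-region summary tables.

AXIS_NAMES <- c("x", "y", "z")
P_THRESHOLDS <- c(p05 = 0.05, p01 = 0.01, p001 = 0.001, p0001 = 0.0001)
STARS <- c(p05 = "*", p01 = "**", p001 = "***", p0001 = "****")
# sign convention: +x lateral, +y superior, +z posterior
DIRECTION_WORDS <- list(
  x = c(pos = "Outward", neg = "Inward"),
  y = c(pos = "Upward", neg = "Downward"),
  z = c(pos = "Backward", neg = "Forward"))

# stack a list of homogeneous models into an n x nodes x 3 array
.model_array <- function(models, template_id = NULL) {
  nodes <- lapply(models, function(m) {
    if (inherits(m, "homogeneous_model")) m$nodes
    else if (inherits(m, "surface_mesh")) m$vertices
    else as.matrix(m)
  })
  nn <- unique(vapply(nodes, nrow, 1L))
  if (length(nn) != 1L) stopf("models have differing node counts")
  ids <- unlist(lapply(models, function(m) {
    if (inherits(m, "homogeneous_model")) m$template_id else NA_character_
  }))
  ids <- unique(ids[!is.na(ids)])
  if (length(ids) > 1L) stopf("models come from different templates")
  if (!is.null(template_id) && length(ids) == 1L && ids != template_id) {
    stopf("template mismatch: %s vs %s", ids, template_id)
  }
  arr <- array(0, c(length(models), nn, 3))
  for (i in seq_along(nodes)) arr[i, , ] <- nodes[[i]]
  attr(arr, "template_id") <- if (length(ids)) ids else template_id
  arr
}

# vectorised per-node-axis mean and (n-1) variance; explicit centering
# keeps tiny variances exact at large coordinate magnitudes
.groupwise_stats <- function(arr) {
  n <- dim(arr)[1]
  nn <- dim(arr)[2]
  M <- matrix(arr, nrow = n)
  mu <- colMeans(M)
  C <- sweep(M, 2, mu)
  v <- colSums(C^2) / (n - 1)
  list(mean = matrix(mu, nn, 3), var = matrix(v, nn, 3))
}

#' Per-node averaged model of a group
#'
#' Arithmetic mean and sample SD (n-1 denominator) of every node
#' coordinate across the group's homogeneous models.
#'
#' @param models list of >= 2 \code{homogeneous_model} objects (or
#'   template-topology meshes / node matrices) from the same template.
#' @param label group label.
#' @return an \code{averaged_model}: list with \code{mean} (nodes x 3),
#'   \code{sd} (nodes x 3), \code{n}, \code{label}, \code{template_id}.
#' @export
average_model <- function(models, label = "group") {
  if (length(models) < 2L) stopf("need >= 2 models to average")
  arr <- .model_array(models)
  st <- .groupwise_stats(arr)
  m <- st$mean
  s <- sqrt(st$var)
  structure(list(mean = m, sd = s, n = length(models), label = label,
                 template_id = attr(arr, "template_id")),
            class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> '%s': n = %d, %d nodes\n",
              x$label, x$n, nrow(x$mean)))
  invisible(x)
}

.check_same_template <- function(a, b) {
  if (nrow(a$mean %||% a$delta) != nrow(b$mean %||% b$delta)) {
    stopf("node counts differ; models are not from the same template")
  }
  ta <- a$template_id; tb <- b$template_id
  if (!is.null(ta) && !is.null(tb) && !is.na(ta) && !is.na(tb) && ta != tb) {
    stopf("template mismatch: %s vs %s", ta, tb)
  }
}

#' Per-node displacement map between two averaged models
#'
#' Delta = mean_A - mean_B per node and axis (mm). With A = HD and B = SD
#' this is the figure-style "HD minus SD" map; swapping the groups negates
#' every entry.
#'
#' @param avg_a,avg_b \code{averaged_model} objects on the same template.
#' @return a \code{difference_map}: list with \code{delta} (nodes x 3,
#'   columns x/y/z), \code{labels} (the two group labels),
#'   \code{orientation} (the sign convention record), \code{template_id}.
#' @export
difference_map <- function(avg_a, avg_b) {
  .check_same_template(avg_a, avg_b)
  delta <- avg_a$mean - avg_b$mean
  colnames(delta) <- AXIS_NAMES
  structure(list(delta = delta,
                 labels = c(avg_a$label, avg_b$label),
                 orientation = paste("+x lateral, +y superior, +z posterior;",
                                     "delta =", avg_a$label, "minus",
                                     avg_b$label),
                 template_id = avg_a$template_id %||% avg_b$template_id),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %s - %s, %d nodes\n",
              x$labels[1], x$labels[2], nrow(x$delta)))
  cat(sprintf("  max |delta| per axis (mm): x %.3f, y %.3f, z %.3f\n",
              max(abs(x$delta[, 1])), max(abs(x$delta[, 2])),
              max(abs(x$delta[, 3]))))
  invisible(x)
}

#' Per-node per-axis significance probability map
#'
#' For every node and axis independently, a two-sided two-sample t-test on
#' the scalar coordinate values of the two groups (pooled-variance
#' Student's t by default, Welch as a variant), with uncorrected p-values
#' banded into the fixed thresholds 0.05 / 0.01 / 0.001 / 0.0001.
#' Zero-variance node-axes with equal means give p = 1; zero variance with
#' unequal means is flagged degenerate (no finite t, no category).
#'
#' @param group_a,group_b lists of >= 2 homogeneous models each.
#' @param variant "student" (pooled variance, default) or "welch".
#' @param fdr apply Benjamini-Hochberg across nodes within each axis
#'   before banding (default FALSE, matching raw per-vertex maps).
#' @return a \code{significance_map}: list with \code{p}, \code{t}
#'   (nodes x 3), \code{category} (nodes x 3 character),
#'   \code{degenerate} (nodes x 3 logical), \code{variant},
#'   \code{template_id}.
#' @export
significance_map <- function(group_a, group_b, variant = c("student", "welch"),
                             fdr = FALSE) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("each group needs >= 2 models for a two-sample t-test")
  }
  A <- .model_array(group_a)
  B <- .model_array(group_b, attr(A, "template_id"))
  n1 <- dim(A)[1]; n2 <- dim(B)[1]
  nn <- dim(A)[2]

  sa <- .groupwise_stats(A); sb <- .groupwise_stats(B)
  m1 <- sa$mean; m2 <- sb$mean
  v1 <- sa$var; v2 <- sb$var

  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    dfm <- array(df, dim(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    dfm <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), dfm)

  # zero-variance detection at rounding scale: coordinates fixed exactly by
  # the landmark superimposition (e.g. the origin landmark) carry only
  # floating-point noise and must not yield spurious t statistics
  scale <- pmax(1, abs(m1), abs(m2))
  zero_se <- se <= 1e-12 * scale
  eq <- zero_se & (abs(m1 - m2) <= 1e-12 * scale)
  deg <- zero_se & !eq
  tt[eq] <- 0; p[eq] <- 1
  tt[deg] <- NA_real_; p[deg] <- NA_real_

  if (fdr) {
    for (ax in 1:3) p[, ax] <- stats::p.adjust(p[, ax], method = "BH")
  }

  cat_m <- matrix(NA_character_, nn, 3)
  ok <- !is.na(p)
  cat_m[ok] <- vapply(p[ok], categorize_p, character(1))

  colnames(tt) <- colnames(p) <- colnames(cat_m) <- AXIS_NAMES
  structure(list(p = p, t = tt, category = cat_m, degenerate = deg,
                 variant = variant, fdr = fdr,
                 n = c(n1, n2),
                 template_id = attr(A, "template_id")),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %d nodes, %s t-test (n = %d vs %d)\n",
              nrow(x$p), x$variant, x$n[1], x$n[2]))
  for (ax in 1:3) {
    cat(sprintf("  %s: %.1f%% of nodes p <= 0.05\n", AXIS_NAMES[ax],
                100 * mean(x$p[, ax] <= 0.05, na.rm = TRUE)))
  }
  invisible(x)
}

#' Band a p-value into the map's significance categories
#'
#' Strongest threshold wins: p <= 0.0001 -> "p0001", else <= 0.001 ->
#' "p001", else <= 0.01 -> "p01", else <= 0.05 -> "p05", else "ns".
#'
#' @param p p-value in [0, 1].
#' @return category string.
#' @export
categorize_p <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stopf("p must be in [0, 1]")
  if (p <= 1e-4) "p0001"
  else if (p <= 1e-3) "p001"
  else if (p <= 1e-2) "p01"
  else if (p <= 0.05) "p05"
  else "ns"
}

#' Accentuated average model
#'
#' Linear extrapolation of the group average away from a reference
#' average: accentuated = ref + k (grp - ref) per node. k = 1 returns the
#' group average, k = 0 the reference; the default k = 2 doubles every
#' displacement to highlight site-specific effects.
#'
#' @param avg_ref,avg_grp \code{averaged_model} objects on the same
#'   template.
#' @param k accentuation coefficient >= 0 (default 2).
#' @return a \code{homogeneous_model} holding the accentuated nodes.
#' @export
accentuate <- function(avg_ref, avg_grp, k = 2) {
  assert_scalar_num(k, "k", min = 0)
  .check_same_template(avg_ref, avg_grp)
  nodes <- avg_ref$mean + k * (avg_grp$mean - avg_ref$mean)
  structure(list(nodes = nodes,
                 template_id = avg_ref$template_id %||% avg_grp$template_id,
                 diagnostics = list(k = k, reference = avg_ref$label,
                                    group = avg_grp$label)),
            class = "homogeneous_model")
}

#' Per-region summary table
#'
#' Collapses the per-node maps into a table of (region, surface, axis)
#' cells: "NS" when no node in the cell reaches p <= 0.05; otherwise the
#' direction word from the sign of the mean displacement over the cell's
#' significant nodes (+x Outward / -x Inward, +y Upward / -y Downward,
#' +z Backward / -z Forward) and stars from the strongest threshold
#' attained by at least 5 percent of the cell's nodes (minimum "*").
#' To reproduce the published table semantics pass the soft-diet group as
#' the first (A) side of the difference map.
#'
#' @param diff a \code{difference_map}.
#' @param sig a \code{significance_map}.
#' @param atlas a \code{RegionAtlas} (list with per-node \code{region} and
#'   \code{surface}) or an \code{hm_template}.
#' @param star_frac fraction of cell nodes needed to attain a starred
#'   threshold (default 0.05).
#' @return a tibble with columns region, surface, axis, direction,
#'   significance, n_nodes, frac_significant, mean_displacement_mm.
#' @export
region_summary <- function(diff, sig, atlas, star_frac = 0.05) {
  if (inherits(atlas, "hm_template")) atlas <- atlas$atlas
  region <- atlas$region
  surface <- atlas$surface
  nn <- nrow(diff$delta)
  if (length(region) != nn || nrow(sig$p) != nn) {
    stopf("atlas, difference map and significance map sizes differ")
  }

  cells <- unique(data.frame(region = region, surface = surface,
                             stringsAsFactors = FALSE))
  cells <- cells[cells$region != "unassigned" &
                 cells$surface != "unassigned", , drop = FALSE]
  cells <- cells[order(match(cells$region, REGION_LEVELS),
                       match(cells$surface, SURFACE_LEVELS)), , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- region == cells$region[i] & surface == cells$surface[i]
    if (!any(sel)) {
      warning(sprintf("atlas cell (%s, %s) is empty", cells$region[i],
                      cells$surface[i]), call. = FALSE)
    }
    for (ax in 1:3) {
      pv <- sig$p[sel, ax]
      dv <- diff$delta[sel, ax]
      sig_sel <- !is.na(pv) & pv <= 0.05
      if (!any(sel) || !any(sig_sel)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = cells$region[i], surface = cells$surface[i],
          axis = AXIS_NAMES[ax], direction = "NS", significance = "NS",
          n_nodes = sum(sel), frac_significant = 0,
          mean_displacement_mm = if (any(sel)) mean(dv) else NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      md <- mean(dv[sig_sel])
      word <- DIRECTION_WORDS[[ax]][if (md >= 0) "pos" else "neg"]
      stars <- "*"
      for (th in names(P_THRESHOLDS)) {
        if (mean(pv <= P_THRESHOLDS[[th]], na.rm = TRUE) >= star_frac) {
          stars <- STARS[[th]]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = cells$region[i], surface = cells$surface[i],
        axis = AXIS_NAMES[ax], direction = unname(word),
        significance = stars, n_nodes = sum(sel),
        frac_significant = mean(sig_sel),
        mean_displacement_mm = md, stringsAsFactors = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
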