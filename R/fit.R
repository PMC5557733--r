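# Homogeneous modeling: fit the fixed-topology template into a specimen
# surface. TPS landmark warp initialises the node positions; iterated
# closest-point projection plus pinned umbrella smoothing of the residual
# displacement field refines them. Node count and index-wise
# correspondence are preserved by construction.

#' Fit the template mesh to a specimen surface
#'
#' (1) Warp template nodes by the thin-plate spline taking the template
#' landmarks onto the specimen landmarks; (2) for \code{n_iters}
#' iterations, project every node to its exact closest point on the target
#' surface, then smooth the resulting displacement-from-warp field with one
#' umbrella (neighbourhood-average) pass of weight \code{smooth_weight},
#' keeping landmark-anchor nodes pinned on their landmark targets.
#'
#' @param template an \code{hm_template}.
#' @param target a \code{surface_mesh} (the specimen surface).
#' @param target_lms the specimen's landmark set (same 69-name schema).
#' @param lambda TPS regularization (default 0).
#' @param n_iters projection/smoothing iterations (default 3).
#' @param smooth_weight umbrella smoothing weight in [0, 1] (default 0.5).
#' @param max_gate_mm fit gate: error if more than \code{gate_frac} of
#'   nodes project farther than this (default 1 mm).
#' @param gate_frac tolerated fraction of far nodes (default 0.05).
#' @return a \code{homogeneous_model}: list with \code{nodes}
#'   (node_count x 3), \code{template_id}, \code{diagnostics} (mean/sd
#'   node-to-surface distance per iteration, mm).
#' @export
fit_template <- function(template, target, target_lms, lambda = 0,
                         n_iters = 3L, smooth_weight = 0.5,
                         max_gate_mm = 1, gate_frac = 0.05) {
  val <- validate_landmarks(target_lms, template)
  if (!val$ok) {
    stopf("target landmarks do not validate against the template schema")
  }
  if (nrow(target$faces) < 1L) stopf("target mesh has no faces")

  s <- template$landmark_schema
  src <- template$nodes[s$anchor, , drop = FALSE]
  dst <- lm_coords(target_lms)[s$name, , drop = FALSE]
  warp <- tps_warp(src, dst, lambda = lambda)
  X0 <- predict(warp, template$nodes)

  nbrs <- vertex_neighbors(template_mesh(template))
  anchors <- s$anchor
  X <- X0
  iters <- list()
  for (k in seq_len(n_iters)) {
    proj <- closest_points(X, target)
    if (mean(proj$distance > max_gate_mm) > gate_frac) {
      stopf(paste0("template fit failed: %.1f%% of nodes project farther",
                   " than %g mm from the target surface"),
            100 * mean(proj$distance > max_gate_mm), max_gate_mm)
    }
    D <- proj$points - X0
    if (smooth_weight > 0) {
      Dm <- .umbrella_average(D, nbrs)
      D <- (1 - smooth_weight) * D + smooth_weight * Dm
    }
    D[anchors, ] <- dst - X0[anchors, , drop = FALSE]
    X <- X0 + D
    dists <- closest_points(X, target)$distance
    iters[[k]] <- c(mean = mean(dists), sd = stats::sd(dists))
  }
  diag <- do.call(rbind, iters)
  model <- structure(list(nodes = X,
                          template_id = template$template_id,
                          diagnostics = list(
                            per_iteration = diag,
                            mean_dist_mm = diag[n_iters, "mean"],
                            sd_dist_mm = diag[n_iters, "sd"])),
                     class = "homogeneous_model")
  model
}

# neighbourhood (umbrella) average of a per-node vector field
.umbrella_average <- function(D, nbrs) {
  out <- D
  for (i in seq_along(nbrs)) {
    nb <- nbrs[[i]]
    if (length(nb)) out[i, ] <- colMeans(D[nb, , drop = FALSE])
  }
  out
}

#' @export
print.homogeneous_model <- function(x, ...) {
  cat(sprintf("<homogeneous_model> %d nodes (template %s)\n",
              nrow(x$nodes), x$template_id))
  if (!is.null(x$diagnostics$mean_dist_mm)) {
    cat(sprintf("  node-to-surface distance: %.4f +/- %.4f mm\n",
                x$diagnostics$mean_dist_mm, x$diagnostics$sd_dist_mm))
  }
  invisible(x)
}

#' Coerce a template-topology mesh to a homogeneous model
#'
#' Simulated specimens share the template topology, so their node arrays
#' already are corresponding-point models.
#'
#' @param mesh a \code{surface_mesh} with exactly the template's node count,
#'   or a plain node matrix.
#' @param template the \code{hm_template}.
#' @return a \code{homogeneous_model}.
#' @export
as_homogeneous_model <- function(mesh, template) {
  nodes <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  if (nrow(nodes) != template$node_count) {
    stopf("node count %d does not match template (%d)",
          nrow(nodes), template$node_count)
  }
  structure(list(nodes = nodes, template_id = template$template_id,
                 diagnostics = list()),
            class = "homogeneous_model")
}

#' Fit quality metrics
#'
#' Mean and SD of the exact node-to-surface distance from the model nodes
#' to the target mesh, and the mean inter-node edge length over the
#' template edges (the mesh-resolution figure).
#'
#' @param model a \code{homogeneous_model}.
#' @param target the specimen \code{surface_mesh} in the same frame.
#' @param template the \code{hm_template} providing the edge topology.
#' @return list with \code{mean_dist_mm}, \code{sd_dist_mm},
#'   \code{mean_edge_mm}.
#' @export
fit_quality <- function(model, target, template) {
  d <- closest_points(model$nodes, target)$distance
  e <- unique(mesh_edges(template_mesh(template)))
  el <- sqrt(rowSums((model$nodes[e[, 1], , drop = FALSE] -
                      model$nodes[e[, 2], , drop = FALSE])^2))
  list(mean_dist_mm = mean(d), sd_dist_mm = stats::sd(d),
       mean_edge_mm = mean(el))
}
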