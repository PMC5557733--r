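# Synthetic specimens: the template deformed by a regional effect field
# plus smooth low-frequency shape noise, with landmark jitter. All
# generators are pure functions of (arguments, seed).

#' Regional displacement effect field
#'
#' Ground-truth displacement field for simulations: each component displaces
#' one atlas region by a fixed mm vector, decaying smoothly outside the
#' region with a Gaussian falloff of the distance to the region's node set
#' (weight 1 inside the region).
#'
#' @param region character vector of atlas region names.
#' @param dx,dy,dz displacement components in mm (recycled).
#' @param falloff falloff width in mm (recycled; default 1.5).
#' @return an \code{effect_field} tibble.
#' @export
effect_field <- function(region = character(), dx = 0, dy = 0, dz = 0,
                         falloff = 1.5) {
  ef <- tibble::tibble(region = as.character(region), dx = dx, dy = dy,
                       dz = dz, falloff = falloff)
  if (nrow(ef) > 0L) {
    if (any(!is.finite(c(ef$dx, ef$dy, ef$dz, ef$falloff)))) {
      stopf("effect field components must be finite")
    }
    if (any(ef$falloff <= 0)) stopf("falloff width must be positive")
    bad <- setdiff(ef$region, REGION_LEVELS)
    if (length(bad)) stopf("unknown region(s): %s", paste(bad, collapse = ", "))
  }
  class(ef) <- c("effect_field", class(ef))
  ef
}

#' Evaluate an effect field at points
#'
#' @param effect an \code{effect_field} (may have zero rows = zero field).
#' @param points n x 3 matrix of evaluation points (mm).
#' @param template the \code{hm_template} whose atlas defines the regions.
#' @return n x 3 matrix of displacements (mm).
#' @export
evaluate_effect_field <- function(effect, points, template) {
  points <- as.matrix(points)
  disp <- matrix(0, nrow(points), 3)
  if (is.null(effect) || nrow(effect) == 0L) return(disp)
  for (i in seq_len(nrow(effect))) {
    u <- c(effect$dx[i], effect$dy[i], effect$dz[i])
    if (all(u == 0)) next
    sel <- template$atlas$region == effect$region[i]
    if (!any(sel)) stopf("region '%s' has no template nodes", effect$region[i])
    rp <- template$nodes[sel, , drop = FALSE]
    # distance from each point to the region's node set
    d2 <- .min_dist2(points, rp)
    w <- exp(-d2 / (2 * effect$falloff[i]^2))
    disp <- disp + w %o% u
  }
  disp
}

# rowwise min squared distance from points to a reference point set
.min_dist2 <- function(p, q) {
  qn <- rowSums(q^2)
  out <- rep(Inf, nrow(p))
  chunk <- max(1L, floor(2e6 / nrow(q)))
  i <- 1L
  while (i <= nrow(p)) {
    j <- min(i + chunk - 1L, nrow(p))
    pp <- p[i:j, , drop = FALSE]
    g <- outer(rowSums(pp^2), qn, "+") - 2 * (pp %*% t(q))
    out[i:j] <- pmax(0, apply(g, 1, min))
    i <- j + 1L
  }
  out
}

# smooth noise basis: K Gaussian radial bumps centred on template nodes
.noise_modes <- function(template, n_modes, width, seed) {
  with_seed(seed, {
    ctr_idx <- sample.int(nrow(template$nodes), n_modes, replace = FALSE)
  })
  ctr <- template$nodes[ctr_idx, , drop = FALSE]
  list(centers = ctr, width = width)
}

.mode_matrix <- function(points, modes) {
  k <- nrow(modes$centers)
  phi <- matrix(0, nrow(points), k)
  for (m in seq_len(k)) {
    d2 <- (points[, 1] - modes$centers[m, 1])^2 +
          (points[, 2] - modes$centers[m, 2])^2 +
          (points[, 3] - modes$centers[m, 3])^2
    phi[, m] <- exp(-d2 / (2 * modes$width^2))
  }
  phi
}

# specimen node displacement given modes and per-specimen loadings (k x 3)
.noise_field <- function(phi, loadings) {
  phi %*% loadings
}

#' Simulate one specimen from the template
#'
#' Applies the effect field plus a smooth random deformation (a small
#' number of low-frequency Gaussian radial modes with Gaussian amplitudes
#' of scale \code{noise_sd}) to the template nodes; landmarks inherit the
#' deformed anchor positions plus isotropic jitter.
#'
#' @param template an \code{hm_template}.
#' @param effect an \code{effect_field} (NULL or zero rows = no effect).
#' @param noise_sd amplitude (mm) of the smooth shape noise modes.
#' @param landmark_jitter_sd isotropic landmark jitter SD (mm).
#' @param seed integer seed; fixed seed reproduces the specimen exactly.
#' @param n_modes number of smooth noise modes (default 12).
#' @param noise_width Gaussian width of the noise modes in mm (default 2).
#' @return list with \code{mesh} (a \code{surface_mesh} with template
#'   topology) and \code{landmarks} (a \code{landmark_set}).
#' @export
simulate_specimen <- function(template, effect = NULL, noise_sd = 0.1,
                              landmark_jitter_sd = 0.05, seed = 1L,
                              n_modes = 12L, noise_width = 2) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (landmark_jitter_sd < 0) stopf("landmark_jitter_sd must be >= 0")
  modes <- .noise_modes(template, n_modes, noise_width,
                        derive_seed(seed, 101L))
  phi <- if (noise_sd > 0) .mode_matrix(template$nodes, modes) else NULL
  .simulate_one(template, effect, noise_sd, landmark_jitter_sd,
                seed, modes, phi)
}

.simulate_one <- function(template, effect, noise_sd, landmark_jitter_sd,
                          seed, modes, phi) {
  nodes <- template$nodes +
    evaluate_effect_field(effect, template$nodes, template)
  if (noise_sd > 0) {
    loadings <- with_seed(derive_seed(seed, 202L), {
      matrix(rnorm(nrow(modes$centers) * 3, sd = noise_sd),
             ncol = 3)
    })
    nodes <- nodes + .noise_field(phi, loadings)
  }
  mesh <- surface_mesh(nodes, template$faces)

  s <- template$landmark_schema
  lp <- nodes[s$anchor, , drop = FALSE]
  if (landmark_jitter_sd > 0) {
    lp <- lp + with_seed(derive_seed(seed, 303L), {
      matrix(rnorm(nrow(lp) * 3, sd = landmark_jitter_sd), ncol = 3)
    })
  }
  lms <- landmark_set(
    tibble::tibble(name = s$name, x = lp[, 1], y = lp[, 2], z = lp[, 3]),
    side = "right",
    roles = list(occlusal = s$name[s$occlusal_plane],
                 posterior = s$name[s$posterior_ref][1],
                 superior = s$name[s$superior_ref][1]))
  list(mesh = mesh, landmarks = lms)
}

#' Simulate a two-group study
#'
#' Group A specimens carry no effect (control / hard-diet analogue); group
#' B specimens carry the effect field (soft-diet analogue). Shape noise is
#' realised as study-level smooth modes with independent per-specimen
#' Gaussian loadings, so specimens are independent draws from a common
#' smooth shape-variation model. Default group sizes 7 and 9.
#'
#' @param template an \code{hm_template}.
#' @param effect an \code{effect_field} applied to group B only.
#' @param noise_sd smooth shape-noise amplitude (mm).
#' @param landmark_jitter_sd landmark jitter SD (mm).
#' @param n_a,n_b group sizes (each >= 2; defaults 7 and 9).
#' @param seed study seed; per-specimen seeds are derived from it.
#' @param labels two group names (default HD, SD).
#' @param n_modes,noise_width noise-basis parameters as in
#'   \code{simulate_specimen}.
#' @return a \code{group_study}: list with \code{group_a}, \code{group_b}
#'   (lists of mesh+landmarks pairs), \code{labels}, \code{seed},
#'   \code{template_id}.
#' @export
simulate_groups <- function(template, effect = NULL, noise_sd = 0.1,
                            landmark_jitter_sd = 0.05, n_a = 7L, n_b = 9L,
                            seed = 1L, labels = c("HD", "SD"),
                            n_modes = 12L, noise_width = 2) {
  if (n_a < 2L || n_b < 2L) {
    stopf("group sizes must be >= 2 (two-sample test undefined otherwise)")
  }
  modes <- .noise_modes(template, n_modes, noise_width,
                        derive_seed(seed, 101L))
  phi <- if (noise_sd > 0) .mode_matrix(template$nodes, modes) else NULL
  zero <- effect_field()
  ga <- lapply(seq_len(n_a), function(i) {
    .simulate_one(template, zero, noise_sd, landmark_jitter_sd,
                  derive_seed(seed, 1000L + i), modes, phi)
  })
  gb <- lapply(seq_len(n_b), function(i) {
    .simulate_one(template, effect, noise_sd, landmark_jitter_sd,
                  derive_seed(seed, 2000L + i), modes, phi)
  })
  structure(list(group_a = ga, group_b = gb, labels = labels,
                 seed = seed, template_id = template$template_id),
            class = "group_study")
}

#' @export
print.group_study <- function(x, ...) {
  cat(sprintf("<group_study> %s: n=%d vs %s: n=%d (template %s, seed %d)\n",
              x$labels[1], length(x$group_a), x$labels[2],
              length(x$group_b), x$template_id, x$seed))
  invisible(x)
}
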