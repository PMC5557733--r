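# Parametric hemimandible template: a closed genus-0 triangulated surface
# built from a superellipsoid-like body plus smooth Gaussian bump components
# for the coronoid, condylar and angular processes, the alveolar ridge,
# molar cusps and the antegonial notch, carrying a 69-landmark schema and a
# per-node region/surface atlas. Construction is fully deterministic.

REGION_LEVELS <- c("coronoid_process", "condyle", "alveolar_process",
                   "inferior_body", "angular_process", "antegonial_notch",
                   "molars", "unassigned")
SURFACE_LEVELS <- c("lateral", "medial", "anterior", "posterior", "superior",
                    "inferior", "occlusal", "labial", "lingual", "unassigned")

# base geometry constants (pre-scale units; overall length rescaled later)
.tmpl_semi <- c(x = 0.6, y = 1.4, z = 5.3)

.tmpl_bumps <- function() {
  nrm <- function(v) v / sqrt(sum(v^2))
  list(
    coronoid   = list(ctr = c(0, 1.10, 2.6),  dir = c(0, 1, 0),
                      amp = 1.9, width = 1.1),
    condyle    = list(ctr = c(0, 0.80, 4.9),  dir = nrm(c(0, 2, 3)),
                      amp = 1.3, width = 0.9),
    angular    = list(ctr = c(0, -1.00, 4.1), dir = nrm(c(0, -0.7, 0.9)),
                      amp = 1.3, width = 1.0),
    antegonial = list(ctr = c(0, -1.30, 2.9), dir = c(0, 1, 0),
                      amp = 0.5, width = 0.7),
    alveolar   = list(ctr = c(0, 1.25, -1.0), dir = c(0, 1, 0),
                      amp = 0.5, width = 1.3),
    molar1     = list(ctr = c(0, 1.45, -0.35), dir = c(0, 1, 0),
                      amp = 0.22, width = 0.32),
    molar2     = list(ctr = c(0, 1.45, -1.00), dir = c(0, 1, 0),
                      amp = 0.22, width = 0.32),
    molar3     = list(ctr = c(0, 1.45, -1.65), dir = c(0, 1, 0),
                      amp = 0.22, width = 0.32),
    masseteric = list(ctr = c(0.55, -0.35, 2.2), dir = c(1, 0, 0),
                      amp = 0.22, width = 1.4),
    medial_fossa = list(ctr = c(-0.5, 0.10, 1.8), dir = c(1, 0, 0),
                      amp = 0.18, width = 1.2),
    incisal    = list(ctr = c(0, 0.10, -5.1), dir = nrm(c(0, 0.35, -1)),
                      amp = 0.45, width = 0.8))
}

# Gaussian bump weight matrix: n x length(bumps)
.bump_weights <- function(p, bumps) {
  w <- matrix(0, nrow(p), length(bumps))
  colnames(w) <- names(bumps)
  for (k in seq_along(bumps)) {
    b <- bumps[[k]]
    d2 <- (p[, 1] - b$ctr[1])^2 + (p[, 2] - b$ctr[2])^2 +
          (p[, 3] - b$ctr[3])^2
    w[, k] <- exp(-d2 / (2 * b$width^2))
  }
  w
}

.apply_bumps <- function(p, bumps) {
  w <- .bump_weights(p, bumps)
  out <- p
  for (k in seq_along(bumps)) {
    b <- bumps[[k]]
    out <- out + (b$amp * w[, k]) %o% b$dir
  }
  out
}

# 69-landmark schema: names, probe coordinates (pre-scale frame of the
# template constants) and frame-construction roles. The anatomy of each
# probe follows standard murine mandibular landmark vocabulary.
.tmpl_landmark_probes <- function() {
  lm <- function(name, x, y, z, occ = FALSE, post = FALSE, sup = FALSE) {
    list(name = name, p = c(x, y, z), occ = occ, post = post, sup = sup)
  }
  out <- list(
    lm("mental_foramen", 0.55, -0.2, -3.1),
    lm("incisor_tip", 0, 0.25, -5.75),
    lm("infradentale", 0, 0.7, -5.0),
    lm("incisor_inferior", 0, -0.7, -4.8),
    lm("symphysis_superior", 0, 0.9, -4.2),
    lm("symphysis_inferior", 0, -1.0, -4.0),
    lm("m1_buccal_cusp", 0.3, 1.75, -0.35, occ = TRUE),
    lm("m1_lingual_cusp", -0.3, 1.75, -0.35, occ = TRUE),
    lm("m2_buccal_cusp", 0.3, 1.75, -1.0, occ = TRUE),
    lm("m2_lingual_cusp", -0.3, 1.75, -1.0, occ = TRUE),
    lm("m3_buccal_cusp", 0.3, 1.75, -1.65, occ = TRUE),
    lm("m3_lingual_cusp", -0.3, 1.75, -1.65, occ = TRUE),
    lm("alveolar_crest_buccal_1", 0.5, 1.2, -0.3),
    lm("alveolar_crest_buccal_2", 0.5, 1.2, -1.0),
    lm("alveolar_crest_buccal_3", 0.5, 1.2, -1.7),
    lm("alveolar_crest_lingual_1", -0.5, 1.2, -0.3),
    lm("alveolar_crest_lingual_2", -0.5, 1.2, -1.0),
    lm("alveolar_crest_lingual_3", -0.5, 1.2, -1.7),
    lm("coronoid_tip", 0, 3.5, 2.6, sup = TRUE),
    lm("coronoid_anterior", 0, 2.2, 2.1),
    lm("coronoid_posterior", 0, 2.3, 3.1),
    lm("coronoid_lateral", 0.35, 2.4, 2.6),
    lm("coronoid_medial", -0.35, 2.4, 2.6),
    lm("sigmoid_notch", 0, 1.3, 3.9),
    lm("condyle_center", 0, 1.4, 6.0, post = TRUE),
    lm("condyle_lateral", 0.4, 1.3, 5.8),
    lm("condyle_medial", -0.4, 1.3, 5.8),
    lm("condyle_anterior", 0, 1.1, 5.4),
    lm("condyle_posterior", 0, 1.0, 6.3),
    lm("condyle_superior", 0, 1.7, 5.9),
    lm("condylar_neck_anterior", 0, 0.7, 4.6),
    lm("condylar_neck_posterior", 0, 0.3, 5.6),
    lm("angular_tip", 0, -1.8, 5.3),
    lm("angular_lateral", 0.3, -1.4, 4.9),
    lm("angular_medial", -0.3, -1.4, 4.9),
    lm("angular_superior", 0, -0.9, 4.9),
    lm("angular_inferior", 0, -1.8, 4.6),
    lm("gonion", 0, -1.5, 5.6),
    lm("antegonial_notch_deepest", 0, -0.85, 2.9),
    lm("antegonial_anterior", 0, -1.1, 2.3),
    lm("antegonial_posterior", 0, -1.2, 3.5))
  zs <- c(-3.5, -2.7, -1.9, -1.1, -0.3, 0.5, 1.2, 1.9)
  for (i in seq_along(zs)) {
    out[[length(out) + 1L]] <-
      lm(sprintf("inferior_border_%d", i), 0, -1.45, zs[i])
  }
  zs <- c(1.6, 2.3, 3.0)
  for (i in seq_along(zs)) {
    out[[length(out) + 1L]] <-
      lm(sprintf("masseteric_ridge_%d", i), 0.62, -0.4, zs[i])
  }
  zs <- c(0.2, 1.2, 2.2)
  for (i in seq_along(zs)) {
    out[[length(out) + 1L]] <-
      lm(sprintf("mylohyoid_line_%d", i), -0.55, 0, zs[i])
  }
  zs <- c(2.6, 3.3, 4.0)
  for (i in seq_along(zs)) {
    out[[length(out) + 1L]] <-
      lm(sprintf("ramus_lateral_%d", i), 0.5, 0.4, zs[i])
    out[[length(out) + 1L]] <-
      lm(sprintf("ramus_medial_%d", i), -0.5, 0.4, zs[i])
  }
  zs <- c(-2.6, -1.6, -0.6)
  for (i in seq_along(zs)) {
    out[[length(out) + 1L]] <-
      lm(sprintf("body_lateral_%d", i), 0.58, 0.3, zs[i])
    out[[length(out) + 1L]] <-
      lm(sprintf("body_medial_%d", i), -0.58, 0.3, zs[i])
  }
  out[[length(out) + 1L]] <- lm("lingual_foramen", -0.5, -0.3, 0.8)
  out[[length(out) + 1L]] <- lm("masseteric_tuberosity", 0.5, -0.8, 3.6)
  out
}

# ring tessellation of a sphere-like closed surface with exactly n nodes
.ring_tessellation <- function(n, semi) {
  n_int <- n - 2L
  # balance meridian spacing against in-ring spacing
  sperp <- sqrt((semi[1]^2 + semi[2]^2) / 2)
  meridian <- pi * sqrt((semi[3]^2 + sperp^2) / 2)
  perim <- 2 * pi * sperp
  R <- max(4L, as.integer(round(sqrt(n_int * meridian * pi / (2 * perim)))))
  if (R > n_int %/% 3L) R <- max(1L, n_int %/% 3L)
  u <- pi * seq_len(R) / (R + 1)
  w <- sin(u)
  cnt <- pmax(3L, as.integer(round(n_int * w / sum(w))))
  # deterministic adjustment to hit the budget exactly
  while (sum(cnt) != n_int) {
    if (sum(cnt) > n_int) {
      i <- which.max(cnt)
      if (cnt[i] <= 3L) stopf("node budget too small for tessellation")
      cnt[i] <- cnt[i] - 1L
    } else {
      i <- which.max(cnt)
      cnt[i] <- cnt[i] + 1L
    }
  }

  nodes <- matrix(0, n, 3)
  ring_ids <- vector("list", R)
  ring_ang <- vector("list", R)
  idx <- 1L
  nodes[idx, ] <- c(0, 0, -semi[3])  # anterior pole
  for (i in seq_len(R)) {
    k <- cnt[i]
    phi <- 2 * pi * (seq_len(k) - 1 + 0.5 * (i %% 2)) / k
    ids <- idx + seq_len(k)
    nodes[ids, ] <- cbind(semi[1] * sin(u[i]) * cos(phi),
                          semi[2] * sin(u[i]) * sin(phi),
                          -semi[3] * cos(u[i]))
    ring_ids[[i]] <- ids
    ring_ang[[i]] <- phi
    idx <- idx + k
  }
  pole2 <- n
  nodes[pole2, ] <- c(0, 0, semi[3])  # posterior pole

  faces <- vector("list", R + 1L)
  # anterior cap
  ids1 <- ring_ids[[1]]
  k1 <- length(ids1)
  faces[[1]] <- cbind(1L, ids1, ids1[c(2:k1, 1)])
  # bands
  for (i in seq_len(R - 1L)) {
    faces[[i + 1L]] <- .stitch_rings(ring_ids[[i]], ring_ang[[i]],
                                     ring_ids[[i + 1L]], ring_ang[[i + 1L]])
  }
  # posterior cap
  idsR <- ring_ids[[R]]
  kR <- length(idsR)
  faces[[R + 1L]] <- cbind(pole2, idsR[c(2:kR, 1)], idsR)

  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"
  mesh <- surface_mesh(nodes, f)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

# zipper triangulation between two closed rings sorted by angle
.stitch_rings <- function(idsA, angA, idsB, angB) {
  nA <- length(idsA); nB <- length(idsB)
  AA <- c(angA, angA[1] + 2 * pi); IA <- c(idsA, idsA[1])
  BB <- c(angB, angB[1] + 2 * pi); IB <- c(idsB, idsB[1])
  out <- matrix(0L, nA + nB, 3)
  i <- 1L; j <- 1L; r <- 1L
  while (i <= nA || j <= nB) {
    if (i <= nA && (j > nB || AA[i + 1L] <= BB[j + 1L])) {
      out[r, ] <- c(IA[i], IA[i + 1L], IB[j])
      i <- i + 1L
    } else {
      out[r, ] <- c(IA[i], IB[j + 1L], IB[j])
      j <- j + 1L
    }
    r <- r + 1L
  }
  out
}

#' Build the default parametric hemimandible template
#'
#' Constructs a deterministic, closed, mouse-scale hemimandible-like surface
#' with a configurable node budget (default 12,186 nodes), a 69-landmark
#' schema anchored to surface nodes, and a per-node region/surface atlas.
#' The same configuration always yields bit-identical output.
#'
#' @param node_count total number of mesh nodes (default 12186).
#' @param length_mm overall antero-posterior length of the hemimandible in
#'   mm (default 12, mouse scale).
#' @return An object of class \code{hm_template} with elements
#'   \code{nodes}, \code{faces}, \code{node_count}, \code{landmark_schema}
#'   (tibble: name, anchor, occlusal_plane, posterior_ref, superior_ref),
#'   \code{atlas} (list with per-node \code{region} and \code{surface}
#'   labels), \code{template_id} and \code{config}.
#' @export
make_template <- function(node_count = 12186L, length_mm = 12) {
  node_count <- as.integer(node_count)
  if (is.na(node_count) || node_count < 100L) {
    stopf(paste0("node budget %d is too small to host 69 distinct landmark",
                 " anchors; need at least 100 nodes"), node_count)
  }
  assert_scalar_num(length_mm, "length_mm", min = 1e-6)

  semi <- .tmpl_semi
  bumps <- .tmpl_bumps()
  mesh <- .ring_tessellation(node_count, semi)
  base <- mesh$vertices
  nodes <- .apply_bumps(base, bumps)

  # rescale so the longest bounding-box edge equals length_mm
  ext <- apply(nodes, 2, function(v) diff(range(v)))
  sc <- length_mm / max(ext)
  nodes <- nodes * sc

  mesh$vertices <- nodes

  # landmark anchors: nearest node to each (scaled) probe, kept distinct
  probes <- .tmpl_landmark_probes()
  used <- logical(node_count)
  anchor <- integer(length(probes))
  nm <- character(length(probes))
  occ <- post <- sup <- logical(length(probes))
  for (i in seq_along(probes)) {
    pr <- probes[[i]]
    d2 <- colSums((t(nodes) - pr$p * sc)^2)
    ord <- order(d2)
    j <- ord[which(!used[ord])[1]]
    used[j] <- TRUE
    anchor[i] <- j
    nm[i] <- pr$name
    occ[i] <- pr$occ; post[i] <- pr$post; sup[i] <- pr$sup
  }
  schema <- tibble::tibble(name = nm, anchor = anchor,
                           occlusal_plane = occ, posterior_ref = post,
                           superior_ref = sup)

  atlas <- .build_atlas(base, mesh, bumps, semi)

  structure(list(
    nodes = nodes,
    faces = mesh$faces,
    node_count = node_count,
    landmark_schema = schema,
    atlas = atlas,
    template_id = sprintf("hemimandible-%d-%g", node_count, length_mm),
    config = list(node_count = node_count, length_mm = length_mm)
  ), class = "hm_template")
}

# region and surface-class labels per node
.build_atlas <- function(base, mesh, bumps, semi) {
  w <- .bump_weights(base, bumps)
  n <- nrow(base)
  region <- rep("unassigned", n)

  wmol <- pmax(w[, "molar1"], w[, "molar2"], w[, "molar3"])
  proc <- cbind(coronoid_process = w[, "coronoid"],
                condyle = w[, "condyle"],
                angular_process = w[, "angular"],
                antegonial_notch = w[, "antegonial"],
                alveolar_process = w[, "alveolar"])
  best <- max.col(proc, ties.method = "first")
  bestw <- proc[cbind(seq_len(n), best)]

  sel <- wmol >= 0.25
  region[sel] <- "molars"
  sel2 <- !sel & bestw >= 0.2
  region[sel2] <- colnames(proc)[best[sel2]]

  # positional fallback for the corpus
  blocal <- semi[2] * sqrt(pmax(0, 1 - (base[, 3] / semi[3])^2))
  lower <- !sel & !sel2 & base[, 2] < -0.45 * blocal & base[, 3] < 2.5
  region[lower] <- "inferior_body"
  upper <- !sel & !sel2 & !lower & base[, 2] > 0.45 * blocal &
    base[, 3] > -2.8 & base[, 3] < 0.9
  region[upper] <- "alveolar_process"

  nrm <- vertex_normals(mesh)
  surf <- rep("unassigned", n)
  dom <- max.col(abs(nrm), ties.method = "first")
  surf[dom == 1 & nrm[, 1] >= 0] <- "lateral"
  surf[dom == 1 & nrm[, 1] < 0] <- "medial"
  surf[dom == 2 & nrm[, 2] >= 0] <- "superior"
  surf[dom == 2 & nrm[, 2] < 0] <- "inferior"
  surf[dom == 3 & nrm[, 3] >= 0] <- "posterior"
  surf[dom == 3 & nrm[, 3] < 0] <- "anterior"
  mol <- region == "molars"
  surf[mol] <- ifelse(nrm[mol, 2] > 0.45, "occlusal",
                      ifelse(nrm[mol, 1] >= 0, "labial", "lingual"))
  list(region = region, surface = surf)
}

#' @export
print.hm_template <- function(x, ...) {
  cat(sprintf("<hm_template> %s: %d nodes, %d faces, %d landmarks\n",
              x$template_id, x$node_count, nrow(x$faces),
              nrow(x$landmark_schema)))
  cat("  regions:",
      paste(names(table(x$atlas$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the template surface as a mesh
#' @param template an \code{hm_template}.
#' @return a \code{surface_mesh}.
#' @export
template_mesh <- function(template) {
  surface_mesh(template$nodes, template$faces)
}

#' Landmark set at the template's anchor nodes
#'
#' @param template an \code{hm_template}.
#' @return A landmark set (tibble with columns name, x, y, z; frame-role
#'   metadata in the \code{roles} attribute; side tag in \code{side}).
#' @export
template_landmarks <- function(template) {
  s <- template$landmark_schema
  p <- template$nodes[s$anchor, , drop = FALSE]
  landmark_set(tibble::tibble(name = s$name, x = p[, 1], y = p[, 2],
                              z = p[, 3]),
               side = "right",
               roles = list(occlusal = s$name[s$occlusal_plane],
                            posterior = s$name[s$posterior_ref][1],
                            superior = s$name[s$superior_ref][1]))
}
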