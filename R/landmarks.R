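#' Named 3D landmark set
#'
#' A landmark set is a tibble with columns \code{name, x, y, z} (mm), a
#' \code{side} tag and optional frame-role metadata (\code{roles}
#' attribute: which landmarks define the occlusal plane, which is the
#' posterior reference, which the superior reference).
#'
#' @param df data frame with columns name, x, y, z.
#' @param side one of "left", "right", "both".
#' @param roles optional list with elements \code{occlusal} (character
#'   vector of landmark names), \code{posterior} (single name),
#'   \code{superior} (single name).
#' @return a \code{landmark_set} tibble.
#' @export
landmark_set <- function(df, side = "right", roles = NULL) {
  df <- tibble::as_tibble(df)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stopf("landmark set needs columns %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  side <- match.arg(side, c("left", "right", "both"))
  attr(df, "side") <- side
  if (!is.null(roles)) attr(df, "roles") <- roles
  class(df) <- c("landmark_set", class(df))
  df
}

lm_coords <- function(ls) {
  m <- cbind(ls$x, ls$y, ls$z)
  rownames(m) <- ls$name
  m
}

lm_point <- function(ls, name) {
  i <- match(name, ls$name)
  if (is.na(i)) stopf("landmark '%s' not present", name)
  c(ls$x[i], ls$y[i], ls$z[i])
}

lm_roles <- function(ls, roles = NULL) {
  r <- roles %||% attr(ls, "roles")
  if (is.null(r)) {
    # fall back to the default schema's role names when present
    d <- default_frame_roles()
    if (all(c(d$occlusal, d$posterior, d$superior) %in% ls$name)) return(d)
    stopf(paste0("no frame roles available: supply `roles` or use a",
                 " landmark set carrying a roles attribute"))
  }
  r
}

#' Default frame-construction roles of the 69-landmark schema
#'
#' The occlusal plane is fitted through the six molar cusp landmarks, the
#' condyle centre is the posterior reference and the coronoid tip the
#' superior reference.
#'
#' @return list with \code{occlusal}, \code{posterior}, \code{superior}.
#' @export
default_frame_roles <- function() {
  list(occlusal = c("m1_buccal_cusp", "m1_lingual_cusp", "m2_buccal_cusp",
                    "m2_lingual_cusp", "m3_buccal_cusp", "m3_lingual_cusp"),
       posterior = "condyle_center",
       superior = "coronoid_tip")
}

#' Validate a landmark set against a schema
#'
#' Report-style validation: lists missing names, unexpected extra names,
#' duplicated names and non-finite coordinates. \code{ok} is TRUE only if
#' all four lists are empty.
#'
#' @param ls a landmark set (or data frame with name, x, y, z).
#' @param schema character vector of expected landmark names, or an
#'   \code{hm_template} whose schema is used.
#' @return list with \code{ok}, \code{missing}, \code{extra},
#'   \code{duplicated}, \code{nonfinite}.
#' @export
validate_landmarks <- function(ls, schema) {
  if (inherits(schema, "hm_template")) schema <- schema$landmark_schema$name
  nm <- as.character(ls$name)
  dup <- unique(nm[duplicated(nm)])
  missing <- setdiff(schema, nm)
  extra <- setdiff(nm, schema)
  bad <- !is.finite(ls$x) | !is.finite(ls$y) | !is.finite(ls$z)
  nonfinite <- unique(nm[bad])
  list(ok = length(missing) == 0L && length(extra) == 0L &&
         length(dup) == 0L && length(nonfinite) == 0L,
       missing = missing, extra = extra, duplicated = dup,
       nonfinite = nonfinite)
}

#' Build the standardized coordinate frame from landmarks
#'
#' The frame places the origin at the mental foramen, takes the y-axis as
#' the unit normal of the least-squares plane through the occlusal (molar
#' cusp) landmarks signed so the coronoid tip is superior, the z-axis as
#' the in-plane direction from the mental foramen towards the condyle
#' centre (posterior positive), and x = y x z, giving a right-handed
#' orthonormal frame: +x lateral, +y superior, +z posterior.
#'
#' @param ls a landmark set containing \code{mental_foramen}, at least 3
#'   occlusal-plane landmarks, a posterior reference and a superior
#'   reference (roles from the set's metadata or \code{roles}).
#' @param roles optional explicit roles list (see \code{landmark_set}).
#' @return a \code{coordinate_frame}: list with \code{origin} (3-vector)
#'   and \code{axes} (3 x 3 orthonormal, rows = x, y, z axes).
#' @export
build_frame <- function(ls, roles = NULL) {
  r <- lm_roles(ls, roles)
  if (!"mental_foramen" %in% ls$name) {
    stopf("required landmark 'mental_foramen' is missing")
  }
  occ_names <- intersect(r$occlusal, ls$name)
  if (length(occ_names) < 3L) {
    stopf("need at least 3 occlusal-plane landmarks, have %d",
          length(occ_names))
  }
  if (!isTRUE(r$posterior %in% ls$name)) {
    stopf("posterior reference landmark '%s' is missing", r$posterior)
  }
  if (!isTRUE(r$superior %in% ls$name)) {
    stopf("superior reference landmark '%s' is missing", r$superior)
  }

  origin <- lm_point(ls, "mental_foramen")
  occ <- lm_coords(ls)[occ_names, , drop = FALSE]
  ctr <- colMeans(occ)
  cc <- sweep(occ, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
    stopf("occlusal-plane landmarks are collinear; plane normal undefined")
  }
  yaxis <- ev$vectors[, 3]
  sup <- lm_point(ls, r$superior)
  if (sum(yaxis * (sup - ctr)) < 0) yaxis <- -yaxis

  post <- lm_point(ls, r$posterior)
  v <- post - origin
  zaxis <- v - sum(v * yaxis) * yaxis
  nz <- sqrt(sum(zaxis^2))
  if (nz < 1e-12) {
    stopf("posterior reference is on the occlusal normal; z-axis undefined")
  }
  zaxis <- zaxis / nz
  xaxis <- c(yaxis[2] * zaxis[3] - yaxis[3] * zaxis[2],
             yaxis[3] * zaxis[1] - yaxis[1] * zaxis[3],
             yaxis[1] * zaxis[2] - yaxis[2] * zaxis[1])
  axes <- rbind(x = xaxis, y = yaxis, z = zaxis)
  structure(list(origin = origin, axes = axes), class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat("<coordinate_frame>\n  origin (mm):",
      sprintf("%.4f", x$origin), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' Transform a mesh or landmark set into a coordinate frame
#'
#' Rigid transform p -> A (p - origin) with A the frame's axis rows;
#' shape-preserving (all pairwise distances unchanged).
#'
#' @param obj a \code{surface_mesh} or \code{landmark_set}.
#' @param frame a \code{coordinate_frame}.
#' @return object of the same type in standardized coordinates.
#' @export
apply_frame <- function(obj, frame) {
  UseMethod("apply_frame")
}

transform_points <- function(p, frame) {
  sweep(p, 2, frame$origin) %*% t(frame$axes)
}

#' @export
apply_frame.surface_mesh <- function(obj, frame) {
  obj$vertices <- transform_points(obj$vertices, frame)
  obj
}

#' @export
apply_frame.landmark_set <- function(obj, frame) {
  p <- transform_points(lm_coords(obj), frame)
  obj$x <- p[, 1]; obj$y <- p[, 2]; obj$z <- p[, 3]
  obj
}

#' @export
apply_frame.default <- function(obj, frame) {
  if (is.matrix(obj) && ncol(obj) == 3L) {
    return(transform_points(obj, frame))
  }
  stopf("apply_frame: unsupported object type")
}

#' Mirror a left-side specimen to right-side orientation
#'
#' Reflects x to -x (and reverses triangle winding for meshes) so left
#' hemimandibles can be pooled with right ones when desired; analyses are
#' side-separate by default.
#'
#' @param obj a \code{surface_mesh} or \code{landmark_set}.
#' @return the mirrored object; a landmark set's side tag is swapped.
#' @export
mirror_x <- function(obj) {
  if (inherits(obj, "surface_mesh")) {
    obj$vertices[, 1] <- -obj$vertices[, 1]
    obj$faces <- obj$faces[, c(1, 3, 2)]
    return(obj)
  }
  if (inherits(obj, "landmark_set")) {
    obj$x <- -obj$x
    side <- attr(obj, "side")
    attr(obj, "side") <- switch(side, left = "right", right = "left", side)
    return(obj)
  }
  stopf("mirror_x: unsupported object type")
}

#' Landmark identification reliability across repeated digitizations
#'
#' For each landmark, the mean pairwise Euclidean distance between the
#' repeats, plus the grand mean across landmarks.
#'
#' @param repeats list of at least two landmark sets on the same schema.
#' @return list with \code{per_landmark} (tibble: name, mean_error_mm) and
#'   \code{grand_mean_mm}.
#' @export
landmark_reliability <- function(repeats) {
  if (!is.list(repeats) || length(repeats) < 2L) {
    stopf("need at least 2 repeated landmark sets")
  }
  nm <- repeats[[1]]$name
  for (r in repeats[-1]) {
    if (!identical(as.character(r$name), as.character(nm))) {
      stopf("landmark schema mismatch across repeats")
    }
  }
  k <- length(repeats)
  pairs <- utils::combn(k, 2)
  err <- numeric(length(nm))
  for (j in seq_len(ncol(pairs))) {
    a <- lm_coords(repeats[[pairs[1, j]]])
    b <- lm_coords(repeats[[pairs[2, j]]])
    err <- err + sqrt(rowSums((a - b)^2))
  }
  err <- unname(err / ncol(pairs))
  list(per_landmark = tibble::tibble(name = as.character(nm),
                                     mean_error_mm = err),
       grand_mean_mm = mean(err))
}
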