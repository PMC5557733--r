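# Mesh file IO: STL (binary and ASCII) and PLY (ASCII, with optional
# per-vertex scalar/colour properties). Units are mm throughout.

#' Read a surface mesh from STL or PLY
#'
#' Dispatches on the file extension (.stl or .ply); STL dialect (ASCII vs
#' binary) is auto-detected. STL vertices are welded exactly so shared
#' corners become shared mesh vertices.
#'
#' @param path file path.
#' @return a \code{surface_mesh}.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path)$mesh,
         stopf("unsupported mesh format '%s' (use .stl or .ply)", ext))
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output path ending in .stl or .ply.
#' @param ascii write ASCII STL instead of binary (default FALSE).
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, ascii = ascii),
         ply = write_ply(mesh, path),
         stopf("unsupported mesh format '%s' (use .stl or .ply)", ext))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = 5L)
  close(con)
  if (length(head) < 5L) stopf("malformed STL %s: file too short", path)
  is_ascii <- identical(rawToChar(head), "solid") && .stl_looks_ascii(path)
  if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path)
}

.stl_looks_ascii <- function(path) {
  # binary STLs may also start with "solid"; check for a "facet" keyword
  txt <- suppressWarnings(readLines(path, n = 5L, warn = FALSE))
  any(grepl("facet|endsolid", txt))
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nt) || nt < 0L) stopf("malformed STL %s: bad triangle count", nt)
  expect <- 84 + nt * 50
  if (file.size(path) < expect) {
    stopf("malformed STL %s: truncated at byte %d (expected %d bytes)",
          path, file.size(path), expect)
  }
  rec <- readBin(con, "raw", n = nt * 50L)
  m <- matrix(rec, nrow = 50L)
  flo <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                 n = 12L * nt, size = 4L, endian = "little")
  flo <- matrix(flo, nrow = 12L)  # rows 1:3 normal, 4:12 vertices
  tri <- t(flo[4:12, , drop = FALSE])
  .weld_triangles(tri)
}

.read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) %% 3L != 0L) {
    stopf("malformed ASCII STL %s: vertex count %d not divisible by 3",
          path, length(vl))
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stopf("malformed ASCII STL %s: bad vertex", path)
  nt <- nrow(nums) / 3L
  tri <- matrix(t(nums), nt, 9, byrow = TRUE)
  .weld_triangles(tri)
}

# weld per-triangle corner soup into shared vertices (exact match)
.weld_triangles <- function(tri) {
  nt <- nrow(tri)
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- pts[uk, , drop = FALSE]
  faces <- cbind(idx[seq_len(nt)], idx[nt + seq_len(nt)],
                 idx[2 * nt + seq_len(nt)])
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  surface_mesh(verts, faces[keep, , drop = FALSE])
}

write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mandmap", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (c in 1:3) {
        p <- v[f[i, c], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mandmap", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- raw(80)
    txt <- charToRaw("mandmap binary STL")
    hdr[seq_along(txt)] <- txt
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    nf <- nrow(f)
    # 12 floats per facet: normal then the three vertices
    dat <- rbind(t(n),
                 matrix(t(v[as.vector(t(f)), , drop = FALSE]), nrow = 9))
    fraw <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
    rec <- matrix(as.raw(0), 50L, nf)
    rec[1:48, ] <- matrix(fraw, nrow = 48L)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY with optional per-vertex properties
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @param scalars named list of per-vertex numeric vectors written as
#'   float properties.
#' @param int_props named list of per-vertex integer vectors.
#' @param colors n x 3 integer matrix (0-255) written as uchar
#'   red/green/blue.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, scalars = NULL, int_props = NULL,
                      colors = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  hdr <- c("ply", "format ascii 1.0", "comment mandmap surface map",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  cols <- list(v[, 1], v[, 2], v[, 3])
  fmt <- c("%.9g", "%.9g", "%.9g")
  for (nmv in names(scalars %||% list())) {
    hdr <- c(hdr, sprintf("property float %s", nmv))
    cols[[length(cols) + 1L]] <- scalars[[nmv]]
    fmt <- c(fmt, "%.9g")
  }
  for (nmv in names(int_props %||% list())) {
    hdr <- c(hdr, sprintf("property int %s", nmv))
    cols[[length(cols) + 1L]] <- as.integer(int_props[[nmv]])
    fmt <- c(fmt, "%d")
  }
  if (!is.null(colors)) {
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
    for (c in 1:3) {
      cols[[length(cols) + 1L]] <- as.integer(colors[, c])
      fmt <- c(fmt, "%d")
    }
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  lines <- do.call(paste, c(mapply(function(x, fm) sprintf(fm, x),
                                   cols, fmt, SIMPLIFY = FALSE),
                            list(sep = " ")))
  flines <- paste("3", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, lines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' @param path file path.
#' @return list with \code{mesh} (a \code{surface_mesh}) and
#'   \code{properties} (tibble of extra per-vertex properties, if any).
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3L || txt[1] != "ply") stopf("not a PLY file: %s", path)
  if (!grepl("ascii", txt[2])) stopf("only ASCII PLY is supported")
  endh <- match("end_header", txt)
  if (is.na(endh)) stopf("malformed PLY %s: no end_header", path)
  hdr <- txt[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)[1]))
  # vertex property names, in order
  vstart <- grep("^element vertex", hdr)[1]
  vend <- grep("^element", hdr)
  vend <- min(c(vend[vend > vstart], endh))
  props <- hdr[(vstart + 1):(vend - 1)]
  props <- props[grepl("^property ", props)]
  pnames <- vapply(strsplit(props, "\\s+"), function(s) s[3], character(1))

  vlines <- txt[endh + seq_len(nv)]
  vals <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                   function(s) as.numeric(s[seq_along(pnames)]),
                   numeric(length(pnames))))
  colnames(vals) <- pnames
  flines <- txt[endh + nv + seq_len(nf)]
  fv <- t(vapply(strsplit(trimws(flines), "\\s+"),
                 function(s) as.integer(s[2:4]), integer(3))) + 1L
  mesh <- surface_mesh(vals[, c("x", "y", "z"), drop = FALSE], fv)
  extra <- setdiff(pnames, c("x", "y", "z"))
  list(mesh = mesh,
       properties = if (length(extra)) {
         tibble::as_tibble(as.data.frame(vals[, extra, drop = FALSE]))
       } else NULL)
}

#' Serialize a template to PLY plus a JSON schema sidecar
#'
#' The PLY carries per-vertex integer region and surface-class codes; the
#' sidecar records the landmark schema (names, anchors, roles) and the
#' code tables.
#'
#' @param template an \code{hm_template}.
#' @param path output .ply path; the sidecar is written next to it as
#'   <path>.json.
#' @return the path, invisibly.
#' @export
write_template <- function(template, path) {
  region_code <- match(template$atlas$region, REGION_LEVELS) - 1L
  surface_code <- match(template$atlas$surface, SURFACE_LEVELS) - 1L
  write_ply(template_mesh(template), path,
            int_props = list(region = region_code, surface = surface_code))
  sidecar <- list(
    template_id = template$template_id,
    config = template$config,
    region_levels = REGION_LEVELS,
    surface_levels = SURFACE_LEVELS,
    landmark_schema = template$landmark_schema)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a template written by \code{write_template}
#' @param path the .ply path.
#' @return an \code{hm_template}.
#' @export
read_template <- function(path) {
  p <- read_ply(path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  schema <- tibble::as_tibble(sidecar$landmark_schema)
  structure(list(
    nodes = p$mesh$vertices,
    faces = p$mesh$faces,
    node_count = nrow(p$mesh$vertices),
    landmark_schema = schema,
    atlas = list(
      region = sidecar$region_levels[p$properties$region + 1L],
      surface = sidecar$surface_levels[p$properties$surface + 1L]),
    template_id = sidecar$template_id,
    config = sidecar$config), class = "hm_template")
}
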