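# Landmark and volume file IO.

#' Read landmarks from CSV or JSON
#'
#' CSV: header \code{name,x,y,z}, coordinates in mm. JSON: object with
#' \code{landmarks} (array of name/x/y/z records), optional \code{side}
#' and \code{roles} (occlusal / posterior / superior schema-role
#' annotations).
#'
#' @param path file path (.csv or .json).
#' @param side side tag when the file does not carry one.
#' @param roles optional roles list overriding the file.
#' @return a \code{landmark_set}.
#' @export
read_landmarks <- function(path, side = "right", roles = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(j$landmarks)
    return(landmark_set(df, side = j$side %||% side,
                        roles = roles %||% j$roles))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  landmark_set(tibble::as_tibble(df), side = side, roles = roles)
}

#' Write landmarks to CSV or JSON
#'
#' @param ls a \code{landmark_set}.
#' @param path output path (.csv keeps only name,x,y,z; .json also stores
#'   the side tag and roles metadata).
#' @return the path, invisibly.
#' @export
write_landmarks <- function(ls, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(side = attr(ls, "side") %||% "right",
           roles = attr(ls, "roles"),
           landmarks = as.data.frame(ls)[, c("name", "x", "y", "z")]),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(ls)[, c("name", "x", "y", "z")], path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a micro-CT volume (NIfTI or TIFF stack)
#'
#' NIfTI spacing is taken from the header (pixdim); for TIFF the spacing
#' must be supplied. A TIFF path may be a multi-page file or a directory
#' of per-slice files ordered by name (slice order = +z).
#'
#' @param path .nii/.nii.gz file, multi-page .tif/.tiff file, or a
#'   directory of TIFF slices.
#' @param spacing_mm voxel spacing override in mm (required for TIFF).
#' @param origin world origin (default c(0,0,0)).
#' @return a \code{volume3d}.
#' @export
read_volume <- function(path, spacing_mm = NULL, origin = c(0, 0, 0)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stopf("no TIFF slices found in %s", path)
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    arr <- simplify2array(slices)
    if (is.null(spacing_mm)) stopf("spacing_mm is required for TIFF input")
    return(volume3d(arr, spacing = spacing_mm, origin = origin))
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr", "img")) {
    img <- RNifti::readNifti(path)
    spacing <- spacing_mm %||% RNifti::pixdim(img)[1]
    return(volume3d(array(as.numeric(img), dim(img)), spacing = spacing,
                    origin = origin))
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(pages)
    if (is.null(spacing_mm)) stopf("spacing_mm is required for TIFF input")
    return(volume3d(arr, spacing = spacing_mm, origin = origin))
  }
  stopf("unsupported volume format: %s", path)
}

#' Write a volume to NIfTI
#' @param volume a \code{volume3d}.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- rep(volume$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a seed label volume (0/1/2 = unlabeled/foreground/background)
#' @param path NIfTI or TIFF path as in \code{read_volume}.
#' @param spacing_mm spacing override (TIFF).
#' @return a \code{seed_image}.
#' @export
read_seeds <- function(path, spacing_mm = 1) {
  v <- read_volume(path, spacing_mm = spacing_mm)
  seed_image(array(as.integer(round(v$intensities)),
                   dim(v$intensities)))
}
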