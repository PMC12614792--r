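# Plain-text interchange formats: fingerprint CSV, ratings CSV, naming and
# assignment CSVs, similarity-matrix CSV.

#' Write a fingerprint set to CSV
#'
#' Columns `material_id,category,scale,attr01..attr16` with the attribute
#' columns in schema order.
#'
#' @param fps Fingerprint set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  fps <- validate_fingerprint_set(fps)
  readr::write_csv(fps[c("material_id", "category", "scale", fp_cols())], path)
  invisible(path)
}

#' Read a fingerprint set from CSV
#'
#' @param path CSV file written by [write_fingerprints()].
#' @return Validated fingerprint-set tibble.
#' @export
read_fingerprints <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          material_id = readr::col_character(),
                          category = readr::col_character(),
                          scale = readr::col_character(),
                          .default = readr::col_double()
                        ))
  validate_fingerprint_set(df)
}

#' Read and validate a raw ratings CSV
#'
#' Expects columns `participant_id,material_id,attribute_id,response` with
#' responses in the 0--100 slider range; rejects duplicate triples and
#' non-numeric or out-of-range responses, reporting row numbers.
#'
#' @param path CSV file.
#' @param slider_range Allowed response range (default `c(0, 100)`).
#' @return Validated ratings tibble.
#' @export
validate_ratings_file <- function(path, slider_range = c(0, 100)) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if ("response" %in% names(df)) {
    resp <- suppressWarnings(as.numeric(df$response))
    bad <- which(is.na(resp) & !is.na(df$response))
    if (length(bad) > 0) {
      rlang::abort(paste0("non-numeric responses at rows: ",
                          paste(utils::head(bad, 5), collapse = ", ")))
    }
    df$response <- resp
  }
  validate_ratings(df, slider_range = slider_range)
}

#' Read free-naming responses (`participant_id,trial,term,rank`)
#' @param path CSV file.
#' @return Tibble of naming responses.
#' @export
read_naming <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("participant_id", "trial", "term", "rank") %in% names(df)))
  df
}

#' Read cluster assignments (`response_id,rater_id,attribute_id`)
#' @param path CSV file.
#' @return Tibble of assignments.
#' @export
read_assignments <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("response_id", "rater_id", "attribute_id") %in% names(df)))
  df
}

#' Write a similarity matrix as a square CSV with id header row/column
#'
#' @param m An `fp_similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "material_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_matrix()]
#' @param path CSV file.
#' @return An `fp_similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- df$material_id
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("fp_similarity_matrix", "matrix", "array"))
}

#' Read an image pair from two raster files
#'
#' Uses EBImage to read PNG/JPEG/TIFF files; grayscale images are replicated
#' to three channels.
#'
#' @param nonspec_path,spec_path Image files.
#' @param sample_size_mm Physical side length of the depicted area.
#' @param material_id Material id (default: non-specular file stem).
#' @return A `material_image_pair`.
#' @export
read_image_pair <- function(nonspec_path, spec_path, sample_size_mm = 26,
                            material_id = NULL) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    rlang::abort("reading image files requires the EBImage package")
  }
  read_one <- function(p) {
    img <- EBImage::readImage(p)
    a <- as.array(img)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    aperm(a, c(2, 1, 3)) # EBImage stores x,y; use row = y
  }
  if (is.null(material_id)) {
    material_id <- sub("\\.[^.]+$", "", basename(nonspec_path))
  }
  material_image_pair(read_one(nonspec_path), read_one(spec_path),
                      sample_size_mm = sample_size_mm,
                      material_id = material_id)
}

#' Write an image pair to PNG files
#'
#' @param pair A `material_image_pair`.
#' @param dir Output directory.
#' @return Character vector of the two paths, invisibly.
#' @export
write_image_pair <- function(pair, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    rlang::abort("writing PNG files requires the png package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(pair$material_id, "_nonspec.png"))
  p2 <- file.path(dir, paste0(pair$material_id, "_spec.png"))
  png::writePNG(pair$frame_nonspec, p1)
  png::writePNG(pair$frame_spec, p2)
  invisible(c(p1, p2))
}
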