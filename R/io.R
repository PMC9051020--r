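## External-interface readers and writers: 8-bit grayscale PNG + JSON
## sidecar for retardation maps, CSV per boundary trace + JSON scan
## metadata for OCT, JSON cohort manifests, CSV profiles.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a retardation map as PNG plus JSON sidecar
#'
#' @param map A [retardation_map()].
#' @param path PNG path; the sidecar replaces the extension with `.json`.
#' @param center_hint Optional nominal center c(row, col) for the sidecar.
#' @return Invisibly, the PNG path.
#' @export
write_retardation_map <- function(map, path, center_hint = NULL) {
  png::writePNG(map$pixels / 255, path)
  sidecar <- list(mode = map$mode, deg_per_px = map$deg_per_px,
                  fov_deg = map$fov_deg, quality_score = map$quality_score,
                  eye = map$eye, center_hint = center_hint)
  write_json_file(sidecar, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a retardation map from PNG plus JSON sidecar
#'
#' @param path PNG path; metadata is read from the `.json` sidecar.
#' @return A [retardation_map()].
#' @export
read_retardation_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_json_file(sidecar_path(path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  pixels <- round(px * 255)
  storage.mode(pixels) <- "integer"
  retardation_map(pixels, deg_per_px = meta$deg_per_px, mode = meta$mode,
                  quality_score = meta$quality_score,
                  fov_deg = unlist(meta$fov_deg), eye = meta$eye)
}

#' Write a boundary trace CSV (`column_px,depth_px,valid`)
#'
#' @param trace A [boundary_trace()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_boundary_trace <- function(trace, path) {
  df <- data.frame(column_px = trace$columns,
                   depth_px = trace$depths,
                   valid = as.integer(trace$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a boundary trace CSV
#'
#' @param path CSV path with header `column_px,depth_px,valid`.
#' @param boundary_name Boundary label for the resulting trace.
#' @return A [boundary_trace()].
#' @export
read_boundary_trace <- function(path, boundary_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("column_px", "depth_px", "valid") %in% names(df))) {
    stop("malformed boundary trace CSV: ", path)
  }
  boundary_trace(df$column_px, df$depth_px, df$valid == 1, boundary_name)
}

read_scan <- function(scan_entry, base_dir) {
  meta <- read_json_file(file.path(base_dir, scan_entry$meta))
  list(anterior = read_boundary_trace(file.path(base_dir, scan_entry$anterior),
                                      "anterior"),
       posterior = read_boundary_trace(
         file.path(base_dir, scan_entry$posterior), "posterior"),
       os_band = read_boundary_trace(file.path(base_dir, scan_entry$os_band),
                                     "os_band"),
       meta = meta, meridian = scan_entry$meridian,
       offset_sign = scan_entry$offset_sign)
}

#' Read a cohort manifest
#'
#' @param path Manifest JSON path as written by [simulate_cohort()].
#' @return The manifest list, with `base_dir` attached.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$subjects) || is.null(m$cohort_label)) {
    stop("malformed manifest: ", path)
  }
  m$base_dir <- dirname(path)
  m
}

#' Write a per-subject profile CSV
#'
#' One row per canonical eccentricity with the subject's thickness and
#' intensity statistics
#' (`eccentricity_deg,thickness_px,ring_mean,cross_amplitude,fit_r2,mode`).
#'
#' @param df Data frame as produced by the pipeline subject stage.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_subject_profile <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
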