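## Lightweight S3 containers shared across the pipeline stages.

#' Boundary trace
#'
#' Per-column depth samples for one named layer boundary of one b-scan,
#' with a per-column validity mask encoding directional visibility.
#'
#' @param columns Strictly increasing lateral pixel indices.
#' @param depths Axial depth per column (px); must be finite where valid.
#' @param valid Logical per-column validity mask.
#' @param boundary_name One of `"anterior"`, `"posterior"`, `"os_band"`.
#' @return An object of class `boundary_trace`.
#' @export
boundary_trace <- function(columns, depths, valid, boundary_name) {
  stopifnot(length(columns) == length(depths),
            length(columns) == length(valid),
            boundary_name %in% c("anterior", "posterior", "os_band"))
  if (length(columns) > 1 && any(diff(columns) <= 0)) {
    stop("columns must be strictly increasing")
  }
  valid <- as.logical(valid)
  if (any(!is.finite(depths[valid]))) {
    stop("depths must be finite where valid")
  }
  structure(list(columns = as.numeric(columns),
                 depths = as.numeric(depths),
                 valid = valid, boundary_name = boundary_name),
            class = "boundary_trace")
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf("<boundary_trace %s: %d columns, %d valid>\n",
              x$boundary_name, length(x$columns), sum(x$valid)))
  invisible(x)
}

#' Retardation map
#'
#' En-face SLP phase-retardation image (8-bit intensities) with geometry
#' and compensation metadata.
#'
#' @param pixels Integer matrix with values in \[0, 255\].
#' @param deg_per_px Angular pixel pitch (deg).
#' @param mode `"fixed"` or `"variable"` corneal compensation.
#' @param quality_score Instrument quality score.
#' @param fov_deg Field of view c(vertical, horizontal), degrees.
#' @param center_px Optional localized macular center c(row, col).
#' @param eye Laterality flag.
#' @return An object of class `retardation_map`.
#' @export
retardation_map <- function(pixels, deg_per_px, mode, quality_score = NA,
                            fov_deg = dim(pixels) * deg_per_px,
                            center_px = NULL, eye = "OD") {
  stopifnot(is.matrix(pixels), deg_per_px > 0,
            mode %in% c("fixed", "variable"))
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]")
  }
  structure(list(pixels = pixels, deg_per_px = deg_per_px, mode = mode,
                 quality_score = quality_score, fov_deg = fov_deg,
                 center_px = center_px, eye = eye),
            class = "retardation_map")
}

#' @export
print.retardation_map <- function(x, ...) {
  cat(sprintf("<retardation_map %s: %dx%d px, %.4f deg/px, quality %s>\n",
              x$mode, nrow(x$pixels), ncol(x$pixels), x$deg_per_px,
              format(x$quality_score)))
  invisible(x)
}

#' Eccentricity profile
#'
#' A quantity (thickness or ring intensity) sampled on the canonical
#' 12-point eccentricity grid, 0.25 to 3.00 degrees.
#'
#' @param values Numeric values, one per grid point, finite.
#' @param kind `"thickness"` or `"intensity"`.
#' @param meridian Meridian label (or `"mean"` for the four-meridian
#'   average, `"all"` for azimuthal ring statistics).
#' @param grid Eccentricity grid; must equal [canonical_grid()].
#' @return An object of class `ecc_profile`.
#' @export
ecc_profile <- function(values, kind = c("thickness", "intensity"),
                        meridian = "all", grid = canonical_grid()) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(grid, canonical_grid()))) {
    stop("profiles must use the canonical 0.25-3.00 degree grid")
  }
  if (length(values) != length(grid) || any(!is.finite(values))) {
    stop("values must be finite, one per grid point")
  }
  structure(list(grid = grid, values = as.numeric(values), kind = kind,
                 meridian = meridian),
            class = "ecc_profile")
}

#' @export
print.ecc_profile <- function(x, ...) {
  cat(sprintf("<ecc_profile %s [%s]>\n", x$kind, x$meridian))
  print(stats::setNames(round(x$values, 3), format(x$grid)))
  invisible(x)
}

#' @export
as.data.frame.ecc_profile <- function(x, ...) {
  data.frame(eccentricity_deg = x$grid, value = x$values, kind = x$kind,
             meridian = x$meridian)
}

## HFL thickness versus lateral column for one meridian scan pair; signed
## eccentricity is attached once the foveal column is known.
new_thickness_profile <- function(columns, thickness_px, thickness_um,
                                  meridian, n_floored = 0L) {
  structure(list(columns = columns, thickness_px = thickness_px,
                 thickness_um = thickness_um, meridian = meridian,
                 n_floored = n_floored),
            class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("<thickness_profile %s: %d columns, %.2f px max>\n",
              x$meridian, length(x$columns), max(x$thickness_px)))
  invisible(x)
}
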